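#' Simulate a spatial panel dataset with layered cell types
#'
#' Emulates an in-situ panel experiment: cells of each type are placed in
#' horizontal layer bands and per-cell panel counts are Poisson draws from
#' the type's expected-count profile, plus a uniform Poisson background
#' ("spillover") at `noise_rate` per gene.
#'
#' @param n_cells total number of cells.
#' @param celltype_profiles numeric matrix of expected counts, genes x types
#'   (rownames = panel genes, colnames = types).
#' @param layer_layout data frame with columns `type`, `ymin`, `ymax`
#'   (micrometers, y increasing downward); each cell's type determines its
#'   band.
#' @param noise_rate expected background counts per gene per cell.
#' @param x_range horizontal extent in micrometers.
#' @param type_props optional sampling proportions over layout rows
#'   (default uniform).
#' @param seed integer seed.
#' @return a `spatial_dataset`: list with `counts` (sparse genes x cells),
#'   `cells` (cell_id, x_um, y_um, true_type, total_transcripts).
#' @export
simulate_spatial <- function(n_cells, celltype_profiles, layer_layout,
                             noise_rate = 0, x_range = c(0, 1000),
                             type_props = NULL, seed = 1L) {
  stop_if_not(nrow(celltype_profiles) > 0, "empty gene panel")
  stop_if_not(all(celltype_profiles >= 0), "profiles must be non-negative")
  stop_if_not(noise_rate >= 0, "noise_rate must be non-negative")
  stop_if_not(all(layer_layout$type %in% colnames(celltype_profiles)),
              "layer_layout types missing from celltype_profiles")
  with_seed(seed, {
    nlay <- nrow(layer_layout)
    pr <- type_props %||% rep(1 / nlay, nlay)
    lay <- sample.int(nlay, n_cells, replace = TRUE, prob = pr)
    y <- runif(n_cells, layer_layout$ymin[lay], layer_layout$ymax[lay])
    x <- runif(n_cells, x_range[1], x_range[2])
    type <- layer_layout$type[lay]
    G <- nrow(celltype_profiles)
    lambda <- celltype_profiles[, type, drop = FALSE] + noise_rate
    cnt <- matrix(rpois(G * n_cells, lambda), G, n_cells)
    counts <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                          "CsparseMatrix")
    rownames(counts) <- rownames(celltype_profiles)
    cells <- data.frame(
      cell_id = sprintf("S%06d", seq_len(n_cells)),
      x_um = x, y_um = y, true_type = type,
      total_transcripts = as.numeric(colSums(cnt)),
      stringsAsFactors = FALSE
    )
    colnames(counts) <- cells$cell_id
    structure(list(counts = counts, cells = cells),
              class = "spatial_dataset")
  })
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d panel genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
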
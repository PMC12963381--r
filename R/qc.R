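#' Filter cells on detected genes and mitochondrial content
#'
#' Retains cells with at least `min_genes` detected genes and a
#' mitochondrial fraction of at most `max_mito` (cells strictly above the
#' mitochondrial cutoff are discarded). The order of surviving cells is
#' preserved and the operation is idempotent.
#'
#' @param ds a `cohort_dataset`.
#' @param min_genes minimum number of detected genes (default 300).
#' @param max_mito maximum mitochondrial fraction (default 0.05).
#' @return the filtered `cohort_dataset`.
#' @export
filter_cells <- function(ds, min_genes = 300, max_mito = 0.05) {
  stopifnot(inherits(ds, "cohort_dataset"))
  stop_if_not(min_genes > 0 && max_mito > 0, "thresholds must be positive")
  keep <- ds$cell_meta$n_genes_detected >= min_genes &
    ds$cell_meta$mito_fraction <= max_mito
  if (!any(keep)) warning("no cells survive filtering")
  ds$counts <- ds$counts[, keep, drop = FALSE]
  ds$cell_meta <- ds$cell_meta[keep, , drop = FALSE]
  rownames(ds$cell_meta) <- NULL
  ds
}

#' Library-size log-normalize a count matrix
#'
#' Per-cell counts are scaled to the median library size (size factor =
#' library / median library) and log(1 + x)-transformed. Cells with an
#' all-zero library have an undefined size factor and are dropped with a
#' warning.
#'
#' @param ds a `cohort_dataset`, or a raw (sparse) genes x cells count
#'   matrix.
#' @return a `normalized_matrix`: list with `values` (genes x cells, log
#'   scale, sparse), `size_factors`, and the `cell_meta` of retained cells
#'   when a `cohort_dataset` was supplied.
#' @export
normalize_log <- function(ds) {
  if (inherits(ds, "cohort_dataset")) {
    counts <- ds$counts
    cell_meta <- ds$cell_meta
    donor_meta <- ds$donor_meta
  } else {
    counts <- ds
    cell_meta <- NULL
    donor_meta <- NULL
  }
  stop_if_not(ncol(counts) > 0, "empty count matrix")
  lib <- Matrix::colSums(counts)
  bad <- lib <= 0
  if (any(bad)) {
    warning(sum(bad), " all-zero cell(s) dropped during normalization")
    counts <- counts[, !bad, drop = FALSE]
    if (!is.null(cell_meta)) cell_meta <- cell_meta[!bad, , drop = FALSE]
    lib <- lib[!bad]
  }
  sf <- lib / median(lib)
  values <- counts %*% Matrix::Diagonal(x = 1 / sf)
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(counts)
  structure(list(values = methods::as(values, "CsparseMatrix"),
                 size_factors = setNames(sf, colnames(counts)),
                 cell_meta = cell_meta, donor_meta = donor_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (log scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Genes are ranked by normalized dispersion: the variance/mean ratio of the
#' back-transformed (expm1) normalized expression, z-scored within 20
#' equal-occupancy mean-expression bins. Genes whose normalized dispersion
#' exceeds `dispersion_threshold` qualify; the top `n_top` by normalized
#' dispersion are returned (ties broken lexicographically by gene id).
#'
#' @param nm a `normalized_matrix`.
#' @param n_top number of genes to return (default 3000).
#' @param dispersion_threshold minimum normalized dispersion (default 0.5).
#' @param n_bins number of equal-occupancy mean bins (default 20).
#' @return character vector of selected gene ids, ranked.
#' @export
select_hvg <- function(nm, n_top = 3000, dispersion_threshold = 0.5,
                       n_bins = 20) {
  stopifnot(inherits(nm, "normalized_matrix"))
  stop_if_not(ncol(nm$values) >= 2, "need at least 2 cells")
  x <- nm$values
  if (methods::is(x, "sparseMatrix")) x@x <- expm1(x@x) else x <- expm1(x)
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * ncol(x) / max(1, ncol(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  genes <- rownames(nm$values) %||% as.character(seq_len(nrow(nm$values)))
  ok <- mu > 0 & is.finite(disp)
  nb <- max(1, min(n_bins, sum(ok)))
  bin <- rep(NA_integer_, length(mu))
  bin[ok] <- if (nb == 1) 1L else {
    as.integer(cut(rank(mu[ok], ties.method = "first"),
                   breaks = nb, labels = FALSE))
  }
  ndisp <- rep(-Inf, length(mu))
  for (b in unique(bin[!is.na(bin)])) {
    i <- which(bin == b)
    m <- mean(disp[i]); s <- sd(disp[i])
    ndisp[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  # constant genes never qualify regardless of bin statistics
  ndisp[disp == 0] <- -Inf
  qual <- which(ndisp > dispersion_threshold)
  ord <- qual[order(-ndisp[qual], genes[qual])]
  genes[head(ord, n_top)]
}

#' Aggregate raw counts into pseudobulk profiles
#'
#' Sums raw counts within each group (by default donor x cluster) and
#' records, per gene and group, the number of nuclei with nonzero
#' expression (used by the pseudobulk DE gene filter).
#'
#' @param ds a `cohort_dataset` (raw counts).
#' @param group_by character vector of `cell_meta` columns defining groups
#'   (default `c("donor_id", "cluster")`).
#' @return a `pseudobulk_table`: list with `counts` (groups x genes integer
#'   matrix), `n_expressing` (groups x genes), `group_meta` (one row per
#'   group, including donor covariates when grouping involves `donor_id`).
#' @export
pseudobulk_aggregate <- function(ds, group_by = c("donor_id", "cluster")) {
  stopifnot(inherits(ds, "cohort_dataset"))
  key <- do.call(paste, c(ds$cell_meta[group_by], sep = "|"))
  f <- factor(key, levels = unique(key))
  # indicator matrix cells x groups; crossprod gives exact integer sums
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  pb <- Matrix::t(ds$counts %*% ind)            # groups x genes
  nex <- Matrix::t((ds$counts > 0) %*% ind)
  pb <- as.matrix(pb); storage.mode(pb) <- "integer"
  nex <- as.matrix(nex); storage.mode(nex) <- "integer"
  rownames(pb) <- rownames(nex) <- levels(f)
  colnames(pb) <- colnames(nex) <- rownames(ds$counts)
  gm <- unique(ds$cell_meta[, group_by, drop = FALSE])
  gm <- gm[match(levels(f), do.call(paste, c(gm, sep = "|"))), ,
           drop = FALSE]
  if ("donor_id" %in% group_by) {
    gm <- merge(gm, ds$donor_meta, by = "donor_id", sort = FALSE)
    gm <- gm[match(levels(f),
                   do.call(paste, c(gm[group_by], sep = "|"))), ,
             drop = FALSE]
  }
  rownames(gm) <- levels(f)
  structure(list(counts = pb, n_expressing = nex, group_meta = gm,
                 group_by = group_by),
            class = "pseudobulk_table")
}

#' @export
print.pseudobulk_table <- function(x, ...) {
  cat(sprintf("pseudobulk_table: %d groups (%s) x %d genes\n",
              nrow(x$counts), paste(x$group_by, collapse = " x "),
              ncol(x$counts)))
  invisible(x)
}
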
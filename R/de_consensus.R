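#' High-confidence consensus of differential-expression calls
#'
#' A gene is high-confidence when it is significant in the hurdle mixed
#' model AND corroborated by at least one of: bootstrap directional support
#' (same direction), pseudobulk significance (same direction), or
#' membership in a co-expression hub set (top-50 kME genes). Genes whose
#' corroborating method disagrees with the mixed model's direction are
#' excluded and logged in the `conflicts` attribute. The direction reported
#' is the mixed model's.
#'
#' @param mixed `de_result` from [fit_hurdle_mixed()].
#' @param bootstrap optional `de_result` from [bootstrap_de()].
#' @param pseudobulk optional `de_result` from [pseudobulk_de()].
#' @param hub_genes optional character vector of co-expression hub genes.
#' @return a `high_confidence_set` data frame: gene, direction, provenance
#'   flags (mixed, bootstrap, pseudobulk, coexpr_hub); attribute
#'   `conflicts` lists excluded genes.
#' @export
consensus_high_confidence <- function(mixed, bootstrap = NULL,
                                      pseudobulk = NULL,
                                      hub_genes = character(0)) {
  stopifnot(inherits(mixed, "de_result"))
  ms <- mixed[mixed$significant, , drop = FALSE]
  conflicts <- character(0)
  rows <- lapply(seq_len(nrow(ms)), function(i) {
    g <- ms$gene[i]
    dir <- ms$direction[i]
    boot_ok <- FALSE; pb_ok <- FALSE
    conflict <- FALSE
    if (!is.null(bootstrap)) {
      b <- bootstrap[bootstrap$gene == g, , drop = FALSE]
      if (nrow(b) == 1 && isTRUE(b$supported)) {
        if (b$direction == dir) boot_ok <- TRUE else conflict <- TRUE
      }
    }
    if (!is.null(pseudobulk)) {
      pbr <- pseudobulk[pseudobulk$gene == g, , drop = FALSE]
      if (nrow(pbr) == 1 && isTRUE(pbr$significant)) {
        if (identical(pbr$direction, dir)) pb_ok <- TRUE
        else conflict <- TRUE
      }
    }
    hub_ok <- g %in% hub_genes
    if (conflict) {
      conflicts <<- c(conflicts, g)
      return(NULL)
    }
    if (!(boot_ok || pb_ok || hub_ok)) return(NULL)
    data.frame(gene = g, direction = dir, mixed = TRUE,
               bootstrap = boot_ok, pseudobulk = pb_ok,
               coexpr_hub = hub_ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), direction = character(0),
                      mixed = logical(0), bootstrap = logical(0),
                      pseudobulk = logical(0), coexpr_hub = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  attr(out, "contrast") <- attr(mixed, "contrast")
  attr(out, "cluster") <- attr(mixed, "cluster")
  class(out) <- c("high_confidence_set", "data.frame")
  out
}

#' Intersect high-confidence sets across conditions
#'
#' Exact set algebra over two or more gene sets (for example region x
#' stage combinations): an UpSet-style membership matrix, the genes shared
#' by all sets, and pairwise overlap counts.
#'
#' @param hc_sets named list of character vectors or `high_confidence_set`
#'   data frames.
#' @return list with `membership` (genes x sets logical matrix),
#'   `shared_all` (character), and `pairwise` (sets x sets overlap counts).
#' @export
intersect_conditions <- function(hc_sets) {
  stop_if_not(length(hc_sets) >= 2, "need at least 2 sets")
  sets <- lapply(hc_sets, function(s) {
    if (is.data.frame(s)) unique(s$gene) else unique(as.character(s))
  })
  genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes) == 1) {
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(NULL, names(sets)))
  }
  rownames(membership) <- genes
  pairwise <- outer(seq_along(sets), seq_along(sets),
                    Vectorize(function(i, j)
                      length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pairwise) <- list(names(sets), names(sets))
  list(membership = membership,
       shared_all = genes[rowSums(membership) == length(sets)],
       pairwise = pairwise)
}
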
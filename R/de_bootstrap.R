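#' Bootstrap directional-support retention rule
#'
#' A gene is retained when its best direction reaches at least
#' `min_support` significant iterations and the opposite direction was
#' never significant (a single opposite-direction call disqualifies,
#' reading "consistent identification" conservatively).
#'
#' @param support_up,support_down per-gene counts of iterations calling
#'   the gene significantly up / down.
#' @param min_support required directional support (default 20).
#' @return list with `support` (max directional count), `direction`, and
#'   `supported` (logical).
#' @export
bootstrap_decision <- function(support_up, support_down,
                               min_support = 20) {
  support <- pmax(support_up, support_down)
  direction <- ifelse(support_up >= support_down, "up", "down")
  supported <- support >= min_support &
    ifelse(direction == "up", support_down, support_up) == 0
  list(support = support, direction = direction, supported = supported)
}

#' Half-sample bootstrap consensus differential expression
#'
#' Repeatedly draws, without replacement, a fraction of the cells of each
#' condition (stratified half-samples by default), reruns the hurdle mixed
#' test on the subsample, and counts per gene how many iterations call it
#' significantly up- or downregulated. A gene is supported when one
#' direction reaches `min_support` iterations and the opposite direction is
#' never significant (any opposite-direction call disqualifies). Subsampling
#' draws from condition-wise sorted cell ids, so results are bit-for-bit
#' reproducible under a fixed seed and invariant to the input cell order.
#'
#' @param nm a `normalized_matrix` built from a `cohort_dataset`.
#' @param contrast a [de_contrast()].
#' @param cluster cluster label to test.
#' @param n_iter number of iterations (default 100).
#' @param frac fraction of cells per condition per iteration (default 0.5).
#' @param min_support directional support required (default 20).
#' @param seed integer seed.
#' @return a `de_result` data frame: gene, support_up, support_down,
#'   support, direction, supported, n_failed; attribute
#'   `method = "bootstrap"`.
#' @export
bootstrap_de <- function(nm, contrast, cluster = NULL, n_iter = 100,
                         frac = 0.5, min_support = 20, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(contrast, "de_contrast"))
  cm <- nm$cell_meta
  dm <- nm$donor_meta
  grp <- dm$pathology_group[match(cm$donor_id, dm$donor_id)]
  sel <- grp %in% c(contrast$baseline, contrast$comparison)
  if (!is.null(cluster)) sel <- sel & cm$cluster == cluster
  stop_if_not(sum(sel) >= 40, "cluster needs at least 40 cells")
  ids_base <- sort(cm$cell_id[sel & grp == contrast$baseline])
  ids_comp <- sort(cm$cell_id[sel & grp == contrast$comparison])

  genes <- rownames(nm$values) %||%
    as.character(seq_len(nrow(nm$values)))
  sup_up <- setNames(integer(length(genes)), genes)
  sup_dn <- sup_up
  n_failed <- 0L
  for (it in seq_len(n_iter)) {
    take <- with_seed(sub_seed(seed, 13L, it), {
      c(sample(ids_base, floor(frac * length(ids_base))),
        sample(ids_comp, floor(frac * length(ids_comp))))
    })
    sub <- nm
    keep <- match(take, cm$cell_id)
    sub$values <- nm$values[, colnames(nm$values) %in% take, drop = FALSE]
    sub$cell_meta <- cm[cm$cell_id %in% take, , drop = FALSE]
    res <- tryCatch(
      fit_hurdle_mixed(sub, contrast, cluster = cluster),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    up <- res$gene[res$significant & res$direction == "up"]
    dn <- res$gene[res$significant & res$direction == "down"]
    sup_up[up] <- sup_up[up] + 1L
    sup_dn[dn] <- sup_dn[dn] + 1L
  }
  flagged <- n_failed > 0.2 * n_iter
  if (flagged) warning("more than 20% of bootstrap iterations failed")
  dec <- bootstrap_decision(sup_up, sup_dn, min_support)
  support <- dec$support
  direction <- dec$direction
  supported <- dec$supported
  out <- data.frame(gene = genes, support_up = as.integer(sup_up),
                    support_down = as.integer(sup_dn),
                    support = as.integer(support),
                    direction = direction, supported = supported,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "bootstrap"
  attr(out, "n_iter") <- n_iter
  attr(out, "n_failed") <- n_failed
  attr(out, "flagged") <- flagged
  attr(out, "contrast") <- contrast$name
  attr(out, "cluster") <- cluster
  class(out) <- c("de_result", "data.frame")
  out
}
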
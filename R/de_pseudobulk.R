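#' Median-of-ratios size factors for pseudobulk libraries
#' @keywords internal
#' @noRd
median_ratio_sf <- function(counts) {
  # counts: samples x genes
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  gmean <- colMeans(lg)
  usable <- is.finite(gmean)
  if (sum(usable) >= 2) {
    sf <- apply(counts[, usable, drop = FALSE], 1, function(r) {
      exp(median(log(r) - gmean[usable], na.rm = TRUE))
    })
    if (all(is.finite(sf) & sf > 0)) return(sf / exp(mean(log(sf))))
  }
  lib <- rowSums(counts)
  lib / exp(mean(log(lib)))
}

#' Profile-likelihood NB Wald test for one gene
#' @keywords internal
#' @noRd
nb_wald_gene <- function(y, X, offs) {
  fit_theta <- function(lt) {
    fam <- MASS::negative.binomial(theta = exp(lt))
    f <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, offset = offs)),
      error = function(e) NULL
    )
    if (is.null(f) || !f$converged) return(list(ll = -Inf, fit = NULL))
    mu <- f$fitted.values
    ll <- sum(stats::dnbinom(y, size = exp(lt), mu = mu, log = TRUE))
    list(ll = ll, fit = f)
  }
  op <- tryCatch(
    optimize(function(lt) fit_theta(lt)$ll, interval = c(-5, 12),
             maximum = TRUE),
    error = function(e) NULL
  )
  if (is.null(op)) return(NULL)
  list(log_theta = op$maximum, ll = op$objective)
}

nb_wald_at_theta <- function(y, X, offs, theta) {
  fam <- MASS::negative.binomial(theta = theta)
  f <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam, offset = offs)),
    error = function(e) NULL
  )
  if (is.null(f)) return(NULL)
  mu <- pmax(f$fitted.values, 1e-10)
  w <- mu / (1 + mu / theta)
  A <- crossprod(X, w * X)
  V <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  co <- f$coefficients
  list(coef = co, se = sqrt(diag(V)), mu = mu)
}

#' Pseudobulk negative-binomial differential expression
#'
#' Tests donor-level summed counts for one cluster and contrast with a
#' negative-binomial generalized linear model (log link) on condition, with
#' median-of-ratios size-factor offsets. Genes expressed in fewer than
#' `min_nuclei` nuclei are dropped before testing. Gene-wise dispersion is
#' estimated by profile maximum likelihood; when 4 or fewer donors per
#' group are available, log-dispersions are moderated halfway toward a
#' log-mean trend fitted across genes. The condition coefficient is tested
#' by a Wald z; BH across retained genes.
#'
#' @param pb a `pseudobulk_table` from [pseudobulk_aggregate()] grouped by
#'   donor and cluster.
#' @param contrast a [de_contrast()].
#' @param cluster cluster label to test (or `NULL` if the table has a
#'   single group level).
#' @param min_nuclei minimum expressing nuclei per gene (default 20).
#' @return a `de_result` data frame: gene, logFC (log2), p, padj,
#'   direction, significant; attribute `method = "pseudobulk"`.
#' @export
pseudobulk_de <- function(pb, contrast, cluster = NULL, min_nuclei = 20) {
  stopifnot(inherits(pb, "pseudobulk_table"),
            inherits(contrast, "de_contrast"))
  gm <- pb$group_meta
  sel <- gm$pathology_group %in% c(contrast$baseline, contrast$comparison)
  if (!is.null(cluster)) sel <- sel & gm$cluster == cluster
  stop_if_not(sum(sel) >= 4, "need at least 2 donors per condition")
  cnt <- pb$counts[sel, , drop = FALSE]
  nex <- pb$n_expressing[sel, , drop = FALSE]
  cond <- as.integer(gm$pathology_group[sel] == contrast$comparison)
  stop_if_not(sum(cond == 0) >= 2 && sum(cond == 1) >= 2,
              "need at least 2 donors per condition")

  keep_genes <- colSums(nex) >= min_nuclei
  cnt <- cnt[, keep_genes, drop = FALSE]
  if (ncol(cnt) == 0) {
    out <- data.frame(gene = character(0), logFC = numeric(0),
                      p = numeric(0), padj = numeric(0),
                      direction = character(0), significant = logical(0))
    attr(out, "method") <- "pseudobulk"
    class(out) <- c("de_result", "data.frame")
    return(out)
  }
  sf <- median_ratio_sf(cnt)
  offs <- log(sf)
  X <- cbind(1, cond)
  moderate <- min(sum(cond == 0), sum(cond == 1)) <= 4

  genes <- colnames(cnt)
  lt <- rep(NA_real_, length(genes))
  mean_norm <- colMeans(sweep(cnt, 1, sf, "/"))
  for (g in seq_along(genes)) {
    r <- nb_wald_gene(cnt[, g], X, offs)
    lt[g] <- if (is.null(r)) NA_real_ else r$log_theta
  }
  if (moderate) {
    ok <- is.finite(lt) & mean_norm > 0
    if (sum(ok) >= 10) {
      tr <- stats::lm(lt[ok] ~ log(mean_norm[ok]))
      lt[ok] <- 0.5 * lt[ok] +
        0.5 * as.numeric(stats::predict(tr))
    }
  }
  est <- se <- rep(NA_real_, length(genes))
  for (g in seq_along(genes)) {
    th <- if (is.finite(lt[g])) exp(lt[g]) else 100
    r <- nb_wald_at_theta(cnt[, g], X, offs, th)
    if (!is.null(r) && all(is.finite(c(r$coef[2], r$se[2])))) {
      est[g] <- r$coef[2]
      se[g] <- r$se[2]
    }
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(gene = genes, logFC = est / log(2), p = p,
                    padj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(is.na(out$logFC), NA_character_,
                          ifelse(out$logFC >= 0, "up", "down"))
  out$significant <- !is.na(out$padj) & out$padj < 0.05
  attr(out, "method") <- "pseudobulk"
  attr(out, "contrast") <- contrast$name
  attr(out, "cluster") <- cluster
  class(out) <- c("de_result", "data.frame")
  out
}
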
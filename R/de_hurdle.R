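#' Define a disease-stage contrast
#'
#' `"early"` compares the intermediate against the low pathology group;
#' `"late"` compares high against intermediate.
#'
#' @param name `"early"` or `"late"`, or `"custom"` with explicit groups.
#' @param baseline,comparison group labels (only for `name = "custom"`).
#' @return a `de_contrast` list: name, baseline, comparison.
#' @export
de_contrast <- function(name = c("early", "late", "custom"),
                        baseline = NULL, comparison = NULL) {
  name <- match.arg(name)
  if (name == "early") {
    baseline <- "low"; comparison <- "intermediate"
  } else if (name == "late") {
    baseline <- "intermediate"; comparison <- "high"
  } else {
    stop_if_not(!is.null(baseline) && !is.null(comparison),
                "custom contrast needs baseline and comparison")
  }
  structure(list(name = name, baseline = baseline,
                 comparison = comparison), class = "de_contrast")
}

#' Per-cell design matrix for the hurdle model
#' @keywords internal
#' @noRd
hurdle_design <- function(cm, dm, comparison) {
  d <- merge(cm, dm, by = "donor_id", sort = FALSE)
  d <- d[match(cm$cell_id, d$cell_id), , drop = FALSE]
  std <- function(x) {
    x <- as.numeric(x)
    if (sd(x) == 0) return(rep(0, length(x)))
    as.numeric(scale(x))
  }
  df <- data.frame(
    condition = as.integer(d$pathology_group == comparison),
    cngeneson = std(d$n_genes_detected),
    age = std(d$age),
    rin = std(d$rin),
    total_counts = std(d$total_counts)
  )
  for (v in c("assay", "sex")) {
    if (length(unique(d[[v]])) > 1) {
      mm <- stats::model.matrix(~x, data.frame(x = factor(d[[v]])))
      df <- cbind(df, mm[, -1, drop = FALSE])
    }
  }
  keep <- vapply(df, function(x) sd(x) > 0, logical(1))
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, keep, drop = FALSE]))
  list(X = X, donor = factor(d$donor_id))
}

#' Ridge-penalized logistic Wald z for the condition coefficient
#' @keywords internal
#' @noRd
pen_logistic_wald <- function(M, z, pen_diag, cond_idx) {
  b <- rep(0, ncol(M))
  pbar <- mean(z)
  b[1] <- qlogis(min(max(pbar, 1e-6), 1 - 1e-6))
  A <- NULL
  for (it in seq_len(12)) {
    eta <- drop(M %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    u <- eta + (z - mu) / w
    A <- crossprod(M, w * M)
    diag(A) <- diag(A) + pen_diag
    bn <- tryCatch(solve(A, crossprod(M, w * u)),
                   error = function(e) NULL)
    if (is.null(bn)) return(list(z = NA_real_, coef = NA_real_,
                                 separated = TRUE))
    delta <- max(abs(bn - b))
    b <- drop(bn)
    if (delta < 1e-6) break
  }
  if (abs(b[cond_idx]) > 15) {
    return(list(z = NA_real_, coef = b[cond_idx], separated = TRUE))
  }
  V <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(V)) return(list(z = NA_real_, coef = b[cond_idx],
                              separated = TRUE))
  list(z = b[cond_idx] / sqrt(V[cond_idx, cond_idx]), coef = b[cond_idx],
       separated = FALSE)
}

#' Ridge-penalized linear Wald z for the condition coefficient
#' @keywords internal
#' @noRd
pen_linear_wald <- function(M, y, pen_diag, cond_idx, p_fixed) {
  A <- crossprod(M)
  diag(A) <- diag(A) + pen_diag
  b <- tryCatch(solve(A, crossprod(M, y)), error = function(e) NULL)
  if (is.null(b)) return(list(z = NA_real_, coef = NA_real_))
  b <- drop(b)
  rss <- sum((y - drop(M %*% b))^2)
  s2 <- rss / max(1, length(y) - p_fixed)
  V <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(V)) return(list(z = NA_real_, coef = b[cond_idx]))
  list(z = b[cond_idx] / sqrt(s2 * V[cond_idx, cond_idx]),
       coef = b[cond_idx])
}

#' Hurdle mixed-model differential expression for one cluster
#'
#' Two-part ("hurdle") test per gene: a logistic model of detection
#' (expressed yes/no) and a linear model of log expression among expressing
#' cells, both on condition plus cell- and donor-level covariates
#' (standardized gene detection rate, assay, age, sex, RIN, total counts).
#' Donor-level correlation is absorbed by a ridge-penalized donor intercept
#' (penalized quasi-likelihood flavour) whose shrinkage is set per gene
#' from a moment estimate of the donor variance; with 4 or fewer donors
#' the donor term is dropped (a donor-level condition is collinear with
#' donor fixed effects) and the fallback recorded per gene. The gene-level
#' p-value combines the two parts' Wald chi-squares on 2 (or fewer)
#' degrees of freedom; BH across genes; significance additionally requires
#' expression in more than 20% of cells in at least one condition and
#' |log2FC| > 0.1.
#'
#' @param nm a `normalized_matrix` built from a `cohort_dataset`.
#' @param contrast a [de_contrast()].
#' @param cluster cluster label to test (or `NULL` to use all cells).
#' @param pct_min,logfc_min,fdr_max published significance filters.
#' @return a `de_result` data frame: gene, logFC (log2), p, padj, pct_base,
#'   pct_comp, direction, significant, note; attribute `method = "mixed"`.
#' @export
fit_hurdle_mixed <- function(nm, contrast, cluster = NULL,
                             pct_min = 0.2, logfc_min = 0.1,
                             fdr_max = 0.05) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(contrast, "de_contrast"))
  stop_if_not(!is.null(nm$cell_meta) && !is.null(nm$donor_meta),
              "nm must carry cell and donor metadata")
  cm <- nm$cell_meta
  dm <- nm$donor_meta
  sel <- dm$pathology_group[match(cm$donor_id, dm$donor_id)] %in%
    c(contrast$baseline, contrast$comparison)
  if (!is.null(cluster)) sel <- sel & cm$cluster == cluster
  stop_if_not(sum(sel) >= 20, "need at least 20 cells in the contrast")
  cm <- cm[sel, , drop = FALSE]
  vals <- as.matrix(nm$values[, sel, drop = FALSE])
  grp <- dm$pathology_group[match(cm$donor_id, dm$donor_id)]
  don_per_grp <- table(unique(data.frame(cm$donor_id, grp))$grp)
  stop_if_not(all(don_per_grp[c(contrast$baseline,
                                contrast$comparison)] >= 2),
              "need at least 2 donors per condition")

  des <- hurdle_design(cm, dm, contrast$comparison)
  X <- des$X
  donor <- droplevels(des$donor)
  D <- nlevels(donor)
  use_donor <- D > 4
  Z <- if (use_donor) {
    stats::model.matrix(~ 0 + donor)
  } else NULL
  M <- if (use_donor) cbind(X, Z) else X
  p_fixed <- ncol(X)
  cond_idx <- match("condition", colnames(X))
  n <- nrow(X)
  nd <- as.integer(table(donor))
  cond <- X[, "condition"]

  genes <- rownames(vals) %||% as.character(seq_len(nrow(vals)))
  out <- data.frame(gene = genes, logFC = NA_real_, p = NA_real_,
                    pct_base = NA_real_, pct_comp = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  base_cells <- cond == 0

  # precomputed per-donor structures shared across genes
  donor_int <- as.integer(donor)
  gd <- as.numeric(rowsum(cond, donor_int) / nd)   # donor-level condition
  grp_mask <- lapply(sort(unique(gd)), function(v) gd == v)
  ex_mat <- vals > 0
  det_per_donor <- t(rowsum(t(ex_mat + 0), donor_int))  # genes x donors
  pct_b <- rowMeans(ex_mat[, base_cells, drop = FALSE])
  pct_c <- rowMeans(ex_mat[, !base_cells, drop = FALSE])

  for (g in seq_len(nrow(vals))) {
    y <- vals[g, ]
    ex <- ex_mat[g, ]
    out$pct_base[g] <- pct_b[g]
    out$pct_comp[g] <- pct_c[g]
    stat <- 0; df <- 0
    sep <- FALSE
    coef_c <- NA_real_

    # detection part (needs variation in the indicator)
    if (any(ex) && !all(ex)) {
      lam_b <- if (use_donor) {
        pd <- (det_per_donor[g, ] + 0.5) / (nd + 1)
        ld <- qlogis(pd)
        # donor variance from within-condition spread (condition is a
        # donor-level covariate, so raw variance would include the effect)
        res <- ld
        for (mk in grp_mask) res[mk] <- ld[mk] - mean(ld[mk])
        sv <- mean(1 / (nd * pd * (1 - pd)))
        sd2 <- max(sum(res^2) / max(1, length(ld) - 2) - sv, 1e-6)
        1 / sd2
      } else 0
      pen <- c(rep(0, p_fixed), rep(lam_b, ncol(M) - p_fixed))
      r <- pen_logistic_wald(M, as.numeric(ex), pen, cond_idx)
      if (r$separated || !is.finite(r$z)) {
        sep <- TRUE
      } else {
        stat <- stat + r$z^2; df <- df + 1
      }
    }

    # continuous part among expressing cells
    exi <- which(ex)
    if (length(exi) >= p_fixed + 2 &&
        sum(cond[exi] == 0) >= 2 && sum(cond[exi] == 1) >= 2) {
      ys <- y[exi]
      Ms <- M[exi, , drop = FALSE]
      lam_c <- if (use_donor) {
        r0 <- ys - drop(X[exi, , drop = FALSE] %*%
                          qr.coef(qr(X[exi, , drop = FALSE]), ys))
        r0[is.na(r0)] <- 0
        di <- donor_int[exi]
        md <- as.numeric(rowsum(r0, di))
        ndl <- as.numeric(rowsum(rep(1, length(di)), di))
        md <- md / ndl
        se2 <- max(var(r0), 1e-8)
        sd2 <- max(var(md) - se2 * mean(1 / ndl), 1e-6)
        min(se2 / sd2, 1e8)
      } else 0
      pen <- c(rep(0, p_fixed), rep(lam_c, ncol(M) - p_fixed))
      rc <- pen_linear_wald(Ms, ys, pen, cond_idx, p_fixed)
      if (is.finite(rc$z)) {
        stat <- stat + rc$z^2; df <- df + 1
        coef_c <- rc$coef
      }
    }

    out$logFC[g] <- if (is.finite(coef_c)) coef_c / log(2) else NA_real_
    out$p[g] <- if (sep) NA_real_
      else if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
    out$note[g] <- paste0(if (use_donor) "pql" else "no_donor_fallback",
                          if (sep) ";separated" else "")
  }
  out$padj <- bh_adjust(out$p)
  out$direction <- ifelse(is.na(out$logFC), NA_character_,
                          ifelse(out$logFC >= 0, "up", "down"))
  out$significant <- !is.na(out$padj) & out$padj < fdr_max &
    !is.na(out$logFC) & abs(out$logFC) > logfc_min &
    (out$pct_base > pct_min | out$pct_comp > pct_min)
  out <- out[, c("gene", "logFC", "p", "padj", "pct_base", "pct_comp",
                 "direction", "significant", "note")]
  attr(out, "method") <- "mixed"
  attr(out, "contrast") <- contrast$name
  attr(out, "cluster") <- cluster
  class(out) <- c("de_result", "data.frame")
  out
}
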
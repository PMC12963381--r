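#' Select a stable reference cell type automatically
#'
#' Among cell types observed (nonzero) in at least `min_presence` of donors,
#' returns the type with the smallest dispersion of its relative abundance
#' (variance of the per-donor proportion divided by its mean), ties broken
#' lexicographically. If no type meets the presence rule, the most prevalent
#' type is used with a warning.
#'
#' @param ct a `composition_table`.
#' @param min_presence required fraction of donors in which the type is
#'   nonzero (default 0.9).
#' @return the reference cell-type id (character).
#' @export
select_reference <- function(ct, min_presence = 0.9) {
  stopifnot(inherits(ct, "composition_table"))
  stop_if_not(ncol(ct$counts) >= 2, "need at least 2 cell types")
  props <- ct$counts / rowSums(ct$counts)
  presence <- colMeans(ct$counts > 0)
  elig <- presence >= min_presence
  if (!any(elig)) {
    warning("no cell type present in >= ", min_presence * 100,
            "% of donors; falling back to the most prevalent type")
    return(colnames(ct$counts)[which.max(colMeans(props))])
  }
  disp <- apply(props, 2, var) / colMeans(props)
  cand <- colnames(ct$counts)[elig]
  cand[order(disp[elig], cand)][1]
}

#' Split-chain Gelman-Rubin R-hat
#' @keywords internal
#' @noRd
split_rhat <- function(draws_by_chain) {
  halves <- do.call(cbind, lapply(draws_by_chain, function(x) {
    n <- floor(length(x) / 2)
    cbind(x[seq_len(n)], x[n + seq_len(n)])
  }))
  m <- ncol(halves); n <- nrow(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2, var))
  B <- n * var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Bayesian Dirichlet-multinomial compositional regression
#'
#' Models donor-level cell-type counts as Dirichlet-multinomial with
#' `alpha_dk = s * softmax_k(b0_k + x_d' beta_k)`, the reference type's
#' coefficients fixed at zero. In the default (unconstrained) mode every
#' non-reference coefficient carries a spike-and-slab prior and its
#' posterior inclusion probability (PIP) is reported. In constrained mode
#' (`constrain_nonpositive = TRUE`) coefficients are restricted to be
#' non-positive (half-normal prior on the loss side), so only relative
#' depletions can be inferred; credibility is then assessed by the 95%
#' credible interval excluding zero, since a point-mass spike is
#' incompatible with half-line support. Effects are reported as
#' log2 fold changes (`beta / ln 2`).
#'
#' Sampling is Metropolis-within-Gibbs with a birth/death move for the
#' inclusion indicators; chains are run sequentially with seeds derived
#' from `mcmc$seed`, so the fit is deterministic for a fixed seed and chain
#' count. Convergence is monitored by split R-hat (threshold 1.05) on the
#' intercepts and precision; results are flagged, never silently dropped.
#'
#' @param ct a `composition_table` (counts + donor design).
#' @param reference reference cell type id, or `"auto"`/`NULL` for
#'   [select_reference()].
#' @param constrain_nonpositive fit the loss-only (beta <= 0) variant.
#' @param mcmc list with `chains`, `warmup`, `samples`, `seed`.
#' @param slab_sd slab SD of the spike-and-slab prior (log scale).
#' @param pi_incl prior inclusion probability of the slab.
#' @param hn_scale half-normal scale of the constrained prior.
#' @param covariates character vector of design columns to model (default
#'   pathology group, sex, APOE, assay and standardized age).
#' @return a `composition_posterior`: list with `pip` (covariate x type),
#'   `log2fc` (posterior means), `beta_draws` (draws x parameters),
#'   `reference`, `mode`, `diagnostics` (R-hat, acceptance), `types`,
#'   `covariate_names`.
#' @export
fit_dirichlet_multinomial <- function(ct, reference = "auto",
                                      constrain_nonpositive = FALSE,
                                      mcmc = list(chains = 4,
                                                  warmup = 1000,
                                                  samples = 1000,
                                                  seed = 1L),
                                      slab_sd = 1.0, pi_incl = 0.2,
                                      hn_scale = 1.0,
                                      covariates = NULL) {
  stopifnot(inherits(ct, "composition_table"))
  Y <- ct$counts
  types <- colnames(Y)
  if (is.null(reference) || identical(reference, "auto")) {
    reference <- select_reference(ct)
  }
  stop_if_not(reference %in% types, "reference not among cell types")
  X <- composition_design(ct$design, covariates)
  ref0 <- match(reference, types) - 1L

  chains <- mcmc$chains %||% 4L
  warmup <- mcmc$warmup %||% 1000L
  samples <- mcmc$samples %||% 1000L
  seed <- mcmc$seed %||% 1L

  fits <- lapply(seq_len(chains), function(ch) {
    with_seed(sub_seed(seed, 77L, ch), {
      dm_chain(Y, X, ref0, constrain_nonpositive, as.integer(warmup),
               as.integer(samples), slab_sd, pi_incl, hn_scale,
               5.0, log(50), 1.5)
    })
  })

  P <- ncol(X); K <- length(types)
  par_names <- as.vector(outer(colnames(X), types,
                               function(a, b) paste(b, a, sep = ":")))
  beta_draws <- do.call(rbind, lapply(fits, `[[`, "beta"))
  colnames(beta_draws) <- par_names
  gamma_all <- do.call(rbind, lapply(fits, `[[`, "gamma"))

  pip <- matrix(colMeans(gamma_all), P, K,
                dimnames = list(colnames(X), types))
  bmean <- matrix(colMeans(beta_draws), P, K,
                  dimnames = list(colnames(X), types))
  log2fc <- bmean / log(2)

  # constrained-mode credibility: 95% CI excluding 0
  ci_hi <- matrix(apply(beta_draws, 2, quantile, probs = 0.975), P, K,
                  dimnames = list(colnames(X), types))
  ci_lo <- matrix(apply(beta_draws, 2, quantile, probs = 0.025), P, K,
                  dimnames = list(colnames(X), types))

  rhat <- c(
    vapply(seq_len(K), function(k) {
      split_rhat(lapply(fits, function(f) f$b0[, k]))
    }, numeric(1)),
    s = split_rhat(lapply(fits, function(f) f$s))
  )
  names(rhat)[seq_len(K)] <- paste0("b0:", types)
  rhat <- rhat[names(rhat) != paste0("b0:", reference)]
  converged <- all(is.na(rhat) | rhat < 1.05)
  if (!converged) warning("split R-hat > 1.05; results flagged")

  structure(list(
    pip = pip, log2fc = log2fc, beta_mean = bmean,
    ci_lower = ci_lo, ci_upper = ci_hi,
    beta_draws = beta_draws,
    reference = reference, types = types,
    covariate_names = colnames(X),
    mode = if (constrain_nonpositive) "constrained" else "spike_slab",
    diagnostics = list(
      rhat = rhat, converged = converged,
      accept_rate = mean(vapply(fits, `[[`, numeric(1), "accept_rate")),
      chains = chains, warmup = warmup, samples = samples, seed = seed
    )
  ), class = "composition_posterior")
}

#' Build the donor-level design matrix for compositional models
#' @keywords internal
#' @noRd
composition_design <- function(design, covariates = NULL) {
  d <- design
  d$age_std <- as.numeric(scale(d$age))
  if (sd(d$age) == 0) d$age_std <- 0
  covariates <- covariates %||%
    intersect(c("pathology_group", "sex", "apoe", "assay", "age_std"),
              names(d))
  # drop covariates without variation (model.matrix would fail)
  keep <- vapply(covariates, function(v) length(unique(d[[v]])) > 1,
                 logical(1))
  covariates <- covariates[keep]
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow(d), 0))
  }
  fml <- stats::reformulate(covariates)
  X <- stats::model.matrix(fml, data = d)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

#' @export
print.composition_posterior <- function(x, ...) {
  cat(sprintf("composition_posterior (%s): %d types, reference %s\n",
              x$mode, length(x$types), x$reference))
  cat(sprintf("  %d covariate columns; converged: %s\n",
              length(x$covariate_names), x$diagnostics$converged))
  invisible(x)
}

#' Extract credible compositional effects
#'
#' Returns effects passing both the credibility rule and the magnitude
#' rule: posterior inclusion probability strictly above `pip_min` (spike-
#' and-slab mode) or a 95% credible interval excluding zero (constrained
#' mode), and absolute posterior-mean log2 fold change strictly above
#' `min_abs_log2fc`. The reference type is never returned.
#'
#' @param post a `composition_posterior`.
#' @param pip_min PIP threshold (default 0.95).
#' @param min_abs_log2fc magnitude threshold on |log2FC| (default 0.1).
#' @param covariates restrict to these covariate columns (default: the
#'   pathology-group contrasts).
#' @return data frame: type, covariate, pip, log2FC, credible.
#' @export
credible_effects <- function(post, pip_min = 0.95, min_abs_log2fc = 0.1,
                             covariates = NULL) {
  stopifnot(inherits(post, "composition_posterior"))
  covariates <- covariates %||%
    grep("^pathology_group", post$covariate_names, value = TRUE)
  covariates <- intersect(covariates, post$covariate_names)
  rows <- expand.grid(covariate = covariates, type = post$types,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$type != post$reference, , drop = FALSE]
  idx <- cbind(match(rows$covariate, post$covariate_names),
               match(rows$type, post$types))
  rows$pip <- post$pip[idx]
  rows$log2FC <- post$log2fc[idx]
  cred <- if (post$mode == "constrained") {
    post$ci_upper[idx] < 0
  } else {
    rows$pip > pip_min
  }
  rows$credible <- cred & abs(rows$log2FC) > min_abs_log2fc
  out <- rows[rows$credible, c("type", "covariate", "pip", "log2FC",
                               "credible")]
  rownames(out) <- NULL
  out
}

#' Beta regression of per-donor cell-type proportions
#'
#' An independent frequentist check on compositional shifts: per cell type,
#' the per-donor proportion (shrunk away from 0 and 1 by
#' `(y (n - 1) + 0.5) / n`) is modeled with a beta distribution and logit
#' link on pathology group plus donor covariates. Types observed (nonzero)
#' in fewer than `min_donors` donors are excluded and reported as such.
#' With one observation per donor and type, a donor random intercept is
#' unidentifiable, so the model uses fixed effects only. P-values are
#' BH-adjusted across tested types.
#'
#' @param ct a `composition_table`.
#' @param contrast pathology-group level to report against the `low`
#'   reference (default `"high"`).
#' @param min_donors minimum number of donors with nonzero counts
#'   (default 3).
#' @return data frame: type, estimate (logit scale), se, z, p, padj,
#'   n_donors, status (`"ok"`, `"excluded"`, `"nonconverged"`).
#' @export
fit_beta_regression <- function(ct, contrast = "high", min_donors = 3) {
  stopifnot(inherits(ct, "composition_table"))
  tot <- rowSums(ct$counts)
  stop_if_not(all(tot > 0), "each donor needs a positive cell total")
  d <- ct$design
  d$age_std <- as.numeric(scale(d$age))
  if (sd(d$age) == 0) d$age_std <- 0
  covs <- c("pathology_group",
            intersect(c("sex", "apoe", "assay", "age_std"), names(d)))
  covs <- covs[vapply(covs, function(v) length(unique(d[[v]])) > 1,
                      logical(1))]
  if (!"pathology_group" %in% covs) {
    stop("pathology_group has no variation; nothing to test",
         call. = FALSE)
  }
  fml <- stats::reformulate(covs, response = "prop")
  coef_name <- paste0("pathology_group", contrast)
  n <- length(tot)
  res <- lapply(colnames(ct$counts), function(ty) {
    nz <- sum(ct$counts[, ty] > 0)
    if (nz < min_donors) {
      return(data.frame(type = ty, estimate = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, n_donors = nz,
                        status = "excluded", stringsAsFactors = FALSE))
    }
    y <- ct$counts[, ty] / tot
    dd <- d
    dd$prop <- (y * (n - 1) + 0.5) / n
    fit <- tryCatch(
      glmmTMB::glmmTMB(fml, data = dd, family = glmmTMB::beta_family()),
      error = function(e) NULL, warning = function(w) NULL
    )
    co <- if (!is.null(fit)) {
      tryCatch(summary(fit)$coefficients$cond, error = function(e) NULL)
    } else NULL
    if (is.null(co) || !coef_name %in% rownames(co) ||
        !all(is.finite(co[coef_name, 1:2]))) {
      return(data.frame(type = ty, estimate = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, n_donors = nz,
                        status = "nonconverged", stringsAsFactors = FALSE))
    }
    data.frame(type = ty, estimate = co[coef_name, "Estimate"],
               se = co[coef_name, "Std. Error"],
               z = co[coef_name, "z value"],
               p = co[coef_name, "Pr(>|z|)"],
               n_donors = nz, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- NA_real_
  ok <- out$status == "ok"
  out$padj[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out
}
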
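#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a hierarchical sub-seed from a top-level seed
#'
#' Deterministic integer substream derivation; keeps results reproducible
#' under partial regeneration (for example re-simulating one donor). Values
#' stay below 2^31 - 1.
#'
#' @keywords internal
#' @noRd
sub_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483629
  for (i in idx) {
    h <- (h * 48271 + as.double(i) + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Benjamini-Hochberg adjustment that tolerates NAs
#' @keywords internal
#' @noRd
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
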
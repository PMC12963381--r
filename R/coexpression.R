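#' Build metacells by neighbourhood aggregation within groups
#'
#' Within each group (typically cluster x donor) with at least `min_cells`
#' cells, cells are embedded by PCA and each accepted seed cell is averaged
#' with its `k - 1` nearest neighbours. Seeds are visited in seeded random
#' order and rejected when their membership would overlap any accepted
#' metacell in more than `max_shared` cells, bounding redundancy. Groups
#' below the threshold contribute no metacells.
#'
#' @param nm a `normalized_matrix`.
#' @param groups group label per cell.
#' @param k metacell size (default 25).
#' @param min_cells minimum group size (default 50).
#' @param max_shared maximum pairwise member overlap (default 10).
#' @param n_pcs PCA dimensionality of the neighbour search (default 10).
#' @param seed integer seed.
#' @return a `metacell_matrix`: list with `expr` (genes x metacells mean
#'   expression), `meta` (metacell_id, group), `members` (list of member
#'   cell indices into the input), `k`.
#' @export
build_metacells <- function(nm, groups, k = 25, min_cells = 50,
                            max_shared = 10, n_pcs = 10, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  groups <- as.character(groups)
  stop_if_not(length(groups) == ncol(nm$values),
              "groups must match the number of cells")
  vals <- as.matrix(nm$values)
  expr_list <- list(); meta_list <- list(); member_list <- list()
  skipped <- character(0)
  for (grp in sort(unique(groups))) {
    idx <- which(groups == grp)
    if (length(idx) < min_cells) {
      skipped <- c(skipped, grp)
      next
    }
    sub <- t(vals[, idx, drop = FALSE])
    np <- min(n_pcs, nrow(sub) - 1, ncol(sub) - 1)
    pc <- prcomp(sub, center = TRUE, scale. = FALSE, rank. = np)$x
    nn <- knn_index(pc, pc, min(k, nrow(pc)))
    order_seeds <- with_seed(sub_seed(seed, 31L, length(expr_list)), {
      sample(seq_len(nrow(pc)))
    })
    accepted <- list()
    for (s in order_seeds) {
      mem <- nn[s, ]
      ok <- all(vapply(accepted, function(a)
        length(intersect(a, mem)) <= max_shared, logical(1)))
      if (ok) accepted[[length(accepted) + 1]] <- mem
    }
    for (a in accepted) {
      expr_list[[length(expr_list) + 1]] <-
        rowMeans(vals[, idx[a], drop = FALSE])
      member_list[[length(member_list) + 1]] <- idx[a]
      meta_list[[length(meta_list) + 1]] <- grp
    }
  }
  if (length(skipped))
    message("groups below min_cells skipped: ",
            paste(skipped, collapse = ", "))
  stop_if_not(length(expr_list) > 0, "no group met the min_cells threshold")
  expr <- do.call(cbind, expr_list)
  rownames(expr) <- rownames(vals)
  colnames(expr) <- sprintf("MC%04d", seq_len(ncol(expr)))
  structure(list(expr = expr,
                 meta = data.frame(metacell_id = colnames(expr),
                                   group = unlist(meta_list),
                                   stringsAsFactors = FALSE),
                 members = member_list, k = k),
            class = "metacell_matrix")
}

#' @export
print.metacell_matrix <- function(x, ...) {
  cat(sprintf("metacell_matrix: %d genes x %d metacells (k = %d)\n",
              nrow(x$expr), ncol(x$expr), x$k))
  invisible(x)
}

#' Scale-free fit index of a soft-thresholded network
#' @keywords internal
#' @noRd
scale_free_r2 <- function(adj) {
  k <- rowSums(adj)
  if (max(k) <= 0) return(NA_real_)
  br <- seq(0, max(k) * (1 + 1e-8), length.out = 11)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- as.numeric(table(bin)) / length(k)
  mk <- tapply(k, bin, mean)
  ok <- pk > 0 & is.finite(mk) & mk > 0
  if (sum(ok) < 4) return(NA_real_)
  f <- stats::lm(log10(pk[ok]) ~ log10(mk[ok]))
  r2 <- summary(f)$r.squared
  slope <- coef(f)[2]
  if (is.na(slope) || slope >= 0) -r2 else r2
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the adjacency `|cor|^power` is formed and the
#' signed scale-free fit R-squared of its degree distribution computed
#' (log-log regression over 10 degree bins; negated when the slope is
#' non-negative). Returns the smallest power reaching `target_r2`,
#' otherwise the power with the best valid fit; if no power yields a valid
#' fit (for example a correlation-free matrix), a default of 6 is returned
#' with a warning.
#'
#' @param mc a `metacell_matrix`.
#' @param powers candidate powers (default 1:20).
#' @param target_r2 target signed R-squared (default 0.8).
#' @return list with `power` and `table` (power, r2, mean_connectivity).
#' @export
choose_soft_power <- function(mc, powers = 1:20, target_r2 = 0.8) {
  stopifnot(inherits(mc, "metacell_matrix"))
  stop_if_not(nrow(mc$expr) >= 30, "need at least 30 genes")
  cm <- abs(cor_safe(mc$expr))
  diag(cm) <- 0
  tab <- data.frame(power = powers, r2 = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    adj <- cm^powers[i]
    tab$r2[i] <- scale_free_r2(adj)
    tab$mean_connectivity[i] <- mean(rowSums(adj))
  }
  # powers whose network is effectively empty (vanishing connectivity)
  # produce spurious scale-free fits; exclude them from selection
  conn_floor <- nrow(mc$expr) / 5000
  elig <- is.finite(tab$r2) & tab$mean_connectivity >= conn_floor
  hit <- which(elig & tab$r2 >= target_r2)
  power <- if (length(hit)) {
    powers[hit[1]]
  } else if (any(elig)) {
    powers[which.max(replace(tab$r2, !elig, -Inf))]
  } else {
    warning("no valid scale-free fit; defaulting to power 6")
    6L
  }
  list(power = power, table = tab)
}

#' Correlation with zero-variance guard (constant rows give 0)
#' @keywords internal
#' @noRd
cor_safe <- function(expr) {
  x <- t(expr)
  s <- apply(x, 2, sd)
  cm <- suppressWarnings(cor(x))
  cm[s == 0, ] <- 0
  cm[, s == 0] <- 0
  diag(cm) <- 1
  cm
}

#' Topological overlap matrix from an adjacency matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with a
#' unit diagonal; entries lie in \[0, 1\] for adjacency entries in \[0, 1\].
#'
#' @param adj symmetric adjacency with zero diagonal, entries in \[0, 1\].
#' @return the TOM matrix.
#' @export
tom_matrix <- function(adj) {
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' First-principal-component module eigengene
#' @keywords internal
#' @noRd
module_eigengene <- function(expr_mod) {
  # expr_mod: genes x metacells
  x <- t(expr_mod)
  s <- apply(x, 2, sd)
  x <- x[, s > 0, drop = FALSE]
  if (ncol(x) == 0) return(rep(0, nrow(x)))
  x <- scale(x)
  pc1 <- prcomp(x, center = FALSE, scale. = FALSE, rank. = 1)$x[, 1]
  orient <- mean(cor(pc1, x))
  if (is.finite(orient) && orient < 0) pc1 <- -pc1
  as.numeric(scale(pc1))
}

#' Detect co-expression modules from metacell expression
#'
#' Builds the unsigned adjacency `|cor|^power`, converts it to topological
#' overlap, clusters `1 - TOM` by average-linkage hierarchical clustering,
#' cuts the tree at a constant height of 0.99, discards clusters smaller
#' than `min_module_size` (genes fall to module 0, "grey"), and merges
#' modules whose eigengenes correlate at or above `1 - merge_height`.
#' Eigengenes are first principal components over metacells, sign-oriented
#' so the mean correlation with member genes is positive.
#'
#' @param mc a `metacell_matrix`.
#' @param power soft-thresholding power (>= 1), e.g. from
#'   [choose_soft_power()].
#' @param min_module_size smallest retained module (default 30).
#' @param merge_height eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param cut_height constant tree-cut height on 1 - TOM (default 0.99).
#' @return a `module_set`: list with `membership` (named integer, 0 =
#'   unassigned), `eigengenes` (metacells x modules), `kme` (genes x
#'   modules), `hub_top10`, `hub_top50`, `power`.
#' @export
detect_modules <- function(mc, power, min_module_size = 30,
                           merge_height = 0.25, cut_height = 0.99) {
  stopifnot(inherits(mc, "metacell_matrix"))
  stop_if_not(power >= 1, "power must be >= 1")
  genes <- rownames(mc$expr)
  adj <- abs(cor_safe(mc$expr))^power
  diag(adj) <- 0
  tom <- tom_matrix(adj)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  membership <- setNames(rep(0L, length(genes)), genes)
  # label retained clusters by decreasing size, ties by first gene
  big <- big[order(-sizes[big], big)]
  for (i in seq_along(big)) {
    membership[cl == as.integer(big[i])] <- i
  }
  if (all(membership == 0)) {
    warning("no module exceeds min_module_size; all genes unassigned")
    return(structure(list(membership = membership,
                          eigengenes = NULL, kme = NULL,
                          hub_top10 = list(), hub_top50 = list(),
                          power = power),
                     class = "module_set"))
  }
  eig <- compute_eigengenes(mc, membership)
  # merge highly correlated module eigengenes
  repeat {
    if (ncol(eig) < 2) break
    cm <- cor(eig)
    diag(cm) <- -Inf
    mx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[mx[1], mx[2]] < 1 - merge_height) break
    keep_m <- as.integer(colnames(eig)[min(mx)])
    drop_m <- as.integer(colnames(eig)[max(mx)])
    membership[membership == drop_m] <- keep_m
    # relabel to consecutive module ids
    old <- sort(unique(membership[membership > 0]))
    membership <- setNames(
      ifelse(membership > 0, match(membership, old), 0L), genes)
    eig <- compute_eigengenes(mc, membership)
  }
  ms <- structure(list(membership = membership, eigengenes = eig,
                       kme = NULL, hub_top10 = list(), hub_top50 = list(),
                       power = power),
                  class = "module_set")
  km <- compute_kme(mc, ms)
  ms$kme <- km$kme
  ms$hub_top10 <- km$hub_top10
  ms$hub_top50 <- km$hub_top50
  ms
}

compute_eigengenes <- function(mc, membership) {
  mods <- sort(unique(membership[membership > 0]))
  eig <- vapply(mods, function(m) {
    module_eigengene(mc$expr[names(membership)[membership == m], ,
                             drop = FALSE])
  }, numeric(ncol(mc$expr)))
  eig <- matrix(eig, ncol = length(mods))
  colnames(eig) <- as.character(mods)
  rownames(eig) <- colnames(mc$expr)
  eig
}

#' @export
print.module_set <- function(x, ...) {
  nm <- sum(x$membership > 0)
  cat(sprintf(
    "module_set: %d modules (power %s), %d assigned / %d genes\n",
    length(unique(x$membership[x$membership > 0])), x$power, nm,
    length(x$membership)))
  invisible(x)
}

#' Module membership correlations (kME) and hub lists
#'
#' `kME(g, M)` is the Pearson correlation of gene `g` with module `M`'s
#' eigengene across metacells (0 by convention for constant genes). Module
#' members are ranked by their own-module kME (descending, ties broken by
#' gene id) to produce top-10 and top-50 hub lists.
#'
#' @param mc a `metacell_matrix`.
#' @param ms a `module_set`.
#' @return list with `kme` (genes x modules), `hub_top10`, `hub_top50`
#'   (named lists of gene ids per module).
#' @export
compute_kme <- function(mc, ms) {
  stopifnot(inherits(mc, "metacell_matrix"), inherits(ms, "module_set"))
  stop_if_not(!is.null(ms$eigengenes), "module set has no eigengenes")
  x <- t(mc$expr)
  s <- apply(x, 2, sd)
  kme <- suppressWarnings(cor(x, ms$eigengenes))
  kme[s == 0, ] <- 0
  kme[!is.finite(kme)] <- 0
  mods <- colnames(ms$eigengenes)
  hub10 <- list(); hub50 <- list()
  for (m in mods) {
    members <- names(ms$membership)[ms$membership == as.integer(m)]
    ranked <- members[order(-kme[members, m], members)]
    hub10[[m]] <- head(ranked, 10)
    hub50[[m]] <- head(ranked, 50)
  }
  list(kme = kme, hub_top10 = hub10, hub_top50 = hub50)
}

#' Bootstrap stability of detected modules
#'
#' Resamples metacells with replacement, re-detects modules with the same
#' parameters, and scores each reference module by its best-match Jaccard
#' index against the re-detected modules; stability is the mean best
#' Jaccard over iterations. Deterministic under `seed`.
#'
#' @param mc a `metacell_matrix`.
#' @param ms the reference `module_set`.
#' @param n_boot iterations (default 100; raise towards several thousand
#'   for publication-grade estimates).
#' @param seed integer seed.
#' @return named numeric vector of per-module stability scores (empty when
#'   the reference has no modules).
#' @export
module_stability <- function(mc, ms, n_boot = 100, seed = 1L) {
  stopifnot(inherits(mc, "metacell_matrix"), inherits(ms, "module_set"))
  mods <- sort(unique(ms$membership[ms$membership > 0]))
  if (length(mods) == 0) return(setNames(numeric(0), character(0)))
  ref_sets <- lapply(mods, function(m)
    names(ms$membership)[ms$membership == m])
  jac <- matrix(0, n_boot, length(mods))
  for (b in seq_len(n_boot)) {
    idx <- with_seed(sub_seed(seed, 41L, b), {
      sample(ncol(mc$expr), replace = TRUE)
    })
    mcb <- mc
    mcb$expr <- mc$expr[, idx, drop = FALSE]
    msb <- suppressWarnings(
      detect_modules(mcb, power = ms$power)
    )
    new_mods <- sort(unique(msb$membership[msb$membership > 0]))
    for (mi in seq_along(mods)) {
      best <- 0
      for (nmod in new_mods) {
        s2 <- names(msb$membership)[msb$membership == nmod]
        j <- length(intersect(ref_sets[[mi]], s2)) /
          length(union(ref_sets[[mi]], s2))
        if (j > best) best <- j
      }
      jac[b, mi] <- best
    }
  }
  setNames(colMeans(jac), paste0("M", mods))
}

#' Summarize differential expression at the module level
#'
#' For each module, the mean logFC over member genes present in the DE
#' table and the number of significantly DE members.
#'
#' @param ms a `module_set`.
#' @param de a `de_result` with columns gene, logFC, significant.
#' @return data frame: module, n_genes, mean_logFC, n_de.
#' @export
module_de_summary <- function(ms, de) {
  stopifnot(inherits(ms, "module_set"))
  mods <- sort(unique(ms$membership[ms$membership > 0]))
  rows <- lapply(mods, function(m) {
    members <- names(ms$membership)[ms$membership == m]
    d <- de[de$gene %in% members, , drop = FALSE]
    data.frame(module = paste0("M", m), n_genes = length(members),
               mean_logFC = if (nrow(d)) mean(d$logFC, na.rm = TRUE)
                            else NA_real_,
               n_de = sum(d$significant, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(module = character(0), n_genes = integer(0),
               mean_logFC = numeric(0), n_de = integer(0))
  rownames(out) <- NULL
  out
}
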
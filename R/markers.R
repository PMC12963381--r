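#' Rank cluster marker genes by Wilcoxon rank-sum test
#'
#' For every gene and cluster, tests the cluster's cells against all other
#' cells on the normalized log values (two-sided Wilcoxon rank-sum; exact
#' when both groups have at most 25 cells and no ties, otherwise normal
#' approximation with tie correction). Reports the expression fraction
#' inside the cluster (`pts`) and in all other cells (`pts_rest`), the fold
#' change of mean back-transformed expression with a pseudocount, and
#' BH-adjusted p-values per cluster.
#'
#' @param nm a `normalized_matrix`.
#' @param labels cluster label per cell.
#' @param logfc_base `"ln"` (natural log, default) or `"log2"`.
#' @param pseudocount added to mean expression before the ratio
#'   (default 1e-9).
#' @return a `marker_stats` data frame: cluster, gene, logFC, pts, pts_rest,
#'   p, padj.
#' @export
rank_markers <- function(nm, labels, logfc_base = c("ln", "log2"),
                         pseudocount = 1e-9) {
  stopifnot(inherits(nm, "normalized_matrix"))
  logfc_base <- match.arg(logfc_base)
  labels <- as.character(labels)
  stop_if_not(length(labels) == ncol(nm$values),
              "labels must match the number of cells")
  clusters <- sort(unique(labels))
  stop_if_not(length(clusters) >= 2, "need at least 2 clusters")
  tab <- table(labels)
  stop_if_not(all(tab >= 2), "each cluster needs at least 2 cells")
  vals <- as.matrix(nm$values)
  expm <- expm1(vals)
  genes <- rownames(vals) %||% as.character(seq_len(nrow(vals)))
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    inc <- labels == cl
    nin <- sum(inc); nout <- sum(!inc)
    p <- numeric(nrow(vals))
    for (g in seq_len(nrow(vals))) {
      x <- vals[g, inc]; y <- vals[g, !inc]
      if (all(x == x[1]) && all(y == x[1])) {
        p[g] <- 1
      } else {
        p[g] <- suppressWarnings(
          wilcox.test(x, y, exact = (nin <= 25 && nout <= 25),
                      correct = TRUE)$p.value
        )
        if (is.na(p[g])) p[g] <- 1
      }
    }
    mu_in <- rowMeans(expm[, inc, drop = FALSE])
    mu_out <- rowMeans(expm[, !inc, drop = FALSE])
    lfc <- log((mu_in + pseudocount) / (mu_out + pseudocount))
    if (logfc_base == "log2") lfc <- lfc / log(2)
    out[[ci]] <- data.frame(
      cluster = cl, gene = genes, logFC = lfc,
      pts = rowMeans(vals[, inc, drop = FALSE] > 0),
      pts_rest = rowMeans(vals[, !inc, drop = FALSE] > 0),
      p = p, padj = bh_adjust(p),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_stats", "data.frame")
  res
}

#' Filter ranked markers by specificity thresholds
#'
#' Applies the strict-inequality marker criteria: `pts > pts_min`,
#' `pts_rest < pts_rest_max`, `pts/pts_rest > ratio_min` (a `pts_rest` of 0
#' counts as an infinite ratio and passes), `logFC > logfc_min`, and
#' `padj < padj_max`. Per-cluster threshold overrides are supported for
#' clusters whose markers are known to be less exclusive.
#'
#' @param ms a `marker_stats` data frame from [rank_markers()].
#' @param pts_min,pts_rest_max,ratio_min,logfc_min,padj_max thresholds.
#' @param overrides optional named list: cluster -> list of threshold
#'   overrides (e.g. `list(Ex5 = list(pts_rest_max = 0.2, ratio_min = 2))`).
#' @return named list of per-cluster data frames ordered by descending
#'   logFC.
#' @export
filter_markers <- function(ms, pts_min = 0.2, pts_rest_max = 0.1,
                           ratio_min = 3, logfc_min = 1.5, padj_max = 0.05,
                           overrides = NULL) {
  stop_if_not(all(c(pts_min, pts_rest_max, ratio_min, logfc_min,
                    padj_max) > 0), "thresholds must be positive")
  clusters <- unique(ms$cluster)
  res <- lapply(clusters, function(cl) {
    th <- list(pts_min = pts_min, pts_rest_max = pts_rest_max,
               ratio_min = ratio_min, logfc_min = logfc_min,
               padj_max = padj_max)
    if (!is.null(overrides[[cl]])) th[names(overrides[[cl]])] <-
        overrides[[cl]]
    d <- ms[ms$cluster == cl, , drop = FALSE]
    ratio <- ifelse(d$pts_rest == 0, Inf, d$pts / d$pts_rest)
    keep <- d$pts > th$pts_min & d$pts_rest < th$pts_rest_max &
      ratio > th$ratio_min & d$logFC > th$logfc_min & d$padj < th$padj_max
    d <- d[keep, , drop = FALSE]
    d[order(-d$logFC, d$gene), , drop = FALSE]
  })
  names(res) <- clusters
  res
}

#' Cosine distance between cluster mean-expression profiles
#'
#' Computes `1 - cosine similarity` between the mean normalized expression
#' vectors of reference and query clusters over a shared gene set (by
#' default the reference's 3000 highly variable genes united with each
#' reference cluster's top 10 markers). Reports, per query cluster, the
#' three nearest reference clusters (ties broken by cluster id).
#'
#' @param ref_nm,query_nm `normalized_matrix` objects.
#' @param ref_labels,query_labels cluster labels per cell.
#' @param gene_set optional explicit gene set; computed when `NULL`.
#' @param n_hvg,n_markers gene-set construction parameters.
#' @return a `cluster_distance` object: list with `distance` (reference x
#'   query matrix in \[0, 2\]; `NA` flags a zero-vector profile), `top3`
#'   (list per query cluster), and `gene_set`.
#' @export
cosine_cluster_distance <- function(ref_nm, ref_labels, query_nm,
                                    query_labels, gene_set = NULL,
                                    n_hvg = 3000, n_markers = 10) {
  if (is.null(gene_set)) {
    hvg <- select_hvg(ref_nm, n_top = n_hvg)
    mk <- rank_markers(ref_nm, ref_labels)
    top <- unlist(lapply(split(mk, mk$cluster), function(d) {
      d <- d[d$padj < 0.05, , drop = FALSE]
      head(d$gene[order(-d$logFC, d$gene)], n_markers)
    }), use.names = FALSE)
    gene_set <- union(hvg, top)
  }
  shared <- Reduce(intersect, list(gene_set, rownames(ref_nm$values),
                                   rownames(query_nm$values)))
  stop_if_not(length(shared) > 0, "no shared genes after intersection")
  prof <- function(nm, labels) {
    labels <- as.character(labels)
    cls <- sort(unique(labels))
    sapply(cls, function(cl)
      Matrix::rowMeans(nm$values[shared, labels == cl, drop = FALSE]))
  }
  rp <- prof(ref_nm, ref_labels)
  qp <- prof(query_nm, query_labels)
  nr <- sqrt(colSums(rp^2)); nq <- sqrt(colSums(qp^2))
  if (any(nr == 0) || any(nq == 0)) {
    warning("zero-vector mean profile(s); distances flagged as NA")
  }
  sim <- crossprod(rp, qp) / (nr %o% nq)
  sim[!is.finite(sim)] <- NA
  d <- 1 - sim
  top3 <- lapply(colnames(d), function(q) {
    ord <- order(d[, q], rownames(d))
    stats::na.omit(rownames(d)[ord])[1:min(3, nrow(d))]
  })
  names(top3) <- colnames(d)
  structure(list(distance = d, top3 = top3, gene_set = shared),
            class = "cluster_distance")
}

#' Brute-force k-nearest-neighbour indices (Euclidean)
#' @keywords internal
#' @noRd
knn_index <- function(ref, query, k) {
  # ref, query: observations in rows
  rn <- rowSums(ref^2)
  qn <- rowSums(query^2)
  d2 <- outer(qn, rn, "+") - 2 * tcrossprod(query, ref)
  idx <- apply(d2, 1, function(r) order(r)[seq_len(k)])
  if (k == 1) matrix(idx, ncol = 1) else t(idx)
}

#' Transfer cluster labels by kNN in a reference PCA space
#'
#' Fits PCA on the reference cells only (reference-mean centering), projects
#' query cells into that space, and labels each query cell by the majority
#' vote among its `k` nearest reference cells (Euclidean). The confidence is
#' the winning vote fraction; ties, and cells whose confidence falls below
#' `min_confidence`, are labeled `"unassigned"`.
#'
#' @param ref_nm reference `normalized_matrix`.
#' @param ref_labels labels per reference cell.
#' @param query_nm query `normalized_matrix`.
#' @param n_pcs number of principal components (default 15).
#' @param k number of neighbours (default 20).
#' @param min_confidence minimum vote fraction (default 0, i.e. no gate).
#' @return data frame: cell_id, label, confidence.
#' @export
knn_label_transfer <- function(ref_nm, ref_labels, query_nm, n_pcs = 15,
                               k = 20, min_confidence = 0) {
  shared <- intersect(rownames(ref_nm$values), rownames(query_nm$values))
  stop_if_not(length(shared) >= n_pcs,
              "shared gene set smaller than n_pcs")
  stop_if_not(k <= ncol(ref_nm$values), "k exceeds the reference size")
  ref <- t(as.matrix(ref_nm$values[shared, , drop = FALSE]))
  qry <- t(as.matrix(query_nm$values[shared, , drop = FALSE]))
  n_pcs <- min(n_pcs, ncol(ref) - 1, nrow(ref) - 1)
  pc <- prcomp(ref, center = TRUE, scale. = FALSE, rank. = n_pcs)
  ref_pc <- pc$x
  qry_pc <- scale(qry, center = pc$center, scale = FALSE) %*% pc$rotation
  nn <- knn_index(ref_pc, qry_pc, k)
  labels <- as.character(ref_labels)
  res <- t(apply(nn, 1, function(idx) {
    v <- table(labels[idx])
    w <- which(v == max(v))
    if (length(w) > 1) c("unassigned", max(v) / k)
    else c(names(v)[w], v[w] / k)
  }))
  label <- res[, 1]
  conf <- as.numeric(res[, 2])
  label[conf < min_confidence] <- "unassigned"
  data.frame(cell_id = colnames(query_nm$values) %||%
               as.character(seq_len(nrow(qry))),
             label = label, confidence = conf,
             stringsAsFactors = FALSE)
}
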
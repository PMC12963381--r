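#' Heuristic marker-score classification of spatial cells
#'
#' Scores each cell for each type as the sum of counts over that type's
#' marker genes divided by the marker-set size, and assigns the
#' highest-scoring type. Ties and all-zero scores yield `"unknown"`.
#' Marker genes absent from the panel are ignored with a one-time warning.
#'
#' @param sd a `spatial_dataset`.
#' @param marker_map named list: type -> character vector of marker genes.
#' @return character vector of per-cell labels.
#' @export
heuristic_classify <- function(sd, marker_map) {
  stopifnot(inherits(sd, "spatial_dataset"))
  stop_if_not(length(marker_map) > 0 &&
                all(lengths(marker_map) > 0), "empty marker map")
  panel <- rownames(sd$counts)
  missing <- setdiff(unlist(marker_map), panel)
  if (length(missing)) {
    warning("marker gene(s) absent from panel ignored: ",
            paste(unique(missing), collapse = ", "))
  }
  scores <- vapply(names(marker_map), function(ty) {
    mk <- intersect(marker_map[[ty]], panel)
    if (length(mk) == 0) return(rep(0, ncol(sd$counts)))
    as.numeric(Matrix::colSums(sd$counts[mk, , drop = FALSE])) /
      length(marker_map[[ty]])
  }, numeric(ncol(sd$counts)))
  scores <- matrix(scores, ncol = length(marker_map),
                   dimnames = list(NULL, names(marker_map)))
  apply(scores, 1, function(s) {
    mx <- max(s)
    if (mx <= 0) return("unknown")
    w <- which(s == mx)
    if (length(w) > 1) "unknown" else colnames(scores)[w]
  })
}

#' Graph-clustering annotation of spatial cells
#'
#' Log-normalizes the panel counts, builds a k-nearest-neighbour graph,
#' partitions it by modularity-maximizing community detection (Leiden),
#' and labels each community by the type with the highest mean heuristic
#' marker score among its members (`"unknown"` if no marker signal).
#' Deterministic under `seed`.
#'
#' @param sd a `spatial_dataset`.
#' @param marker_map named list: type -> marker genes.
#' @param resolution community-detection resolution (default 1.0).
#' @param k_graph neighbours in the kNN graph (default 15).
#' @param seed integer seed.
#' @return character vector of per-cell labels.
#' @export
cluster_annotate <- function(sd, marker_map, resolution = 1.0,
                             k_graph = 15, seed = 1L) {
  stopifnot(inherits(sd, "spatial_dataset"))
  n <- ncol(sd$counts)
  stop_if_not(n >= 2, "need at least 2 cells")
  nm <- normalize_log(sd$counts)
  emb <- t(as.matrix(nm$values))
  kk <- min(k_graph + 1, nrow(emb))
  nn <- knn_index(emb, emb, kk)
  edges <- do.call(rbind, lapply(seq_len(nrow(nn)), function(i) {
    js <- setdiff(nn[i, ], i)
    if (length(js)) cbind(i, js) else NULL
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(igraph::add_vertices(
    g, max(0, n - igraph::vcount(g))))
  comm <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution)
  })
  member <- igraph::membership(comm)
  # per-cell heuristic scores, averaged per community
  panel <- rownames(sd$counts)
  scores <- vapply(names(marker_map), function(ty) {
    mk <- intersect(marker_map[[ty]], panel)
    if (length(mk) == 0) return(rep(0, n))
    as.numeric(Matrix::colSums(sd$counts[mk, , drop = FALSE])) /
      length(marker_map[[ty]])
  }, numeric(n))
  scores <- matrix(scores, ncol = length(marker_map),
                   dimnames = list(NULL, names(marker_map)))
  labels <- character(n)
  for (cid in unique(member)) {
    inc <- member == cid
    ms <- colMeans(scores[inc, , drop = FALSE])
    labels[inc] <- if (max(ms) <= 0) "unknown"
      else names(marker_map)[which.max(ms)]
  }
  labels
}

#' Ensemble voting over independent per-cell annotations
#'
#' Integrates two or more per-cell label vectors by plurality vote. The
#' confidence is the winning vote share among cast votes; `"unknown"`
#' votes stay in the denominator unless all methods abstain. Cells are
#' retained only when confidence strictly exceeds `min_confidence`; vote
#' ties are never retained.
#'
#' @param vote_sets named list of per-cell label vectors (aligned).
#' @param min_confidence retention threshold (default 0.5, strict).
#' @return an `ensemble_annotation` data frame: one column per method,
#'   consensus, confidence, retained.
#' @export
ensemble_vote <- function(vote_sets, min_confidence = 0.5) {
  stop_if_not(length(vote_sets) >= 2, "need at least 2 vote sets")
  n <- unique(lengths(vote_sets))
  stop_if_not(length(n) == 1, "vote sets must be aligned (equal length)")
  m <- length(vote_sets)
  votes <- do.call(cbind, vote_sets)
  consensus <- character(n)
  confidence <- numeric(n)
  for (i in seq_len(n)) {
    v <- votes[i, ]
    informative <- v[v != "unknown"]
    if (length(informative) == 0) {
      consensus[i] <- "unknown"; confidence[i] <- 0
      next
    }
    tab <- table(informative)
    w <- which(tab == max(tab))
    if (length(w) > 1) {
      # tie between labels: report one deterministically but with the
      # tied (non-majority) confidence so the cell is never retained
      consensus[i] <- sort(names(tab)[w])[1]
    } else {
      consensus[i] <- names(tab)[w]
    }
    confidence[i] <- max(tab) / m
  }
  out <- data.frame(votes, consensus = consensus,
                    confidence = confidence,
                    retained = confidence > min_confidence,
                    stringsAsFactors = FALSE)
  class(out) <- c("ensemble_annotation", "data.frame")
  out
}

#' Transfer neuronal subtypes onto well-covered spatial cells
#'
#' Restricts a single-nucleus reference to the spatial panel genes and
#' delegates to [knn_label_transfer()]. Only cells whose consensus label is
#' neuronal and whose total transcript count strictly exceeds
#' `min_transcripts` receive a subtype label; the rest are `NA`.
#'
#' @param sd a `spatial_dataset`.
#' @param ref_nm reference `normalized_matrix` (subtype-labeled cells).
#' @param ref_labels subtype label per reference cell.
#' @param eligible logical per spatial cell: consensus label is neuronal.
#' @param min_transcripts transcript gate (default 50, strict).
#' @param n_pcs,k transfer parameters (defaults 15 and 20).
#' @return data frame: cell_id, subtype, subtype_confidence (NA for
#'   ineligible cells).
#' @export
subtype_transfer <- function(sd, ref_nm, ref_labels, eligible,
                             min_transcripts = 50, n_pcs = 15, k = 20) {
  stopifnot(inherits(sd, "spatial_dataset"))
  shared <- intersect(rownames(ref_nm$values), rownames(sd$counts))
  if (length(shared) < n_pcs) {
    warning("shared panel smaller than n_pcs; reducing n_pcs to ",
            length(shared) - 1)
    n_pcs <- max(2, length(shared) - 1)
  }
  pass <- eligible & sd$cells$total_transcripts > min_transcripts
  out <- data.frame(cell_id = sd$cells$cell_id,
                    subtype = NA_character_,
                    subtype_confidence = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(pass)) return(out)
  qnm <- normalize_log(sd$counts[shared, pass, drop = FALSE])
  ref_sub <- ref_nm
  ref_sub$values <- ref_nm$values[shared, , drop = FALSE]
  tr <- knn_label_transfer(ref_sub, ref_labels, qnm,
                           n_pcs = n_pcs, k = k)
  out$subtype[pass] <- tr$label
  out$subtype_confidence[pass] <- tr$confidence
  out
}
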
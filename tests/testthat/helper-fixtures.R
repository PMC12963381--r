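# Shared fixture builders; everything is generated in code at test time.

# wrap a plain matrix as a normalized_matrix (genes x cells, log scale)
make_nm <- function(values, cell_meta = NULL, donor_meta = NULL) {
  structure(list(values = values,
                 size_factors = rep(1, ncol(values)),
                 cell_meta = cell_meta, donor_meta = donor_meta),
            class = "normalized_matrix")
}

# minimal cohort_dataset built by hand from a counts matrix
make_cohort <- function(counts, donor_id, cluster = "Ex1",
                        pathology_group = NULL, region = "synthetic") {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("C%06d", seq_len(ncol(counts)))
  cluster <- rep_len(cluster, ncol(counts))
  cell_meta <- data.frame(
    cell_id = colnames(counts), donor_id = donor_id, region = region,
    cluster = cluster,
    n_genes_detected = Matrix::colSums(counts > 0),
    mito_fraction = 0,
    total_counts = Matrix::colSums(counts),
    stringsAsFactors = FALSE
  )
  donors <- unique(donor_id)
  if (is.null(pathology_group))
    pathology_group <- rep("low", length(donors))
  donor_meta <- data.frame(
    donor_id = donors,
    pathology_group = factor(pathology_group,
                             levels = c("low", "intermediate", "high")),
    sex = "F", age = 75, apoe = "e33", assay = "v3", rin = 7,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_meta = cell_meta, donor_meta = donor_meta),
            class = "cohort_dataset")
}

# donor-level pseudobulk table built directly (for NB-test calibration)
make_pb <- function(counts, pathology_group, cluster = "Ex1",
                    n_expressing = NULL) {
  # counts: donors x genes
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%04d", seq_len(ncol(counts)))
  nd <- nrow(counts)
  if (is.null(n_expressing))
    n_expressing <- matrix(25L, nd, ncol(counts),
                           dimnames = dimnames(counts))
  gm <- data.frame(
    donor_id = sprintf("D%03d", seq_len(nd)),
    cluster = cluster,
    pathology_group = factor(pathology_group,
                             levels = c("low", "intermediate", "high")),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- rownames(n_expressing) <- rownames(gm) <- gm$donor_id
  structure(list(counts = counts, n_expressing = n_expressing,
                 group_meta = gm, group_by = c("donor_id", "cluster")),
            class = "pseudobulk_table")
}

# brute-force two-sided Wilcoxon rank-sum p-value by full enumeration
brute_wilcoxon_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2, function(i) sum(r[i]))
  mu <- mean(w_all)
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  p
}

# brute-force BH step-up rejections at level alpha
brute_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= (seq_len(m) / m) * alpha)
  rej <- rep(FALSE, m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}
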
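test_that("marker ranking handles ties, pseudocounts and exact cases", {
  vals <- rbind(
    flat  = rep(log1p(2), 6),
    clean = log1p(c(5, 6, 7, 1, 2, 3)),
    only_in = log1p(c(4, 5, 6, 0, 0, 0))
  )
  colnames(vals) <- sprintf("c%d", 1:6)
  labels <- rep(c("A", "B"), each = 3)
  ms <- rank_markers(make_nm(vals), labels)
  a <- ms[ms$cluster == "A", ]
  # gene identical in all cells: p = 1 after tie handling, logFC = 0
  expect_equal(a$p[a$gene == "flat"], 1)
  expect_equal(a$logFC[a$gene == "flat"], 0)
  # 3v3 {5,6,7} vs {1,2,3}: exact two-sided rank-sum p = 0.1
  expect_equal(a$p[a$gene == "clean"], 0.1)
  # expressed only inside the cluster: pts_rest 0, finite logFC
  expect_equal(a$pts_rest[a$gene == "only_in"], 0)
  expect_true(is.finite(a$logFC[a$gene == "only_in"]))
  expect_gt(a$logFC[a$gene == "only_in"], 10)
})

test_that("Wilcoxon p-values match brute-force enumeration (groups <= 8)", {
  set.seed(44)
  for (rep in 1:6) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx, 1)  # continuous, so the exact (tie-free) path is used
    y <- rnorm(ny, 0)
    m <- matrix(log1p(abs(c(x, y))), 1)
    m <- rbind(m, m)  # rank_markers needs >= 1 gene; duplicate row
    rownames(m) <- c("g1", "g2")
    labels <- c(rep("A", nx), rep("B", ny))
    ms <- rank_markers(make_nm(m), labels)
    p_pkg <- ms$p[ms$cluster == "A" & ms$gene == "g1"]
    p_brute <- brute_wilcoxon_p(log1p(abs(x)), log1p(abs(y)))
    expect_equal(p_pkg, p_brute, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up rule", {
  set.seed(10)
  p <- runif(40)^2
  padj <- p.adjust(p, "BH")
  expect_equal(padj <= 0.05, brute_bh_reject(p, 0.05))
  # and within rank_markers output, padj is monotone in p per cluster
  vals <- matrix(log1p(rpois(20 * 12, 3)), 20, 12,
                 dimnames = list(sprintf("G%02d", 1:20), NULL))
  ms <- rank_markers(make_nm(vals), rep(c("A", "B"), each = 6))
  for (cl in c("A", "B")) {
    d <- ms[ms$cluster == cl, ]
    d <- d[order(d$p), ]
    expect_true(all(diff(d$padj) >= -1e-12))
    expect_true(all(d$padj >= d$p - 1e-12))
  }
})

test_that("marker filters apply strict published inequalities", {
  ms <- data.frame(
    cluster = "A",
    gene = c("fails_rest", "passes", "boundary_lfc", "zero_rest"),
    logFC = c(2.0, 2.0, 1.5, 2.0),
    pts = c(0.5, 0.5, 0.5, 0.5),
    pts_rest = c(0.2, 0.05, 0.05, 0.0),
    p = 0.001, padj = c(0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
  got <- filter_markers(ms)$A$gene
  expect_false("fails_rest" %in% got)   # pts_rest not < 0.1
  expect_true("passes" %in% got)
  expect_false("boundary_lfc" %in% got) # logFC exactly 1.5 fails strict >
  expect_true("zero_rest" %in% got)     # pts_rest 0 -> infinite ratio
  # per-cluster overrides relax thresholds
  ov <- filter_markers(ms, overrides = list(A = list(logfc_min = 1.0)))
  expect_true("boundary_lfc" %in% ov$A$gene)
})

test_that("cosine cluster distances match hand-computed geometry", {
  # profiles (1,1,0) and (1,0,0): distance = 1 - 1/sqrt(2)
  ref <- cbind(a1 = c(1, 1, 0), a2 = c(1, 1, 0),
               b1 = c(1, 0, 0), b2 = c(1, 0, 0))
  rownames(ref) <- c("g1", "g2", "g3")
  labels <- c("A", "A", "B", "B")
  cd <- cosine_cluster_distance(make_nm(ref), labels, make_nm(ref), labels,
                                gene_set = rownames(ref))
  expect_equal(cd$distance["A", "B"], 1 - 1 / sqrt(2), tolerance = 1e-12)
  # self-match: zero diagonal, top-1 is self
  expect_equal(unname(diag(cd$distance)), c(0, 0), tolerance = 1e-12)
  expect_equal(cd$top3$A[1], "A")
  # orthogonal one-hot profiles have distance 1
  orth <- cbind(x1 = c(1, 0), x2 = c(1, 0), y1 = c(0, 1), y2 = c(0, 1))
  rownames(orth) <- c("g1", "g2")
  cd2 <- cosine_cluster_distance(make_nm(orth), c("X", "X", "Y", "Y"),
                                 make_nm(orth), c("X", "X", "Y", "Y"),
                                 gene_set = rownames(orth))
  expect_equal(cd2$distance["X", "Y"], 1, tolerance = 1e-12)
  # symmetry under swapping reference and query
  cd3 <- cosine_cluster_distance(make_nm(ref), labels, make_nm(orth),
                                 c("X", "X", "Y", "Y"),
                                 gene_set = c("g1", "g2"))
  cd4 <- cosine_cluster_distance(make_nm(orth), c("X", "X", "Y", "Y"),
                                 make_nm(ref), labels,
                                 gene_set = c("g1", "g2"))
  expect_equal(cd3$distance, t(cd4$distance), tolerance = 1e-12)
  # scale invariance to positive rescaling of one dataset
  cd5 <- cosine_cluster_distance(make_nm(ref * 7), labels, make_nm(orth),
                                 c("X", "X", "Y", "Y"),
                                 gene_set = c("g1", "g2"))
  expect_equal(cd5$distance, cd3$distance, tolerance = 1e-12)
})

test_that("kNN label transfer recovers well-separated clusters", {
  set.seed(77)
  centers <- matrix(c(0, 0, 20, 0, 0, 20), 3, 2, byrow = TRUE)
  mk <- function(n_per) {
    m <- do.call(cbind, lapply(1:3, function(k)
      t(matrix(rnorm(n_per * 2, 0, 0.5), n_per, 2) +
          rep(centers[k, ], each = n_per))))
    m <- rbind(m, matrix(rnorm(ncol(m) * 18, 0, 0.3), 18))
    rownames(m) <- sprintf("G%02d", 1:20)
    m
  }
  ref <- mk(40); qry <- mk(15)
  ref_lab <- rep(c("A", "B", "C"), each = 40)
  qry_lab <- rep(c("A", "B", "C"), each = 15)
  tr <- knn_label_transfer(make_nm(ref), ref_lab, make_nm(qry),
                           n_pcs = 5, k = 10)
  expect_gte(mean(tr$label == qry_lab), 0.99)
  # query identical to a reference cell in a tight cluster: confidence 1
  q1 <- make_nm(ref[, 1, drop = FALSE])
  tr1 <- knn_label_transfer(make_nm(ref), ref_lab, q1, n_pcs = 5, k = 10)
  expect_equal(tr1$label, "A")
  expect_equal(tr1$confidence, 1)
  # a high confidence gate marks boundary cells unassigned
  trg <- knn_label_transfer(make_nm(ref), ref_lab, make_nm(qry),
                            n_pcs = 5, k = 10, min_confidence = 0.99)
  expect_true(all(trg$label[trg$confidence < 0.99] == "unassigned"))
  # self-transfer recovers every cell that is its own nearest neighbour
  self <- knn_label_transfer(make_nm(ref), ref_lab, make_nm(ref),
                             n_pcs = 5, k = 1)
  expect_equal(self$label, ref_lab)
  expect_error(knn_label_transfer(make_nm(ref), ref_lab, make_nm(qry),
                                  k = 1000), "k exceeds")
})
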
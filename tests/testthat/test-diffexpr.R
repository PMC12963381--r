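test_that("stage contrasts map to the documented group pairs", {
  early <- de_contrast("early")
  late <- de_contrast("late")
  expect_equal(c(early$baseline, early$comparison),
               c("low", "intermediate"))
  expect_equal(c(late$baseline, late$comparison),
               c("intermediate", "high"))
})

test_that("published significance filters gate the mixed model", {
  # gene A: strong detection shift but < 20% expression in both groups;
  # gene B: detectable but null; gene C: strong and detectable
  set.seed(55)
  n_don <- 12; n_cell <- 40
  donors <- rep(sprintf("D%03d", 1:n_don), each = n_cell)
  grp <- rep(rep(c("low", "intermediate"), each = n_don / 2), each = n_cell)
  cond <- as.integer(grp == "intermediate")
  n <- length(donors)
  counts <- rbind(
    A = rbinom(n, 1, ifelse(cond == 1, 0.17, 0.03)) * rpois(n, 3),
    B = rpois(n, 2),
    C = rpois(n, exp(1 + 1.2 * cond)),
    matrix(rpois(40 * n, 1), 40, n)
  )
  counts["A", counts["A", ] > 0] <- pmax(counts["A", counts["A", ] > 0], 1)
  ds <- make_cohort(counts, donor_id = donors,
                    pathology_group = rep(c("low", "intermediate"),
                                          each = n_don / 2))
  de <- fit_hurdle_mixed(normalize_log(ds), de_contrast("early"))
  a <- de[de$gene == "A", ]
  expect_lt(max(a$pct_base, a$pct_comp), 0.2)
  expect_false(a$significant)  # whatever its p, the pct filter blocks it
  expect_true(de[de$gene == "C", "significant"])
  expect_false(de[de$gene == "B", "significant"])
})

test_that("bootstrap retention uses the exact directional-support rule", {
  d <- bootstrap_decision(support_up = c(19L, 20L, 20L, 50L),
                          support_down = c(0L, 0L, 1L, 60L),
                          min_support = 20)
  expect_equal(d$supported, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(d$direction[2], "up")
  expect_equal(d$direction[4], "down")
  # monotonicity: raising min_support never grows the supported set
  set.seed(3)
  up <- rpois(50, 12); dn <- rpois(50, 2) * rbinom(50, 1, 0.3)
  s20 <- bootstrap_decision(up, dn, 20)$supported
  s30 <- bootstrap_decision(up, dn, 30)$supported
  expect_true(all(s30 <= s20))
})

test_that("bootstrap support is seed-reproducible and order-invariant", {
  cfg <- cohort_config(n_donors_per_group = 4, n_celltypes = 1,
                       baseline_props = 1, n_cells_per_donor = 30,
                       n_genes = 40, n_de_genes = 4, de_log2fc = 2,
                       seed = 61)
  sim <- simulate_cohort(cfg)
  nm <- normalize_log(sim$dataset)
  b1 <- bootstrap_de(nm, de_contrast("early"), cluster = "Ex1",
                     n_iter = 8, min_support = 4, seed = 17)
  b2 <- bootstrap_de(nm, de_contrast("early"), cluster = "Ex1",
                     n_iter = 8, min_support = 4, seed = 17)
  expect_identical(b1$support_up, b2$support_up)
  # permuting the cell order leaves support untouched
  perm <- sample(ncol(nm$values))
  nmp <- nm
  nmp$values <- nm$values[, perm]
  nmp$cell_meta <- nm$cell_meta[perm, ]
  b3 <- bootstrap_de(nmp, de_contrast("early"), cluster = "Ex1",
                     n_iter = 8, min_support = 4, seed = 17)
  expect_identical(b1$support_up, b3$support_up)
  expect_identical(b1$support_down, b3$support_down)
})

test_that("pseudobulk NB testing applies the nuclei filter exactly", {
  set.seed(71)
  nd <- 12
  counts <- matrix(rpois(nd * 30, 40), nd, 30)
  nex <- matrix(3L, nd, 30)
  nex[, 1] <- c(19L, rep(0L, nd - 1))   # 19 expressing nuclei in total
  nex[, 2] <- c(20L, rep(0L, nd - 1))   # exactly 20 passes
  nex[, 3:30] <- 5L                     # 60 in total
  pb <- make_pb(counts, rep(c("low", "intermediate"), each = nd / 2),
                n_expressing = nex)
  de <- pseudobulk_de(pb, de_contrast("early"), min_nuclei = 20)
  expect_false("G0001" %in% de$gene)
  expect_true("G0002" %in% de$gene)
  # monotonicity: a larger filter never grows the tested set
  de2 <- pseudobulk_de(pb, de_contrast("early"), min_nuclei = 40)
  expect_true(all(de2$gene %in% de$gene))
  expect_false("G0002" %in% de2$gene)
})

test_that("pseudobulk NB detects strong donor-level fold changes", {
  set.seed(72)
  nd <- 20; ng <- 200
  cond <- rep(c(0, 1), each = nd / 2)
  mu <- matrix(50, nd, ng)
  mu[, 1:20] <- mu[, 1:20] * outer(4^cond, rep(1, 20))
  counts <- matrix(rnbinom(nd * ng, mu = mu, size = 8), nd, ng)
  pb <- make_pb(counts, ifelse(cond == 0, "low", "intermediate"))
  de <- pseudobulk_de(pb, de_contrast("early"))
  planted <- sprintf("G%04d", 1:20)
  expect_gte(mean(de$significant[de$gene %in% planted]), 0.9)
  expect_true(all(de$direction[de$gene %in% planted & de$significant] ==
                    "up"))
  expect_lt(mean(de$significant[!de$gene %in% planted]), 0.1)
})

test_that("the consensus rule requires the mixed model plus one ally", {
  mixed <- data.frame(
    gene = c("m_only", "m_boot", "m_pb", "m_hub", "m_conflict"),
    logFC = c(1, 1, 1, 1, 1), p = 1e-6, padj = 1e-5,
    pct_base = 0.5, pct_comp = 0.5,
    direction = "up", significant = TRUE, note = "pql",
    stringsAsFactors = FALSE)
  class(mixed) <- c("de_result", "data.frame")
  attr(mixed, "method") <- "mixed"
  boot <- data.frame(gene = c("m_boot", "m_conflict", "b_only"),
                     support_up = c(40L, 0L, 80L),
                     support_down = c(0L, 35L, 0L),
                     support = c(40L, 35L, 80L),
                     direction = c("up", "down", "up"),
                     supported = TRUE, stringsAsFactors = FALSE)
  class(boot) <- c("de_result", "data.frame")
  pbde <- data.frame(gene = c("m_pb", "b_only"), logFC = c(0.9, 1.2),
                     p = 1e-4, padj = 1e-3, direction = "up",
                     significant = TRUE, stringsAsFactors = FALSE)
  class(pbde) <- c("de_result", "data.frame")
  hc <- consensus_high_confidence(mixed, boot, pbde,
                                  hub_genes = c("m_hub"))
  expect_setequal(hc$gene, c("m_boot", "m_pb", "m_hub"))
  expect_false("m_only" %in% hc$gene)     # one method is not enough
  expect_false("b_only" %in% hc$gene)     # allies without the mixed model
  expect_equal(attr(hc, "conflicts"), "m_conflict")
  expect_true(all(hc$mixed))
  expect_true(all(hc$bootstrap | hc$pseudobulk | hc$coexpr_hub))
})

test_that("condition intersections equal brute-force set algebra", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
               C = c("g3", "g5"), D = c("g3", "g2"))
  res <- intersect_conditions(sets)
  expect_equal(res$shared_all, "g3")
  expect_equal(res$pairwise["A", "B"], 2)
  expect_equal(res$pairwise["C", "D"], 1)
  for (g in rownames(res$membership)) {
    for (s in names(sets)) {
      expect_equal(res$membership[g, s], g %in% sets[[s]])
    }
  }
  # identical sets intersect fully; disjoint sets never do
  same <- intersect_conditions(list(a = c("x", "y"), b = c("x", "y")))
  expect_setequal(same$shared_all, c("x", "y"))
  disj <- intersect_conditions(list(a = "x", b = "y"))
  expect_length(disj$shared_all, 0)
  expect_equal(disj$pairwise["a", "b"], 0)
  # randomized sets against an independent enumeration
  set.seed(91)
  rsets <- lapply(1:4, function(i) sample(sprintf("g%02d", 1:30), 12))
  names(rsets) <- LETTERS[1:4]
  rres <- intersect_conditions(rsets)
  brute_shared <- Reduce(intersect, rsets)
  expect_setequal(rres$shared_all, brute_shared)
})
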
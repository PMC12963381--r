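test_that("a fixed seed fully determines the simulated cohort", {
  cfg <- cohort_config(n_donors_per_group = 2, n_celltypes = 3,
                       n_cells_per_donor = 40, n_genes = 50, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$dataset$cell_meta, b$dataset$cell_meta)
  expect_identical(a$dataset$donor_meta, b$dataset$donor_meta)
  expect_identical(a$truth, b$truth)
  # spatial and calcium generators are deterministic too
  prof <- matrix(5, 4, 2, dimnames = list(letters[1:4], c("A", "B")))
  lay <- data.frame(type = c("A", "B"), ymin = c(0, 100), ymax = c(100, 200))
  s1 <- simulate_spatial(30, prof, lay, seed = 3)
  s2 <- simulate_spatial(30, prof, lay, seed = 3)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cells, s2$cells)
  c1 <- simulate_calcium(event_times_s = list(c(5, 20)), noise_sd = 0.05,
                         seed = 9)
  c2 <- simulate_calcium(event_times_s = list(c(5, 20)), noise_sd = 0.05,
                         seed = 9)
  expect_identical(c1$traces, c2$traces)
})

test_that("null configurations plant no structure", {
  cfg <- cohort_config(n_donors_per_group = 3, n_celltypes = 4,
                       n_cells_per_donor = 200, n_genes = 40,
                       n_de_genes = 0, de_log2fc = 0,
                       comp_log2fc = rep(0, 4), seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$truth$de_genes), 0)
  expect_true(all(sim$truth$comp_log2fc == 0))
  expect_length(sim$truth$module_membership, 0)
  # group-wise mean proportions differ only by sampling noise
  ct <- simulate_composition(cohort_config(
    n_donors_per_group = 40, n_celltypes = 4, n_cells_per_donor = 2000,
    comp_log2fc = rep(0, 4), seed = 5))
  props <- ct$counts / rowSums(ct$counts)
  g <- ct$design$pathology_group
  gap <- max(abs(colMeans(props[g == "high", ]) -
                   colMeans(props[g == "low", ])))
  # SE of a group-mean difference here is ~0.01; 4 SDs as noise bound
  expect_lt(gap, 0.04)
})

test_that("per-donor cell-type counts sum to the donor totals", {
  cfg <- cohort_config(n_donors_per_group = 4, n_celltypes = 5,
                       n_cells_per_donor = 123, n_genes = 10, seed = 3)
  ct <- simulate_composition(cfg)
  expect_true(all(rowSums(ct$counts) == 123))
  sim <- simulate_cohort(cfg)
  per_donor <- table(sim$dataset$cell_meta$donor_id)
  expect_true(all(per_donor == 123))
})

test_that("planted compositional shift reproduces the target log2 ratio", {
  # Monte-Carlo oracle: empirical high/low log2 ratio of the mean
  # proportion of the shifted type, averaged over 50 replicate seeds
  lfc <- vapply(1:50, function(r) {
    cfg <- cohort_config(n_donors_per_group = 10, n_celltypes = 8,
                         n_cells_per_donor = 2000,
                         comp_log2fc = c(-1, rep(0, 7)), seed = 9000 + r)
    ct <- simulate_composition(cfg)
    props <- ct$counts[, "Ex1"] / rowSums(ct$counts)
    g <- ct$design$pathology_group
    log2(mean(props[g == "high"]) / mean(props[g == "low"]))
  }, numeric(1))
  expect_lt(abs(mean(lfc) - (-1)), 0.15)
})

test_that("negative-binomial marginals match closed-form moments", {
  # dropout disabled, no donor effect, no modules: counts for one gene are
  # iid NB(mu, theta) across >= 1e5 cells; check mean and variance
  cfg <- cohort_config(n_donors_per_group = 1, n_celltypes = 1,
                       baseline_props = 1, comp_log2fc = 0,
                       n_cells_per_donor = 100000, n_genes = 5,
                       donor_sd = 0, nb_dispersion = 2,
                       dropout_midpoint = -30, gene_sdlog = 0.5, seed = 4)
  sim <- simulate_cohort(cfg)
  x <- as.matrix(sim$dataset$counts)
  for (g in seq_len(nrow(x))) {
    m <- mean(x[g, ]); v <- var(x[g, ])
    expected_v <- m + m^2 / 2
    expect_lt(abs(v - expected_v) / expected_v, 0.1)
  }
})

test_that("spatial generator respects layer bands and profiles", {
  prof <- matrix(0, 6, 2, dimnames = list(sprintf("g%d", 1:6),
                                          c("A", "Ex5")))
  prof[1:3, "A"] <- 4; prof[4:6, "Ex5"] <- 4
  lay <- data.frame(type = c("A", "Ex5"), ymin = c(0, 200),
                    ymax = c(200, 400))
  sd0 <- simulate_spatial(200, prof, lay, noise_rate = 0, seed = 6)
  ex5 <- sd0$cells$true_type == "Ex5"
  expect_true(all(sd0$cells$y_um[ex5] >= 200 & sd0$cells$y_um[ex5] <= 400))
  # one-hot profiles with zero noise: cells express only own markers
  expect_true(all(sd0$counts[1:3, ex5] == 0))
  expect_true(all(sd0$counts[4:6, !ex5] == 0))
  expect_equal(sd0$cells$total_transcripts,
               as.numeric(Matrix::colSums(sd0$counts)))
})

test_that("per-cell transcript totals follow the Poisson tail", {
  # total counts per cell are Poisson with the profile's total mean (60);
  # compare the >50 fraction with the closed-form tail within a CI
  prof <- matrix(6, 10, 1, dimnames = list(sprintf("g%d", 1:10), "A"))
  lay <- data.frame(type = "A", ymin = 0, ymax = 100)
  n <- 4000
  sd0 <- simulate_spatial(n, prof, lay, noise_rate = 0, seed = 8)
  frac <- mean(sd0$cells$total_transcripts > 50)
  p_true <- stats::ppois(50, 60, lower.tail = FALSE)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(frac - p_true), 4 * se)
})

test_that("calcium traces have the documented shape and length", {
  cts <- simulate_calcium(duration_s = 100, rate_hz = 5,
                          event_times_s = list(numeric(0)),
                          drift = 0, noise_sd = 0, seed = 1)
  expect_length(cts$traces[[1]], 500)
  expect_true(all(abs(cts$traces[[1]] - cts$traces[[1]][1]) < 1e-12))
  expect_error(simulate_calcium(event_times_s = list(5), decay_s = 0),
               "decay_s")
  expect_error(simulate_calcium(duration_s = 10,
                                event_times_s = list(50)),
               "within")
})

test_that("cohort datasets round-trip through the MTX + TSV layout", {
  cfg <- cohort_config(n_donors_per_group = 2, n_celltypes = 2,
                       n_cells_per_donor = 30, n_genes = 25, seed = 12)
  sim <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(sim$dataset, d)
  back <- read_cohort(d)
  expect_equal(as.matrix(back$counts), as.matrix(sim$dataset$counts))
  expect_equal(back$cell_meta$cluster, sim$dataset$cell_meta$cluster)
  expect_equal(as.character(back$donor_meta$pathology_group),
               as.character(sim$dataset$donor_meta$pathology_group))
  validate_cohort(back)
  # spatial and calcium round-trips
  prof <- matrix(5, 4, 2, dimnames = list(letters[1:4], c("A", "B")))
  lay <- data.frame(type = c("A", "B"), ymin = c(0, 100), ymax = c(100, 200))
  sp <- simulate_spatial(20, prof, lay, seed = 3)
  write_spatial(sp, d)
  sp2 <- read_spatial(d)
  expect_equal(as.matrix(sp2$counts), as.matrix(sp$counts))
  cts <- simulate_calcium(event_times_s = list(c(1, 2), numeric(0)),
                          noise_sd = 0.02, seed = 2)
  write_calcium(cts, d)
  cts2 <- read_calcium(d)
  expect_equal(cts2$traces$T001, cts$traces$T001, tolerance = 1e-12)
  expect_equal(cts2$rate_hz, cts$rate_hz)
})
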
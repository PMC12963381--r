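#' Configuration for a synthetic donor-structured single-nucleus cohort
#'
#' Defines the generative model for [simulate_cohort()]: a Dirichlet-
#' multinomial draw of per-donor cell-type counts around group-shifted
#' baseline proportions, and per-cell negative-binomial gene counts with a
#' donor-level log-normal random effect, planted condition (differential
#' expression) effects, planted latent-factor co-expression modules, and
#' logistic dropout.
#'
#' Pathology groups are ordered `low < intermediate < high`.
#' `comp_log2fc[k]` is the *total* log2 shift of type `k`'s relative
#' abundance between the high and low groups (the intermediate group gets
#' half the shift). `de_log2fc` is the *per-group-step* log2 change of a
#' planted gene's mean, so both the early (intermediate vs low) and late
#' (high vs intermediate) contrasts carry the same effect.
#'
#' @param n_donors_per_group integer, donors in each of the three pathology
#'   groups (scalar or length-3 vector named low/intermediate/high).
#' @param n_celltypes number of cell types (clusters).
#' @param baseline_props baseline cell-type proportions (sums to 1).
#' @param comp_log2fc per-type log2 abundance shift, high vs low group.
#' @param conc Dirichlet concentration governing donor-to-donor
#'   compositional overdispersion (larger = closer to the group mean).
#' @param n_cells_per_donor cells drawn per donor.
#' @param n_genes number of genes.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param de_log2fc log2 expression change per group step for planted genes.
#' @param de_min_meanlog planted DE genes are drawn only from genes whose
#'   base log-mean is at least this value, so the planted truth is
#'   identifiable under detection-fraction filters (default `log(0.3)`).
#' @param donor_sd SD of the donor-level log-mean random effect.
#' @param nb_dispersion negative-binomial size parameter theta
#'   (variance = mu + mu^2/theta).
#' @param dropout_midpoint log-mean at which detection probability is 0.5.
#' @param dropout_slope slope of the logistic detection curve in log-mean.
#' @param gene_meanlog,gene_sdlog log-normal distribution of gene base means.
#' @param n_modules,module_size,module_strength planted co-expression
#'   modules: number, genes per module, and latent-factor loading in \[0,1\].
#' @param covariate_comp_logit optional named list of per-type logit shifts
#'   attached to donor covariates (currently supports `sex`), for
#'   confounding experiments; `NULL` (default) means covariates carry no
#'   true effect.
#' @param region region label recorded for every cell.
#' @param seed integer seed; fully determines the output.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_donors_per_group = 10,
                          n_celltypes = 8,
                          baseline_props = rep(1 / n_celltypes, n_celltypes),
                          comp_log2fc = rep(0, n_celltypes),
                          conc = 50,
                          n_cells_per_donor = 500,
                          n_genes = 300,
                          n_de_genes = 0,
                          de_log2fc = 0,
                          de_min_meanlog = log(0.3),
                          donor_sd = 0.3,
                          nb_dispersion = 2,
                          dropout_midpoint = -2,
                          dropout_slope = 1,
                          gene_meanlog = log(0.3),
                          gene_sdlog = 1,
                          n_modules = 0,
                          module_size = 50,
                          module_strength = 0.8,
                          covariate_comp_logit = NULL,
                          region = "synthetic",
                          seed = 1L) {
  if (length(n_donors_per_group) == 1) {
    n_donors_per_group <- rep(n_donors_per_group, 3)
  }
  stop_if_not(length(n_donors_per_group) == 3,
              "n_donors_per_group must be scalar or length 3")
  names(n_donors_per_group) <- c("low", "intermediate", "high")
  stop_if_not(abs(sum(baseline_props) - 1) < 1e-9,
              "baseline_props must sum to 1 (tolerance 1e-9)")
  stop_if_not(all(baseline_props > 0), "baseline_props must be positive")
  stop_if_not(length(baseline_props) == n_celltypes,
              "baseline_props length must equal n_celltypes")
  stop_if_not(length(comp_log2fc) == n_celltypes,
              "comp_log2fc length must equal n_celltypes")
  stop_if_not(nb_dispersion > 0, "nb_dispersion must be > 0")
  stop_if_not(conc > 0, "conc must be > 0")
  stop_if_not(all(c(n_celltypes, n_cells_per_donor, n_genes,
                    n_donors_per_group) > 0),
              "count parameters must be positive")
  stop_if_not(module_strength >= 0 && module_strength <= 1,
              "module_strength must lie in [0, 1]")
  if (n_modules > 0) {
    stop_if_not(n_modules * module_size + n_de_genes <= n_genes,
                "modules and DE genes exceed the gene universe")
  }
  structure(list(
    n_donors_per_group = n_donors_per_group,
    n_celltypes = as.integer(n_celltypes),
    baseline_props = baseline_props,
    comp_log2fc = comp_log2fc,
    conc = conc,
    n_cells_per_donor = as.integer(n_cells_per_donor),
    n_genes = as.integer(n_genes),
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc,
    de_min_meanlog = de_min_meanlog,
    donor_sd = donor_sd,
    nb_dispersion = nb_dispersion,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    gene_meanlog = gene_meanlog,
    gene_sdlog = gene_sdlog,
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    module_strength = module_strength,
    covariate_comp_logit = covariate_comp_logit,
    region = region,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

celltype_names <- function(k) sprintf("Ex%d", seq_len(k))

#' Draw donor covariates for a synthetic cohort
#' @keywords internal
#' @noRd
draw_donor_meta <- function(config) {
  n <- config$n_donors_per_group
  groups <- factor(rep(names(n), n),
                   levels = c("low", "intermediate", "high"))
  d <- length(groups)
  data.frame(
    donor_id = sprintf("D%03d", seq_len(d)),
    pathology_group = groups,
    sex = factor(sample(c("F", "M"), d, replace = TRUE)),
    age = round(rnorm(d, 78, 7), 1),
    apoe = factor(sample(c("e33", "e34", "e44"), d, replace = TRUE,
                         prob = c(0.6, 0.3, 0.1))),
    assay = factor(sample(c("v2", "v3"), d, replace = TRUE)),
    rin = round(pmin(10, pmax(4, rnorm(d, 7, 1))), 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-donor cell-type composition counts
#'
#' The compositional half of [simulate_cohort()], exposed on its own because
#' composition testing needs only the donors-by-types count table. Per-donor
#' proportions are Dirichlet around group-shifted baseline proportions
#' (concentration `conc`) and counts are multinomial given the donor total,
#' i.e. counts are Dirichlet-multinomial.
#'
#' @param config a [cohort_config()].
#' @return a `composition_table`: list with `counts` (donors x types integer
#'   matrix), `design` (donor covariates), and `truth` (per-type planted
#'   high-vs-low log2 abundance shifts).
#' @export
simulate_composition <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    donor_meta <- draw_donor_meta(config)
    K <- config$n_celltypes
    types <- celltype_names(K)
    base_logit <- log(config$baseline_props)
    gstep <- (as.integer(donor_meta$pathology_group) - 1) / 2  # 0, .5, 1
    counts <- matrix(0L, nrow(donor_meta), K,
                     dimnames = list(donor_meta$donor_id, types))
    for (d in seq_len(nrow(donor_meta))) {
      eta <- base_logit + config$comp_log2fc * log(2) * gstep[d]
      if (!is.null(config$covariate_comp_logit$sex) &&
          donor_meta$sex[d] == "F") {
        eta <- eta + config$covariate_comp_logit$sex
      }
      p <- exp(eta - max(eta)); p <- p / sum(p)
      g <- rgamma(K, shape = config$conc * p, rate = 1)
      if (sum(g) <= 0) g <- p
      counts[d, ] <- as.integer(rmultinom(1, config$n_cells_per_donor,
                                          g / sum(g)))
    }
    structure(list(counts = counts, design = donor_meta,
                   truth = setNames(config$comp_log2fc, types)),
              class = "composition_table")
  })
}

#' Simulate a donor-structured single-nucleus cohort with known truth
#'
#' Generates sparse gene-by-cell counts with per-cell donor, region and
#' cluster labels and per-donor covariates, following the generative model
#' described in [cohort_config()]. All planted structure (differentially
#' expressed genes, compositional shifts, module memberships) is returned as
#' ground truth for recovery testing.
#'
#' @param config a [cohort_config()].
#' @return list with elements `dataset` (a `cohort_dataset`: `counts` sparse
#'   dgCMatrix genes x cells, `gene_ids`, `cell_meta`, `donor_meta`) and
#'   `truth` (a `ground_truth`: `de_genes` data frame (gene, cluster, sign),
#'   `comp_log2fc`, `module_membership` named integer vector).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  comp <- simulate_composition(config)
  donor_meta <- comp$design
  K <- config$n_celltypes
  types <- celltype_names(K)
  G <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))

  with_seed(sub_seed(config$seed, 1L), {
    base_logmu <- rnorm(G, config$gene_meanlog, config$gene_sdlog)

    # planted DE genes: cycled over clusters, alternating sign
    de_genes <- data.frame(gene = character(0), cluster = character(0),
                           sign = integer(0), stringsAsFactors = FALSE)
    de_effect <- matrix(0, G, K)  # per-step log-mean shift, gene x cluster
    if (config$n_de_genes > 0) {
      pool <- which(base_logmu >= config$de_min_meanlog)
      stop_if_not(length(pool) >= config$n_de_genes,
                  "not enough sufficiently expressed genes for n_de_genes")
      idx <- sample(pool, config$n_de_genes)
      sgn <- rep_len(c(1L, -1L), config$n_de_genes)
      clus <- rep_len(seq_len(K), config$n_de_genes)
      de_genes <- data.frame(gene = gene_ids[idx], cluster = types[clus],
                             sign = sgn, stringsAsFactors = FALSE)
      de_effect[cbind(idx, clus)] <- sgn * config$de_log2fc * log(2)
    }

    # planted modules: disjoint blocks drawn from non-DE genes, with a
    # graded loading profile so each module has a distinguished hub gene
    module_membership <- integer(0)
    module_hubs <- character(0)
    mod_loading <- rep(0, G)
    mod_of_gene <- rep(0L, G)
    if (config$n_modules > 0) {
      pool <- setdiff(seq_len(G), which(rowSums(abs(de_effect)) > 0))
      picked <- sample(pool, config$n_modules * config$module_size)
      mod_of_gene[picked] <- rep(seq_len(config$n_modules),
                                 each = config$module_size)
      # hub carries a clearly separated top loading; members share a
      # common base mean so kME ordering reflects loadings, not depth
      grade <- c(1, seq(0.8, 0.55, length.out = config$module_size - 1))
      mod_loading[picked] <- config$module_strength *
        rep(grade, config$n_modules)
      base_logmu[picked] <- log(1)
      module_membership <- setNames(mod_of_gene[picked], gene_ids[picked])
      module_hubs <- setNames(
        gene_ids[picked[seq(1, by = config$module_size,
                            length.out = config$n_modules)]],
        seq_len(config$n_modules))
    }

    donor_eff <- rnorm(nrow(donor_meta), 0, config$donor_sd)
  })

  blocks <- vector("list", nrow(donor_meta))
  cell_meta_list <- vector("list", nrow(donor_meta))
  gstep <- as.integer(donor_meta$pathology_group) - 1  # 0, 1, 2 group steps
  for (d in seq_len(nrow(donor_meta))) {
    blocks_d <- with_seed(sub_seed(config$seed, 2L, d), {
      nd <- comp$counts[d, ]
      ncell <- sum(nd)
      cl <- rep(seq_len(K), nd)
      # log mean: gene base + donor effect + DE effect (per group step)
      logmu <- matrix(base_logmu + donor_eff[d], G, ncell)
      if (config$n_de_genes > 0) {
        logmu <- logmu + de_effect[, cl, drop = FALSE] * gstep[d]
      }
      if (config$n_modules > 0) {
        z <- matrix(rnorm(config$n_modules * ncell), config$n_modules, ncell)
        logmu <- logmu + (mod_loading * z[pmax(mod_of_gene, 1L), ,
                                          drop = FALSE])
      }
      mu <- exp(logmu)
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                    G, ncell)
      pdet <- plogis(config$dropout_slope * (logmu - config$dropout_midpoint))
      cnt <- cnt * matrix(rbinom(length(pdet), 1L, pdet), G, ncell)
      list(counts = methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                "CsparseMatrix"),
           cluster = types[cl])
    })
    blocks[[d]] <- blocks_d$counts
    cell_meta_list[[d]] <- data.frame(
      donor_id = donor_meta$donor_id[d],
      region = config$region,
      cluster = blocks_d$cluster,
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(cbind, blocks)
  cell_meta <- do.call(rbind, cell_meta_list)
  cell_meta$cell_id <- sprintf("C%06d", seq_len(nrow(cell_meta)))
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_meta$cell_id
  cell_meta$n_genes_detected <- Matrix::colSums(counts > 0)
  cell_meta$total_counts <- Matrix::colSums(counts)
  mito <- grepl("^MT-", gene_ids)
  cell_meta$mito_fraction <- if (any(mito)) {
    as.numeric(Matrix::colSums(counts[mito, , drop = FALSE]) /
                 pmax(cell_meta$total_counts, 1))
  } else 0
  cell_meta <- cell_meta[, c("cell_id", "donor_id", "region", "cluster",
                             "n_genes_detected", "mito_fraction",
                             "total_counts")]
  rownames(cell_meta) <- NULL

  ds <- structure(list(counts = counts, gene_ids = gene_ids,
                       cell_meta = cell_meta, donor_meta = donor_meta),
                  class = "cohort_dataset")
  truth <- structure(list(de_genes = de_genes,
                          comp_log2fc = comp$truth,
                          module_membership = module_membership,
                          module_hubs = module_hubs),
                     class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d genes x %d cells, %d donors, %d clusters\n",
              nrow(x$counts), ncol(x$counts), nrow(x$donor_meta),
              length(unique(x$cell_meta$cluster))))
  invisible(x)
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table: %d donors x %d cell types\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Validate the internal consistency of a cohort dataset
#'
#' Checks the invariants that downstream stages rely on: every cell's donor
#' exists in the donor table, detected-gene counts match the matrix, and
#' mitochondrial fractions lie in \[0, 1\].
#'
#' @param ds a `cohort_dataset`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_cohort <- function(ds) {
  stopifnot(inherits(ds, "cohort_dataset"))
  stop_if_not(all(ds$cell_meta$donor_id %in% ds$donor_meta$donor_id),
              "cell donor_id missing from donor_meta")
  ngd <- Matrix::colSums(ds$counts > 0)
  stop_if_not(all(ngd == ds$cell_meta$n_genes_detected),
              "n_genes_detected inconsistent with counts")
  stop_if_not(all(ds$cell_meta$mito_fraction >= 0 &
                    ds$cell_meta$mito_fraction <= 1),
              "mito_fraction outside [0, 1]")
  invisible(TRUE)
}
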
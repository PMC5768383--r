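#' Configuration for the paired-cohort simulator
#'
#' Defines the study conditions of a two-cohort experiment with planted,
#' cross-cohort-shared co-expression modules. Defaults mirror a two-cancer
#' comparison at HPV16-positive scale: cohort A with 13 cancer vs 14 normal
#' samples, cohort B with 8 vs 8, eight modules of 40 genes each.
#'
#' Module genes follow a single latent factor per module:
#' `g = factor_loading * u_m + sqrt(1 - factor_loading^2) * eps`, with
#' `u_m` a per-sample module factor and `eps` i.i.d. noise, both standard
#' normal, the whole profile scaled by `noise_sd` and shifted to `baseline`.
#' The population correlation between two genes of the same module is thus
#' `factor_loading^2`. Background genes are pure noise. In cohort B a
#' `rewire_fraction` of each module's genes are re-drawn as background
#' noise, degrading cross-cohort module preservation; at 1 the module has no
#' structure left in B.
#'
#' Optionally, modules can be grouped into meta-branches whose latent
#' factors are correlated (`branch_cor`), which plants a two-level eigengene
#' network like the two major eigengene branches seen in real tumor cohorts.
#'
#' @param n_genes Total genes, planted modules plus background.
#' @param module_sizes Integer vector of planted module sizes (may be empty).
#' @param n_cancer_a,n_normal_a,n_cancer_b,n_normal_b Sample counts per
#'   cohort and group.
#' @param factor_loading In (0, 1]; within-module correlation strength
#'   (population within-module correlation = `factor_loading^2`).
#' @param de_fraction In \[0, 1\]; fraction of each module's genes given a
#'   cancer-vs-normal mean shift (sampled per module without replacement).
#' @param de_effect Non-negative shift, in log-intensity units, added to
#'   cancer samples of differentially expressed genes.
#' @param noise_sd Positive scale of gene profiles.
#' @param rewire_fraction In \[0, 1\]; scalar or one value per module.
#' @param baseline Mean log intensity of every gene.
#' @param branches Optional integer vector, one entry per module, assigning
#'   modules to meta-branches; `NULL` for independent module factors.
#' @param branch_cor In \[0, 1); correlation of module factors within a
#'   meta-branch.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 400,
                       module_sizes = rep(40L, 8),
                       n_cancer_a = 13, n_normal_a = 14,
                       n_cancer_b = 8, n_normal_b = 8,
                       factor_loading = 0.9,
                       de_fraction = 0.5,
                       de_effect = 1,
                       noise_sd = 1,
                       rewire_fraction = 0,
                       baseline = 8,
                       branches = NULL,
                       branch_cor = 0,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, module_sizes = as.integer(module_sizes),
    n_cancer_a = n_cancer_a, n_normal_a = n_normal_a,
    n_cancer_b = n_cancer_b, n_normal_b = n_normal_b,
    factor_loading = factor_loading, de_fraction = de_fraction,
    de_effect = de_effect, noise_sd = noise_sd,
    rewire_fraction = rewire_fraction, baseline = baseline,
    branches = branches, branch_cor = branch_cor, seed = as.integer(seed)
  )
  fail <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  scalar_num <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  if (!scalar_num(n_genes) || n_genes < 0) fail("n_genes", "must be >= 0")
  if (length(cfg$module_sizes) && any(cfg$module_sizes < 2)) {
    fail("module_sizes", "each planted module needs >= 2 genes")
  }
  if (sum(cfg$module_sizes) > n_genes) {
    fail("module_sizes", "sum of module sizes exceeds n_genes")
  }
  for (f in c("n_cancer_a", "n_normal_a", "n_cancer_b", "n_normal_b")) {
    if (!scalar_num(cfg[[f]]) || cfg[[f]] < 2) fail(f, "needs >= 2 samples")
  }
  if (!scalar_num(factor_loading) || factor_loading <= 0 ||
      factor_loading > 1) {
    fail("factor_loading", "must be in (0, 1]")
  }
  if (!scalar_num(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    fail("de_fraction", "must be in [0, 1]")
  }
  if (!scalar_num(de_effect) || de_effect < 0) {
    fail("de_effect", "must be >= 0")
  }
  if (!scalar_num(noise_sd) || noise_sd <= 0) fail("noise_sd", "must be > 0")
  if (!is.numeric(cfg$rewire_fraction) ||
      any(cfg$rewire_fraction < 0 | cfg$rewire_fraction > 1)) {
    fail("rewire_fraction", "must be in [0, 1]")
  }
  if (!length(cfg$rewire_fraction) %in% c(1L, length(cfg$module_sizes)) &&
      length(cfg$module_sizes) > 0) {
    fail("rewire_fraction", "must be scalar or one value per module")
  }
  if (!is.null(branches)) {
    if (length(branches) != length(cfg$module_sizes)) {
      fail("branches", "needs one branch id per module")
    }
  }
  if (!scalar_num(branch_cor) || branch_cor < 0 || branch_cor >= 1) {
    fail("branch_cor", "must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

simulate_cohort <- function(cfg, n_cancer, n_normal, prefix, truth) {
  n_samples <- n_cancer + n_normal
  sample_ids <- c(
    sprintf("%s_cancer_%02d", prefix, seq_len(n_cancer)),
    sprintf("%s_normal_%02d", prefix, seq_len(n_normal))
  )
  groups <- stats::setNames(
    rep(c("cancer", "normal"), c(n_cancer, n_normal)), sample_ids)
  n_modules <- length(cfg$module_sizes)
  # module factors, optionally correlated within meta-branches
  factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  if (!is.null(cfg$branches) && cfg$branch_cor > 0 && n_modules > 0) {
    for (b in unique(cfg$branches)) {
      idx <- which(cfg$branches == b)
      shared <- stats::rnorm(n_samples)
      factors[idx, ] <- sqrt(cfg$branch_cor) *
        matrix(shared, length(idx), n_samples, byrow = TRUE) +
        sqrt(1 - cfg$branch_cor) * factors[idx, , drop = FALSE]
    }
  }
  # standardize each realized factor: its scale is arbitrary, and fixing
  # it pins the within-module correlation at factor_loading^2 regardless
  # of the luck of the per-cohort factor draw
  if (n_modules > 0) {
    factors <- t(scale(t(factors)))
  }
  lam <- cfg$factor_loading
  vals <- matrix(stats::rnorm(cfg$n_genes * n_samples), cfg$n_genes, n_samples)
  for (m in seq_len(n_modules)) {
    rows <- which(truth$module == sprintf("M%d", m))
    vals[rows, ] <- lam *
      matrix(factors[m, ], length(rows), n_samples, byrow = TRUE) +
      sqrt(1 - lam^2) * vals[rows, , drop = FALSE]
  }
  vals <- cfg$baseline + cfg$noise_sd * vals
  de <- truth$is_de_a
  if (any(de) && cfg$de_effect > 0) {
    vals[de, seq_len(n_cancer)] <- vals[de, seq_len(n_cancer)] + cfg$de_effect
  }
  dimnames(vals) <- list(truth$gene_id, sample_ids)
  expression_study(vals, groups, name = paste0("cohort_", prefix))
}

#' Simulate a pair of expression studies with planted consensus modules
#'
#' Generates two cohorts that share the same planted module memberships,
#' with independent samples per cohort, plus a known truth table. In cohort
#' B, a `rewire_fraction` of each module's genes are re-drawn as background
#' noise (and lose their differential-expression shift there), which
#' degrades module preservation between the cohorts.
#'
#' @param config A [sim_config()].
#' @return A list with elements `study_a`, `study_b` (both
#'   [expression_study()]) and `truth`, a tibble with columns `gene_id`,
#'   `module` (`"M1"`, ... or `"background"`), `is_de_a`, `is_de_b`,
#'   `rewired`.
#' @export
#' @examples
#' sim <- simulate_pair(sim_config(n_genes = 60, module_sizes = c(20, 20),
#'   seed = 1))
#' sim$study_a
#' dplyr::count(sim$truth, module)
simulate_pair <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  cfg <- config
  # Staged sub-seeds: truth, cohort A, cohort B base, rewire mask, redraw.
  # The rewire mask and redraw come last with their own streams, so runs
  # that differ only in rewire_fraction share the same truth, cohort A and
  # base cohort B draws (common random numbers across degradation levels).
  stage_seed <- withr::with_seed(cfg$seed,
    sample.int(.Machine$integer.max - 1L, 5L))
  n_modules <- length(cfg$module_sizes)
  gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  module <- rep("background", cfg$n_genes)
  pos <- 0L
  for (m in seq_len(n_modules)) {
    module[pos + seq_len(cfg$module_sizes[m])] <- sprintf("M%d", m)
    pos <- pos + cfg$module_sizes[m]
  }
  # per-module DE genes, sampled without replacement
  is_de <- rep(FALSE, cfg$n_genes)
  withr::with_seed(stage_seed[1], {
    for (m in seq_len(n_modules)) {
      rows <- which(module == sprintf("M%d", m))
      n_de <- round(cfg$de_fraction * length(rows))
      if (n_de > 0) is_de[sample(rows, n_de)] <- TRUE
    }
  })
  rw <- rep(cfg$rewire_fraction, length.out = max(n_modules, 1L))
  rewired <- rep(FALSE, cfg$n_genes)
  withr::with_seed(stage_seed[4], {
    for (m in seq_len(n_modules)) {
      rows <- which(module == sprintf("M%d", m))
      n_rw <- round(rw[m] * length(rows))
      if (n_rw > 0) rewired[sample(rows, n_rw)] <- TRUE
    }
  })
  truth <- tibble::tibble(
    gene_id = gene_id, module = module,
    is_de_a = is_de, is_de_b = is_de & !rewired,
    rewired = rewired
  )
  study_a <- withr::with_seed(stage_seed[2],
    simulate_cohort(cfg, cfg$n_cancer_a, cfg$n_normal_a, "A", truth))
  study_b <- withr::with_seed(stage_seed[3],
    simulate_cohort(cfg, cfg$n_cancer_b, cfg$n_normal_b, "B", truth))
  if (any(rewired)) {
    redraw <- withr::with_seed(stage_seed[5],
      matrix(stats::rnorm(sum(rewired) * ncol(study_b$values)),
        sum(rewired), ncol(study_b$values)))
    # rewired genes become background noise in B and lose their DE shift
    # there (is_de_b is FALSE for them)
    vals <- study_b$values
    vals[rewired, ] <- cfg$baseline + cfg$noise_sd * redraw
    study_b <- expression_study(vals, sample_groups(study_b),
      name = study_b$name)
  }
  list(study_a = study_a, study_b = study_b, truth = truth)
}

#' Write a simulated pair to disk as TSV fixtures
#'
#' Emits `expr_a.tsv`, `meta_a.tsv`, `expr_b.tsv`, `meta_b.tsv` and
#' `truth.tsv` in the dialect read by [read_expression_tsv()]. Numeric
#' values round-trip losslessly, and a fixed simulation seed yields
#' byte-identical files across runs.
#'
#' @param study_a,study_b [expression_study()] objects.
#' @param truth Truth tibble from [simulate_pair()].
#' @param directory Writable output directory (created if needed).
#' @return Named character vector of the five file paths.
#' @export
write_fixture <- function(study_a, study_b, truth, directory) {
  if (!is.character(directory) || length(directory) != 1 ||
      !nzchar(directory)) {
    stop("`directory` must be a non-empty path", call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(
    expr_a = file.path(directory, "expr_a.tsv"),
    meta_a = file.path(directory, "meta_a.tsv"),
    expr_b = file.path(directory, "expr_b.tsv"),
    meta_b = file.path(directory, "meta_b.tsv"),
    truth = file.path(directory, "truth.tsv")
  )
  write_matrix(study_a$values, paths[["expr_a"]])
  write_matrix(study_b$values, paths[["expr_b"]])
  write_meta <- function(meta, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("sample_id\tgroup",
      paste(meta$sample_id, meta$group, sep = "\t")), con, sep = "\n")
  }
  write_meta(study_a$metadata, paths[["meta_a"]])
  write_meta(study_b$metadata, paths[["meta_b"]])
  con <- file(paths[["truth"]], "wb")
  writeLines(c("gene_id\tmodule\tis_de_a\tis_de_b",
    paste(truth$gene_id, truth$module,
      ifelse(truth$is_de_a, "TRUE", "FALSE"),
      ifelse(truth$is_de_b, "TRUE", "FALSE"), sep = "\t")), con, sep = "\n")
  close(con)
  paths
}
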
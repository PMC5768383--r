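#' Eigengene-network preservation between two cohorts
#'
#' For modules i and j with eigengenes `Ei`, `Ej` in cohorts A and B, the
#' pairwise preservation is
#' `P_ij = 1 - |cor(Ei(A), Ej(A)) - cor(Ei(B), Ej(B))| / 2`,
#' which is 1 when the two modules relate identically in both cohorts and 0
#' when their correlations are maximally discordant (+1 vs -1). The
#' per-module preservation is `D_i = mean_{j != i} P_ij` and the overall
#' preservation `D` is the mean of the `D_i` (equivalently the mean
#' off-diagonal of P).
#'
#' @param eigs_a,eigs_b `eigengene_set` objects from [module_eigengenes()],
#'   one per cohort, covering the same module colors.
#' @return A `preservation_result`: list with `P` (module x module matrix,
#'   unit diagonal), `module_d` (tibble `module`, `d`), `overall_d`,
#'   `cohorts`.
#' @export
preservation_matrix <- function(eigs_a, eigs_b) {
  stopifnot(inherits(eigs_a, "eigengene_set"),
    inherits(eigs_b, "eigengene_set"))
  only_a <- setdiff(eigs_a$modules, eigs_b$modules)
  only_b <- setdiff(eigs_b$modules, eigs_a$modules)
  if (length(only_a) || length(only_b)) {
    stop("modules present in one cohort only: ",
      paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }
  mods <- eigs_a$modules
  if (length(mods) < 2) stop("need >= 2 shared modules", call. = FALSE)
  cor_a <- stats::cor(eigs_a$E[, mods, drop = FALSE])
  cor_b <- stats::cor(eigs_b$E[, mods, drop = FALSE])
  p <- 1 - abs(cor_a - cor_b) / 2
  diag(p) <- 1
  d_i <- vapply(seq_along(mods), function(i) mean(p[i, -i]), numeric(1))
  structure(
    list(
      P = p,
      module_d = tibble::tibble(module = mods, d = d_i),
      overall_d = mean(d_i),
      cohorts = c(eigs_a$cohort, eigs_b$cohort)
    ),
    class = "preservation_result"
  )
}

#' @export
print.preservation_result <- function(x, ...) {
  cat(sprintf("<preservation_result %s vs %s>  %d modules, overall D = %.2f\n",
    x$cohorts[1], x$cohorts[2], nrow(x$P), x$overall_d))
  invisible(x)
}

#' Overall preservation from per-module values
#'
#' The unweighted mean of the per-module preservation indices `D_i`,
#' reported at full precision together with the conventional 2-decimal
#' rounding.
#'
#' @param d_values Numeric vector of per-module preservation indices.
#' @return List with `value` (full precision) and `rounded` (2 decimals).
#' @export
#' @examples
#' overall_preservation(c(0.811, 0.938, 0.933, 0.92, 0.835, 0.963, 0.92,
#'   0.919))
overall_preservation <- function(d_values) {
  if (!length(d_values)) stop("need at least one per-module value",
    call. = FALSE)
  if (!is.numeric(d_values) || anyNA(d_values)) {
    stop("`d_values` must be numeric without missing values", call. = FALSE)
  }
  v <- mean(d_values)
  list(value = v, rounded = round(v, 2))
}

#' Preservation as a function of cross-cohort degradation
#'
#' Validation harness for the preservation statistic: simulates paired
#' cohorts at several `rewire_fraction` levels and several seeds per level,
#' computes the eigengenes of the planted modules in each cohort, and
#' reports the mean overall preservation D per level. Modules are taken
#' from the simulation truth (`modules = "truth"`, the default) so the
#' measured trend isolates the statistic's response to cross-cohort
#' degradation from module-detection noise; `modules = "detect"` instead
#' detects modules on the reference cohort's (A) own topological-overlap
#' dissimilarity. The same seeds are reused across levels, which — together
#' with the simulator's staged random streams — makes the comparison across
#' levels a paired one. Expected D never increases with rewiring.
#'
#' @param config Base [sim_config()]; its `rewire_fraction` and `seed` are
#'   overridden per run.
#' @param rewire_levels Numeric vector of >= 2 rewire fractions.
#' @param seeds Integer vector of >= 3 seeds per level.
#' @param modules `"truth"` (default) or `"detect"`.
#' @param beta,mode,height,min_size Network and cut parameters (used only
#'   for `modules = "detect"`).
#' @return Tibble with `rewire_fraction`, `mean_d`, `n_seeds`.
#' @export
preservation_trend <- function(config, rewire_levels = c(0, 0.5, 1),
                               seeds = 1:3, modules = c("truth", "detect"),
                               beta = 6, mode = "unsigned",
                               height = 0.95, min_size = 25) {
  modules <- match.arg(modules)
  if (length(rewire_levels) < 2) stop("need >= 2 rewire levels",
    call. = FALSE)
  if (length(seeds) < 3) stop("need >= 3 seeds per level", call. = FALSE)
  one <- function(level, seed) {
    cfg <- config
    cfg$rewire_fraction <- level
    cfg$seed <- as.integer(seed)
    tryCatch({
      sim <- simulate_pair(cfg)
      if (modules == "truth") {
        mem <- stats::setNames(
          ifelse(sim$truth$module == "background", "grey",
            sim$truth$module),
          sim$truth$gene_id)
        asn <- assign_colors(mem)
        pres <- preservation_matrix(
          module_eigengenes(sim$study_a, asn),
          module_eigengenes(sim$study_b, asn))
        pres$overall_d
      } else {
        fit <- run_consensus_pipeline(sim$study_a, sim$study_b,
          beta = beta, mode = mode, height = height, min_size = min_size,
          reference = "a")
        fit$preservation$overall_d
      }
    }, error = function(e) {
      stop(sprintf("pipeline failed at rewire %g, seed %d: %s",
        level, seed, conditionMessage(e)), call. = FALSE)
    })
  }
  purrr::map_dfr(rewire_levels, function(level) {
    ds <- vapply(seeds, function(s) one(level, s), numeric(1))
    tibble::tibble(rewire_fraction = level, mean_d = mean(ds),
      n_seeds = length(seeds))
  })
}
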
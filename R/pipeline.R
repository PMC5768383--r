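#' Run the consensus-module pipeline on a pair of cohorts
#'
#' Chains the standard steps: per-cohort correlation, soft-threshold
#' adjacency, topological overlap, a clustering dissimilarity, average-
#' linkage dendrogram, fixed-height cut with minimum module size, per-cohort
#' module eigengenes, eigengene networks, and the cross-cohort preservation
#' statistic.
#'
#' By default the dendrogram is built on the consensus dissimilarity
#' (`reference = "consensus"`, elementwise `combiner` of the two TOMs).
#' `reference = "a"` instead defines modules on cohort A's own
#' dissimilarity and evaluates their preservation in B — the classic
#' reference/test design used by the degradation harness
#' [preservation_trend()].
#'
#' @param study_a,study_b [expression_study()] cohorts.
#' @param genes Optional gene subset (e.g. hub genes from
#'   [consensus_connectivity_filter()]); default: all genes shared by both
#'   studies, in cohort-A order.
#' @param beta,mode Soft-threshold parameters for [adjacency()].
#' @param combiner Consensus combiner for [consensus_dissimilarity()].
#' @param height,min_size Fixed-height cut parameters for [static_cut()].
#' @param reference `"consensus"` (default) or `"a"`.
#' @return A `consensus_fit`: list with `assignment`
#'   (`module_assignment`), `tree` (`hclust`), `eigengenes_a`,
#'   `eigengenes_b` (`eigengene_set`), `network_a`, `network_b`
#'   (`eigengene_network`, `NULL` if < 2 modules), `preservation`
#'   (`preservation_result`, `NULL` if < 2 modules) and `params`.
#' @export
run_consensus_pipeline <- function(study_a, study_b, genes = NULL,
                                   beta = 6, mode = "unsigned",
                                   combiner = "min",
                                   height = 0.95, min_size = 25,
                                   reference = c("consensus", "a")) {
  reference <- match.arg(reference)
  if (is.null(genes)) {
    genes <- intersect(gene_ids(study_a), gene_ids(study_b))
  }
  if (length(genes) < 2) stop("need >= 2 shared genes", call. = FALSE)
  tom_a <- topological_overlap(
    adjacency(correlation_matrix(study_a, genes), beta = beta, mode = mode))
  tom_b <- topological_overlap(
    adjacency(correlation_matrix(study_b, genes), beta = beta, mode = mode))
  dissim <- if (reference == "consensus") {
    consensus_dissimilarity(tom_a, tom_b, combiner = combiner)
  } else {
    d <- 1 - tom_a
    diag(d) <- 0
    d
  }
  tree <- average_linkage_tree(dissim)
  assignment <- static_cut(tree, height = height, min_size = min_size)
  n_mod <- length(assignment$colors)
  eigs_a <- eigs_b <- net_a <- net_b <- pres <- NULL
  if (n_mod >= 1) {
    eigs_a <- module_eigengenes(study_a, assignment)
    eigs_b <- module_eigengenes(study_b, assignment)
  }
  if (n_mod >= 2) {
    net_a <- eigengene_network(eigs_a)
    net_b <- eigengene_network(eigs_b)
    pres <- preservation_matrix(eigs_a, eigs_b)
  }
  structure(
    list(
      assignment = assignment, tree = tree,
      eigengenes_a = eigs_a, eigengenes_b = eigs_b,
      network_a = net_a, network_b = net_b,
      preservation = pres,
      params = list(beta = beta, mode = mode, combiner = combiner,
        height = height, min_size = min_size, reference = reference,
        n_genes = length(genes))
    ),
    class = "consensus_fit"
  )
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat(sprintf(
    "<consensus_fit>  %d genes -> %d modules (grey: %d)\n",
    x$params$n_genes, length(x$assignment$colors),
    sum(x$assignment$assignment$module == "grey")))
  if (!is.null(x$preservation)) {
    cat(sprintf("  overall preservation D = %.3f\n",
      x$preservation$overall_d))
  }
  invisible(x)
}
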
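mw_one <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  all_vals <- c(x, y)
  if (max(all_vals) == min(all_vals)) {
    # both groups constant and equal: U sits at its null mean
    return(c(statistic = n1 * n2 / 2, p_value = 1))
  }
  r <- rank(all_vals)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(all_vals))
  if (!ties && min(n1, n2) <= 8) {
    # exact two-sided p from the null distribution of U
    p <- if (u > n1 * n2 / 2) {
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, n1, n2)
    }
    p <- min(2 * p, 1)
  } else {
    n <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(c(statistic = u, p_value = 1))
    z <- u - n1 * n2 / 2
    z <- z - sign(z) * 0.5  # continuity correction
    p <- min(2 * stats::pnorm(-abs(z / sqrt(sigma2))), 1)
  }
  c(statistic = u, p_value = p)
}

#' Mann-Whitney differential-expression screen
#'
#' Tests every gene for a cancer-vs-normal location shift with the two-sided
#' Mann-Whitney U test. The p-value is exact (full null distribution of U)
#' when the smaller group has at most 8 samples and the gene has no tied
#' values; otherwise the tie-corrected normal approximation with continuity
#' correction is used — matching `wilcox.test()` conventions.
#'
#' @param study An [expression_study()]; both groups need >= 2 samples.
#' @param alpha Significance threshold; a gene is significant when its
#'   (optionally adjusted) p-value is `< alpha`.
#' @param adjust `"none"` (default) or `"bh"` for Benjamini-Hochberg
#'   adjustment before thresholding.
#' @return A `de_result`: list with `table` (tibble: `gene_id`, `statistic`
#'   = U for cancer over normal, `p_value`, `p_adjusted` if requested,
#'   `significant`), `alpha`, `adjust` and the study `name`.
#' @export
mann_whitney_de <- function(study, alpha = 0.05, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(study, "expression_study"))
  grp <- sample_groups(study)
  if (sum(grp == "cancer") < 2 || sum(grp == "normal") < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  ca <- study$values[, grp == "cancer", drop = FALSE]
  no <- study$values[, grp == "normal", drop = FALSE]
  res <- vapply(seq_len(nrow(ca)), function(i) mw_one(ca[i, ], no[i, ]),
    c(statistic = 0, p_value = 0))
  tab <- tibble::tibble(
    gene_id = gene_ids(study),
    statistic = unname(res["statistic", ]),
    p_value = unname(res["p_value", ])
  )
  if (adjust == "bh") {
    tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
    tab$significant <- tab$p_adjusted < alpha
  } else {
    tab$significant <- tab$p_value < alpha
  }
  structure(
    list(table = tab, alpha = alpha, adjust = adjust, name = study$name),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result '%s'>  %d genes, %d significant at alpha = %g%s\n",
    x$name, nrow(x$table), sum(x$table$significant), x$alpha,
    if (x$adjust == "bh") " (BH-adjusted)" else ""))
  invisible(x)
}

#' Significant genes of a DE result
#' @param de A `de_result` from [mann_whitney_de()].
#' @return Character vector of significant gene ids, in study order.
#' @export
significant_genes <- function(de) {
  stopifnot(inherits(de, "de_result"))
  de$table$gene_id[de$table$significant]
}

#' Intersect two cohorts' significant gene sets
#'
#' Returns the genes significant in both cohorts (in cohort-A order) plus a
#' summary of the per-cohort agreement rates (`n_common / n_sig`).
#'
#' @param de_a,de_b `de_result` objects computed on overlapping gene
#'   universes.
#' @return List with `genes` (character vector) and `summary`, a one-row
#'   tibble: `n_sig_a`, `n_sig_b`, `n_common`, `rate_a`, `rate_b`.
#' @export
common_de_genes <- function(de_a, de_b) {
  stopifnot(inherits(de_a, "de_result"), inherits(de_b, "de_result"))
  if (!length(intersect(de_a$table$gene_id, de_b$table$gene_id))) {
    stop("the two results share no genes (disjoint universes)",
      call. = FALSE)
  }
  sig_a <- significant_genes(de_a)
  sig_b <- significant_genes(de_b)
  common <- sig_a[sig_a %in% sig_b]
  rate <- function(n_common, n_sig, cohort) {
    if (n_sig == 0) {
      warning("no significant genes in cohort ", cohort,
        "; rate reported as 0", call. = FALSE)
      return(0)
    }
    n_common / n_sig
  }
  summary <- tibble::tibble(
    n_sig_a = length(sig_a), n_sig_b = length(sig_b),
    n_common = length(common),
    rate_a = rate(length(common), length(sig_a), "A"),
    rate_b = rate(length(common), length(sig_b), "B")
  )
  list(genes = common, summary = summary)
}

#' Consensus-connectivity hub-gene filter
#'
#' For each cohort, computes each gene's soft-threshold network connectivity
#' `k_i = sum_j a_ij` (diagonal excluded) from the cohort's adjacency, takes
#' the consensus connectivity `min(k_i^A, k_i^B)`, and keeps the `n_keep`
#' genes with the largest consensus connectivity. Ties are broken by
#' lexicographic gene id, making the result invariant to input gene order.
#'
#' @param study_a,study_b [expression_study()] cohorts.
#' @param genes Genes to rank; must be present in both studies.
#' @param n_keep Number of hub genes to keep (`<= length(genes)`).
#' @param beta Soft-threshold power passed to [adjacency()].
#' @param mode `"unsigned"` or `"signed"` adjacency.
#' @return Character vector of `n_keep` gene ids, ordered by decreasing
#'   consensus connectivity.
#' @export
consensus_connectivity_filter <- function(study_a, study_b, genes, n_keep,
                                          beta = 6,
                                          mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  missing_a <- setdiff(genes, gene_ids(study_a))
  missing_b <- setdiff(genes, gene_ids(study_b))
  if (length(missing_a) || length(missing_b)) {
    stop("genes absent from a study: ",
      paste(utils::head(unique(c(missing_a, missing_b)), 5), collapse = ", "),
      call. = FALSE)
  }
  if (n_keep > length(genes)) {
    stop("n_keep (", n_keep, ") exceeds number of genes (", length(genes),
      ")", call. = FALSE)
  }
  k_of <- function(study) {
    a <- adjacency(correlation_matrix(study, genes), beta = beta, mode = mode)
    rowSums(a) - 1
  }
  k_cons <- pmin(k_of(study_a), k_of(study_b))
  ord <- order(-k_cons, names(k_cons))
  names(k_cons)[ord][seq_len(n_keep)]
}
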
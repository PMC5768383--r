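#' Gene-gene Pearson correlation matrix
#'
#' Correlations are computed across all samples of the study (cancer and
#' normal together), since module structure is defined on the whole cohort.
#' Constant genes, whose correlation is undefined, get correlation 0 to all
#' other genes (with a warning) and 1 to themselves.
#'
#' @param study An [expression_study()] with >= 3 samples.
#' @param genes Optional subset (and order) of genes; default all.
#' @return Symmetric genes x genes correlation matrix.
#' @export
correlation_matrix <- function(study, genes = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 3) {
    stop("need at least 3 samples to estimate correlations", call. = FALSE)
  }
  if (is.null(genes)) genes <- gene_ids(study)
  missing <- setdiff(genes, gene_ids(study))
  if (length(missing)) {
    stop("genes not in study: ", paste(utils::head(missing, 5),
      collapse = ", "), call. = FALSE)
  }
  x <- t(study$values[genes, , drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("constant genes set to zero correlation: ",
      paste(utils::head(genes[sds == 0], 5), collapse = ", "),
      call. = FALSE)
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Soft-threshold adjacency
#'
#' Raises correlation-based similarity to a power so that strong
#' co-expression dominates without a hard cutoff. Unsigned:
#' `a = |cor|^beta`; signed: `a = ((1 + cor)/2)^beta`.
#'
#' @param cor_mat Symmetric correlation matrix.
#' @param beta Soft power, `>= 1` (`beta = 1`, unsigned recovers `|cor|`).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return Adjacency matrix in \[0, 1\] with unit diagonal and attributes
#'   `beta`, `mode`.
#' @export
adjacency <- function(cor_mat, beta = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1) {
    stop("`beta` must be a single number >= 1", call. = FALSE)
  }
  a <- if (mode == "unsigned") abs(cor_mat)^beta else ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "mode") <- mode
  a
}

#' Topological overlap matrix
#'
#' The topological overlap between genes i and j combines their direct
#' adjacency with the adjacency they share through common neighbors:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`. The diagonal is set to 1 by convention; if a
#' denominator is exactly 0 (fully isolated pair) the overlap is 0.
#'
#' @param adj Adjacency matrix from [adjacency()].
#' @return Symmetric TOM with entries in \[0, 1\] and unit diagonal.
#' @export
topological_overlap <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  a <- adj
  diag(a) <- 0
  l <- a %*% a           # L_ij: u = i, j terms vanish with zero diagonal
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  tom <- (l + a) / denom
  tom[denom == 0] <- 0
  tom <- (tom + t(tom)) / 2  # symmetrize fp noise from matrix product
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Consensus dissimilarity of two cohort networks
#'
#' Combines the two cohorts' topological overlap matrices elementwise —
#' `min` (default, the conservative consensus: a gene pair is only as
#' similar as it is in its weaker cohort) or `mean` — and returns
#' `1 - consensusTOM` with a zero diagonal. This is the dissimilarity the
#' consensus dendrogram is built on.
#'
#' @param tom_a,tom_b TOM matrices over identical gene sets in identical
#'   order.
#' @param combiner `"min"` (default) or `"mean"`.
#' @return Symmetric dissimilarity matrix in \[0, 1\], zero diagonal.
#' @export
consensus_dissimilarity <- function(tom_a, tom_b,
                                    combiner = c("min", "mean")) {
  combiner <- match.arg(combiner)
  ga <- rownames(tom_a)
  gb <- rownames(tom_b)
  if (!identical(ga, gb)) {
    diff <- union(setdiff(ga, gb), setdiff(gb, ga))
    if (length(diff)) {
      stop("gene sets differ between cohorts: ",
        paste(utils::head(diff, 10), collapse = ", "), call. = FALSE)
    }
    stop("gene order differs between the two TOM matrices", call. = FALSE)
  }
  cons <- if (combiner == "min") pmin(tom_a, tom_b) else (tom_a + tom_b) / 2
  d <- 1 - cons
  diag(d) <- 0
  d
}
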
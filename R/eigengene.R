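#' Module eigengene: first principal component of a module
#'
#' Member genes are standardized (zero mean, unit variance across samples)
#' and the module's expression submatrix is decomposed by SVD. The
#' eigengene E is the leading sample-side singular vector (unit norm), a
#' sample-length summary profile of the module; it is the first principal
#' component, a weighted combination `C1*g1 + C2*g2 + ... + Cn*gn` of the
#' standardized member genes. Its sign is oriented so that it correlates
#' positively with the module's mean standardized profile. Variance
#' explained is the leading eigenvalue over the trace of the module's
#' gene-gene correlation matrix.
#'
#' @param study An [expression_study()] with >= 3 samples.
#' @param genes Member genes (>= 2).
#' @param module Optional module label carried along in the result.
#' @param drop_constant Drop constant genes with a warning instead of
#'   erroring.
#' @return An `eigengene`: list with `eigengene` (named unit vector over
#'   samples), `loadings` (unit-norm gene weights `C_k`, in member-gene
#'   order), `var_explained`, `module`, `cohort`, `genes`.
#' @export
module_eigengene <- function(study, genes, module = NA_character_,
                             drop_constant = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 3) stop("need >= 3 samples", call. = FALSE)
  missing <- setdiff(genes, gene_ids(study))
  if (length(missing)) {
    stop("genes not in study: ", paste(utils::head(missing, 5),
      collapse = ", "), call. = FALSE)
  }
  x <- study$values[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    if (drop_constant) {
      warning("dropping constant genes: ",
        paste(genes[sds == 0], collapse = ", "), call. = FALSE)
      x <- x[sds > 0, , drop = FALSE]
      genes <- genes[sds > 0]
    } else {
      stop("constant gene(s) cannot be standardized: ",
        paste(genes[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  if (length(genes) < 2) stop("a module needs >= 2 member genes",
    call. = FALSE)
  xs <- t(scale(t(x)))  # genes standardized across samples
  sv <- svd(xs)
  e <- sv$v[, 1]
  loadings <- sv$u[, 1]
  # orient: positive correlation with the mean standardized member profile
  s <- sum(e * colMeans(xs))
  if (s < 0) {
    e <- -e
    loadings <- -loadings
  }
  structure(
    list(
      eigengene = stats::setNames(e, colnames(x)),
      loadings = stats::setNames(loadings, genes),
      var_explained = sv$d[1]^2 / sum(sv$d^2),
      module = module, cohort = study$name, genes = genes
    ),
    class = "eigengene"
  )
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf(
    "<eigengene %s / %s>  %d genes, %d samples, var explained %.3f\n",
    x$module, x$cohort, length(x$genes), length(x$eigengene),
    x$var_explained))
  invisible(x)
}

#' Eigengenes of every (non-grey) module in a study
#'
#' @param study An [expression_study()].
#' @param assignment A `module_assignment` from [static_cut()]; grey genes
#'   are ignored.
#' @param drop_constant Passed to [module_eigengene()].
#' @return An `eigengene_set`: list with `E` (samples x modules matrix of
#'   eigengenes, columns in module color order), `var_explained` (named),
#'   `cohort`, `modules`.
#' @export
module_eigengenes <- function(study, assignment, drop_constant = FALSE) {
  stopifnot(inherits(assignment, "module_assignment"))
  mods <- assignment$colors
  if (!length(mods)) stop("assignment contains no non-grey modules",
    call. = FALSE)
  eigs <- lapply(mods, function(m) {
    module_eigengene(study, module_genes(assignment, m), module = m,
      drop_constant = drop_constant)
  })
  e_mat <- do.call(cbind, lapply(eigs, `[[`, "eigengene"))
  colnames(e_mat) <- mods
  structure(
    list(
      E = e_mat,
      var_explained = stats::setNames(
        vapply(eigs, `[[`, numeric(1), "var_explained"), mods),
      cohort = study$name, modules = mods
    ),
    class = "eigengene_set"
  )
}

#' @export
print.eigengene_set <- function(x, ...) {
  cat(sprintf("<eigengene_set '%s'>  %d modules x %d samples\n",
    x$cohort, length(x$modules), nrow(x$E)))
  invisible(x)
}

#' Eigengene network of one cohort
#'
#' Pairwise Pearson correlations among a cohort's module eigengenes, the
#' derived dissimilarity `1 - cor`, and an average-linkage dendrogram of the
#' modules — the module-level analogue of the gene network.
#'
#' @param eigs An `eigengene_set` with >= 2 modules.
#' @return An `eigengene_network`: list with `cor` (module x module),
#'   `dissim`, `tree` (`hclust`), `cohort`.
#' @export
eigengene_network <- function(eigs) {
  stopifnot(inherits(eigs, "eigengene_set"))
  if (length(eigs$modules) < 2) stop("need >= 2 modules", call. = FALSE)
  cc <- stats::cor(eigs$E)
  diag(cc) <- 1
  d <- 1 - cc
  diag(d) <- 0
  structure(
    list(cor = cc, dissim = d, tree = average_linkage_tree(d),
      cohort = eigs$cohort),
    class = "eigengene_network"
  )
}

#' @export
print.eigengene_network <- function(x, ...) {
  cat(sprintf("<eigengene_network '%s'>  %d modules\n", x$cohort,
    nrow(x$cor)))
  invisible(x)
}
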
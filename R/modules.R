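#' Standard module color palette
#'
#' Colors are assigned to modules in decreasing size order from this fixed
#' sequence; `"grey"` is reserved for unassigned genes. When there are more
#' modules than palette entries, labels continue as `module_<k>`.
#'
#' @return Character vector of color names.
#' @export
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Average-linkage (UPGMA) gene dendrogram
#'
#' @param dissim Symmetric dissimilarity matrix with zero diagonal, n >= 2.
#' @return An `stats::hclust` tree (method `"average"`); merge heights are
#'   non-decreasing for a proper dissimilarity.
#' @export
average_linkage_tree <- function(dissim) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  if (nrow(dissim) < 2) stop("need at least 2 genes to cluster",
    call. = FALSE)
  if (max(abs(dissim - t(dissim))) > 1e-8) {
    stop("dissimilarity matrix is not symmetric", call. = FALSE)
  }
  stats::hclust(stats::as.dist(dissim), method = "average")
}

#' Color-label candidate modules by decreasing size
#'
#' Largest module gets `"turquoise"`, second `"blue"`, and so on through
#' [module_colors()]; equal sizes are broken by the position of each
#' module's first gene, so labelling is deterministic. Genes labelled
#' `"grey"` on input stay grey.
#'
#' @param membership Character (or factor/integer) vector of candidate
#'   module ids per gene, named by gene id; `"grey"` marks unassigned genes.
#' @return A `module_assignment`: list with `assignment` (tibble `gene_id`,
#'   `module`), `colors` (labels in size order) and `sizes` (named integer
#'   vector including grey).
#' @export
assign_colors <- function(membership) {
  if (is.null(names(membership))) {
    stop("`membership` must be named by gene id", call. = FALSE)
  }
  mem <- as.character(membership)
  names(mem) <- names(membership)
  ids <- setdiff(unique(mem), "grey")
  if (length(ids)) {
    size <- vapply(ids, function(i) sum(mem == i), integer(1))
    first <- vapply(ids, function(i) which(mem == i)[1], integer(1))
    ord <- ids[order(-size, first)]
    pal <- module_colors()
    labels <- if (length(ord) <= length(pal)) {
      pal[seq_along(ord)]
    } else {
      c(pal, sprintf("module_%d", seq_len(length(ord) - length(pal))))
    }
    lut <- stats::setNames(labels, ord)
    out <- ifelse(mem == "grey", "grey", lut[mem])
  } else {
    out <- mem
  }
  assignment <- tibble::tibble(gene_id = names(mem), module = unname(out))
  colors <- if (length(ids)) unname(lut[ord]) else character(0)
  sizes <- table(factor(assignment$module, levels = c(colors, "grey")))
  structure(
    list(assignment = assignment, colors = colors,
      sizes = stats::setNames(as.integer(sizes), names(sizes))),
    class = "module_assignment"
  )
}

#' Cut a dendrogram at a fixed height into consensus modules
#'
#' Branches of the tree below `height` become candidate modules; candidates
#' smaller than `min_size` are relabelled `"grey"` (unassigned), and the
#' survivors are color-labelled by decreasing size via [assign_colors()].
#' This is the static, fixed-height cut — deliberately not a dynamic tree
#' cut.
#'
#' @param tree `hclust` tree from [average_linkage_tree()].
#' @param height Cut height on the merge-height (dissimilarity) scale,
#'   in (0, max merge height\].
#' @param min_size Minimum module size (default 25 genes).
#' @return A `module_assignment` (see [assign_colors()]).
#' @export
static_cut <- function(tree, height = 0.95, min_size = 25) {
  stopifnot(inherits(tree, "hclust"))
  if (!is.numeric(height) || length(height) != 1 || height <= 0) {
    stop("`height` must be a single positive number", call. = FALSE)
  }
  if (min_size < 1) stop("`min_size` must be >= 1", call. = FALSE)
  cl <- stats::cutree(tree, h = height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  mem <- ifelse(cl %in% as.integer(keep), as.character(cl), "grey")
  names(mem) <- tree$labels
  assign_colors(mem)
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment>  %d genes, %d modules (+ grey)\n",
    nrow(x$assignment), length(x$colors)))
  if (length(x$sizes)) {
    cat(paste(sprintf("  %s: %d", names(x$sizes), x$sizes), collapse = "\n"),
      "\n")
  }
  invisible(x)
}

#' Genes of one module
#' @param assignment A `module_assignment`.
#' @param module Module color label.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(assignment, module) {
  stopifnot(inherits(assignment, "module_assignment"))
  assignment$assignment$gene_id[assignment$assignment$module == module]
}
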
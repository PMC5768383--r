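#' Construct an expression study
#'
#' Bundles a genes x samples matrix of log-scale intensities with its sample
#' metadata (group = `"cancer"` or `"normal"`). This is the container every
#' downstream step of the pipeline consumes; one `expression_study` per cohort.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Log-scale intensities; no missing
#'   values allowed.
#' @param groups Either a named character vector (`sample_id -> group`) or a
#'   data frame with columns `sample_id` and `group`. Groups must be
#'   `"cancer"` or `"normal"` and cover every column of `values`.
#' @param name Study label, e.g. `"HNC"` or `"CC"`.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (matrix), `metadata` (tibble with `sample_id`, `group`) and
#'   `name`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' grp <- setNames(c("cancer", "cancer", "normal", "normal"), colnames(m))
#' expression_study(m, grp, name = "demo")
expression_study <- function(values, groups, name = "study") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids)",
      call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicated gene ids: ", paste(unique(dup), collapse = ", "),
      call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values; impute or filter first",
      call. = FALSE)
  }
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      stop("metadata must have columns `sample_id` and `group`", call. = FALSE)
    }
    meta <- tibble::tibble(
      sample_id = as.character(groups$sample_id),
      group = as.character(groups$group)
    )
  } else {
    if (is.null(names(groups))) {
      stop("`groups` must be named by sample id or be a data frame",
        call. = FALSE)
    }
    meta <- tibble::tibble(
      sample_id = names(groups),
      group = as.character(groups)
    )
  }
  bad <- setdiff(unique(meta$group), c("cancer", "normal"))
  if (length(bad)) {
    stop("group labels must be 'cancer' or 'normal'; found: ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
      call. = FALSE)
  }
  absent <- setdiff(meta$sample_id, colnames(values))
  if (length(absent)) {
    stop("metadata samples missing from matrix: ",
      paste(absent, collapse = ", "), call. = FALSE)
  }
  # metadata order is authoritative for column order
  values <- values[, meta$sample_id, drop = FALSE]
  structure(
    list(values = values, metadata = meta, name = name),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf(
    "<expression_study '%s'>  %d genes x %d samples (%s)\n",
    x$name, nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Sample group labels of a study
#'
#' @param study An [expression_study()].
#' @return Character vector of `"cancer"`/`"normal"` labels in sample order.
#' @export
sample_groups <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  stats::setNames(study$metadata$group, study$metadata$sample_id)
}

#' Gene ids of a study
#' @param study An [expression_study()].
#' @return Character vector of gene ids in matrix row order.
#' @export
gene_ids <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  rownames(study$values)
}
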
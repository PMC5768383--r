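#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a differential-expression result
#'
#' @param x A `de_result` from [mann_whitney_de()].
#' @param ... Unused.
#' @return Tibble with `gene_id`, `statistic`, `p_value` (and `p_adjusted`
#'   when BH was requested), `significant`.
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname tidy.de_result
#' @return For `glance()`: one row with `n_genes`, `n_significant`,
#'   `alpha`, `adjust`.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_significant = sum(x$table$significant),
    alpha = x$alpha, adjust = x$adjust
  )
}

#' Tidy a module assignment
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `module`.
#' @method tidy module_assignment
#' @export
tidy.module_assignment <- function(x, ...) x$assignment

#' @rdname tidy.module_assignment
#' @method glance module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$assignment),
    n_modules = length(x$colors),
    n_grey = sum(x$assignment$module == "grey"),
    largest = if (length(x$colors)) unname(x$sizes[x$colors[1]]) else 0L
  )
}

#' Tidy a preservation result
#'
#' `tidy()` gives the per-module preservation indices `D_i`; `glance()` the
#' overall preservation D (full precision and rounded to 2 decimals, the
#' conventional reporting precision).
#'
#' @param x A `preservation_result` from [preservation_matrix()].
#' @param ... Unused.
#' @method tidy preservation_result
#' @export
tidy.preservation_result <- function(x, ...) x$module_d

#' @rdname tidy.preservation_result
#' @method glance preservation_result
#' @export
glance.preservation_result <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$P),
    overall_d = x$overall_d,
    overall_d_rounded = round(x$overall_d, 2)
  )
}

#' Tidy a consensus pipeline fit
#'
#' One row per detected module: size, variance explained by the eigengene
#' in each cohort, and per-module preservation.
#'
#' @param x A `consensus_fit` from [run_consensus_pipeline()].
#' @param ... Unused.
#' @method tidy consensus_fit
#' @export
tidy.consensus_fit <- function(x, ...) {
  mods <- x$assignment$colors
  out <- tibble::tibble(
    module = mods,
    size = unname(x$assignment$sizes[mods])
  )
  if (!is.null(x$eigengenes_a)) {
    out$var_explained_a <- unname(x$eigengenes_a$var_explained[mods])
    out$var_explained_b <- unname(x$eigengenes_b$var_explained[mods])
  }
  if (!is.null(x$preservation)) {
    out <- dplyr::left_join(out, x$preservation$module_d, by = "module")
  }
  out
}

#' @rdname tidy.consensus_fit
#' @method glance consensus_fit
#' @export
glance.consensus_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = x$params$n_genes,
    n_modules = length(x$assignment$colors),
    n_grey = sum(x$assignment$assignment$module == "grey"),
    overall_d = if (is.null(x$preservation)) NA_real_ else
      x$preservation$overall_d
  )
}
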
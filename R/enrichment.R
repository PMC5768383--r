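#' Read a GMT gene-set collection
#'
#' GMT is the standard tab-separated gene-set format: one set per line,
#' fields `name`, `description`, then member genes. Duplicate members
#' within a set are counted once.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: named list of character vectors, with
#'   attribute `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file is empty: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: need name, description, members",
        i), call. = FALSE)
    }
    nms[i] <- fields[1]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("malformed GMT line %d: set '%s' has no members",
        i, fields[1]), call. = FALSE)
    }
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    stop("duplicated set names: ",
      paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  structure(sets, class = "gene_set_collection", source = basename(path))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s'>  %d sets\n",
    attr(x, "source") %||% "", length(x)))
  invisible(x)
}

ease_tail <- function(k, term_in_bg, n_bg, n_module) {
  # one-sided hypergeometric upper tail with overlap decremented by one
  if (k <= 1) return(1)
  stats::phyper(k - 2, term_in_bg, n_bg - term_in_bg, n_module,
    lower.tail = FALSE)
}

#' Over-representation of gene sets in modules (EASE / Fisher)
#'
#' For each module and each gene set, builds the 2x2 overlap table on the
#' background universe and computes the one-sided hypergeometric upper-tail
#' p-value (Fisher) together with the conservative EASE score — the same
#' tail with the observed overlap decremented by one (p = 1 when the
#' overlap is <= 1). Benjamini-Hochberg adjustment of the EASE p-values is
#' applied within each module across its terms.
#'
#' @param modules Named list of character vectors (module -> member genes),
#'   a single character vector (treated as one module), or a
#'   `module_assignment` (grey excluded).
#' @param background Character vector: the gene universe (every module gene
#'   must belong to it).
#' @param collection A `gene_set_collection` from [read_gmt()] or a named
#'   list of character vectors.
#' @return Tibble with one row per (module, term): `module`, `term`,
#'   `overlap`, `module_size`, `term_size` (within the background),
#'   `background_size`, `p_fisher`, `p_ease`, `p_bh`.
#' @export
ease_enrichment <- function(modules, background, collection) {
  if (inherits(modules, "module_assignment")) {
    modules <- stats::setNames(
      lapply(modules$colors, function(m) module_genes(modules, m)),
      modules$colors)
  }
  if (is.character(modules)) modules <- list(module = modules)
  if (is.null(names(modules)) || any(!nzchar(names(modules)))) {
    stop("`modules` must be a named list", call. = FALSE)
  }
  background <- unique(as.character(background))
  n_bg <- length(background)
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  rows <- purrr::map_dfr(names(modules), function(mod) {
    genes <- unique(modules[[mod]])
    absent <- setdiff(genes, background)
    if (length(absent)) {
      stop("module '", mod, "' gene(s) absent from background: ",
        paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
    n_module <- length(genes)
    per_term <- purrr::map_dfr(names(collection), function(term) {
      term_genes <- intersect(unique(collection[[term]]), background)
      k <- length(intersect(genes, term_genes))
      kk <- length(term_genes)
      p_fisher <- stats::phyper(k - 1, kk, n_bg - kk, n_module,
        lower.tail = FALSE)
      tibble::tibble(
        module = mod, term = term, overlap = k,
        module_size = n_module, term_size = kk, background_size = n_bg,
        p_fisher = p_fisher,
        p_ease = ease_tail(k, kk, n_bg, n_module)
      )
    })
    per_term$p_bh <- stats::p.adjust(per_term$p_ease, method = "BH")
    per_term
  })
  dplyr::arrange(rows, .data$module, .data$p_ease, .data$term)
}
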
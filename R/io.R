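#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file is tab-separated with a header row; the first column
#' holds gene ids (header `gene_id`, or `ID_REF` for series-matrix-style
#' exports) and the remaining columns are samples. The metadata file has
#' columns `sample_id` and `group` (`cancer`/`normal`). Metadata order is
#' authoritative: samples are returned in metadata order, and matrix columns
#' absent from the metadata are dropped with a warning. A metadata sample
#' missing from the matrix is an error.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param name Study label; defaults to the expression file name.
#' @param impute `"none"` (default; missing values are an error) or
#'   `"row-median"` to replace missing cells by the gene's median.
#' @return An [expression_study()].
#' @export
read_expression_tsv <- function(path, metadata_path,
                                name = NULL, impute = c("none", "row-median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
    check.names = FALSE, colClasses = "character")
  if (!ncol(raw) >= 2) stop("expression file needs gene id + sample columns",
    call. = FALSE)
  id_col <- names(raw)[1]
  if (!id_col %in% c("gene_id", "ID_REF")) {
    stop("first column must be `gene_id` (or `ID_REF`); found `", id_col, "`",
      call. = FALSE)
  }
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated gene ids in ", path, ": ", paste(dup, collapse = ", "),
      call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
    dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("", "NA")),
    arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
      vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]),
      call. = FALSE)
  }
  rownames(num) <- ids
  if (anyNA(num)) {
    if (impute == "row-median") {
      num <- t(apply(num, 1, function(r) {
        r[is.na(r)] <- stats::median(r, na.rm = TRUE)
        r
      }))
    } else {
      na_genes <- ids[apply(num, 1, anyNA)]
      stop("missing values in genes: ",
        paste(utils::head(na_genes, 5), collapse = ", "),
        if (length(na_genes) > 5) ", ..." else "",
        "; use impute = 'row-median' to impute", call. = FALSE)
    }
  }
  meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
    check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata must have columns `sample_id` and `group`", call. = FALSE)
  }
  absent <- setdiff(meta$sample_id, colnames(num))
  if (length(absent)) {
    stop("metadata samples missing from matrix: ",
      paste(absent, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(colnames(num), meta$sample_id)
  if (length(extra)) {
    warning("dropping ", length(extra), " sample(s) absent from metadata: ",
      paste(extra, collapse = ", "), call. = FALSE)
    num <- num[, meta$sample_id, drop = FALSE]
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  expression_study(num, meta, name = name)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Microarray matrices carry several probes per gene; module analysis wants
#' one row per gene symbol. `max_mean` keeps, for each gene, the probe with
#' the highest mean expression (the convention of the co-expression module
#' literature); `mean` averages all of a gene's probes per sample. Probes
#' absent from the map are dropped.
#'
#' @param study An [expression_study()] whose rows are probes.
#' @param probe_map Data frame with columns `probe_id`, `gene_symbol`.
#' @param method `"max_mean"` (default) or `"mean"`.
#' @return An [expression_study()] with one row per mapped gene symbol, in
#'   order of first appearance of each symbol among the study's probes.
#' @export
collapse_probes <- function(study, probe_map, method = c("max_mean", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  if (is.null(probe_map) || nrow(probe_map) == 0) {
    stop("probe map is empty", call. = FALSE)
  }
  if (!all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    stop("probe map must have columns `probe_id` and `gene_symbol`",
      call. = FALSE)
  }
  map <- tibble::tibble(
    probe_id = as.character(probe_map$probe_id),
    gene_symbol = as.character(probe_map$gene_symbol)
  )
  map <- dplyr::distinct(map)
  map <- dplyr::filter(map, .data$probe_id %in% rownames(study$values))
  if (nrow(map) == 0) stop("no probe in the map is present in the matrix",
    call. = FALSE)
  probe_order <- match(map$probe_id, rownames(study$values))
  map <- map[order(probe_order), , drop = FALSE]
  symbols <- unique(map$gene_symbol)
  rows <- lapply(symbols, function(sym) {
    probes <- map$probe_id[map$gene_symbol == sym]
    sub <- study$values[probes, , drop = FALSE]
    if (method == "max_mean") {
      means <- rowMeans(sub)
      # ties broken by probe order in the matrix (first wins)
      sub[which.max(means), ]
    } else {
      colMeans(sub)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- symbols
  expression_study(out, sample_groups(study), name = study$name)
}

fmt_num <- function(x) {
  # %.17g survives a write/read round trip exactly
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a numeric matrix as TSV
#'
#' First column `gene_id` (or the matrix's row identity), remaining columns
#' named by the matrix colnames. Values are written with enough digits to
#' round-trip losslessly (at least 12 significant digits).
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "gene_id") {
  stopifnot(is.matrix(m))
  con <- tryCatch(suppressWarnings(file(path, "wb")),
    error = function(e) {
      stop("cannot open for writing: ", path, call. = FALSE)
    })
  on.exit(close(con))
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- if (nrow(m)) {
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
    }, character(1))
  } else {
    character(0)
  }
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read back a matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
    check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol(raw) - 1)
    colnames(m) <- names(raw)[-1]
    return(m)
  }
  m <- array(as.numeric(as.matrix(raw[, -1, drop = FALSE])),
    dim = c(nrow(raw), ncol(raw) - 1),
    dimnames = list(raw[[1]], names(raw)[-1]))
  m
}

#' Write / read a module assignment table
#'
#' Two-column TSV `gene_id`, `module`.
#'
#' @param assignment A [module_assignment] (or any data frame with `gene_id`
#'   and `module` columns).
#' @param path Output path.
#' @return `path` invisibly (writer); tibble with `gene_id`, `module`
#'   (reader).
#' @export
write_module_assignment <- function(assignment, path) {
  df <- if (inherits(assignment, "module_assignment")) {
    assignment$assignment
  } else {
    assignment
  }
  stopifnot(all(c("gene_id", "module") %in% names(df)))
  con <- tryCatch(suppressWarnings(file(path, "wb")),
    error = function(e) {
      stop("cannot open for writing: ", path, call. = FALSE)
    })
  on.exit(close(con))
  writeLines(c("gene_id\tmodule",
    paste(df$gene_id, df$module, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' @rdname write_module_assignment
#' @export
read_module_assignment <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
    check.names = FALSE, colClasses = "character")
  tibble::tibble(gene_id = raw$gene_id, module = raw$module)
}
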
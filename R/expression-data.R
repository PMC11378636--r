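#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric samples-by-genes matrix of
#' `log2(1 + TPM)` expression values. Both the transfer source domain
#' (e.g. a pan-cancer tumor compendium) and the target domain (e.g. a
#' cell-line panel) are represented with this container so that every
#' downstream step sees the same unit and orientation.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   `colnames(values)`).
#'
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   row and column names set, carrying its identifiers.
#' @export
#' @examples
#' em <- expression_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("S1", "S2"), c("TP53", "EGFR", "MYC"))))
#' dim(em)
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample_ids and gene_ids are required (or set as dimnames)", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values)) stop("length(sample_ids) != nrow(values)", call. = FALSE)
  if (length(gene_ids) != ncol(values)) stop("length(gene_ids) != ncol(values)", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression matrices must be complete and finite", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x), " samples x ", ncol(x),
      " genes (log2(1+TPM))\n", sep = "")
  invisible(x)
}

#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "gene_id", values_to = "expression")
}

#' Measurement table container
#'
#' Samples-by-features matrix of one molecular measurement type. All types
#' are continuous except mutation status, which is binary 0/1. Missing
#' entries are allowed (samples with a missing target are dropped per
#' feature at task-alignment time; values are never imputed).
#'
#' @param values numeric matrix, samples in rows, measurement features in
#'   columns; `NA` marks missing entries.
#' @param measurement_type one of `"metabolite"`, `"protein"`, `"cnv"`,
#'   `"gene_effect"`, `"drug_sensitivity"`, `"mutation"`.
#' @param sample_ids,feature_ids identifiers; default to dimnames.
#'
#' @return An object of class `measurement_table` with attributes
#'   `measurement_type` and `value_kind` (`"continuous"` or `"binary"`;
#'   binary iff the type is mutation).
#' @export
measurement_table <- function(values, measurement_type,
                              sample_ids = rownames(values),
                              feature_ids = colnames(values)) {
  types <- c("metabolite", "protein", "cnv", "gene_effect",
             "drug_sensitivity", "mutation")
  measurement_type <- match.arg(measurement_type, types)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("measurement values must be numeric", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values)) {
    stop("identifier lengths do not match the value matrix", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  value_kind <- if (measurement_type == "mutation") "binary" else "continuous"
  if (value_kind == "binary") {
    obs <- values[!is.na(values)]
    if (!all(obs %in% c(0, 1))) {
      stop("mutation tables must contain only 0/1 (or missing) entries", call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values,
            measurement_type = measurement_type,
            value_kind = value_kind,
            class = c("measurement_table", "matrix", "array"))
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("<measurement_table> ", nrow(x), " samples x ", ncol(x), " ",
      attr(x, "measurement_type"), " features (",
      attr(x, "value_kind"), ")\n", sep = "")
  invisible(x)
}

# gene-symbol heuristic used for orientation auto-detection: symbols are
# upper-case alphanumerics with at least two letters (TP53, EGFR), while
# panel sample ids are usually a short prefix plus a counter (S1,
# ACH-000001) or mixed-case accessions
.looks_like_genes <- function(ids) {
  mean(grepl("^[A-Z][A-Z0-9._-]*$", ids) &
         nchar(gsub("[^A-Za-z]", "", ids)) >= 2)
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV (delimiter sniffed from the header line) with one header
#' row and one leading identifier column, and returns the canonical
#' samples-in-rows orientation. Orientation can be forced, or auto-detected
#' by scoring which axis looks like gene symbols.
#'
#' @param path file path.
#' @param orientation `"auto"` (default), `"samples"` (rows already are
#'   samples) or `"genes"` (rows are genes; the matrix is transposed).
#'
#' @return An [expression_matrix].
#' @details Duplicate gene columns are collapsed to the first occurrence
#'   with a warning; duplicate sample ids are an error. Any non-numeric
#'   cell (including literal `"NA"`) is a parse error naming the offending
#'   row and column: expression matrices must be complete.
#' @export
read_expression <- function(path, orientation = c("auto", "samples", "genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no data rows in ", path, call. = FALSE)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value %s at row '%s', column '%s'",
                 dQuote(raw[bad[1L], bad[2L]]), row_ids[bad[1L]], col_ids[bad[2L]]),
         call. = FALSE)
  }
  dimnames(num) <- list(row_ids, col_ids)

  id_col <- tolower(colnames(df)[1L])
  rows_are_samples <- switch(orientation,
    samples = TRUE,
    genes = FALSE,
    auto = if (grepl("gene|symbol", id_col)) FALSE
           else if (grepl("sample|cell|line|model|depmap", id_col)) TRUE
           else .looks_like_genes(col_ids) >= .looks_like_genes(row_ids))
  if (!rows_are_samples) num <- t(num)

  gene_ids <- colnames(num)
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warning("collapsing ", length(dups),
            " duplicate gene column(s) to first occurrence: ",
            paste(utils::head(dups, 5L), collapse = ", "), call. = FALSE)
    num <- num[, !duplicated(gene_ids), drop = FALSE]
  }
  expression_matrix(num)
}

#' Write an expression matrix to delimited text
#'
#' @param x an [expression_matrix].
#' @param path output path; `.csv` extension selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measurement table from delimited text
#'
#' Samples in rows, one header row, one leading sample-id column. Empty
#' strings, `"NA"` and `"NaN"` (case-insensitive) are read as missing.
#'
#' @param path file path.
#' @param measurement_type passed to [measurement_table()].
#' @return A [measurement_table].
#' @export
read_measurements <- function(path, measurement_type) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[toupper(trimws(raw)) %in% c("", "NA", "NAN")] <- NA
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(num) & !is.na(raw)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric measurement value %s at row '%s', column '%s'",
                 dQuote(raw[idx[1L], idx[2L]]), df[[1L]][idx[1L]],
                 colnames(df)[-1L][idx[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(df[[1L]], colnames(df)[-1L])
  measurement_table(num, measurement_type)
}

#' Write a measurement table to delimited text
#' @param x a [measurement_table].
#' @param path output path; `.csv` selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align expression with one measurement feature into a supervised task
#'
#' Intersects the sample sets of the expression and measurement containers,
#' drops samples whose target value is missing, and restricts the
#' expression matrix to the selected genes in the given order.
#'
#' @param expr an [expression_matrix] (target-domain expression).
#' @param meas a [measurement_table].
#' @param feature_id one feature (column) of `meas` to predict.
#' @param selected_genes character vector of gene ids, a subset of
#'   `colnames(expr)`; column order of the design matrix follows it exactly.
#'
#' @return An object of class `aligned_task`: list with `X` (n x k numeric
#'   matrix), `y` (length-n numeric), `sample_ids`, `feature_id`,
#'   `value_kind`.
#' @export
align_task <- function(expr, meas, feature_id, selected_genes) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(meas, "measurement_table"))
  if (!feature_id %in% colnames(meas)) {
    stop("unknown measurement feature: ", feature_id, call. = FALSE)
  }
  unknown <- setdiff(selected_genes, colnames(expr))
  if (length(unknown)) {
    stop("selected genes absent from expression matrix: ",
         paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
  }
  shared <- intersect(rownames(expr), rownames(meas))
  if (!length(shared)) stop("no shared samples between expression and measurements",
                            call. = FALSE)
  y <- unclass(meas)[shared, feature_id]
  keep <- !is.na(y)
  if (!any(keep)) stop("all shared samples have a missing target for ", feature_id,
                       call. = FALSE)
  shared <- shared[keep]
  structure(list(
    X = unclass(expr)[shared, selected_genes, drop = FALSE],
    y = unname(y[keep]),
    sample_ids = shared,
    feature_id = feature_id,
    value_kind = attr(meas, "value_kind")
  ), class = "aligned_task")
}

#' @export
print.aligned_task <- function(x, ...) {
  cat("<aligned_task> feature ", x$feature_id, ": n = ", length(x$y),
      ", k = ", ncol(x$X), " genes (", x$value_kind, ")\n", sep = "")
  invisible(x)
}
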
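#' Construct an abundance table
#'
#' An abundance table holds a non-negative taxon x sample (or sample x taxon)
#' matrix of species-level abundances, together with its orientation.
#' Taxonomic profilers emit tables with one column per sample
#' (`"taxa_as_rows"`); the modelling pipeline consumes the transpose.
#'
#' @param values Numeric matrix with unique rownames and colnames. All
#'   entries must be finite and non-negative.
#' @param orientation Either `"taxa_as_rows"` (profiler-native) or
#'   `"samples_as_rows"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry both rownames and colnames", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "abundances must be finite and >= 0; offending cell row '%s', column '%s' (value %s)",
      rownames(values)[i[1]], colnames(values)[i[2]], format(values[bad[1]])
    ), call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("row and column ids must be unique", call. = FALSE)
  }
  structure(list(values = values, orientation = orientation),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<abundance_table> %d x %d, orientation: %s\n", d[1], d[2], x$orientation))
  invisible(x)
}

#' Taxa and sample ids of an abundance table
#'
#' @param table An [abundance_table()].
#' @return Character vector of taxon names (`taxa()`) or sample ids
#'   (`samples()`).
#' @export
taxa <- function(table) {
  if (table$orientation == "taxa_as_rows") rownames(table$values) else colnames(table$values)
}

#' @rdname taxa
#' @export
samples <- function(table) {
  if (table$orientation == "taxa_as_rows") colnames(table$values) else rownames(table$values)
}

#' Read an abundance table from delimited text
#'
#' Expects a header row of ids and a first column of ids: in the
#' profiler-native orientation the header holds sample ids and the first
#' column taxon names. Non-numeric or negative cells are rejected with an
#' error that names the offending row and column.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter; TAB by default.
#' @param orientation Orientation declared for the file, see
#'   [abundance_table()].
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, delimiter = "\t",
                                 orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  m <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(num))
    stop(sprintf("non-numeric abundance at row '%s', column '%s': '%s'",
                 rownames(num)[i[1]], colnames(num)[i[2]], m[bad[1]]), call. = FALSE)
  }
  abundance_table(num, orientation)
}

#' Write an abundance table to delimited text
#'
#' Inverse of [read_abundance_table()]: a read-write-read round trip
#' preserves ids and values.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @param delimiter Field delimiter; TAB by default.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, delimiter = "\t") {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- if (table$orientation == "taxa_as_rows") "taxon" else "sample_id"
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transpose a profiler-native table to one sample per row
#'
#' @param table An [abundance_table()] in `"taxa_as_rows"` orientation.
#'   Passing an already transposed table is a warning-level no-op, so
#'   pre-transposed input is tolerated.
#' @return An [abundance_table()] with `orientation = "samples_as_rows"`.
#' @export
transpose_to_samples <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$orientation == "samples_as_rows") {
    warning("table is already samples_as_rows; returning it unchanged", call. = FALSE)
    return(table)
  }
  abundance_table(t(table$values), "samples_as_rows")
}

#' Attach binary disease-status labels to an abundance table
#'
#' Produces the labelled sample x feature dataset the classifier consumes.
#' Row i of `X` always corresponds to `sample_ids[i]`; samples are never
#' silently reordered.
#'
#' @param table An [abundance_table()] in `"samples_as_rows"` orientation.
#' @param labels Named vector (names = sample ids) or two-column data.frame
#'   (`sample_id`, `label`) of 0/1 labels; 1 = case (PD), 0 = control.
#' @return An object of class `labeled_dataset` with fields `X`, `y`,
#'   `feature_names`, `sample_ids`.
#' @export
attach_labels <- function(table, labels) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$orientation != "samples_as_rows") {
    stop("table must be in samples_as_rows orientation; see transpose_to_samples()",
         call. = FALSE)
  }
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "label") %in% names(labels))) {
      stop("label data.frame needs columns 'sample_id' and 'label'", call. = FALSE)
    }
    labels <- stats::setNames(labels$label, labels$sample_id)
  }
  ids <- rownames(table$values)
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0) {
    stop(sprintf("unlabeled sample(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  y <- as.numeric(labels[ids])
  if (!all(y %in% c(0, 1))) {
    stop("labels must be 0 (control) or 1 (case)", call. = FALSE)
  }
  labeled_dataset(table$values, y)
}

#' Construct a labelled dataset directly
#'
#' @param X Sample x feature numeric matrix with dimnames.
#' @param y Numeric 0/1 vector, one label per row of `X`.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(X, y) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  structure(list(X = X, y = as.integer(y),
                 feature_names = colnames(X), sample_ids = rownames(X)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (%d cases / %d controls)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' Read a two-column label file
#'
#' @param path Delimited text with header `sample_id<TAB>label`.
#' @param delimiter Field delimiter; TAB by default.
#' @return Named numeric vector of 0/1 labels.
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("label file needs columns 'sample_id' and 'label'", call. = FALSE)
  }
  lab <- suppressWarnings(as.numeric(df$label))
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  stats::setNames(lab, df$sample_id)
}

#' Write a two-column label file
#'
#' @param labels Named 0/1 vector.
#' @param path Output path.
#' @param delimiter Field delimiter; TAB by default.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = delimiter, quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
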
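# Reading of sample and subsample CSV tables, and subsample merging.
#
# Tables are RFC-4180 CSV: comma delimiter, first row is the header, quoted
# fields permitted, empty cell reads as the empty string. Every cell is kept
# verbatim as a string (no type coercion, whitespace preserved).

# Low-level CSV reader shared by sample and subsample tables.
read_csv_records <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    stop("table file not found: ", path, call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0L) stop("table file is empty: ", path, call. = FALSE)
  bad <- which(!is.na(nf) & nf != nf[1])
  if (length(bad)) {
    stop(sprintf("ragged CSV in %s: row %d has %d field(s) but the header has %d",
                 path, bad[1], nf[bad[1]], nf[1]), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0), strip.white = FALSE,
                        blank.lines.skip = TRUE)
  header <- names(df)
  dup <- unique(header[duplicated(header)])
  if (length(dup)) {
    stop("duplicate column name(s) in header of ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(header) == 0L || all(header == "")) {
    stop("table ", path, " has no usable header", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, as.character)
  })
  list(columns = header, rows = rows)
}

#' Read a sample table from CSV
#'
#' One sample per data row; column order is preserved and all values are
#' strings. The identifier column must be present and its values must be
#' unique and non-empty.
#'
#' @param path path to the CSV file.
#' @param index name of the identifier column (default `"sample_name"`).
#' @return a [new_sample_table()] object.
#' @export
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("sample_name,protocol", "s1,ATAC", "s2,RNA"), csv)
#' tbl <- read_sample_table(csv)
#' n_samples(tbl)
read_sample_table <- function(path, index = "sample_name") {
  rec <- read_csv_records(path)
  if (!index %in% rec$columns) {
    stop("sample table ", path, " lacks the identifier column ",
         sQuote(index), call. = FALSE)
  }
  tbl <- new_sample_table(rec$rows, rec$columns, index)
  ids <- sample_ids(tbl)
  if (any(ids == "")) {
    warning("sample table ", path, " contains row(s) with an empty ",
            sQuote(index), " value", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample identifier(s) in ", path, ": ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Read a subsample table from CSV
#'
#' A subsample table may contain several rows per sample identifier; its
#' non-identifier columns contribute multi-valued attributes at merge time
#' (see [merge_subsamples()]). Reading is purely local: identifiers are not
#' checked against any sample table here.
#'
#' @inheritParams read_sample_table
#' @return an object of class `pep_subsample_table`.
#' @export
read_subsample_table <- function(path, index = "sample_name") {
  rec <- read_csv_records(path)
  if (!index %in% rec$columns) {
    stop("subsample table ", path, " lacks the identifier column ",
         sQuote(index), call. = FALSE)
  }
  structure(list(rows = rec$rows, columns = rec$columns, index = index),
            class = "pep_subsample_table")
}

#' Merge subsample rows into multi-valued sample attributes
#'
#' For each sample with k >= 1 subsample rows, every non-identifier subsample
#' column becomes a list-valued attribute of length k on that sample, in
#' subsample row order. Empty subsample cells contribute empty strings so all
#' merged attributes of a sample have equal length. Samples without subsample
#' rows are untouched. A subsample column that collides with an existing
#' scalar column replaces it (with a message).
#'
#' @param samples a `pep_sample_table`.
#' @param sub a `pep_subsample_table`; every identifier in it must match a
#'   sample.
#' @return the merged `pep_sample_table`.
#' @export
merge_subsamples <- function(samples, sub) {
  stopifnot(inherits(samples, "pep_sample_table"),
            inherits(sub, "pep_subsample_table"))
  if (length(sub$rows) == 0L) return(samples)
  ids <- sample_ids(samples)
  sub_ids <- vapply(sub$rows, function(r) as.character(r[[sub$index]][1]), "")
  orphan <- setdiff(unique(sub_ids), ids)
  if (length(orphan)) {
    stop("subsample row(s) reference unknown sample identifier(s): ",
         paste(sQuote(orphan), collapse = ", "), call. = FALSE)
  }
  value_cols <- setdiff(sub$columns, sub$index)
  replaced <- intersect(value_cols, samples$columns)
  if (length(replaced)) {
    message("subsample merge replaces existing attribute(s): ",
            paste(replaced, collapse = ", "))
  }
  for (i in seq_along(samples$rows)) {
    hits <- which(sub_ids == ids[i])
    if (length(hits) == 0L) next
    for (cn in value_cols) {
      samples$rows[[i]][[cn]] <- vapply(
        sub$rows[hits], function(r) as.character(r[[cn]] %||% ""), "")
    }
  }
  add_columns(samples, value_cols)
}
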
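#' Sample table container
#'
#' A sample table holds one record per sample. Each record is an ordered
#' named list mapping attribute names to character vectors: length-1 vectors
#' are scalar attributes straight from the CSV; longer vectors arise from
#' subsample merging (or from modifiers acting on merged values). `columns`
#' preserves attribute order across the table and `index` names the
#' identifier attribute (by default `"sample_name"`).
#'
#' @param rows list of named lists; every value must be a character vector.
#' @param columns ordered character vector of attribute names.
#' @param index name of the identifier attribute.
#' @return An object of class `pep_sample_table`.
#' @export
new_sample_table <- function(rows = list(), columns = character(),
                             index = "sample_name") {
  stopifnot(is.list(rows), is.character(columns), is_scalar_string(index))
  structure(list(rows = rows, columns = columns, index = index),
            class = "pep_sample_table")
}

#' Number of samples in a table
#' @param x a `pep_sample_table`.
#' @return integer count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, c("pep_sample_table", "pep_subsample_table")))
  length(x$rows)
}

#' Identifier values, in row order
#' @param x a `pep_sample_table` (or subsample table).
#' @return character vector of identifiers (one per row).
#' @export
sample_ids <- function(x) {
  vapply(x$rows, function(r) as.character(r[[x$index]][1] %||% ""), "")
}

#' @export
print.pep_sample_table <- function(x, ...) {
  cat(sprintf("PEP sample table: %d sample(s), %d attribute(s)\n",
              length(x$rows), length(x$columns)))
  if (length(x$columns)) {
    cat("  attributes:", paste(x$columns, collapse = ", "), "\n")
  }
  if (length(x$rows)) {
    ids <- sample_ids(x)
    shown <- utils::head(ids, 6L)
    cat("  samples:", paste(shown, collapse = ", "),
        if (length(ids) > 6L) sprintf("... (%d more)", length(ids) - 6L) else "",
        "\n")
  }
  invisible(x)
}

#' Convert a sample table to a data.frame
#'
#' Scalar attributes become character columns; any attribute that is
#' multi-valued for at least one sample becomes a list column so no
#' information is lost. Attributes a sample lacks appear as `NA`.
#'
#' @param x a `pep_sample_table`.
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a `data.frame` with one row per sample.
#' @export
as.data.frame.pep_sample_table <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  cols <- lapply(x$columns, function(cn) {
    vals <- lapply(x$rows, function(r) r[[cn]])
    if (all(vapply(vals, function(v) is.null(v) || length(v) == 1L, TRUE))) {
      vapply(vals, function(v) if (is.null(v)) NA_character_ else v, "")
    } else {
      I(vals)
    }
  })
  names(cols) <- x$columns
  out <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE,
                       optional = TRUE)
  if (nrow(out) == 0L && length(x$rows) == 0L && length(x$columns) > 0L) {
    out <- out[0L, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Look up one sample record by identifier
#' @param x a `pep_sample_table`.
#' @param id identifier value.
#' @return the sample as a named list of character vectors.
#' @export
get_sample <- function(x, id) {
  stopifnot(inherits(x, "pep_sample_table"))
  hit <- which(sample_ids(x) == id)
  if (length(hit) != 1L) stop("no sample with identifier ", sQuote(id))
  x$rows[[hit]]
}

# Append new attribute names to the column order, preserving existing order.
add_columns <- function(tbl, new) {
  tbl$columns <- c(tbl$columns, setdiff(new, tbl$columns))
  tbl
}
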
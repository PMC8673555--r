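# Top-level entry points: turn files on disk into a processed Project.

new_project <- function(config, samples, active_amendments = character()) {
  structure(list(config = config, samples = samples,
                 active_amendments = as.character(active_amendments)),
            class = "pep_project")
}

#' Load and process a PEP from its configuration file
#'
#' Runs the full processing pipeline, in fixed order: (1) imports are
#' resolved; (2) requested amendments are applied (they may replace the
#' sample table path, so this precedes table reading); (3) the sample table
#' and any subsample table(s) are read and merged; (4) sample modifiers are
#' applied in the order remove, append, duplicate, imply, derive. All
#' relative paths in a config resolve against the directory of the file that
#' states them. Loading is deterministic: the same files, amendment list,
#' and environment always give an identical project.
#'
#' The identifier attribute defaults to `sample_name` and can be changed
#' with the config key `sample_table_index`.
#'
#' @param config_path path to the YAML configuration file.
#' @param amendments ordered character vector of amendment names to
#'   activate (later names take priority).
#' @param env named environment-variable mapping used for `$VAR` expansion
#'   in paths and derive templates; `NULL` means the process environment.
#' @return an object of class `pep_project` with elements `config`
#'   (resolved config), `samples` (processed [new_sample_table()]), and
#'   `active_amendments`.
#' @seealso [load_project_from_table()] for a config-less PEP.
#' @export
load_project <- function(config_path, amendments = NULL, env = NULL) {
  cfg <- read_config_file(config_path, env)
  cfg <- resolve_imports(cfg, env = env)
  cfg <- apply_amendments(cfg, amendments %||% character())
  index <- as.character(cfg[["sample_table_index"]] %||% "sample_name")

  samples <- if (!is.null(cfg$sample_table)) {
    read_sample_table(as_path_string(cfg$sample_table), index)
  } else {
    new_sample_table(index = index)
  }
  for (sp in as.character(unlist(cfg$subsample_table %||% character()))) {
    samples <- merge_subsamples(samples, read_subsample_table(sp, index))
  }
  samples <- process_samples(samples, cfg$sample_modifiers, env)
  new_project(cfg, samples, amendments %||% character())
}

#' Load a table-only PEP from a bare CSV
#'
#' The configuration file is optional in the PEP format: a sample table by
#' itself is a valid project. The resulting project has a minimal config
#' (just the table path) and samples read verbatim; a header-only CSV gives
#' a project with zero samples.
#'
#' @param csv_path path to the sample table CSV.
#' @param index name of the identifier column.
#' @return a `pep_project`.
#' @export
load_project_from_table <- function(csv_path, index = "sample_name") {
  samples <- read_sample_table(csv_path, index)
  cfg <- list(sample_table = normalizePath(csv_path, winslash = "/"))
  new_project(cfg, samples)
}

#' Access the processed sample table of a project
#'
#' @param x a `pep_project`.
#' @param format `"table"` for the internal `pep_sample_table`,
#'   `"data.frame"` for a data.frame (multi-valued attributes become list
#'   columns).
#' @return the processed samples in the requested form.
#' @export
sample_table <- function(x, format = c("data.frame", "table")) {
  stopifnot(inherits(x, "pep_project"))
  format <- match.arg(format)
  if (format == "table") x$samples else as.data.frame(x$samples)
}

#' Access the resolved configuration of a project
#' @param x a `pep_project`.
#' @return the resolved config as a named list.
#' @export
project_config <- function(x) {
  stopifnot(inherits(x, "pep_project"))
  x$config
}

#' @export
print.pep_project <- function(x, ...) {
  src <- attr(x$config, "source_path")
  cat("PEP project",
      if (!is.null(src)) paste0("(", basename(src), ")") else "(table-only)",
      "\n")
  cat(sprintf("  samples: %d\n", length(x$samples$rows)))
  if (length(x$samples$columns)) {
    cat("  attributes:", paste(x$samples$columns, collapse = ", "), "\n")
  }
  if (length(x$active_amendments)) {
    cat("  active amendments:", paste(x$active_amendments, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.pep_project <- function(object, ...) {
  mods <- intersect(sample_modifier_types(),
                    names(object$config$sample_modifiers %||% list()))
  out <- list(
    source = attr(object$config, "source_path"),
    n_samples = length(object$samples$rows),
    attributes = object$samples$columns,
    active_amendments = object$active_amendments,
    available_amendments = amendment_names(object$config),
    sample_modifiers = mods
  )
  class(out) <- "summary.pep_project"
  out
}

#' @export
print.summary.pep_project <- function(x, ...) {
  cat("PEP project summary\n")
  cat("  config: ", x$source %||% "(none)", "\n", sep = "")
  cat("  samples: ", x$n_samples, "\n", sep = "")
  cat("  attributes: ", paste(x$attributes, collapse = ", "), "\n", sep = "")
  cat("  sample modifiers: ",
      if (length(x$sample_modifiers)) paste(x$sample_modifiers, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  amendments: ",
      if (length(x$available_amendments))
        paste(x$available_amendments, collapse = ", ") else "(none)",
      if (length(x$active_amendments))
        paste0(" [active: ", paste(x$active_amendments, collapse = ", "), "]")
      else "", "\n", sep = "")
  invisible(x)
}
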
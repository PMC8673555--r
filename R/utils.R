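`%||%` <- function(x, y) if (is.null(x)) y else x

#' Effective environment-variable mapping
#'
#' Most entry points accept an `env` argument so that template and path
#' expansion can be made reproducible; `NULL` means the process environment.
#' @noRd
effective_env <- function(env = NULL) {
  if (is.null(env)) as.list(Sys.getenv()) else as.list(env)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Collapse a value read from YAML to a character scalar for path use
#' @noRd
as_path_string <- function(x) {
  if (!is.atomic(x) || length(x) != 1L) {
    stop("expected a single path string, got: ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  as.character(x)
}

#' Make a path absolute relative to a base directory
#'
#' Relative paths in a PEP config resolve against the directory of the file
#' that states them, so a PEP stays relocatable as a directory.
#' @noRd
absolutize <- function(path, dir) {
  if (grepl("^(/|~)", path)) {
    normalizePath(path, winslash = "/", mustWork = FALSE)
  } else {
    normalizePath(file.path(dir, path), winslash = "/", mustWork = FALSE)
  }
}
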
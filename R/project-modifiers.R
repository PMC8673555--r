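# Project modifiers: import (merge configs across files, nearest wins) and
# amend (embedded, activatable config variants).

# Fold `top` over `base`, whole top-level key replacement. Amendment sections
# union at the amendment-name level: an amendment redefined in `top` replaces
# the one in `base` wholesale. Import lists are never carried into the result
# (they are consumed by resolution).
override_config <- function(base, top) {
  for (k in setdiff(names(top), "project_modifiers")) {
    base[[k]] <- top[[k]]
  }
  tpm <- top$project_modifiers
  if (!is.null(tpm)) {
    pm <- base$project_modifiers %||% list()
    for (k in setdiff(names(tpm), c("amend", "import"))) pm[[k]] <- tpm[[k]]
    if (!is.null(tpm$amend)) {
      am <- pm$amend %||% list()
      am[names(tpm$amend)] <- tpm$amend
      pm$amend <- am
    }
    if (length(pm)) base$project_modifiers <- pm
  }
  base
}

#' Resolve config imports into a single flat config
#'
#' Imports cascade recursively, most distant files first, so for each
#' top-level key the nearest file that defines it wins: the importing file
#' overrides everything it imports, and within one import list later entries
#' override earlier ones. Merging replaces whole top-level keys (the
#' `sample_table` of the nearest file is selected; tables are never merged
#' row-wise). Amendment sections are unioned by name, an importing file's
#' same-named amendment replacing the imported one wholesale. The resolved
#' config contains no `import` entries; `amend` is retained for
#' introspection.
#'
#' @param config a config list as returned by [read_config_file()].
#' @param visited absolute paths already on the import chain (cycle
#'   detection); defaults to the config's own source path.
#' @param env named environment-variable mapping (`NULL`: process env).
#' @return the resolved config list.
#' @export
resolve_imports <- function(config, visited = NULL, env = NULL) {
  if (is.null(visited)) visited <- attr(config, "source_path") %||% character()
  imports <- config$project_modifiers$import
  if (is.null(imports) || length(imports) == 0L) return(config)
  base <- list()
  for (p in as.character(unlist(imports))) {
    pn <- normalizePath(p, winslash = "/", mustWork = FALSE)
    if (pn %in% visited) {
      stop("import cycle detected: ",
           paste(c(visited, pn), collapse = " -> "), call. = FALSE)
    }
    if (!file.exists(pn)) {
      stop("import target not found: ", pn, call. = FALSE)
    }
    child <- read_config_file(pn, env)
    child <- resolve_imports(child, visited = c(visited, pn), env = env)
    base <- override_config(base, child)
  }
  self <- config
  self$project_modifiers$import <- NULL
  if (length(self$project_modifiers) == 0L) self$project_modifiers <- NULL
  out <- override_config(base, self)
  attr(out, "source_path") <- attr(config, "source_path")
  out
}

#' List the amendments a config defines
#' @param config a config list.
#' @return character vector of amendment names (possibly empty).
#' @export
amendment_names <- function(config) {
  names(config$project_modifiers$amend) %||% character()
}

#' Apply activated amendments to a config
#'
#' Each active amendment, in activation order, replaces the top-level config
#' keys it names; later activations override earlier ones. Inactive
#' amendments leave the config untouched. An amendment may not itself add
#' project modifiers (imports or nested amendments).
#'
#' @param config a config list (imports already resolved).
#' @param active ordered character vector of amendment names to activate.
#' @return the amended config list.
#' @export
apply_amendments <- function(config, active = character()) {
  active <- as.character(active %||% character())
  if (length(active) == 0L) return(config)
  avail <- amendment_names(config)
  unknown <- setdiff(active, avail)
  if (length(unknown)) {
    stop("unknown amendment(s): ", paste(sQuote(unknown), collapse = ", "),
         "; available: ",
         if (length(avail)) paste(sQuote(avail), collapse = ", ") else "(none)",
         call. = FALSE)
  }
  for (nm in active) {
    ov <- config$project_modifiers$amend[[nm]]
    if ("project_modifiers" %in% names(ov) || "import" %in% names(ov) ||
        "amend" %in% names(ov)) {
      stop("amendment ", sQuote(nm),
           " may not add project modifiers (import/amend)", call. = FALSE)
    }
    for (k in names(ov)) config[[k]] <- ov[[k]]
  }
  attr(config, "active_amendments") <- active
  config
}
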
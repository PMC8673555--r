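# Reading of YAML project configuration files.
#
# A config is kept as a plain named list preserving every key the author
# wrote (unknown keys pass through untouched). Path-valued fields
# (sample_table, subsample_table, import targets — including inside
# amendment overrides) are expanded for environment variables and made
# absolute against the directory of the file that states them, so a PEP
# remains relocatable as a directory.

CONFIG_PATH_KEYS <- c("sample_table", "subsample_table")

#' Names of the recognized project modifiers
#' @return character vector: `import`, `amend`.
#' @export
project_modifier_types <- function() c("import", "amend")

# Expand $VAR / ${VAR} in a path using the same single-pass rules as derive
# templates ({attr} references are not meaningful in config paths).
expand_env_path <- function(path, env = NULL) {
  resolve_template(path, sample = list(), env = env)
}

resolve_config_paths <- function(cfg, dir, env = NULL) {
  fix <- function(x) {
    vapply(as.character(x), function(p) absolutize(expand_env_path(p, env), dir),
           "", USE.NAMES = FALSE)
  }
  for (k in intersect(CONFIG_PATH_KEYS, names(cfg))) {
    v <- fix(cfg[[k]])
    cfg[[k]] <- if (length(v) == 1L) v else as.list(v)
  }
  pm <- cfg$project_modifiers
  if (!is.null(pm)) {
    if (!is.null(pm$import)) pm$import <- as.list(fix(pm$import))
    if (!is.null(pm$amend)) {
      pm$amend <- lapply(pm$amend, function(ov) {
        for (k in intersect(CONFIG_PATH_KEYS, names(ov))) {
          v <- fix(ov[[k]])
          ov[[k]] <- if (length(v) == 1L) v else as.list(v)
        }
        ov
      })
    }
    cfg$project_modifiers <- pm
  }
  cfg
}

#' Read one project configuration file
#'
#' Parses the YAML mapping, expands environment variables in path-valued
#' fields, and resolves relative paths against the config file's directory.
#' No project modifiers are applied; see [resolve_imports()] and
#' [apply_amendments()].
#'
#' @param path path to the YAML config.
#' @param env named environment-variable mapping (`NULL`: process env).
#' @return the config as a named list, with the absolute source path in
#'   `attr(, "source_path")`.
#' @export
read_config_file <- function(path, env = NULL) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  abs <- normalizePath(path, winslash = "/", mustWork = TRUE)
  cfg <- tryCatch(yaml::read_yaml(abs),
                  error = function(e) {
                    stop("failed to parse YAML config ", abs, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg) || (length(cfg) > 0L && is.null(names(cfg)))) {
    stop("config ", abs, " must be a YAML mapping (key: value pairs)",
         call. = FALSE)
  }
  cfg <- resolve_config_paths(cfg, dirname(abs), env)
  attr(cfg, "source_path") <- abs
  cfg
}
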
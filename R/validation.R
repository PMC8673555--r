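# Two-stage schema validation of processed projects.
#
# Schemas are JSON or YAML documents in a small JSON-Schema dialect:
# standard keywords `properties` (with `type`, `enum`, `pattern`),
# `required`, plus two extensions — `imports` (a list of other schema files
# that must ALL validate) and `required_files` (sample attributes whose
# values must point to existing files). Sample rules live under
# `properties: samples: items:` (or a top-level `samples:` shortcut); every
# other property describes the project config. Validation runs in two
# stages: stage 1 checks the resolved config, stage 2 checks each sample
# AFTER all modifiers have been applied, so attributes added by append or
# derive are visible to the validator.

VALIDATION_STAGES <- c("config", "sample")

read_schema_doc <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Load a PEP schema, resolving its imports
#'
#' A schema may list other schemas under `imports`; these are resolved
#' recursively (relative to the importing schema's directory) and retained
#' individually, not merged, so each can be checked on its own — a project
#' must satisfy every schema in the chain to be valid. Cyclic imports are an
#' error; remote URLs are rejected.
#'
#' @param ref path to a schema file (`.yaml`/`.yml` or `.json`).
#' @param visited internal: absolute paths already on the import chain.
#' @return an object of class `pep_schema`: a list with element `schemas`,
#'   ordered most-imported first, each entry holding `source` and `doc`.
#' @export
load_schema <- function(ref, visited = character()) {
  if (grepl("^[a-z][a-z0-9+.-]*://", ref)) {
    stop("remote schema references are not supported: ", ref,
         "; use a local file path", call. = FALSE)
  }
  if (!file.exists(ref)) stop("schema file not found: ", ref, call. = FALSE)
  abs <- normalizePath(ref, winslash = "/", mustWork = TRUE)
  if (abs %in% visited) {
    stop("schema import cycle detected: ",
         paste(c(visited, abs), collapse = " -> "), call. = FALSE)
  }
  doc <- tryCatch(read_schema_doc(abs),
                  error = function(e) {
                    stop("failed to parse schema ", abs, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!is.list(doc)) stop("schema ", abs, " is not a mapping", call. = FALSE)
  chain <- list()
  for (imp in as.character(unlist(doc$imports %||% character()))) {
    ip <- if (grepl("^(/|~)", imp) || grepl("^[a-z][a-z0-9+.-]*://", imp)) imp
          else file.path(dirname(abs), imp)
    sub <- load_schema(ip, visited = c(visited, abs))
    chain <- c(chain, sub$schemas)
  }
  chain <- c(chain, list(list(source = abs, doc = doc)))
  structure(list(schemas = chain), class = "pep_schema")
}

new_failure <- function(stage, schema, subject, rule, message) {
  data.frame(stage = stage, schema = schema, subject = subject,
             rule = rule, message = message, stringsAsFactors = FALSE)
}

no_failures <- function() {
  new_failure(character(0), character(0), character(0), character(0),
              character(0))
}

new_validation_report <- function(failures,
                                  stages = VALIDATION_STAGES) {
  rownames(failures) <- NULL
  structure(list(passed = nrow(failures) == 0L, failures = failures,
                 stages = stages),
            class = "pep_validation_report")
}

#' @export
print.pep_validation_report <- function(x, ...) {
  if (x$passed) {
    cat("Validation PASSED (0 failures)\n")
  } else {
    cat(sprintf("Validation FAILED: %d failure(s)\n", nrow(x$failures)))
    for (i in seq_len(nrow(x$failures))) {
      f <- x$failures[i, ]
      cat(sprintf("  [%s] %s: %s (%s)\n", f$stage, f$subject, f$message,
                  f$rule))
    }
  }
  invisible(x)
}

# ---- keyword checks (type / enum / pattern) --------------------------------

# Sample attribute values are always strings; typed schemas are checked by
# parsing the string. Config values keep their YAML types.
value_has_type <- function(v, type) {
  chk_scalar <- function(el) {
    switch(type,
      string  = is.character(el) || is.factor(el),
      number  = is.numeric(el) ||
        (is.character(el) && grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", el)),
      integer = (is.numeric(el) && el == floor(el)) ||
        (is.character(el) && grepl("^-?[0-9]+$", el)),
      boolean = is.logical(el) ||
        (is.character(el) && tolower(el) %in% c("true", "false")),
      `null`  = is.null(el),
      TRUE)
  }
  switch(type,
    array  = length(v) > 1L || (is.list(v) && is.null(names(v))),
    object = is.list(v) && !is.null(names(v)),
    all(vapply(unlist(v) %||% v, chk_scalar, TRUE)))
}

check_value_rules <- function(value, rules, subject, stage, schema_src) {
  fails <- no_failures()
  flat <- unlist(value, use.names = FALSE)
  if (!is.null(rules$type)) {
    if (!value_has_type(value, as.character(rules$type))) {
      fails <- rbind(fails, new_failure(stage, schema_src, subject, "type",
        sprintf("value %s is not of type %s",
                paste(sQuote(format(flat)), collapse = ","), rules$type)))
    }
  }
  if (!is.null(rules$enum)) {
    allowed <- as.character(unlist(rules$enum))
    bad <- setdiff(as.character(flat), allowed)
    if (length(bad)) {
      fails <- rbind(fails, new_failure(stage, schema_src, subject, "enum",
        sprintf("value %s not among allowed values [%s]",
                paste(sQuote(bad), collapse = ","),
                paste(allowed, collapse = ", "))))
    }
  }
  if (!is.null(rules$pattern) && is.character(flat)) {
    bad <- flat[!grepl(as.character(rules$pattern), flat, perl = TRUE)]
    if (length(bad)) {
      fails <- rbind(fails, new_failure(stage, schema_src, subject, "pattern",
        sprintf("value %s does not match pattern %s",
                paste(sQuote(bad), collapse = ","), rules$pattern)))
    }
  }
  fails
}

# ---- required_files --------------------------------------------------------

#' Check that file-valued sample attributes point to existing files
#'
#' For each named attribute, every element of the sample's value must be the
#' path of an existing regular file (directories do not count). An absent
#' attribute is itself a failure. Failures are returned as data, never
#' raised.
#'
#' @param sample a sample record (named list of character vectors).
#' @param names attribute names to check.
#' @param id identifier used in failure messages.
#' @return a data.frame of failures (zero rows when all files exist).
#' @export
check_required_files <- function(sample, names, id = "(sample)") {
  fails <- no_failures()
  for (nm in names) {
    if (!nm %in% base::names(sample)) {
      fails <- rbind(fails, new_failure("sample", NA_character_, id,
        "required_files", sprintf("attribute %s is absent", sQuote(nm))))
      next
    }
    for (el in as.character(sample[[nm]])) {
      if (!(file.exists(el) && !dir.exists(el))) {
        fails <- rbind(fails, new_failure("sample", NA_character_, id,
          "required_files",
          sprintf("attribute %s: file does not exist: %s", sQuote(nm), el)))
      }
    }
  }
  fails
}

# ---- schema anatomy --------------------------------------------------------

schema_sample_rules <- function(doc) {
  doc$samples %||% doc$properties$samples$items
}

schema_config_rules <- function(doc) {
  props <- doc$properties %||% list()
  props <- props[setdiff(names(props), "samples")]
  req <- setdiff(as.character(unlist(doc$required %||% character())), "samples")
  list(properties = props, required = req)
}

# ---- two-stage validation --------------------------------------------------

validate_one_schema <- function(project, doc, src) {
  fails <- no_failures()
  cfg <- project$config
  crules <- schema_config_rules(doc)
  for (k in crules$required) {
    if (!k %in% names(cfg)) {
      fails <- rbind(fails, new_failure("config", src, "config", "required",
        sprintf("config key %s is required but absent", sQuote(k))))
    }
  }
  for (k in intersect(names(crules$properties), names(cfg))) {
    fails <- rbind(fails, check_value_rules(cfg[[k]], crules$properties[[k]],
                                            paste0("config:", k), "config", src))
  }

  srules <- schema_sample_rules(doc)
  if (!is.null(srules)) {
    req <- as.character(unlist(srules$required %||% character()))
    props <- srules$properties %||% list()
    rfiles <- as.character(unlist(srules$required_files %||% character()))
    ids <- sample_ids(project$samples)
    for (i in seq_along(project$samples$rows)) {
      r <- project$samples$rows[[i]]
      id <- if (nzchar(ids[i])) ids[i] else sprintf("(row %d)", i)
      for (a in setdiff(req, names(r))) {
        fails <- rbind(fails, new_failure("sample", src, id, "required",
          sprintf("sample attribute %s is required but absent", sQuote(a))))
      }
      for (a in intersect(names(props), names(r))) {
        fails <- rbind(fails, check_value_rules(r[[a]], props[[a]],
          paste0(id, ":", a), "sample", src))
      }
      rf <- check_required_files(r, rfiles, id)
      if (nrow(rf)) {
        rf$schema <- src
        fails <- rbind(fails, rf)
      }
    }
  }
  fails
}

#' Validate a processed project against a schema
#'
#' Two-stage validation: stage 1 checks the resolved configuration, stage 2
#' checks each processed sample (after modifiers), including
#' `required_files` existence checks. With schema imports, the project must
#' validate against every schema in the chain; the report breaks failures
#' down per schema. Failures are data, not exceptions.
#'
#' @param project a `pep_project` (fully processed).
#' @param schema a `pep_schema` from [load_schema()], or a path to one.
#' @return a `pep_validation_report`: `passed` (logical), `failures`
#'   (data.frame with stage, schema, subject, rule, message), `stages`.
#' @export
validate_pep <- function(project, schema) {
  stopifnot(inherits(project, "pep_project"))
  if (is.character(schema)) schema <- load_schema(schema)
  stopifnot(inherits(schema, "pep_schema"))
  fails <- no_failures()
  for (entry in schema$schemas) {
    fails <- rbind(fails, validate_one_schema(project, entry$doc,
                                              basename(entry$source)))
  }
  new_validation_report(fails)
}

# ---- generic structural validation -----------------------------------------

check_config_structure <- function(cfg) {
  fails <- no_failures()
  fail <- function(rule, msg) {
    new_failure("config", "generic", "config", rule, msg)
  }
  pm <- cfg$project_modifiers
  if (!is.null(pm)) {
    if (!is.list(pm) || is.null(names(pm))) {
      fails <- rbind(fails, fail("project_modifiers",
                                 "project_modifiers must be a mapping"))
    } else {
      bad <- setdiff(names(pm), project_modifier_types())
      if (length(bad)) {
        fails <- rbind(fails, fail("project_modifiers",
          sprintf("unknown project_modifiers subsection(s): %s; legal: %s",
                  paste(bad, collapse = ", "),
                  paste(project_modifier_types(), collapse = ", "))))
      }
    }
  }
  sm <- cfg$sample_modifiers
  if (!is.null(sm)) {
    if (!is.list(sm) || is.null(names(sm))) {
      fails <- rbind(fails, fail("sample_modifiers",
                                 "sample_modifiers must be a mapping"))
    } else {
      bad <- setdiff(names(sm), sample_modifier_types())
      if (length(bad)) {
        fails <- rbind(fails, fail("sample_modifiers",
          sprintf("unknown sample_modifiers subsection(s): %s; legal: %s",
                  paste(bad, collapse = ", "),
                  paste(sample_modifier_types(), collapse = ", "))))
      }
      if (!is.null(sm$remove) && !is.character(as.character(unlist(sm$remove)))) {
        fails <- rbind(fails, fail("remove", "remove must be a list of names"))
      }
      for (k in c("append", "duplicate")) {
        if (!is.null(sm[[k]]) &&
            (!is.list(sm[[k]]) || is.null(names(sm[[k]])))) {
          fails <- rbind(fails, fail(k, paste0(k, " must be a mapping")))
        }
      }
      if (!is.null(sm$imply)) {
        ok <- is.list(sm$imply) &&
          all(vapply(sm$imply, function(r) {
            is.list(r) && all(c("if", "then") %in% names(r))
          }, TRUE))
        if (!ok) {
          fails <- rbind(fails, fail("imply",
            "imply must be a list of rules with 'if' and 'then' sections"))
        }
      }
      if (!is.null(sm$derive)) {
        ok <- is.list(sm$derive) &&
          all(c("attributes", "sources") %in% names(sm$derive))
        if (!ok) {
          fails <- rbind(fails, fail("derive",
            "derive must have 'attributes' and 'sources' sections"))
        }
      }
    }
  }
  if (!is.null(cfg$sample_table) &&
      !(is.atomic(cfg$sample_table) && length(cfg$sample_table) == 1L)) {
    fails <- rbind(fails, fail("sample_table",
                               "sample_table must be a single path string"))
  }
  fails
}

#' Validate a project against the generic PEP structure
#'
#' Structure-only validation: the config may only use the recognized
#' project- and sample-modifier subsections with well-formed shapes, and
#' every sample must carry a non-empty, unique identifier. Accepts a
#' processed `pep_project`, a raw config list, or a config file path, so
#' that malformed configs that cannot be fully loaded can still be
#' diagnosed.
#'
#' @param x a `pep_project`, a config list, or a YAML config path.
#' @return a `pep_validation_report`.
#' @export
validate_generic <- function(x) {
  UseMethod("validate_generic")
}

#' @export
validate_generic.character <- function(x) {
  cfg <- yaml::read_yaml(x)
  if (is.null(cfg)) cfg <- list()
  validate_generic(cfg)
}

#' @export
validate_generic.list <- function(x) {
  new_validation_report(check_config_structure(x), stages = "config")
}

#' @export
validate_generic.pep_project <- function(x) {
  fails <- check_config_structure(x$config)
  ids <- sample_ids(x$samples)
  for (i in seq_along(ids)) {
    if (!nzchar(ids[i])) {
      fails <- rbind(fails, new_failure("sample", "generic",
        sprintf("(row %d)", i), "identifier",
        sprintf("sample lacks a non-empty %s", sQuote(x$samples$index))))
    }
  }
  dup <- unique(ids[nzchar(ids) & duplicated(ids)])
  for (d in dup) {
    fails <- rbind(fails, new_failure("sample", "generic", d, "identifier",
      "duplicate sample identifier"))
  }
  new_validation_report(fails)
}
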
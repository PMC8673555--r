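# The five sample modifiers: remove, append, duplicate, imply, derive.
#
# Modifiers transform processed sample attributes from the project config
# alone, so the CSV sample table never needs editing when a project moves
# between analyses or computing environments.

#' Names of the recognized sample modifiers, in application order
#'
#' The engine applies modifiers in this fixed order. `derive` runs last so
#' its templates can reference attributes added by `append`, `duplicate`, or
#' `imply`; `imply` runs after `append`/`duplicate` so conditions can react
#' to attributes those modifiers introduce.
#'
#' @return character vector of the five modifier names, in order.
#' @export
sample_modifier_types <- function() {
  c("remove", "append", "duplicate", "imply", "derive")
}

#' Remove attributes from all samples
#'
#' Removing an attribute present on no sample is a no-op with a warning.
#'
#' @param samples a `pep_sample_table`.
#' @param names character vector of attribute names to remove.
#' @return the modified table.
#' @export
apply_remove <- function(samples, names) {
  stopifnot(inherits(samples, "pep_sample_table"))
  names <- as.character(names %||% character())
  if (length(names) == 0L) return(samples)
  present <- unique(unlist(lapply(samples$rows, base::names)))
  absent <- setdiff(names, present)
  if (length(absent)) {
    warning("remove: attribute(s) present on no sample: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  samples$rows <- lapply(samples$rows, function(r) r[setdiff(base::names(r), names)])
  samples$columns <- setdiff(samples$columns, names)
  samples
}

#' Append constant attributes to all samples
#'
#' Each constant is set on every sample that does not already define the
#' attribute; values coming from the sample table are ground truth and are
#' never overwritten.
#'
#' @param samples a `pep_sample_table`.
#' @param constants named list/vector of attribute name to constant value.
#' @return the modified table.
#' @export
apply_append <- function(samples, constants) {
  stopifnot(inherits(samples, "pep_sample_table"))
  constants <- as.list(constants %||% list())
  if (length(constants) == 0L) return(samples)
  if (is.null(names(constants)) || any(names(constants) == "")) {
    stop("append requires a mapping of attribute name to value", call. = FALSE)
  }
  for (nm in names(constants)) {
    val <- as.character(constants[[nm]])
    samples$rows <- lapply(samples$rows, function(r) {
      if (!nm %in% base::names(r)) r[[nm]] <- val
      r
    })
  }
  add_columns(samples, names(constants))
}

#' Duplicate attributes under new names
#'
#' For each `old = "new"` pair every sample gains attribute `new` holding an
#' independent copy of `old`'s value (scalar or list); `old` is retained.
#'
#' @param samples a `pep_sample_table`.
#' @param mapping named list/vector: old attribute name -> new attribute name.
#' @return the modified table.
#' @export
apply_duplicate <- function(samples, mapping) {
  stopifnot(inherits(samples, "pep_sample_table"))
  mapping <- as.list(mapping %||% list())
  if (length(mapping) == 0L) return(samples)
  olds <- names(mapping)
  news <- vapply(mapping, as.character, "")
  if (is.null(olds) || any(olds == "")) {
    stop("duplicate requires a mapping of old name to new name", call. = FALSE)
  }
  clash <- olds == news
  if (any(clash)) {
    stop("duplicate: old and new attribute names must differ: ",
         paste(olds[clash], collapse = ", "), call. = FALSE)
  }
  ids <- sample_ids(samples)
  for (k in seq_along(olds)) {
    for (i in seq_along(samples$rows)) {
      if (!olds[k] %in% base::names(samples$rows[[i]])) {
        warning(sprintf("duplicate: sample %s lacks attribute %s; skipped",
                        sQuote(ids[i]), sQuote(olds[k])), call. = FALSE)
        next
      }
      samples$rows[[i]][[news[k]]] <- samples$rows[[i]][[olds[k]]]
    }
  }
  add_columns(samples, news)
}

#' Conditionally set attributes (imply)
#'
#' Each rule is a list with elements `if` (attribute -> required value or
#' list of alternative values) and `then` (attribute -> value to set). A
#' sample must satisfy ALL `if` conditions to receive the `then` settings;
#' matching overwrites prior values of the set attributes. A condition on an
#' attribute the sample lacks never matches. `then` values must not be null.
#'
#' @param samples a `pep_sample_table`.
#' @param rules list of `if`/`then` rules, applied in order.
#' @return the modified table.
#' @export
apply_imply <- function(samples, rules) {
  stopifnot(inherits(samples, "pep_sample_table"))
  rules <- rules %||% list()
  if (length(rules) == 0L) return(samples)
  for (rule in rules) {
    conds <- rule[["if"]]
    sets <- rule[["then"]]
    if (is.null(conds) || length(conds) == 0L ||
        is.null(sets) || length(sets) == 0L) {
      stop("imply rules need non-empty 'if' and 'then' sections", call. = FALSE)
    }
    if (any(vapply(sets, is.null, TRUE))) {
      stop("imply 'then' values must not be null", call. = FALSE)
    }
    matches <- vapply(samples$rows, function(r) {
      all(vapply(names(conds), function(a) {
        a %in% base::names(r) &&
          any(r[[a]] %in% as.character(unlist(conds[[a]])))
      }, TRUE))
    }, TRUE)
    for (i in which(matches)) {
      for (a in names(sets)) {
        samples$rows[[i]][[a]] <- as.character(sets[[a]])
      }
    }
    samples <- add_columns(samples, names(sets))
  }
  samples
}

#' Resolve a derive template for one sample
#'
#' Substitutes, in a single left-to-right pass, `{attr}` with the sample's
#' current value of `attr` and `$NAME` / `${NAME}` with the value from `env`.
#' Substituted text is never re-expanded. Referencing an attribute the
#' sample lacks is an error; an environment variable absent from `env` is
#' left verbatim with a warning, so a project authored for another machine
#' still loads for inspection.
#'
#' @param template template string.
#' @param sample a sample record (named list of character vectors).
#' @param env named mapping of environment variables; `NULL` means the
#'   process environment.
#' @return the resolved string.
#' @export
#' @examples
#' resolve_template("/data/{sample_name}.fq", list(sample_name = "s1"),
#'                  env = list())
resolve_template <- function(template, sample, env = NULL) {
  stopifnot(is_scalar_string(template))
  env <- effective_env(env)
  pat <- "\\{[A-Za-z_][A-Za-z0-9_]*\\}|\\$\\{[A-Za-z_][A-Za-z0-9_]*\\}|\\$[A-Za-z_][A-Za-z0-9_]*"
  m <- gregexpr(pat, template, perl = TRUE)[[1]]
  if (m[1] == -1L) return(template)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out <- character(0)
  pos <- 1L
  for (k in seq_along(starts)) {
    out <- c(out, substr(template, pos, starts[k] - 1L))
    tok <- substr(template, starts[k], starts[k] + lens[k] - 1L)
    if (startsWith(tok, "{")) {
      nm <- substr(tok, 2L, nchar(tok) - 1L)
      if (!nm %in% names(sample)) {
        stop("template references attribute ", sQuote(nm),
             " which the sample lacks", call. = FALSE)
      }
      val <- sample[[nm]]
      if (length(val) != 1L) {
        stop("template references multi-valued attribute ", sQuote(nm),
             "; cannot substitute unambiguously", call. = FALSE)
      }
      out <- c(out, as.character(val))
    } else {
      nm <- if (startsWith(tok, "${")) substr(tok, 3L, nchar(tok) - 1L)
            else substr(tok, 2L, nchar(tok))
      if (nm %in% names(env)) {
        out <- c(out, as.character(env[[nm]]))
      } else {
        warning("environment variable ", tok,
                " is unset; left verbatim", call. = FALSE)
        out <- c(out, tok)
      }
    }
    pos <- starts[k] + lens[k]
  }
  out <- c(out, substr(template, pos, nchar(template)))
  paste(out, collapse = "")
}

#' Derive attribute values from string templates
#'
#' `spec` has two parts: `attributes`, the attribute names to derive, and
#' `sources`, a mapping of source key to template string. For each derived
#' attribute of each sample, any value exactly equal to a source key is
#' replaced by the resolved template; values matching no source key are left
#' unchanged. List values are resolved element-wise.
#'
#' @param samples a `pep_sample_table`.
#' @param spec list with `attributes` (character) and `sources` (named list
#'   of templates).
#' @param env named environment-variable mapping (`NULL`: process env).
#' @return the modified table.
#' @export
apply_derive <- function(samples, spec, env = NULL) {
  stopifnot(inherits(samples, "pep_sample_table"))
  if (is.null(spec)) return(samples)
  attrs <- as.character(spec$attributes %||% character())
  sources <- as.list(spec$sources %||% list())
  if (length(attrs) == 0L) {
    stop("derive requires a non-empty 'attributes' list", call. = FALSE)
  }
  if (length(sources) == 0L || is.null(names(sources)) ||
      !all(vapply(sources, is_scalar_string, TRUE))) {
    stop("derive requires 'sources': a mapping of source key to template string",
         call. = FALSE)
  }
  ids <- sample_ids(samples)
  for (i in seq_along(samples$rows)) {
    r <- samples$rows[[i]]
    for (a in intersect(attrs, names(r))) {
      r[[a]] <- vapply(r[[a]], function(el) {
        if (el %in% names(sources)) {
          tryCatch(resolve_template(sources[[el]], r, env),
                   error = function(e) {
                     stop(sprintf("derive failed for sample %s, attribute %s: %s",
                                  sQuote(ids[i]), sQuote(a), conditionMessage(e)),
                          call. = FALSE)
                   })
        } else el
      }, "", USE.NAMES = FALSE)
    }
    samples$rows[[i]] <- r
  }
  samples
}

#' Apply a full sample_modifiers config section
#'
#' Applies the recognized modifiers in the fixed order of
#' [sample_modifier_types()]: remove, append, duplicate, imply, derive.
#' Absent subsections are skipped; an unknown subsection name is an error.
#'
#' @param samples a `pep_sample_table`.
#' @param modifiers the parsed `sample_modifiers` config section (a named
#'   list), or `NULL` for none.
#' @param env named environment-variable mapping (`NULL`: process env).
#' @return the processed table.
#' @export
process_samples <- function(samples, modifiers, env = NULL) {
  stopifnot(inherits(samples, "pep_sample_table"))
  if (is.null(modifiers) || length(modifiers) == 0L) return(samples)
  legal <- sample_modifier_types()
  unknown <- setdiff(names(modifiers), legal)
  if (length(unknown)) {
    stop("unknown sample_modifiers subsection(s): ",
         paste(sQuote(unknown), collapse = ", "),
         "; legal names are: ", paste(legal, collapse = ", "), call. = FALSE)
  }
  for (mod in legal) {
    if (!mod %in% names(modifiers)) next
    samples <- switch(mod,
      remove    = apply_remove(samples, modifiers$remove),
      append    = apply_append(samples, modifiers$append),
      duplicate = apply_duplicate(samples, modifiers$duplicate),
      imply     = apply_imply(samples, modifiers$imply),
      derive    = apply_derive(samples, modifiers$derive, env))
  }
  samples
}
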
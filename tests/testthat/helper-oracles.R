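# Independent brute-force oracles, written without reusing any engine code,
# used to cross-check import resolution and the sample-modifier engine on
# randomly generated inputs.

# ---- import cascade oracle -------------------------------------------------

# Flatten an import tree depth-first (most distant files first, import lists
# in listed order, the importing file last) and fold top-level keys so the
# nearest definition wins. Works on configs whose non-import keys are plain
# scalars, which is all the random DAG generator emits.
oracle_flatten_imports <- function(path) {
  flatten <- function(p) {
    cfg <- yaml::read_yaml(p)
    out <- list()
    for (ip in as.character(unlist(cfg$project_modifiers$import))) {
      ipp <- if (grepl("^/", ip)) ip else file.path(dirname(p), ip)
      out <- c(out, flatten(ipp))
    }
    cfg$project_modifiers$import <- NULL
    if (length(cfg$project_modifiers) == 0L) cfg$project_modifiers <- NULL
    c(out, list(cfg))
  }
  merged <- list()
  for (cfg in flatten(path)) {
    for (k in names(cfg)) merged[[k]] <- cfg[[k]]
  }
  merged
}

# Write a random 3-file import DAG (root.yaml importing some of b.yaml,
# c.yaml; b may import c). Keys are plain scalars drawn from a small pool.
# Returns the root config path.
random_import_dag <- function(dir, seed) {
  set.seed(seed)
  keys <- c("genome", "alpha", "beta", "gamma", "kappa")
  rand_cfg <- function() {
    picked <- sample(keys, sample(1:4, 1))
    stats::setNames(as.list(paste0("v", sample(1000, length(picked)))), picked)
  }
  b <- rand_cfg()
  c_ <- rand_cfg()
  root <- rand_cfg()
  if (stats::runif(1) < 0.5) {
    b$project_modifiers <- list(import = list("c.yaml"))
  }
  targets <- sample(list("b.yaml", "c.yaml", c("b.yaml", "c.yaml"),
                         c("c.yaml", "b.yaml")), 1)[[1]]
  root$project_modifiers <- list(import = as.list(targets))
  for (nm in c("b.yaml", "c.yaml", "root.yaml")) {
    cfg <- switch(nm, b.yaml = b, c.yaml = c_, root.yaml = root)
    writeLines(yaml::as.yaml(cfg), file.path(dir, nm))
  }
  file.path(dir, "root.yaml")
}

# ---- sample-modifier oracle ------------------------------------------------

# Character-scan template substitution, mechanically unlike the engine's
# regex tokenizer. Assumes referenced attributes exist (the generator
# guarantees it); unset env vars are kept verbatim.
oracle_template <- function(tpl, r, env) {
  out <- ""
  i <- 1L
  n <- nchar(tpl)
  while (i <= n) {
    ch <- substr(tpl, i, i)
    if (ch == "{") {
      close <- regexpr("}", substr(tpl, i, n), fixed = TRUE)
      nm <- substr(tpl, i + 1L, i + close - 2L)
      out <- paste0(out, r[[nm]])
      i <- i + close
    } else if (ch == "$") {
      rest <- substr(tpl, i + 1L, n)
      if (startsWith(rest, "{")) {
        close <- regexpr("}", rest, fixed = TRUE)
        nm <- substr(rest, 2L, close - 1L)
        consumed <- close + 1L
        verbatim <- paste0("${", nm, "}")
      } else {
        m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
        nm <- if (length(m)) m else ""
        consumed <- nchar(nm) + 1L
        verbatim <- paste0("$", nm)
      }
      if (!nzchar(nm)) {
        out <- paste0(out, "$")
        i <- i + 1L
        next
      }
      out <- paste0(out, if (nm %in% names(env)) env[[nm]] else verbatim)
      i <- i + consumed
    } else {
      out <- paste0(out, ch)
      i <- i + 1L
    }
  }
  out
}

# Plain per-sample interpreter of a sample_modifiers section; operates on a
# bare list of named lists, independent of the pep_sample_table class.
oracle_modify <- function(rows, modifiers, env = list()) {
  for (nm in as.character(unlist(modifiers$remove))) {
    rows <- lapply(rows, function(r) {
      r[[nm]] <- NULL
      r
    })
  }
  for (nm in names(modifiers$append)) {
    rows <- lapply(rows, function(r) {
      if (is.null(r[[nm]])) r[[nm]] <- as.character(modifiers$append[[nm]])
      r
    })
  }
  for (old in names(modifiers$duplicate)) {
    new <- as.character(modifiers$duplicate[[old]])
    rows <- lapply(rows, function(r) {
      if (!is.null(r[[old]])) r[[new]] <- r[[old]]
      r
    })
  }
  for (rule in modifiers$imply) {
    rows <- lapply(rows, function(r) {
      ok <- TRUE
      for (a in names(rule[["if"]])) {
        want <- as.character(unlist(rule[["if"]][[a]]))
        if (is.null(r[[a]]) || !any(r[[a]] %in% want)) ok <- FALSE
      }
      if (ok) {
        for (a in names(rule[["then"]])) {
          r[[a]] <- as.character(rule[["then"]][[a]])
        }
      }
      r
    })
  }
  if (!is.null(modifiers$derive)) {
    srcs <- modifiers$derive$sources
    for (a in as.character(unlist(modifiers$derive$attributes))) {
      rows <- lapply(rows, function(r) {
        if (is.null(r[[a]])) return(r)
        r[[a]] <- vapply(r[[a]], function(el) {
          if (el %in% names(srcs)) oracle_template(srcs[[el]], r, env) else el
        }, "", USE.NAMES = FALSE)
        r
      })
    }
  }
  rows
}

# Random table (<=5 samples x <=5 attributes) plus a random modifier config
# exercising all five modifiers with sensible targets.
random_modifier_case <- function(seed) {
  set.seed(seed)
  n <- sample(1:5, 1)
  extra <- sample(c("protocol", "organism", "batch", "lane"),
                  sample(0:3, 1))
  cols <- unique(c("sample_name", extra, "path"))
  rows <- lapply(seq_len(n), function(i) {
    r <- list(sample_name = paste0("s", i))
    for (a in setdiff(cols, c("sample_name", "path"))) {
      r[[a]] <- sample(c("human", "mouse", "ATAC", "RNA", paste0("x", i)), 1)
    }
    if ("path" %in% cols) {
      r[["path"]] <- sample(c("srcA", "srcB", "plain_value"), 1)
    }
    r
  })
  mods <- list()
  which_mods <- sample(c("remove", "append", "duplicate", "imply", "derive"),
                       sample(1:5, 1))
  if ("remove" %in% which_mods && length(setdiff(cols, c("sample_name", "path")))) {
    mods$remove <- list(sample(setdiff(cols, c("sample_name", "path")), 1))
  }
  if ("append" %in% which_mods) {
    nm <- sample(c("genome", "assay", cols[length(cols)]), 1)
    mods$append <- stats::setNames(list(paste0("const", sample(99, 1))), nm)
  }
  if ("duplicate" %in% which_mods) {
    old <- sample(setdiff(cols, "path"), 1)
    mods$duplicate <- stats::setNames(list(paste0(old, "_copy")), old)
  }
  if ("imply" %in% which_mods) {
    a <- sample(cols, 1)
    want <- sample(c("human", "ATAC", "nomatch"), 1)
    mods$imply <- list(list(
      "if" = stats::setNames(list(want), a),
      "then" = list(implied = paste0("y", sample(99, 1)))))
  }
  if ("derive" %in% which_mods && "path" %in% cols) {
    mods$derive <- list(
      attributes = list("path"),
      sources = list(srcA = "$DATA/{sample_name}.fq",
                     srcB = "/fixed/{sample_name}/$MISSING_VAR.fq"))
  }
  list(rows = rows, modifiers = mods, env = list(DATA = "/data"))
}
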
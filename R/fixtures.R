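# Synthetic-PEP generator: writes parameterized config + CSV (+ schema-ready
# data files) fixture sets so every part of the engine can be exercised with
# small, locally generated, plain-text projects. Generation is fully
# deterministic under a fixed seed (byte-identical files).

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_slug <- function(n = 1, len = 6) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
  }, "")
}

#' Describe a synthetic PEP to generate
#'
#' @param n_samples number of samples.
#' @param attributes extra attribute columns beyond the identifier; values
#'   are seeded random slugs, except `organism`, drawn from human/mouse.
#' @param modifiers subset of [sample_modifier_types()] to include in the
#'   generated config.
#' @param import_depth length of the import chain above the main config
#'   (depth 2 means the config imports a parent which imports a
#'   grandparent).
#' @param n_amendments number of amendments (`amendment1`, ...) to embed,
#'   each overriding a `variant` key.
#' @param subsample_multiplicity subsample rows per sample (0 for no
#'   subsample table).
#' @param seed integer seed; the same seed always produces byte-identical
#'   files.
#' @return an object of class `pep_fixture_spec`.
#' @export
pep_fixture_spec <- function(n_samples = 3, attributes = c("protocol", "organism"),
                             modifiers = character(), import_depth = 0,
                             n_amendments = 0, subsample_multiplicity = 0,
                             seed = 1) {
  bad <- setdiff(modifiers, sample_modifier_types())
  if (length(bad)) {
    stop("unknown modifier(s) in fixture spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 attributes = as.character(attributes),
                 modifiers = as.character(modifiers),
                 import_depth = as.integer(import_depth),
                 n_amendments = as.integer(n_amendments),
                 subsample_multiplicity = as.integer(subsample_multiplicity),
                 seed = as.integer(seed)),
            class = "pep_fixture_spec")
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

write_csv_records <- function(columns, rows, path) {
  lines <- paste(csv_quote(columns), collapse = ",")
  for (r in rows) {
    lines <- c(lines, paste(csv_quote(as.character(r)), collapse = ","))
  }
  write_lines_lf(lines, path)
}

#' Generate a synthetic PEP on disk
#'
#' Writes `config.yaml`, `samples.csv`, and — depending on the spec — a
#' subsample table, an import chain, amendments, and touched `.fq` data
#' files (so `required_files` schemas can pass against the fixture). Every
#' generated PEP is structurally valid ([validate_generic()] passes).
#'
#' @param spec a [pep_fixture_spec()].
#' @param outdir output directory (created if needed).
#' @return character vector manifest of written files (paths relative to
#'   `outdir`), invisibly sorted in written order.
#' @export
generate_pep <- function(spec, outdir) {
  stopifnot(inherits(spec, "pep_fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  manifest <- character(0)
  with_fixture_seed(spec$seed, {
    ids <- paste0("sample", seq_len(spec$n_samples))
    columns <- c("sample_name", spec$attributes)
    rows <- lapply(ids, function(id) {
      vals <- lapply(spec$attributes, function(a) {
        if (a == "organism") sample(c("human", "mouse"), 1) else rand_slug()
      })
      stats::setNames(c(list(id), vals), columns)
    })
    mods <- list()

    if ("remove" %in% spec$modifiers) {
      columns <- c(columns, "scratch")
      rows <- lapply(rows, function(r) c(r, list(scratch = rand_slug())))
      mods$remove <- list("scratch")
    }
    if ("append" %in% spec$modifiers) {
      mods$append <- list(genome = "hg38")
    }
    if ("duplicate" %in% spec$modifiers) {
      first <- spec$attributes[1]
      mods$duplicate <- stats::setNames(list(paste0(first, "_copy")), first)
    }
    if ("imply" %in% spec$modifiers) {
      mods$imply <- list(list(
        "if" = list(organism = "human"),
        "then" = list(genome_assembly = "hg38")))
    }
    if ("derive" %in% spec$modifiers) {
      columns <- c(columns, "read1")
      rows <- lapply(rows, function(r) c(r, list(read1 = "source1")))
      dir.create(file.path(outdir, "data"), showWarnings = FALSE)
      for (id in ids) {
        fq <- file.path(outdir, "data", paste0(id, ".fq"))
        write_lines_lf(sprintf("@%s", id), fq)
        manifest <- c(manifest, file.path("data", paste0(id, ".fq")))
      }
      mods$derive <- list(
        attributes = list("read1"),
        sources = list(source1 = file.path(outdir, "data", "{sample_name}.fq")))
    }

    write_csv_records(columns, rows, file.path(outdir, "samples.csv"))
    manifest <- c(manifest, "samples.csv")

    cfg <- list(sample_table = "samples.csv")

    if (spec$subsample_multiplicity > 0) {
      sub_rows <- list()
      for (id in ids) {
        for (k in seq_len(spec$subsample_multiplicity)) {
          sub_rows <- c(sub_rows, list(list(
            sample_name = id,
            replicate_file = paste0(rand_slug(), "_", k, ".fq"))))
        }
      }
      write_csv_records(c("sample_name", "replicate_file"), sub_rows,
                        file.path(outdir, "subsamples.csv"))
      manifest <- c(manifest, "subsamples.csv")
      cfg$subsample_table <- "subsamples.csv"
    }

    pm <- list()
    if (spec$import_depth > 0) {
      for (d in seq(spec$import_depth, 1)) {
        parent <- list()
        parent[[paste0("layer", d)]] <- rand_slug()
        if (d < spec$import_depth) {
          parent$project_modifiers <- list(
            import = list(paste0("import_", d + 1, ".yaml")))
        }
        fn <- paste0("import_", d, ".yaml")
        write_lines_lf(strsplit(yaml::as.yaml(parent), "\n")[[1]],
                       file.path(outdir, fn))
        manifest <- c(manifest, fn)
      }
      pm$import <- list("import_1.yaml")
    }
    if (spec$n_amendments > 0) {
      pm$amend <- stats::setNames(
        lapply(seq_len(spec$n_amendments), function(i) {
          list(variant = paste0("variant", i))
        }),
        paste0("amendment", seq_len(spec$n_amendments)))
    }
    if (length(pm)) cfg$project_modifiers <- pm
    if (length(mods)) cfg$sample_modifiers <- mods

    write_lines_lf(strsplit(yaml::as.yaml(cfg), "\n")[[1]],
                   file.path(outdir, "config.yaml"))
    manifest <- c(manifest, "config.yaml")
  })
  manifest
}

#' Write the bundled worked-example PEPs
#'
#' Writes six tiny example projects, one per feature — `remove`, `append`,
#' `duplicate`, `imply`, `derive`, and `amend` — each a config paired with a
#' minimal sample CSV. These are the canonical worked examples of each
#' modifier and are used as golden tests: their processed output is
#' hand-derivable.
#'
#' @param outdir output directory (one subdirectory per example).
#' @return character vector manifest of written files relative to `outdir`.
#' @export
generate_example_peps <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(example, file, lines) {
    dir.create(file.path(outdir, example), showWarnings = FALSE)
    write_lines_lf(lines, file.path(outdir, example, file))
    manifest <<- c(manifest, file.path(example, file))
  }

  emit("remove", "project_config.yaml", c(
    "sample_table: samples.csv",
    "sample_modifiers:",
    "  remove:",
    "    - genome"))
  emit("remove", "samples.csv", c(
    "sample_name,protocol,genome",
    "s1,ATAC,hg38",
    "s2,RNA,hg38"))

  emit("append", "project_config.yaml", c(
    "sample_table: samples.csv",
    "sample_modifiers:",
    "  append:",
    "    genome: hg38"))
  emit("append", "samples.csv", c(
    "sample_name,protocol",
    "s1,ATAC",
    "s2,RNA"))

  emit("duplicate", "project_config.yaml", c(
    "sample_table: samples.csv",
    "sample_modifiers:",
    "  duplicate:",
    "    Genome: newattr"))
  emit("duplicate", "samples.csv", c(
    "sample_name,Genome",
    "s1,hg38",
    "s2,mm10"))

  emit("imply", "project_config.yaml", c(
    "sample_table: samples.csv",
    "sample_modifiers:",
    "  imply:",
    "    - if:",
    "        organism: human",
    "      then:",
    "        genome_assembly: hg38"))
  emit("imply", "samples.csv", c(
    "sample_name,organism",
    "s1,human",
    "s2,mouse"))

  emit("derive", "project_config.yaml", c(
    "sample_table: samples.csv",
    "sample_modifiers:",
    "  derive:",
    "    attributes: [read1, read2]",
    "    sources:",
    "      key1: \"/path/{attr}/{sample_name}.fq\"",
    "      key2: \"/path2/{attr}/{sample_name}.fq\""))
  emit("derive", "samples.csv", c(
    "sample_name,attr,read1,read2",
    "s1,data,key1,key2",
    "s2,data,key1,key2"))

  emit("amend", "project_config.yaml", c(
    "sample_table: annotation.csv",
    "project_modifiers:",
    "  amend:",
    "    my_project2:",
    "      sample_table: annotation2.csv",
    "    my_project3:",
    "      sample_table: annotation3.csv"))
  emit("amend", "annotation.csv", c(
    "sample_name,protocol",
    "a1,ATAC",
    "a2,RNA"))
  emit("amend", "annotation2.csv", c(
    "sample_name,protocol",
    "b1,ChIP"))
  emit("amend", "annotation3.csv", c(
    "sample_name,protocol",
    "c1,WGBS",
    "c2,RRBS",
    "c3,ATAC"))

  manifest
}
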
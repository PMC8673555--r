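write_schema <- function(dir, name, lines) {
  write_pep_files(dir, stats::setNames(list(lines), name))
  file.path(dir, name)
}

pipeline_schema_lines <- c(
  "description: toy pipeline schema",
  "properties:",
  "  samples:",
  "    type: array",
  "    items:",
  "      type: object",
  "      properties:",
  "        genome:",
  "          type: string",
  "          enum: [hg38, mm10]",
  "        read1:",
  "          type: string",
  "      required: [read1, read2, genome]")

test_that("schemas load from YAML and JSON with imports kept separate", {
  dir <- withr::local_tempdir()
  sp <- write_schema(dir, "one.yaml", pipeline_schema_lines)
  sc <- load_schema(sp)
  expect_s3_class(sc, "pep_schema")
  expect_length(sc$schemas, 1L)

  jp <- file.path(dir, "one.json")
  jsonlite::write_json(yaml::read_yaml(sp), jp, auto_unbox = TRUE)
  expect_length(load_schema(jp)$schemas, 1L)

  write_schema(dir, "base.yaml", c("properties:", "  samples:", "    items:",
                                   "      required: [sample_name]"))
  ip <- write_schema(dir, "special.yaml", c("imports:", "  - base.yaml",
                                            pipeline_schema_lines))
  chain <- load_schema(ip)
  expect_length(chain$schemas, 2L)
  # imported schema first, importing schema last
  expect_match(chain$schemas[[1]]$source, "base\\.yaml$")

  cyc <- write_schema(dir, "cyc.yaml", c("imports:", "  - cyc.yaml"))
  expect_error(load_schema(cyc), "cycle")
  expect_error(load_schema("https://example.org/s.yaml"), "remote")
  expect_error(load_schema(file.path(dir, "nope.yaml")), "not found")
})

test_that("two-stage validation reports failures on processed samples", {
  dir <- withr::local_tempdir()
  write_pep_files(dir, list(
    "project_config.yaml" = c("sample_table: samples.csv",
                              "sample_modifiers:",
                              "  append:",
                              "    genome: hg38",
                              "    read2: auto.fq"),
    "samples.csv" = c("sample_name,read1", "s1,a.fq", "s2,b.fq")))
  sp <- write_schema(dir, "schema.yaml", pipeline_schema_lines)
  prj <- load_project(file.path(dir, "project_config.yaml"))
  rep <- validate_pep(prj, load_schema(sp))
  # raw table lacks read2 and genome; both arrive via append, so this passes
  expect_true(rep$passed)
  expect_equal(nrow(rep$failures), 0L)

  # without the modifiers the same schema names the missing attribute/sample
  raw <- load_project_from_table(file.path(dir, "samples.csv"))
  rep2 <- validate_pep(raw, load_schema(sp))
  expect_false(rep2$passed)
  expect_true(any(grepl("read2", rep2$failures$message)))
  expect_true(any(rep2$failures$subject == "s1"))
  expect_true(all(rep2$failures$stage == "sample"))
})

test_that("config-level rules are checked in stage 1", {
  dir <- withr::local_tempdir()
  cfgp <- basic_pep(dir, "genome_build: hg38")
  sp <- write_schema(dir, "cfg.yaml", c(
    "properties:",
    "  genome_build:",
    "    enum: [hg19, hg38]",
    "required: [genome_build, output_dir]"))
  rep <- validate_pep(load_project(cfgp), load_schema(sp))
  expect_false(rep$passed)
  expect_equal(rep$failures$stage, "config")
  expect_true(any(grepl("output_dir", rep$failures$message)))
  # enum ok for the present key
  expect_false(any(rep$failures$rule == "enum"))
})

test_that("enum, pattern, and type keywords catch bad values", {
  dir <- withr::local_tempdir()
  write_pep_files(dir, list(
    "project_config.yaml" = "sample_table: samples.csv",
    "samples.csv" = c("sample_name,genome,nreads",
                      "s1,danRer11,abc")))
  sp <- write_schema(dir, "s.yaml", c(
    "properties:",
    "  samples:",
    "    items:",
    "      properties:",
    "        genome:",
    "          enum: [hg38, mm10]",
    "        nreads:",
    "          type: integer",
    "        sample_name:",
    "          pattern: \"^s[0-9]+$\""))
  rep <- validate_pep(load_project(file.path(dir, "project_config.yaml")),
                      load_schema(sp))
  expect_false(rep$passed)
  expect_setequal(rep$failures$rule, c("enum", "type"))
})

test_that("an empty schema passes and a report's flag matches its failures", {
  dir <- withr::local_tempdir()
  cfgp <- basic_pep(dir)
  sp <- write_schema(dir, "empty.yaml", "description: no rules")
  rep <- validate_pep(load_project(cfgp), load_schema(sp))
  expect_true(rep$passed)
  expect_identical(rep$passed, nrow(rep$failures) == 0L)
})

test_that("required_files checks every element and flags absences", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "good.fq")
  writeLines("@r1", good)
  s <- list(sample_name = "s1", read1 = good,
            read2 = file.path(dir, "missing.fq"),
            multi = c(good, file.path(dir, "gone.fq")))
  expect_equal(nrow(check_required_files(s, "read1", "s1")), 0L)
  f <- check_required_files(s, "read2", "s1")
  expect_equal(nrow(f), 1L)
  expect_match(f$message, "missing.fq")
  # one good and one missing element -> exactly one failure naming it
  fm <- check_required_files(s, "multi", "s1")
  expect_equal(nrow(fm), 1L)
  expect_match(fm$message, "gone.fq")
  # absent attribute is a failure; a directory does not count as a file
  expect_equal(nrow(check_required_files(s, "absent", "s1")), 1L)
  sdir <- list(read1 = dir)
  expect_equal(nrow(check_required_files(sdir, "read1", "s1")), 1L)
})

test_that("required_files participates in schema validation", {
  dir <- withr::local_tempdir()
  writeLines("@r", file.path(dir, "s1.fq"))
  write_pep_files(dir, list(
    "project_config.yaml" = c("sample_table: samples.csv",
                              "sample_modifiers:",
                              "  derive:",
                              "    attributes: [read1]",
                              "    sources:",
                              paste0("      local: \"", dir, "/{sample_name}.fq\"")),
    "samples.csv" = c("sample_name,read1", "s1,local", "s2,local")))
  sp <- write_schema(dir, "files.yaml", c(
    "properties:",
    "  samples:",
    "    items:",
    "      required_files: [read1]"))
  rep <- validate_pep(load_project(file.path(dir, "project_config.yaml")),
                      load_schema(sp))
  # s1.fq exists, s2.fq does not
  expect_false(rep$passed)
  expect_equal(rep$failures$subject, "s2")
  expect_match(rep$failures$message, "s2.fq")
})

test_that("generic validation accepts sound projects and flags misspellings", {
  dir <- withr::local_tempdir()
  cfgp <- basic_pep(dir, c("sample_modifiers:",
                           "  append:",
                           "    genome: hg38"))
  expect_true(validate_generic(load_project(cfgp))$passed)

  bad <- list(sample_table = "x.csv",
              sample_modifiers = list(appendd = list(genome = "hg38")))
  rep <- validate_generic(bad)
  expect_false(rep$passed)
  expect_match(rep$failures$message, "appendd")

  badpm <- list(project_modifiers = list(imports = list("x.yaml")))
  expect_false(validate_generic(badpm)$passed)

  # empty identifier is a structural failure on the project form
  prj <- load_project(cfgp)
  prj$samples$rows[[1]]$sample_name <- ""
  repp <- validate_generic(prj)
  expect_false(repp$passed)
  expect_true(any(repp$failures$rule == "identifier"))
})
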
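# Helpers to build small PEPs on disk inside tests.

write_pep_files <- function(dir, files) {
  for (nm in names(files)) {
    path <- file.path(dir, nm)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    con <- file(path, open = "wb")
    writeLines(files[[nm]], con, sep = "\n")
    close(con)
  }
  file.path(dir, names(files)[1])
}

# A minimal two-sample PEP; returns the config path.
basic_pep <- function(dir, extra_config = character(0)) {
  write_pep_files(dir, list(
    "project_config.yaml" = c("sample_table: samples.csv", extra_config),
    "samples.csv" = c("sample_name,protocol",
                      "s1,ATAC",
                      "s2,RNA")))
}

# Build a sample table object directly (no disk) from a list of named lists.
make_table <- function(rows, index = "sample_name") {
  columns <- unique(unlist(lapply(rows, names)))
  new_sample_table(rows, columns, index)
}

# Sort each row's attributes by name for order-insensitive comparison.
sorted_rows <- function(rows) {
  lapply(rows, function(r) r[order(names(r))])
}
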
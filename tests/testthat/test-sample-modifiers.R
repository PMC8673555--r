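two_samples <- function() {
  make_table(list(
    list(sample_name = "s1", organism = "human", genome = "hg38"),
    list(sample_name = "s2", organism = "mouse", genome = "mm10")))
}

test_that("remove deletes the attribute everywhere and nothing else", {
  tbl <- two_samples()
  out <- apply_remove(tbl, "genome")
  expect_false("genome" %in% out$columns)
  expect_false(any(vapply(out$rows, function(r) "genome" %in% names(r), TRUE)))
  expect_equal(get_sample(out, "s1")$organism, "human")
  expect_identical(apply_remove(tbl, character(0)), tbl)
  expect_warning(out2 <- apply_remove(tbl, "absent"), "absent")
  expect_equal(out2$rows, tbl$rows)
})

test_that("append adds constants without overwriting table values", {
  tbl <- two_samples()
  out <- apply_append(tbl, list(assay = "ATAC"))
  expect_true(all(vapply(out$rows, function(r) r$assay == "ATAC", TRUE)))
  expect_equal(out$columns, c("sample_name", "organism", "genome", "assay"))
  # table-derived values are ground truth
  kept <- apply_append(tbl, list(genome = "hg19"))
  expect_equal(get_sample(kept, "s1")$genome, "hg38")
  expect_equal(get_sample(kept, "s2")$genome, "mm10")
  expect_identical(apply_append(tbl, list()), tbl)
  # idempotence: a second application changes nothing
  expect_identical(apply_append(out, list(assay = "ATAC")), out)
})

test_that("duplicate copies values independently under the new name", {
  tbl <- two_samples()
  out <- apply_duplicate(tbl, list(genome = "newattr"))
  expect_equal(get_sample(out, "s1")$newattr, "hg38")
  expect_equal(get_sample(out, "s1")$genome, "hg38")
  expect_error(apply_duplicate(tbl, list(genome = "genome")), "differ")
  expect_identical(apply_duplicate(tbl, list()), tbl)
  # list values are copied, and mutating the copy leaves the original alone
  ltbl <- make_table(list(list(sample_name = "s1", read1 = c("a.fq", "b.fq"))))
  dup <- apply_duplicate(ltbl, list(read1 = "read1_copy"))
  dup$rows[[1]]$read1_copy[1] <- "changed"
  expect_equal(dup$rows[[1]]$read1, c("a.fq", "b.fq"))
})

test_that("imply requires all conditions and overwrites targets on match", {
  tbl <- make_table(list(
    list(sample_name = "s1", organism = "human", protocol = "ATAC"),
    list(sample_name = "s2", organism = "human", protocol = "RNA"),
    list(sample_name = "s3", organism = "mouse", protocol = "ATAC")))
  rule <- list("if" = list(organism = "human", protocol = "ATAC"),
               "then" = list(genome_assembly = "hg38"))
  out <- apply_imply(tbl, list(rule))
  expect_equal(get_sample(out, "s1")$genome_assembly, "hg38")
  expect_null(get_sample(out, "s2")$genome_assembly)
  expect_null(get_sample(out, "s3")$genome_assembly)
  # list-valued condition matches membership
  alt <- apply_imply(tbl, list(list(
    "if" = list(organism = list("human", "rat")),
    "then" = list(clade = "mammal"))))
  expect_equal(get_sample(alt, "s1")$clade, "mammal")
  # condition on an absent attribute never matches; no-rule is identity
  none <- apply_imply(tbl, list(list("if" = list(ghost = "x"),
                                     "then" = list(flag = "y"))))
  expect_equal(none$rows, tbl$rows)
  expect_identical(apply_imply(tbl, list()), tbl)
  expect_error(apply_imply(tbl, list(list("if" = list(), "then" = list(a = "b")))),
               "non-empty")
  expect_error(apply_imply(tbl, list(list("if" = list(a = "b"),
                                          "then" = list(a = NULL)))),
               "null")
})

test_that("template resolution is single-pass over attributes and env", {
  s <- list(sample_name = "s1", attr = "data", b = "{a}", a = "x")
  expect_equal(resolve_template("{sample_name}", s, env = list()), "s1")
  expect_equal(resolve_template("no placeholders", s, env = list()),
               "no placeholders")
  expect_equal(resolve_template("/path/{attr}/{sample_name}.fq", s,
                                env = list()), "/path/data/s1.fq")
  # substituted text is never re-expanded
  expect_equal(resolve_template("{a}{b}", s, env = list()), "x{a}")
  expect_equal(resolve_template("$DATAPATH/{sample_name}.fq", s,
                                env = list(DATAPATH = "/data")), "/data/s1.fq")
  expect_equal(resolve_template("${DATAPATH}!", s,
                                env = list(DATAPATH = "/d")), "/d!")
  expect_error(resolve_template("{missing}", s, env = list()), "missing")
  expect_warning(out <- resolve_template("$UNSET_XYZ/{attr}", s, env = list()),
                 "UNSET_XYZ")
  expect_equal(out, "$UNSET_XYZ/data")
})

test_that("derive rewrites only values equal to a source key", {
  tbl <- make_table(list(
    list(sample_name = "s1", attr = "data", read1 = "key1"),
    list(sample_name = "s2", attr = "data", read1 = "untouched.fq")))
  spec <- list(attributes = list("read1"),
               sources = list(key1 = "/path/{attr}/{sample_name}.fq"))
  out <- apply_derive(tbl, spec, env = list())
  expect_equal(get_sample(out, "s1")$read1, "/path/data/s1.fq")
  expect_equal(get_sample(out, "s2")$read1, "untouched.fq")
  # derive is idempotent once values no longer match a source key
  expect_equal(apply_derive(out, spec, env = list())$rows, out$rows)
  # list values resolve element-wise
  ltbl <- make_table(list(
    list(sample_name = "s1", attr = "d", read1 = c("key1", "plain"))))
  lout <- apply_derive(ltbl, spec, env = list())
  expect_equal(lout$rows[[1]]$read1, c("/path/d/s1.fq", "plain"))
  # failures carry the sample identifier and attribute
  bad <- make_table(list(list(sample_name = "s9", read1 = "key1")))
  expect_error(apply_derive(bad, spec, env = list()), "s9.*read1")
  expect_error(apply_derive(tbl, list(attributes = list(), sources = list(a = "t"))),
               "attributes")
  expect_error(apply_derive(tbl, list(attributes = list("read1"), sources = list())),
               "sources")
})

test_that("process_samples applies the fixed modifier order", {
  tbl <- make_table(list(list(sample_name = "s1", path = "src")))
  mods <- list(
    append = list(genome = "hg38", attr = "data"),
    imply = list(list("if" = list(genome = "hg38"),
                      "then" = list(species = "human"))),
    derive = list(attributes = list("path"),
                  sources = list(src = "/p/{attr}/{species}/{sample_name}.fq")))
  out <- process_samples(tbl, mods, env = list())
  # imply saw append's output, derive saw both
  expect_equal(get_sample(out, "s1")$species, "human")
  expect_equal(get_sample(out, "s1")$path, "/p/data/human/s1.fq")
  expect_identical(process_samples(tbl, NULL), tbl)
  expect_identical(process_samples(tbl, list()), tbl)
  expect_error(process_samples(tbl, list(appendd = list(a = "b"))),
               "appendd.*remove, append, duplicate, imply, derive")
})

test_that("modifiers preserve sample count and order and untouched attributes", {
  tbl <- make_table(list(
    list(sample_name = "s1", organism = "human", keepme = "  spaced  "),
    list(sample_name = "s2", organism = "mouse", keepme = "x,y")))
  mods <- list(remove = list("organism"), append = list(g = "1"),
               imply = list(list("if" = list(g = "1"),
                                 "then" = list(h = "2"))))
  out <- process_samples(tbl, mods)
  expect_equal(sample_ids(out), c("s1", "s2"))
  expect_equal(get_sample(out, "s1")$keepme, "  spaced  ")
  expect_equal(get_sample(out, "s2")$keepme, "x,y")
})
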
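# Reading, labelling, deduplication and terminal-missing filtering.

`%+%` <- function(a, b) paste0(a, b)

write_fasta_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("FASTA round-trip preserves ids and residues, normalizes case", {
  path <- write_fasta_lines(c(">a1|Arabidopsis thaliana|Arabidopsis|ITS1", "acgtACGT",
                              ">a2|A. lyrata|Arabidopsis|ITS1", "GGGCC", "CAT"))
  recs <- read_its_fasta(path)
  expect_equal(recs$id, c("a1", "a2"))
  expect_equal(recs$residues, c("ACGTACGT", "GGGCCCAT"))  # uppercased, unwrapped
  expect_equal(recs$species[1], "Arabidopsis thaliana")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_its_fasta(recs, out)
  again <- read_its_fasta(out)
  expect_equal(again[, c("id", "residues")], recs[, c("id", "residues")])
})

test_that("U and T are both accepted and preserved as read", {
  path <- write_fasta_lines(c(">r1|||ITS2", "ACGU", ">r2|||ITS2", "ACGT"))
  recs <- read_its_fasta(path)
  expect_equal(recs$residues, c("ACGU", "ACGT"))
})

test_that("illegal residues and missing region labels are rejected", {
  bad <- write_fasta_lines(c(">x|||ITS1", "ACXGT"))
  expect_error(read_its_fasta(bad), "illegal character")
  noregion <- write_fasta_lines(c(">x", "ACGT"))
  expect_error(read_its_fasta(noregion), "without region")
  expect_equal(read_its_fasta(noregion, region = "ITS1")$region, "ITS1")
})

test_that("metadata sidecar fills fields missing from headers", {
  path <- write_fasta_lines(c(">acc1", "ACGT", ">acc2", "GGCC"))
  md <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(id = c("acc1", "acc2"),
                         species = c("sp A", "sp B"),
                         group = c("subgenusA", "subgenusB"),
                         region = c("ITS2", "ITS2")),
              md, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_its_fasta(path, metadata = md)
  expect_equal(recs$species, c("sp A", "sp B"))
  expect_equal(recs$group, c("subgenusA", "subgenusB"))
  expect_equal(recs$region, c("ITS2", "ITS2"))
})

test_that("dedupe keeps one haplotype per species, across-species copies stay", {
  recs <- make_records(c("ACGT", "ACGT", "ACGA", "ACGT"),
                       species = c("sp1", "sp1", "sp1", "sp2"))
  out <- dedupe_identical(recs)
  expect_equal(out$id, c("s1", "s3", "s4"))  # same-species duplicate dropped
  # gaps are ignored for identity; T vs U distinct unless collapsed
  recs2 <- make_records(c("AC-GT", "ACGT", "ACGU"), species = "sp1")
  expect_equal(nrow(dedupe_identical(recs2)), 2)
  expect_equal(nrow(dedupe_identical(recs2, collapse_tu = TRUE)), 1)
})

test_that("dedupe is idempotent and safe on empty input", {
  withr::with_seed(11, {
    recs <- make_records(replicate(30, random_rna(8, c("A", "C", "G", "T"))),
                         species = sample(c("a", "b", "c"), 30, replace = TRUE))
  })
  once <- dedupe_identical(recs)
  expect_identical(dedupe_identical(once), once)
  expect_equal(nrow(dedupe_identical(recs[0, ])), 0)
})

test_that("terminal missing-data filter applies the threshold rule", {
  recs <- make_records(c(strrep("N", 11) %+% "ACGTACGT",
                         "NNACGTACGT",
                         "ACGT",
                         "ACGTACGT" %+% strrep("-", 12)))
  out <- filter_terminal_missing(recs, max_terminal = 10)
  expect_equal(out$id, c("s2", "s3"))
  expect_equal(attr(out, "removed")$id, c("s1", "s4"))
  # surviving residues untouched
  expect_equal(out$residues, recs$residues[2:3])
  # zero threshold still keeps clean sequences
  expect_equal(filter_terminal_missing(make_records("ACGT"), 0)$id, "s1")
})
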
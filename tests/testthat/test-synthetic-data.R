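# Synthetic ITS-like family generator.

test_that("ancestors carry the conserved motifs and the planted fold", {
  cf <- synth_config("ITS1", seed = 5)
  anc <- build_ancestor(cf)
  s <- anc$record$residues
  expect_equal(nchar(s), 263)
  expect_true(startsWith(s, "TCGAA"))
  expect_true(endsWith(s, "TTCGA"))
  expect_true(grepl("AAGGAA", s, fixed = TRUE))
  expect_equal(count_hairpins(anc$structure), cf$n_stems)
  expect_lte(abs(gc_content(s) - cf$gc_target), 0.02)
  # the planted structure is a valid, stabilizing fold of the ancestor
  expect_silent(validate_structure(s, anc$structure))
  expect_lt(anc$structure$energy, 0)

  cf2 <- synth_config("ITS2", seed = 5)
  anc2 <- build_ancestor(cf2)
  expect_equal(nchar(anc2$record$residues), 206)
  expect_equal(count_hairpins(anc2$structure), 3)
  expect_false(grepl("AAGGAA", anc2$record$residues, fixed = TRUE))
})

test_that("infeasible length budgets are rejected", {
  expect_error(synth_config("ITS1", length = 60), "infeasible")
})

test_that("zero divergence copies the ancestor; seeds reproduce families", {
  cf <- synth_config("ITS1", divergence = 0, seed = 6)
  fam <- synth_family(cf)
  expect_equal(nrow(fam$records), cf$n_groups * cf$n_species_per_group)
  expect_true(all(fam$records$residues == fam$ancestor$residues))

  cf2 <- synth_config("ITS2", divergence = 0.2, seed = 7)
  expect_identical(synth_family(cf2)$records, synth_family(cf2)$records)
})

test_that("full compensation keeps every planted stem pairable", {
  cf <- synth_config("ITS1", compensatory_fraction = 1, divergence = 0.3, seed = 8)
  fam <- synth_family(cf)
  pr <- fam$planted$pairs
  ok_pair <- function(a, b) paste0(a, b) %in% ALLOWED_STEPS
  for (k in seq_len(nrow(fam$records))) {
    ch <- strsplit(gsub("T", "U", fam$records$residues[k], fixed = TRUE), "")[[1]]
    good <- vapply(seq_len(nrow(pr)), function(q)
      ok_pair(ch[pr[q, 1]], ch[pr[q, 2]]), logical(1))
    expect_true(all(good), info = paste("tip", k))
  }
  # motifs never mutate
  expect_true(all(startsWith(fam$records$residues, "TCGAA")))
  expect_true(all(endsWith(fam$records$residues, "TTCGA")))
  expect_true(all(grepl("AAGGAA", fam$records$residues, fixed = TRUE)))
})

test_that("divergence produces within-family variation at the expected order", {
  cf <- synth_config("ITS2", divergence = 0.15, seed = 9)
  fam <- synth_family(cf)
  diffs <- vapply(fam$records$residues, function(s) {
    a <- strsplit(s, "")[[1]]; b <- strsplit(fam$ancestor$residues, "")[[1]]
    sum(a != b)
  }, 0L)
  expect_true(all(diffs > 0))
  # multiple hits cap realized differences below the Poisson mean
  expect_lt(mean(diffs), 0.15 * 206)
  expect_gt(mean(diffs), 0.15 * 206 * 0.5)
})

test_that("family writer emits FASTA, sidecar and planted structure", {
  fam <- synth_family(synth_config("ITS2", seed = 10))
  dir <- withr::local_tempdir()
  paths <- write_synth_family(fam, dir)
  expect_true(all(file.exists(paths)))
  back <- read_its_fasta(paths["fasta"])
  expect_equal(back$residues, fam$records$residues)
  expect_equal(back$group, fam$records$group)
  md <- read.delim(paths["metadata"])
  expect_equal(nrow(md), nrow(fam$records))
})
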
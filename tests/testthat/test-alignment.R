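# Alignment descriptive statistics, ambiguous-column removal, indel coding,
# GC content.

test_that("variable and parsimony-informative columns follow parsimony rules", {
  a <- its_alignment(paste0("r", 1:4), c("AT", "AT", "GC", "GC"))
  s <- variable_and_pi_sites(a)
  expect_equal(c(s$n_variable, s$n_pi), c(2, 2))
  expect_equal(s$pct_variable, 100)

  b <- its_alignment(paste0("r", 1:3), c("AA", "AA", "AA"))
  sb <- variable_and_pi_sites(b)
  expect_equal(c(sb$n_variable, sb$n_pi), c(0, 0))

  # singleton state: variable but not informative
  d <- its_alignment(paste0("r", 1:4), c("AT", "AT", "AT", "AC"))
  sd_ <- variable_and_pi_sites(d)
  expect_equal(c(sd_$n_variable, sd_$n_pi), c(1, 0))

  # gaps and ambiguity codes are not states
  e <- its_alignment(paste0("r", 1:4), c("A-", "AR", "A-", "AN"))
  se <- variable_and_pi_sites(e)
  expect_equal(c(se$n_variable, se$n_pi), c(0, 0))

  expect_error(its_alignment("r1", "ACGT"), "at least 2 rows")
})

test_that("site classification matches a per-column brute-force oracle", {
  classify_col <- function(col) {
    col[col == "U"] <- "T"
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    c(variable = length(tab) >= 2, pi = sum(tab >= 2) >= 2)
  }
  withr::with_seed(71, {
    for (rep in 1:25) {
      m <- matrix(sample(c("A", "C", "G", "T", "-", "N", "R"), 6 * 20,
                         replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.03, 0.03)),
                  nrow = 6)
      a <- its_alignment(paste0("r", 1:6), apply(m, 1, paste, collapse = ""))
      s <- variable_and_pi_sites(a)
      oracle <- t(apply(m, 2, classify_col))
      expect_equal(s$n_variable, sum(oracle[, "variable"]))
      expect_equal(s$n_pi, sum(oracle[, "pi"]))
    }
  })
})

test_that("PI count never exceeds variable count and never grows when a row is dropped", {
  withr::with_seed(72, {
    for (rep in 1:10) {
      rows <- replicate(5, random_rna(15, c("A", "C", "G", "T")))
      a <- its_alignment(paste0("r", 1:5), rows)
      s <- variable_and_pi_sites(a)
      expect_lte(s$n_pi, s$n_variable)
      sub <- variable_and_pi_sites(its_alignment(paste0("r", 1:4), rows[-5]))
      expect_lte(sub$n_pi, s$n_pi)
    }
  })
})

test_that("ambiguous-column removal drops coded and masked columns", {
  a <- its_alignment(c("r1", "r2"), c("ART", "AAT"))
  res <- remove_ambiguous_columns(a)
  expect_equal(res$alignment$rows, c("AT", "AT"))
  expect_equal(res$column_map$old, c(1, 3))

  clean <- its_alignment(c("r1", "r2"), c("ACGT", "ACGA"))
  expect_equal(remove_ambiguous_columns(clean)$alignment$rows, clean$rows)

  masked <- remove_ambiguous_columns(clean, mask = list(c(1, 1)))
  expect_equal(masked$alignment$rows, c("CGT", "CGA"))
  expect_error(remove_ambiguous_columns(clean, mask = list(c(2, 9))), "out of bounds")
})

test_that("simple indel coding applies the exact-span and containment rules", {
  a <- its_alignment(c("r1", "r2", "r3"), c("A--T", "A--T", "ACGT"))
  cg <- code_gaps_binary(a)
  expect_equal(nrow(cg$characters), 1)
  expect_equal(cg$characters$start, 2)
  expect_equal(cg$characters$end, 3)
  expect_equal(unname(cg$states[, 1]), c(1L, 1L, 0L))

  # span 2-3 strictly contains span 3-3: the long-gap row scores missing
  b <- its_alignment(c("r1", "r2", "r3"), c("A--T", "AC-T", "ACGT"))
  cgb <- code_gaps_binary(b)
  expect_equal(cgb$characters, data.frame(start = c(2, 3), end = c(3, 3)))
  expect_equal(unname(cgb$states[, "indel_2_3"]), c(1L, 0L, 0L))
  expect_equal(unname(cgb$states[, "indel_3_3"]), c(NA_integer_, 1L, 0L))

  # no gaps, no characters
  expect_equal(ncol(code_gaps_binary(its_alignment(c("r1", "r2"),
                                                   c("ACGT", "ACGA")))$states), 0)
})

test_that("indel matrix writer emits 0/1/? TSV plus a NEXUS block", {
  a <- its_alignment(c("r1", "r2", "r3"), c("A--T", "AC-T", "ACGT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_indel_matrix(code_gaps_binary(a), path)
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  expect_equal(tab$indel_3_3, c("?", "1", "0"))
  nex <- readLines(paste0(path, ".nex"))
  expect_true(any(grepl("NCHAR=2", nex)))
})

test_that("GC content counts determined bases and honours its invariances", {
  expect_equal(unname(gc_content("GGCC")), 1)
  expect_equal(unname(gc_content("ATAT")), 0)
  expect_equal(unname(gc_content("ACGT")), 0.5)
  expect_equal(unname(gc_content("ACGTNN--RY")), 0.5)  # N/ambiguity/gaps ignored
  expect_error(gc_content("NNN"), "no countable bases")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  withr::with_seed(73, {
    for (rep in 1:20) {
      s <- random_rna(30, c("A", "C", "G", "T"))
      g <- unname(gc_content(s))
      rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      comp_s <- paste(comp[strsplit(s, "")[[1]]], collapse = "")
      expect_equal(unname(gc_content(rev_s)), g)
      expect_equal(unname(gc_content(comp_s)), g)
    }
  })
})
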
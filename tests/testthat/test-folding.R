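# Folding engines: base-pair maximization, MFE, suboptimal enumeration,
# energy evaluation.

test_that("nussinov handles worked examples", {
  expect_equal(nussinov_maxpairs("GCGAAACGC")$max_pairs, brute_max_pairs("GCGAAACGC"))
  expect_equal(nussinov_maxpairs("GCGAAACGC")$max_pairs, 3)

  res <- nussinov_maxpairs("AAAA")
  expect_equal(res$max_pairs, 0)
  expect_equal(res$structure$dotbracket, "....")

  res2 <- nussinov_maxpairs("GAAAC")
  expect_equal(res2$max_pairs, 1)
  expect_equal(unname(res2$structure$pairs[1, ]), c(1L, 5L))

  expect_error(nussinov_maxpairs("GANAC"), "outside A/C/G/T/U")
})

test_that("nussinov equals brute-force maximum pairing on short sequences", {
  withr::with_seed(101, {
    for (rep in 1:120) {
      s <- random_rna(sample(5:13, 1))
      expect_equal(nussinov_maxpairs(s)$max_pairs, brute_max_pairs(s),
                   info = s)
    }
  })
})

test_that("fold_mfe reproduces hand-computed energies", {
  open <- fold_mfe("AAAAAAA")
  expect_equal(open$dotbracket, ".......")
  expect_equal(open$energy, 0)

  st <- fold_mfe("GGGAAAACCC")
  expect_equal(st$dotbracket, "(((....)))")
  # two GC/GC stacks plus a size-4 hairpin loop, summed from the shipped table
  m <- default_energy_model()
  expect_equal(st$energy, 2 * m$stack["GC", "GC"] + m$hairpin[4])

  expect_error(fold_mfe("ACGTX"), "outside A/C/G/T/U")
})

test_that("fold_mfe is deterministic and invariant under T/U relabeling", {
  withr::with_seed(102, s <- random_rna(60))
  a <- fold_mfe(s)
  b <- fold_mfe(s)
  expect_identical(a$dotbracket, b$dotbracket)
  expect_identical(a$energy, b$energy)
  s_dna <- gsub("U", "T", s, fixed = TRUE)
  expect_equal(fold_mfe(s_dna)$energy, a$energy)
  expect_equal(fold_mfe(s_dna)$dotbracket, a$dotbracket)
})

test_that("fold_mfe is never beaten by the nussinov structure's energy", {
  withr::with_seed(103, {
    for (rep in 1:20) {
      s <- random_rna(sample(10:40, 1))
      mfe <- fold_mfe(s)
      nus <- nussinov_maxpairs(s)$structure
      expect_lte(mfe$energy, evaluate_energy(s, nus) + 1e-9)
    }
  })
})

test_that("evaluate_energy decomposes loops correctly", {
  expect_equal(evaluate_energy("AAAAAAA", "......."), 0)
  m <- default_energy_model()
  # single pair: one size-3 hairpin loop, no other terms in this model
  expect_equal(evaluate_energy("GAAAC", "(...)"), m$hairpin[3])
  # bulge and multiloop decompositions against hand sums
  expect_equal(evaluate_energy("GGAAAACCA", "((....)).") ,
               m$stack["GC", "GC"] + m$hairpin[4])
  expect_equal(evaluate_energy("GGAAAAACC", "((.....))"),
               m$stack["GC", "GC"] + m$hairpin[5])
  # internal consistency with the DP energy
  withr::with_seed(104, {
    for (rep in 1:15) {
      s <- random_rna(sample(20:70, 1))
      st <- fold_mfe(s)
      expect_equal(evaluate_energy(s, st), st$energy, tolerance = 1e-9)
    }
  })
  expect_error(evaluate_energy("GAAAC", rna_structure(dotbracket = "(....")),
               "unbalanced")
})

test_that("fold_mfe energy equals the exhaustive-enumeration minimum (short)", {
  withr::with_seed(105, {
    for (rep in 1:80) {
      s <- random_rna(sample(5:13, 1))
      expect_equal(fold_mfe(s)$energy, brute_min_energy(s), tolerance = 1e-9,
                   info = s)
    }
  })
})

test_that("suboptimal enumeration honours its contracts", {
  # open chain: single structure
  fr <- fold_suboptimal("AAAAAAA")
  expect_equal(fr$n_structures, 1)
  expect_equal(fr$les, 0)

  fr2 <- fold_suboptimal("GGGAAAACCC")
  expect_identical(fr2$structures[[1]]$dotbracket, fold_mfe("GGGAAAACCC")$dotbracket)
  expect_equal(fr2$les, fr2$structures[[1]]$energy)

  withr::with_seed(106, seqs <- replicate(6, random_rna(sample(50:90, 1))))
  for (s in seqs) {
    fr <- fold_suboptimal(s, max_structures = 8, percent_window = 25,
                          min_pair_distance = 3)
    expect_lte(fr$n_structures, 8)
    energies <- vapply(fr$structures, `[[`, 0, "energy")
    expect_identical(energies, sort(energies))        # non-decreasing
    expect_equal(energies[1], fr$les)
    threshold <- fr$les * (1 - 25 / 100)
    expect_true(all(energies <= threshold + 1e-6))    # all within the window
    if (fr$n_structures > 1) {
      combs <- utils::combn(fr$n_structures, 2)
      dists <- apply(combs, 2, function(ij)
        length(setdiff(union(apply(fr$structures[[ij[1]]]$pairs, 1, paste, collapse = ":"),
                             apply(fr$structures[[ij[2]]]$pairs, 1, paste, collapse = ":")),
                       intersect(apply(fr$structures[[ij[1]]]$pairs, 1, paste, collapse = ":"),
                                 apply(fr$structures[[ij[2]]]$pairs, 1, paste, collapse = ":")))))
      expect_true(all(dists >= 3))
    }
    # deterministic
    fr_b <- fold_suboptimal(s, max_structures = 8, percent_window = 25,
                            min_pair_distance = 3)
    expect_identical(vapply(fr$structures, `[[`, "", "dotbracket"),
                     vapply(fr_b$structures, `[[`, "", "dotbracket"))
  }
})

test_that("energy model file parses completely and symmetrically", {
  m <- read_energy_model()
  expect_true(all(is.finite(m$stack)))
  # thermodynamic symmetry: stack(P,Q) == stack(rev(Q),rev(P))
  rev1 <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (p in rownames(m$stack))
    for (q in colnames(m$stack))
      expect_equal(m$stack[p, q], m$stack[rev1[[q]], rev1[[p]]])
  # Watson-Crick stacks are stabilizing; loop penalties non-negative
  wc <- c("AU", "UA", "GC", "CG")
  expect_true(all(m$stack[wc, wc] < 0))
  expect_true(all(m$hairpin[is.finite(m$hairpin)] >= 0))
  expect_true(all(m$hairpin[seq_len(m$min_loop - 1)] == Inf))
  # log extrapolation beyond the table end is increasing
  e31 <- itsfold:::loop_penalty(m$hairpin, 31, m$loop_coef)
  e60 <- itsfold:::loop_penalty(m$hairpin, 60, m$loop_coef)
  expect_gt(e31, m$hairpin[30])
  expect_gt(e60, e31)
})
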
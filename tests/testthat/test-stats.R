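# Rank tests and descriptive summaries.

test_that("Mann-Whitney worked examples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_method, "exact")

  # perfect symmetry with ties: permutation branch, p near 1
  res2 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(res2$p_method, "permutation")
  expect_gt(res2$p_value, 0.9)

  # two-sided p unchanged under group swap
  withr::with_seed(401, { x <- rnorm(8); y <- rnorm(6) })
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  expect_warning(res3 <- mann_whitney_u(c(2, 2), c(2, 2, 2)), "constant")
  expect_equal(res3$p_value, 1)
})

test_that("exact p equals full enumeration for small tie-free samples", {
  withr::with_seed(402, {
    for (rep in 1:30) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      vals <- sample(1000, n + m)   # tie-free
      x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
      for (alt in c("two_sided", "greater", "less")) {
        expect_equal(mann_whitney_u(x, y, alt)$p_value, brute_mw_p(x, y, alt),
                     tolerance = 1e-12,
                     info = sprintf("n=%d m=%d alt=%s", n, m, alt))
      }
    }
  })
})

test_that("shifting one group up never increases the one-sided 'greater' p", {
  withr::with_seed(403, {
    for (rep in 1:10) {
      x <- rnorm(6); y <- rnorm(6)
      p0 <- mann_whitney_u(x, y, "greater")$p_value
      p1 <- mann_whitney_u(x + 1.5, y, "greater")$p_value
      expect_lte(p1, p0 + 1e-12)
    }
  })
})

test_that("large samples switch to the corrected normal approximation", {
  withr::with_seed(404, { x <- rnorm(30); y <- rnorm(25, 0.5) })
  res <- mann_whitney_u(x, y)
  expect_equal(res$p_method, "normal_approx")
  expect_equal(res$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("Kruskal-Wallis matches the rank-sum formula and Mann-Whitney at k=2", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  # H = 12 / (N (N + 1)) * sum n_i (Rbar_i - Rbar)^2, no ties
  N <- 6; rbar <- c(1.5, 3.5, 5.5); H <- 12 / (N * (N + 1)) * sum(2 * (rbar - 3.5)^2)
  expect_equal(res$statistic, H)
  expect_equal(res$p_value, pchisq(H, df = 2, lower.tail = FALSE))

  expect_warning(resc <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5))), "constant")
  expect_equal(c(resc$statistic, resc$p_value), c(0, 1))
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")

  # k = 2: same verdict as Mann-Whitney at alpha = 0.05 on tie-free data
  withr::with_seed(405, {
    for (rep in 1:20) {
      x <- sample(1000, 8); y <- sample(1000, 8) + sample(c(0, 500), 1)
      p_kw <- kruskal_wallis(list(x, y))$p_value
      p_mw <- mann_whitney_u(x, y)$p_value
      expect_equal(p_kw < 0.05, p_mw < 0.05)
    }
  })
})

test_that("H is invariant under strictly monotone transforms", {
  withr::with_seed(406, groups <- list(rnorm(7), rnorm(5, 1), rnorm(6, 2)))
  h0 <- kruskal_wallis(groups)$statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(v) 3 * v - 10))$statistic, h0)
})

test_that("descriptive summaries report sd, extremes and the modal value", {
  d <- describe_values(c(1, 2, 3))
  expect_equal(c(d$mean, d$sd, d$min, d$max), c(2, 1, 1, 3))
  expect_equal(describe_values(c(7, 7, 3))$mode, 7)
  expect_equal(describe_values(c(2, 3))$mode, 2)     # tie broken toward smallest
  single <- describe_values(5)
  expect_equal(c(single$sd, single$n), c(0, 1))
  expect_error(describe_values(numeric(0)), "empty")
})

test_that("Holm adjustment is available but leaves single p-values alone", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
})
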
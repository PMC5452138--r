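# Rank-based two-group and k-group comparisons and descriptive summaries.
#
# p-value policy for the Mann-Whitney test: exact enumeration of the U null
# distribution when n+m <= 25 without ties; seeded Monte-Carlo permutation
# (default 1e5 draws) when ties are present in a small sample; tie- and
# continuity-corrected normal approximation otherwise. Exact and normal
# branches are computed by stats::wilcox.test; the permutation branch is
# implemented here. No multiple-testing correction by default (a Holm option
# exists), matching the convention of reporting raw p-values.

new_test_result <- function(method, statistic, p_value, n_per_group,
                            ties_present, p_method, alternative, effect = NA_real_) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n_per_group = n_per_group,
                 ties_present = ties_present, p_method = p_method,
                 alternative = alternative, effect_rank_biserial = effect),
            class = "its_test")
}

#' @export
print.its_test <- function(x, ...) {
  cat(sprintf("<its_test> %s (%s): statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$method, x$alternative, x$statistic, x$p_value, x$p_method,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank test
#'
#' The U statistic for `x` is computed from joint midranks. See the file
#' header for the exact/permutation/normal p-value policy. The rank-biserial
#' correlation `2U/(nm) - 1` is reported alongside as an effect size.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (for `x`
#'   relative to `y`).
#' @param n_perm Monte-Carlo permutation draws for the tied small-sample
#'   branch.
#' @param perm_seed seed for the permutation branch.
#' @return an object of class `its_test`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two_sided", "less", "greater"),
                           n_perm = 1e5, perm_seed = 1L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  alt_r <- c(two_sided = "two.sided", less = "less", greater = "greater")[alternative]

  if (length(unique(pooled)) == 1) {
    warning("pooled data are constant; p = 1")
    return(new_test_result("mann_whitney", U, 1, c(n, m), ties, "degenerate",
                           alternative, 2 * U / (n * m) - 1))
  }

  if (!ties && N <= 25) {
    p <- suppressWarnings(wilcox.test(x, y, alternative = alt_r,
                                      exact = TRUE)$p.value)
    p_method <- "exact"
  } else if (ties && N <= 25) {
    p <- withr::with_seed(perm_seed, {
      stat_perm <- vapply(seq_len(n_perm), function(b)
        sum(r[sample.int(N, n)]) - n * (n + 1) / 2, numeric(1))
      mid <- n * m / 2
      eps <- 1e-9
      extreme <- switch(alternative,
        two_sided = abs(stat_perm - mid) >= abs(U - mid) - eps,
        greater = stat_perm >= U - eps,
        less = stat_perm <= U + eps)
      (1 + sum(extreme)) / (n_perm + 1)
    })
    p_method <- "permutation"
  } else {
    p <- suppressWarnings(wilcox.test(x, y, alternative = alt_r, exact = FALSE,
                                      correct = TRUE)$p.value)
    p_method <- "normal_approx"
  }
  new_test_result("mann_whitney", U, min(p, 1), c(n, m), ties, p_method,
                  alternative, 2 * U / (n * m) - 1)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups list of (>= 2) non-empty numeric vectors.
#' @return an object of class `its_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) == 0)) stop("all groups must be non-empty")
  pooled <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1) {
    warning("pooled data are constant; H = 0, p = 1")
    return(new_test_result("kruskal_wallis", 0, 1, vapply(groups, length, 0L),
                           ties, "degenerate", "two_sided"))
  }
  kt <- kruskal.test(pooled, g)
  new_test_result("kruskal_wallis", kt$statistic, kt$p.value,
                  vapply(groups, length, 0L), ties, "chi_square", "two_sided")
}

#' Descriptive summary of a numeric vector
#'
#' Mean, sample standard deviation (n-1 denominator; 0 when n = 1), min, max
#' and mode. Mode ties are broken toward the smallest value.
#'
#' @param values non-empty numeric vector.
#' @param label optional group label.
#' @return one-row data.frame with columns `label`, `n`, `mean`, `sd`,
#'   `min`, `max`, `mode`.
#' @export
describe_values <- function(values, label = "all") {
  if (length(values) == 0) stop("empty input")
  ux <- sort(unique(values))
  counts <- tabulate(match(values, ux))
  data.frame(label = label, n = length(values), mean = mean(values),
             sd = if (length(values) == 1) 0 else sd(values),
             min = min(values), max = max(values),
             mode = ux[which.max(counts)], stringsAsFactors = FALSE)
}

#' Holm correction for a set of test results
#'
#' Optional multiple-testing adjustment (off by default throughout the
#' pipeline, which reports raw p-values).
#'
#' @param p numeric vector of p-values.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
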
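# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's dynamic-programming code paths: structures are found by
# exhaustive enumeration and statistics by full enumeration of labelings.

ALLOWED_STEPS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# all non-crossing pair sets (as 2-column matrices, possibly empty) for a
# short sequence, honouring the minimum hairpin-loop constraint
enumerate_structures <- function(seq, min_loop = 3) {
  ch <- strsplit(gsub("T", "U", toupper(seq), fixed = TRUE), "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j || j - i <= min_loop)
      return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)
    for (k in seq(i + min_loop + 1, j)) {
      if (!paste0(ch[i], ch[k]) %in% ALLOWED_STEPS) next
      for (left in rec(i + 1, k - 1))
        for (right in rec(k + 1, j))
          out[[length(out) + 1]] <- rbind(c(i, k), left, right)
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# brute-force minimum energy: evaluate every enumerated structure
brute_min_energy <- function(seq, model = default_energy_model()) {
  structs <- enumerate_structures(seq, model$min_loop)
  energies <- vapply(structs, function(p) {
    st <- rna_structure(pairs = p, length = nchar(seq))
    evaluate_energy(seq, st, model)
  }, numeric(1))
  min(energies)
}

brute_max_pairs <- function(seq, min_loop = 3) {
  max(vapply(enumerate_structures(seq, min_loop), nrow, 0L))
}

# hairpin loops by direct definition: pairs with no paired base strictly inside
brute_hairpin_count <- function(pairs, n) {
  if (nrow(pairs) == 0) return(0L)
  paired <- sort(c(pairs))
  sum(vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    !any(paired > i & paired < j)
  }, logical(1)))
}

# exact two-sided/one-sided Mann-Whitney p by enumeration of all labelings
brute_mw_p <- function(x, y, alternative = "two_sided") {
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(N, n)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  mid <- n * m / 2
  eps <- 1e-9
  switch(alternative,
         two_sided = if (u_obs >= mid) min(1, 2 * mean(u_all >= u_obs - eps))
                     else min(1, 2 * mean(u_all <= u_obs + eps)),
         greater = mean(u_all >= u_obs - eps),
         less = mean(u_all <= u_obs + eps))
}

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

modal_value <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

make_records <- function(residues, species = paste0("sp", seq_along(residues)),
                         group = "g1", region = "ITS1",
                         id = paste0("s", seq_along(residues))) {
  data.frame(id = id, species = species, group = group, region = region,
             residues = residues, stringsAsFactors = FALSE)
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}
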
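# Per-sequence structural statistics: the quantities summarized per group in
# the results tables (LES, number of structures, hairpins, paired bases).

#' Count hairpin loops in a structure
#'
#' A hairpin loop is a pair `(i, j)` with no paired base strictly between `i`
#' and `j` — equivalently a maximal `"(...)"` match of `(` dots `)` adjacency
#' in the dot-bracket string. Multiloops contribute no hairpin of their own.
#'
#' @param structure an [rna_structure()] or a dot-bracket string.
#' @return hairpin-loop count.
#' @export
count_hairpins <- function(structure) {
  db <- if (is.character(structure)) structure else structure$dotbracket
  dotbracket_to_pairs(db)  # errors on unbalanced input
  length(gregexpr("\\(\\.*\\)", db)[[1]][gregexpr("\\(\\.*\\)", db)[[1]] > 0])
}

#' Paired-nucleotide statistics of a structure
#'
#' @param structure an [rna_structure()] or a dot-bracket string.
#' @return list with `n_paired` (2 x number of pairs) and `pct_paired`
#'   (percent of sequence length).
#' @export
paired_stats <- function(structure) {
  if (is.character(structure)) structure <- rna_structure(dotbracket = structure)
  n <- nchar(structure$dotbracket)
  n_paired <- 2L * nrow(structure$pairs)
  list(n_paired = n_paired, pct_paired = 100 * n_paired / n)
}

#' Per-sequence structure features
#'
#' Combines a fold result and its source record into the per-sequence feature
#' row: LES and structure count from the fold, hairpin and paired statistics
#' computed on the optimal (first) structure.
#'
#' @param fold a `fold_result` from [fold_suboptimal()] (or an
#'   [rna_structure()] from [fold_mfe()], in which case `n_structures` is 1).
#' @param record one-row sequence-set data.frame the fold was produced from.
#' @return one-row data.frame with columns `id`, `species`, `group`,
#'   `region`, `length`, `les`, `n_structures`, `n_hairpins`, `n_paired`,
#'   `pct_paired`.
#' @export
featurize <- function(fold, record) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  if (inherits(fold, "rna_structure"))
    fold <- structure(list(structures = list(fold), les = fold$energy,
                           n_structures = 1L), class = "fold_result")
  stopifnot(inherits(fold, "fold_result"))
  best <- fold$structures[[1]]
  L <- nchar(best$dotbracket)
  if (L != nchar(ungap(record$residues)))
    stop("fold length ", L, " does not match ungapped record length for '",
         record$id, "'")
  ps <- paired_stats(best)
  data.frame(id = record$id, species = record$species, group = record$group,
             region = record$region, length = L, les = fold$les,
             n_structures = fold$n_structures,
             n_hairpins = count_hairpins(best),
             n_paired = ps$n_paired, pct_paired = ps$pct_paired,
             stringsAsFactors = FALSE)
}
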
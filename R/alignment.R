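# Alignment descriptive statistics and gap coding.
#
# Coordinates are 1-based, closed intervals throughout. Gap and ambiguity
# characters are excluded as states when counting variable and
# parsimony-informative columns (standard parsimony convention); T and U are
# collapsed to one state for counting since they encode the same base.

UNAMBIG <- c("A", "C", "G", "T", "U")

#' Construct an alignment object
#'
#' @param labels record ids (one per row).
#' @param rows equal-length gapped residue strings.
#' @param region region label (`"ITS1"`/`"ITS2"`).
#' @param group taxonomic-group label.
#' @return object of class `its_alignment`.
#' @export
its_alignment <- function(labels, rows, region = "ITS1", group = "all") {
  rows <- toupper(as.character(rows))
  if (length(rows) < 2) stop("an alignment needs at least 2 rows")
  if (length(labels) != length(rows)) stop("labels/rows length mismatch")
  if (length(unique(nchar(rows))) != 1) stop("alignment rows differ in length")
  region <- match.arg(region, REGIONS)
  bad <- setdiff(unique(unlist(strsplit(rows, ""))), SEQ_ALPHABET)
  if (length(bad)) stop("illegal alignment character(s): ", paste(bad, collapse = ", "))
  structure(list(labels = as.character(labels), rows = rows,
                 region = region, group = as.character(group)),
            class = "its_alignment")
}

#' @export
print.its_alignment <- function(x, ...) {
  cat(sprintf("<its_alignment> %s / %s: %d rows x %d columns\n",
              x$group, x$region, length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

#' Read an aligned FASTA file as an alignment object
#'
#' @inheritParams read_its_fasta
#' @param group group label attached to the alignment.
#' @return an [its_alignment()] object.
#' @export
read_aligned_fasta <- function(path, region = "ITS1", group = "all") {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  ids <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[`, "", 1)
  its_alignment(ids, as.character(seqs), region = region, group = group)
}

#' Variable and parsimony-informative sites
#'
#' A column is *variable* when at least two distinct unambiguous base states
#' occur among the rows (gaps and IUPAC ambiguity codes are not states; T and
#' U count as one state). A variable column is *parsimony-informative* when at
#' least two states each occur in at least two rows.
#'
#' @param alignment an [its_alignment()] object.
#' @param species optional species label per row, used for the species count.
#' @return a one-row data.frame with columns `group`, `region`,
#'   `n_individuals`, `n_species`, `alignment_length`, `n_variable`,
#'   `pct_variable`, `n_pi`, `pct_pi`.
#' @export
variable_and_pi_sites <- function(alignment, species = NULL) {
  stopifnot(inherits(alignment, "its_alignment"))
  m <- aln_matrix(alignment)
  m[m == "U"] <- "T"
  L <- ncol(m)
  variable <- logical(L)
  pi <- logical(L)
  for (j in seq_len(L)) {
    states <- m[, j][m[, j] %in% c("A", "C", "G", "T")]
    if (length(states) == 0) next
    tab <- table(states)
    variable[j] <- length(tab) >= 2
    pi[j] <- sum(tab >= 2) >= 2
  }
  data.frame(
    group = alignment$group, region = alignment$region,
    n_individuals = nrow(m),
    n_species = if (is.null(species)) NA_integer_ else length(unique(species)),
    alignment_length = L,
    n_variable = sum(variable), pct_variable = 100 * sum(variable) / L,
    n_pi = sum(pi), pct_pi = 100 * sum(pi) / L,
    stringsAsFactors = FALSE)
}

#' Delete ambiguous columns from an alignment
#'
#' Removes every column containing an IUPAC ambiguity code or `N` (anything
#' other than `A/C/G/T/U/-`), plus any user-masked column ranges — the mask is
#' how alignment regions judged ambiguous by eye enter the pipeline.
#'
#' @param alignment an [its_alignment()] object.
#' @param mask optional list of `c(start, end)` 1-based closed column ranges
#'   (or a 2-column matrix) to delete regardless of content.
#' @return list with elements `alignment` (the reduced alignment) and
#'   `column_map` (data.frame `old`, `new` for surviving columns).
#' @export
remove_ambiguous_columns <- function(alignment, mask = NULL) {
  stopifnot(inherits(alignment, "its_alignment"))
  m <- aln_matrix(alignment)
  L <- ncol(m)
  drop <- apply(m, 2, function(col) any(!col %in% c(UNAMBIG, "-")))
  if (!is.null(mask)) {
    if (is.list(mask)) mask <- do.call(rbind, mask)
    mask <- matrix(as.integer(mask), ncol = 2)
    if (any(mask[, 1] > mask[, 2]) || any(mask < 1) || any(mask > L))
      stop("mask range out of bounds (alignment length ", L, ")")
    for (k in seq_len(nrow(mask))) drop[mask[k, 1]:mask[k, 2]] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) == 0) stop("all columns removed")
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- its_alignment(alignment$labels, rows, alignment$region, alignment$group)
  list(alignment = out,
       column_map = data.frame(old = keep, new = seq_along(keep)))
}

# maximal gap runs of one row as (start, end) pairs
gap_runs <- function(row_chars) {
  r <- rle(row_chars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel coding of alignment gaps
#'
#' Each distinct gap span (identical start and end columns across rows)
#' becomes one binary character. A row scores 1 when it exhibits exactly that
#' span as a maximal gap run, 0 when none of its gaps overlap the span, and
#' missing (`NA`) when one of its gap runs strictly contains the span (the
#' character is then unobservable in that row).
#'
#' @param alignment an [its_alignment()] object.
#' @return list with `characters` (data.frame `start`, `end`, one row per
#'   indel character, ordered by start then end) and `states` (rows x
#'   characters matrix of 0/1/`NA`).
#' @export
code_gaps_binary <- function(alignment) {
  stopifnot(inherits(alignment, "its_alignment"))
  m <- aln_matrix(alignment)
  runs <- lapply(seq_len(nrow(m)), function(i) gap_runs(m[i, ]))
  spans <- unique(do.call(rbind, runs))
  if (is.null(spans) || nrow(spans) == 0) {
    return(list(characters = data.frame(start = integer(), end = integer()),
                states = matrix(NA_integer_, nrow(m), 0,
                                dimnames = list(alignment$labels, NULL))))
  }
  spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
  states <- matrix(NA_integer_, nrow(m), nrow(spans))
  for (k in seq_len(nrow(spans))) {
    s <- spans[k, 1]; e <- spans[k, 2]
    for (i in seq_len(nrow(m))) {
      ri <- runs[[i]]
      if (nrow(ri) == 0) { states[i, k] <- 0L; next }
      exact <- any(ri[, 1] == s & ri[, 2] == e)
      contains <- any(ri[, 1] <= s & ri[, 2] >= e & !(ri[, 1] == s & ri[, 2] == e))
      states[i, k] <- if (exact) 1L else if (contains) NA_integer_ else 0L
    }
  }
  dimnames(states) <- list(alignment$labels,
                           sprintf("indel_%d_%d", spans[, 1], spans[, 2]))
  list(characters = data.frame(start = spans[, 1], end = spans[, 2]),
       states = states)
}

#' Write an indel character matrix as TSV and a NEXUS-style block
#'
#' @param coding result of [code_gaps_binary()].
#' @param path output TSV path (`0/1/?` coding). A NEXUS-style `CHARACTERS`
#'   block is appended to `paste0(path, ".nex")`.
#' @return `path`, invisibly.
#' @export
write_indel_matrix <- function(coding, path) {
  st <- coding$states
  txt <- apply(st, c(1, 2), function(v) if (is.na(v)) "?" else as.character(v))
  df <- data.frame(id = rownames(st), txt, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nex <- c("BEGIN CHARACTERS;",
           sprintf("  DIMENSIONS NCHAR=%d;", ncol(st)),
           "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
           "  MATRIX",
           sprintf("    %s  %s", rownames(st),
                   apply(txt, 1, paste, collapse = "")),
           "  ;", "END;")
  writeLines(nex, paste0(path, ".nex"))
  invisible(path)
}

#' GC content of sequences
#'
#' Per-record GC fraction: `(G + C + S) / n`, where `n` counts the bases whose
#' GC status is determined (`A, C, G, T, U` plus the two-state codes `S` and
#' `W`). `N`, other ambiguity codes and gaps are ignored.
#'
#' @param x a sequence-set data.frame or a character vector of residues.
#' @return named numeric vector of per-record GC fractions (take `mean()` for
#'   a group mean).
#' @export
gc_content <- function(x) {
  residues <- if (is.data.frame(x)) x$residues else as.character(x)
  ids <- if (is.data.frame(x)) x$id else names(x)
  if (length(residues) < 1) stop("gc_content needs at least one record")
  out <- vapply(toupper(residues), function(s) {
    ch <- strsplit(s, "")[[1]]
    num <- sum(ch %in% c("G", "C", "S"))
    den <- sum(ch %in% c("A", "C", "G", "T", "U", "S", "W"))
    if (den == 0) stop("sequence with no countable bases")
    num / den
  }, numeric(1), USE.NAMES = FALSE)
  names(out) <- ids
  out
}
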
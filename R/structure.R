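# Secondary-structure container and standard structure file formats.

#' Construct a secondary-structure object
#'
#' A structure is a set of mutually non-crossing base pairs on a sequence,
#' carried as both a 1-based pair list and a dot-bracket string, with a free
#' energy in kcal/mol. Either `pairs` or `dotbracket` may be supplied; the
#' other is derived.
#'
#' @param pairs integer matrix with columns `i`, `j` (1-based, `i < j`), or
#'   `NULL` for an open chain.
#' @param length sequence length (needed when deriving dot-bracket from pairs).
#' @param dotbracket balanced dot-bracket string.
#' @param energy free energy in kcal/mol.
#' @param sequence optional residue string the structure belongs to.
#' @return object of class `rna_structure`.
#' @export
rna_structure <- function(pairs = NULL, length = NULL, dotbracket = NULL,
                          energy = NA_real_, sequence = NULL) {
  if (is.null(dotbracket)) {
    if (is.null(length)) stop("need 'length' when building from pairs")
    dotbracket <- pairs_to_dotbracket(pairs, length)
  }
  if (is.null(pairs)) pairs <- dotbracket_to_pairs(dotbracket)
  pairs <- matrix(as.integer(pairs), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  if (!is.null(sequence) && nchar(sequence) != nchar(dotbracket))
    stop("sequence and dot-bracket lengths differ")
  structure(list(dotbracket = dotbracket, pairs = pairs,
                 energy = as.numeric(energy), sequence = sequence),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %d nt, %d pairs, energy %s kcal/mol\n",
              nchar(x$dotbracket), nrow(x$pairs),
              ifelse(is.na(x$energy), "NA", sprintf("%.2f", x$energy))))
  if (!is.null(x$sequence)) cat(x$sequence, "\n")
  cat(x$dotbracket, "\n")
  invisible(x)
}

#' Convert a pair list to a dot-bracket string
#'
#' @param pairs 2-column integer matrix of 1-based pairs (`i < j`), or `NULL`.
#' @param length sequence length.
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, length) {
  db <- rep(".", length)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    if (anyDuplicated(c(pairs))) stop("a base occurs in more than one pair")
    if (any(pairs < 1) || any(pairs > length)) stop("pair index out of range")
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  out <- paste(db, collapse = "")
  dotbracket_to_pairs(out)  # errors if crossing/unbalanced
  out
}

#' Parse a dot-bracket string into a pair list
#'
#' @param dotbracket dot-bracket string over `(`, `)`, `.`.
#' @return 2-column integer matrix of 1-based pairs.
#' @export
dotbracket_to_pairs <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad)) stop("illegal dot-bracket character(s): ", paste(bad, collapse = ", "))
  open <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  out <- vector("list", sum(ch == ")"))
  np <- 0L
  for (k in seq_along(ch)) {
    if (ch[k] == "(") open <- c(open, k)
    else if (ch[k] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket at position ", k)
      np <- np + 1L
      out[[np]] <- c(open[length(open)], k)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket: unmatched '(' at position ", open[1])
  if (np == 0) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, out[seq_len(np)])
  m <- m[order(m[, 1]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

# partner vector: partner[i] = j if (i,j) or (j,i) paired, else 0
partner_vector <- function(structure, n = nchar(structure$dotbracket)) {
  p <- integer(n)
  pr <- structure$pairs
  if (nrow(pr)) {
    p[pr[, 1]] <- pr[, 2]
    p[pr[, 2]] <- pr[, 1]
  }
  p
}

#' Validate a structure against a sequence and an energy model
#'
#' Checks the pairing constraints: only allowed pairs (`AU, UA, GC, CG, GU,
#' UG` after T→U mapping), minimum hairpin loop size, no crossing pairs, and
#' dot-bracket/pair consistency.
#'
#' @param sequence residue string over `A/C/G/T/U`.
#' @param structure an [rna_structure()].
#' @param model an energy model (for `min_loop`); default model if omitted.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_structure <- function(sequence, structure, model = default_energy_model()) {
  seq_u <- toupper(gsub("T", "U", toupper(sequence), fixed = TRUE))
  n <- nchar(seq_u)
  if (nchar(structure$dotbracket) != n)
    stop("structure length ", nchar(structure$dotbracket), " != sequence length ", n)
  if (!identical(unname(dotbracket_to_pairs(structure$dotbracket)),
                 unname(structure$pairs[order(structure$pairs[, 1]), , drop = FALSE])))
    stop("dot-bracket and pair list disagree")
  pr <- structure$pairs
  if (nrow(pr)) {
    ch <- strsplit(seq_u, "")[[1]]
    pt <- pair_type_chr(ch[pr[, 1]], ch[pr[, 2]])
    if (any(pt == 0))
      stop("disallowed pair at (", pr[which(pt == 0)[1], 1], ",", pr[which(pt == 0)[1], 2], ")")
    if (any(pr[, 2] - pr[, 1] - 1 < model$min_loop))
      stop("hairpin loop below minimum size ", model$min_loop)
  }
  invisible(TRUE)
}

pair_type_chr <- function(a, b) {
  key <- paste0(a, b)
  types <- c(AU = 1, UA = 2, GC = 3, CG = 4, GU = 5, UG = 6)
  out <- types[key]
  out[is.na(out)] <- 0
  unname(out)
}

#' Write a structure in connect (CT) format
#'
#' Standard 6-column, 1-based CT format: index, base, previous, next, partner
#' (0 when unpaired), index.
#'
#' @param sequence residue string.
#' @param structure an [rna_structure()].
#' @param path output path.
#' @param title title for the header line.
#' @return `path`, invisibly.
#' @export
write_ct <- function(sequence, structure, path, title = "structure") {
  n <- nchar(sequence)
  ch <- strsplit(toupper(sequence), "")[[1]]
  p <- partner_vector(structure, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d  ENERGY = %.2f  %s", n,
                     ifelse(is.na(structure$energy), 0, structure$energy), title), con)
  writeLines(sprintf("%5d %s %7d %5d %5d %5d",
                     1:n, ch, 0:(n - 1), c(2:n, 0), p, 1:n), con)
  invisible(path)
}

#' Read a connect (CT) file
#'
#' @param path CT file path.
#' @return list with `sequence`, `structure` (an [rna_structure()]) and
#'   `title`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty CT file")
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(head_fields[1])
  energy <- if (length(head_fields) >= 4 && head_fields[2] == "ENERGY")
    as.numeric(head_fields[4]) else NA_real_
  body <- lines[2:(n + 1)]
  f <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  seq <- paste(f[, 2], collapse = "")
  partner <- as.integer(f[, 5])
  idx <- which(partner > seq_len(n))
  pairs <- cbind(idx, partner[idx])
  st <- rna_structure(pairs = pairs, length = n, energy = energy, sequence = seq)
  list(sequence = seq, structure = st,
       title = paste(head_fields[-(1:4)], collapse = " "))
}

#' Write a structure in dot-bracket format
#'
#' Three lines: FASTA-style header, sequence, dot-bracket with `(energy)`
#' appended.
#'
#' @inheritParams write_ct
#' @param id record id for the header line.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(sequence, structure, path, id = "seq") {
  writeLines(c(paste0(">", id), toupper(sequence),
               sprintf("%s (%.2f)", structure$dotbracket,
                       ifelse(is.na(structure$energy), 0, structure$energy))),
             path)
  invisible(path)
}
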
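# Reading, validating, labelling and filtering ITS sequence sets.
#
# A sequence set is a plain data.frame with columns id, species, group,
# region, residues (uppercase IUPAC DNA/RNA, '-' allowed in aligned
# contexts). FASTA headers follow the pipe convention "id|species|group|region";
# fields missing from the header may be supplied through a tab-separated
# metadata sidecar with columns id, species, group, region.

new_records <- function(id, species, group, region, residues) {
  data.frame(id = as.character(id), species = as.character(species),
             group = as.character(group), region = as.character(region),
             residues = as.character(residues), stringsAsFactors = FALSE)
}

validate_records <- function(records, allow_gaps = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("id", "species", "group", "region", "residues") %in% names(records)))
  if (nrow(records) == 0) return(invisible(records))
  bad_region <- !records$region %in% REGIONS
  if (any(bad_region))
    stop("invalid region label(s): ", paste(unique(records$region[bad_region]), collapse = ", "),
         " (must be one of ", paste(REGIONS, collapse = ", "), ")")
  if (any(!nzchar(records$residues)))
    stop("record(s) with empty sequence: ",
         paste(records$id[!nzchar(records$residues)], collapse = ", "))
  allowed <- SEQ_ALPHABET
  if (!allow_gaps) allowed <- setdiff(allowed, "-")
  for (k in seq_len(nrow(records))) {
    chars <- unique(strsplit(records$residues[k], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop("record '", records$id[k], "' contains illegal character(s): ",
           paste(bad, collapse = ", "))
  }
  ungapped <- gsub("-", "", records$residues, fixed = TRUE)
  if (any(!nzchar(ungapped)))
    stop("record(s) with all-gap sequence: ", paste(records$id[!nzchar(ungapped)], collapse = ", "))
  invisible(records)
}

ungap <- function(residues) gsub("-", "", residues, fixed = TRUE)

#' Read ITS sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a sequence-set
#' data.frame. Headers are interpreted as pipe-delimited
#' `"id|species|group|region"`; fields absent from the header can be supplied
#' via `metadata` (a data.frame or the path of a TSV sidecar with columns
#' `id`, `species`, `group`, `region`). Residues are uppercased; `T` and `U`
#' are both accepted and preserved as read.
#'
#' @param path FASTA file path.
#' @param region default region label (`"ITS1"` or `"ITS2"`) applied to
#'   records whose header/sidecar carries none.
#' @param metadata optional metadata sidecar (data.frame or TSV path).
#' @return data.frame with columns `id`, `species`, `group`, `region`,
#'   `residues`.
#' @export
read_its_fasta <- function(path, region = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("FASTA file '", path, "' contains no records")
  headers <- names(seqs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  get_field <- function(f, k) if (length(f) >= k && nzchar(trimws(f[k]))) trimws(f[k]) else NA_character_
  ids <- vapply(fields, get_field, "", 1)
  species <- vapply(fields, get_field, "", 2)
  group <- vapply(fields, get_field, "", 3)
  reg <- vapply(fields, get_field, "", 4)

  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read.delim(metadata, stringsAsFactors = FALSE) else metadata
    stopifnot("id" %in% names(md))
    m <- match(ids, md$id)
    fill <- function(x, col) {
      if (!col %in% names(md)) return(x)
      ifelse(is.na(x) & !is.na(m), as.character(md[[col]][m]), x)
    }
    species <- fill(species, "species")
    group <- fill(group, "group")
    reg <- fill(reg, "region")
  }
  if (!is.null(region)) {
    region <- match.arg(region, REGIONS)
    reg[is.na(reg)] <- region
  }
  if (anyNA(reg))
    stop("records without region label and no default given: ",
         paste(ids[is.na(reg)], collapse = ", "))
  species[is.na(species)] <- "unknown"
  group[is.na(group)] <- "unknown"

  records <- new_records(ids, species, group, reg,
                         toupper(as.character(seqs)))
  validate_records(records)
  records
}

#' Write a sequence set as FASTA
#'
#' Headers follow the `"id|species|group|region"` convention so that
#' [read_its_fasta()] round-trips.
#'
#' @param records sequence-set data.frame.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_its_fasta <- function(records, path, width = 70) {
  validate_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    writeLines(sprintf(">%s|%s|%s|%s", records$id[k], records$species[k],
                       records$group[k], records$region[k]), con)
    s <- records$residues[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Drop duplicate haplotypes within species
#'
#' For each (species, exact ungapped residue string) pair only the
#' first-encountered record is kept, so each haplotype of a species enters the
#' analysis once. Identical sequences from *different* species are all kept.
#' Input order is otherwise preserved.
#'
#' @param records sequence-set data.frame (one region).
#' @param collapse_tu if `TRUE`, `T` and `U` are treated as the same state
#'   when comparing sequences; by default they are distinct as read.
#' @return the deduplicated sequence set.
#' @export
dedupe_identical <- function(records, collapse_tu = FALSE) {
  validate_records(records)
  if (nrow(records) == 0) return(records)
  if (length(unique(records$region)) > 1)
    stop("dedupe_identical expects records from a single region")
  key_seq <- ungap(records$residues)
  if (collapse_tu) key_seq <- gsub("U", "T", key_seq, fixed = TRUE)
  keep <- !duplicated(paste(records$species, key_seq, sep = "\r"))
  records[keep, , drop = FALSE]
}

#' Remove sequences with long terminal missing-data runs
#'
#' Records whose run of leading or trailing `N`/`-` characters exceeds
#' `max_terminal` are removed. The removed ids are attached as attribute
#' `"removed"` (a data.frame with columns `id`, `reason`) and optionally
#' written as a TSV report.
#'
#' @param records sequence-set data.frame.
#' @param max_terminal maximum tolerated terminal run of `N`/`-` (default 10).
#' @param report_path optional path for a TSV removal report.
#' @return the filtered sequence set with attribute `"removed"`.
#' @export
filter_terminal_missing <- function(records, max_terminal = 10, report_path = NULL) {
  stopifnot(max_terminal >= 0)
  validate_records(records)
  lead <- attr(regexpr("^[N-]*", records$residues), "match.length")
  trail <- attr(regexpr("[N-]*$", records$residues), "match.length")
  drop <- lead > max_terminal | trail > max_terminal
  removed <- data.frame(
    id = records$id[drop],
    reason = sprintf("terminal missing run %d > %d", pmax(lead, trail)[drop], max_terminal),
    stringsAsFactors = FALSE)
  if (!is.null(report_path))
    write.table(removed, report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- records[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}
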
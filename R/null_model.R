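# Length- and GC-matched randomization null.
#
# For each real spacer sequence the null is one random sequence of exactly
# the same (ungapped) length whose G+C count equals round(gc * length) — an
# exact-count composition drawn as a uniform permutation, so "similar GC
# content" holds to the rounding bound 0.5/length. A dinucleotide-preserving
# shuffle of the source is available as a stricter alternative null.

derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 1e5 * 20011 + index * 7919) %% 2147483629)
}

#' Matched random sequence for one record
#'
#' Output length equals the source's ungapped length; the G+C count equals
#' `round(gc * length)`, with G vs C (and A vs T) split as evenly as
#' possible, any odd remainder assigned by the seeded generator; positions
#' are a uniform random permutation. Deterministic in `(record, seed)`.
#'
#' @param record one-row sequence-set data.frame.
#' @param seed integer seed.
#' @param mode `"composition"` (exact-count match, default), `"iid"`
#'   (independent draws with GC probability equal to the source GC), or
#'   `"dinucleotide"` (dinucleotide-preserving shuffle of the source).
#' @return one-row sequence-set data.frame; id is `<source_id>.null`.
#' @export
matched_random_sequence <- function(record, seed,
                                    mode = c("composition", "iid", "dinucleotide")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(record), nrow(record) == 1)
  src <- ungap(record$residues)
  L <- nchar(src)
  gc <- unname(gc_content(src))
  residues <- withr::with_seed(seed, {
    if (mode == "composition") {
      n_gc <- round(gc * L)
      n_at <- L - n_gc
      g <- n_gc %/% 2
      if (n_gc %% 2 == 1) g <- g + (runif(1) < 0.5)
      a <- n_at %/% 2
      if (n_at %% 2 == 1) a <- a + (runif(1) < 0.5)
      bases <- c(rep("G", g), rep("C", n_gc - g), rep("A", a), rep("T", n_at - a))
      paste(sample(bases), collapse = "")
    } else if (mode == "iid") {
      paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                   prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
            collapse = "")
    } else {
      dinucleotide_shuffle_chr(src)
    }
  })
  new_records(paste0(record$id, ".null"), record$species, record$group,
              record$region, residues)
}

#' Generate a matched null cohort
#'
#' One matched random sequence per input record; per-record seeds are derived
#' deterministically from `master_seed` and record order (a stable hash,
#' recorded in the provenance attribute for audit).
#'
#' @param records sequence-set data.frame.
#' @param master_seed integer master seed.
#' @inheritParams matched_random_sequence
#' @return sequence-set data.frame of null records, same number of rows as
#'   the input, with attribute `"provenance"` (data.frame `source_id`,
#'   `null_id`, `length`, `gc_source`, `gc_null`, `seed`).
#' @export
generate_null_cohort <- function(records, master_seed,
                                 mode = c("composition", "iid", "dinucleotide")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0) {
    out <- records
    attr(out, "provenance") <- data.frame(source_id = character(), null_id = character(),
                                          length = integer(), gc_source = numeric(),
                                          gc_null = numeric(), seed = integer())
    return(out)
  }
  seeds <- vapply(seq_len(nrow(records)), function(i) derive_seed(master_seed, i), 1L)
  nulls <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    matched_random_sequence(records[i, , drop = FALSE], seeds[i], mode = mode)))
  attr(nulls, "provenance") <- data.frame(
    source_id = records$id, null_id = nulls$id,
    length = nchar(nulls$residues),
    gc_source = unname(gc_content(ungap(records$residues))),
    gc_null = unname(gc_content(nulls$residues)),
    seed = seeds, stringsAsFactors = FALSE)
  nulls
}

# Dinucleotide-preserving shuffle (Altschul-Erickson): treat the sequence as
# an Eulerian walk on the 4-vertex dinucleotide multigraph; fix a random
# last-edge arborescence toward the final base, shuffle the remaining edge
# orders, and rebuild the walk.
dinucleotide_shuffle_chr <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n <= 2) return(s)
  verts <- unique(ch)
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  last <- ch[n]
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1)]
    }, "")
    # check the designated last edges form paths leading to 'last'
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  pools <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]])) {
      drop1 <- match(last_edge[[v]], e)
      e <- e[-drop1]
    }
    if (length(e) > 1) e <- e[sample.int(length(e))]
    c(e, if (!is.na(last_edge[[v]])) last_edge[[v]])
  })
  names(pools) <- verts
  out <- character(n)
  out[1] <- ch[1]
  for (k in 2:n) {
    v <- out[k - 1]
    out[k] <- pools[[v]][1]
    pools[[v]] <- pools[[v]][-1]
  }
  paste(out, collapse = "")
}

#' Write null-cohort provenance as TSV
#'
#' @param nulls result of [generate_null_cohort()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_null_provenance <- function(nulls, path) {
  prov <- attr(nulls, "provenance")
  if (is.null(prov)) stop("no provenance attribute on the null cohort")
  write.table(prov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
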
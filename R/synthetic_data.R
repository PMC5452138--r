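# ITS-like synthetic sequence families with controllable structural
# constraint.
#
# An ancestor is assembled from reverse-complementary stem blocks arranged to
# fold into a fixed number of hairpins, the conserved spacer motifs (terminal
# TCGAA.../...TTCGA complementary ends forming the closing helix, and for
# ITS1-like sequences the central AAGGAA), and filler bases budgeted to hit a
# GC target. Tips then evolve on a star phylogeny; substitutions that land in
# a planted stem co-mutate the partner base (restoring an allowed pair, GU
# included) with probability `compensatory_fraction` — the knob controlling
# how strongly structure is conserved under divergence.

#' Configuration for the synthetic ITS family generator
#'
#' Region defaults emulate the two spacers: ITS1-like sequences are 263 nt
#' with 7 stems and the central `AAGGAA` motif; ITS2-like are 206 nt with 3
#' stems. Both carry the complementary terminal motifs `TCGAA`/`TTCGA` that
#' close the fold.
#'
#' @param region `"ITS1"` or `"ITS2"`.
#' @param n_groups number of taxonomic groups.
#' @param n_species_per_group tips per group.
#' @param length sequence length in nt (region default if `NULL`).
#' @param gc_target target GC fraction (default 0.55).
#' @param n_stems number of hairpin-forming stem blocks (region default if
#'   `NULL`).
#' @param stem_length paired bases per stem arm (default 8).
#' @param divergence expected substitutions per site per lineage.
#' @param compensatory_fraction probability that a stem substitution
#'   co-mutates the partner base to restore pairing.
#' @param mutable_motifs allow substitutions inside the conserved motifs
#'   (off by default; on for sensitivity analysis).
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(region = c("ITS1", "ITS2"), n_groups = 4,
                         n_species_per_group = 3, length = NULL,
                         gc_target = 0.55, n_stems = NULL, stem_length = 8,
                         divergence = 0.15, compensatory_fraction = 0.9,
                         mutable_motifs = FALSE, seed = 1L) {
  region <- match.arg(region)
  length <- length %||% if (region == "ITS1") 263L else 206L
  n_stems <- n_stems %||% if (region == "ITS1") 7L else 3L
  motifs <- if (region == "ITS1") list(terminal5 = "TCGAA", terminal3 = "TTCGA",
                                       central = "AAGGAA")
            else list(terminal5 = "TCGAA", terminal3 = "TTCGA")
  stopifnot(gc_target >= 0, gc_target <= 1,
            compensatory_fraction >= 0, compensatory_fraction <= 1,
            divergence >= 0, n_stems >= 1, stem_length >= 2)
  motif_len <- sum(nchar(unlist(motifs)))
  loop_base <- 4L
  if (n_stems * (2L * stem_length + loop_base) + motif_len + n_stems + 1L > length)
    stop("infeasible length budget: stems + motifs exceed sequence length")
  structure(list(region = region, n_groups = as.integer(n_groups),
                 n_species_per_group = as.integer(n_species_per_group),
                 length = as.integer(length), gc_target = gc_target,
                 n_stems = as.integer(n_stems),
                 stem_length = as.integer(stem_length), motifs = motifs,
                 loop_base = loop_base, divergence = divergence,
                 compensatory_fraction = compensatory_fraction,
                 mutable_motifs = mutable_motifs, seed = as.integer(seed)),
            class = "synth_config")
}

# split `total` into `k` near-equal non-negative integers (remainder first)
split_even <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  if (total %% k > 0) out[seq_len(total %% k)] <- base + 1L
  out
}

#' Build a synthetic ancestor sequence and its planted structure
#'
#' Assembles terminal motifs (closing helix), `n_stems` GC-rich
#' reverse-complementary stem blocks with hairpin loops, the central motif
#' (ITS1-like), and filler drawn to hit the GC target exactly at the count
#' level. Also returns the intended (planted) secondary structure, whose
#' hairpin-loop count equals `n_stems`.
#'
#' @param config a [synth_config()].
#' @return list with `record` (one-row sequence set) and `structure`
#'   (the planted [rna_structure()] with its evaluated energy).
#' @export
build_ancestor <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    L <- cf$length
    term5 <- strsplit(cf$motifs$terminal5, "")[[1]]
    term3 <- strsplit(cf$motifs$terminal3, "")[[1]]
    central <- if (!is.null(cf$motifs$central)) strsplit(cf$motifs$central, "")[[1]] else character(0)

    filler <- L - length(term5) - length(term3) - length(central) -
      cf$n_stems * (2L * cf$stem_length + cf$loop_base)
    # hairpin loops stay short (so they cannot fold themselves); all filler
    # goes to the multiloop spacers
    loop_len <- rep(cf$loop_base, cf$n_stems)
    spacer_len <- split_even(filler, cf$n_stems + 1L)

    # all-GC stem arms: maximal thermodynamic contrast with the AT-richer
    # spacers, so the planted fold dominates
    gc_arm <- cf$stem_length
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    stems <- lapply(seq_len(cf$n_stems), function(k) {
      arm <- character(cf$stem_length)
      gc_pos <- sample.int(cf$stem_length, gc_arm)
      arm[gc_pos] <- sample(c("G", "C"), gc_arm, replace = TRUE)
      arm[-gc_pos] <- sample(c("A", "T"), cf$stem_length - gc_arm, replace = TRUE)
      list(left = arm, right = rev(unname(comp[arm])))
    })

    # loops are all-A (a 4-nt oligo-A loop is a poor pairing partner, so the
    # planted hairpin loops stay open); spacers are random sequence carrying
    # the remaining GC budget at exact count
    n_spacer <- sum(spacer_len)
    target_gc <- round(cf$gc_target * L)
    fixed_gc <- sum(c(term5, term3, central) %in% c("G", "C")) +
      2L * cf$n_stems * gc_arm
    free_gc <- target_gc - fixed_gc
    if (free_gc < 0 || free_gc > n_spacer)
      stop("infeasible GC budget: target ", target_gc, ", fixed ", fixed_gc,
           ", spacer positions ", n_spacer)
    free_bases <- sample(c("A", "T"), n_spacer, replace = TRUE)
    free_bases[sample.int(n_spacer, free_gc)] <- sample(c("G", "C"), free_gc,
                                                        replace = TRUE)

    take_free <- local({
      cursor <- 0L
      function(k) {
        out <- free_bases[cursor + seq_len(k)]
        cursor <<- cursor + k
        out
      }
    })
    draw_loop <- function(k) rep("A", k)

    # assemble; central motif sits in the middle spacer
    central_spacer <- (cf$n_stems + 2L) %/% 2L
    seq_chars <- character(0)
    pairs <- matrix(integer(0), 0, 2)
    stem_left_start <- integer(cf$n_stems)
    append_seg <- function(chars) {
      start <- length(seq_chars) + 1L
      seq_chars <<- c(seq_chars, chars)
      start
    }
    append_seg(term5)
    for (k in seq_len(cf$n_stems)) {
      sp <- take_free(spacer_len[k])
      if (k == central_spacer && length(central)) sp <- c(sp, central)
      append_seg(sp)
      stem_left_start[k] <- append_seg(stems[[k]]$left)
      append_seg(draw_loop(loop_len[k]))
      right_start <- append_seg(stems[[k]]$right)
      pairs <- rbind(pairs, cbind(
        stem_left_start[k] + seq_len(cf$stem_length) - 1L,
        right_start + cf$stem_length - seq_len(cf$stem_length)))
    }
    sp <- take_free(spacer_len[cf$n_stems + 1L])
    if (central_spacer == cf$n_stems + 1L && length(central)) sp <- c(sp, central)
    append_seg(sp)
    append_seg(term3)
    stopifnot(length(seq_chars) == L)
    # terminal closing helix
    nt <- length(term5)
    pairs <- rbind(cbind(seq_len(nt), L + 1L - seq_len(nt)), pairs)

    residues <- paste(seq_chars, collapse = "")
    st <- rna_structure(pairs = pairs, length = L, sequence = residues)
    st$energy <- evaluate_energy(residues, st)
    rec <- new_records(paste0("ancestor_", cf$region), "ancestor", "ancestor",
                       cf$region, residues)
    list(record = rec, structure = st)
  })
}

#' Evolve a synthetic family from an ancestor
#'
#' Star phylogeny: every tip receives `Poisson(divergence * length)`
#' substitutions independently. A substitution landing in a planted stem
#' co-mutates the partner base to restore an allowed pair (GU permitted) with
#' probability `compensatory_fraction`; motif positions are immutable unless
#' `mutable_motifs` is set. Deterministic in the config seed.
#'
#' @param ancestor one-row sequence set from [build_ancestor()].
#' @param planted the planted [rna_structure()] from [build_ancestor()].
#' @param config the same [synth_config()].
#' @return sequence-set data.frame with `n_groups * n_species_per_group`
#'   rows; ids encode group and tip.
#' @export
evolve_family <- function(ancestor, planted, config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  anc <- strsplit(ancestor$residues, "")[[1]]
  L <- length(anc)
  partner <- partner_vector(planted, L)
  motif_pos <- integer(0)
  if (!cf$mutable_motifs) {
    nt5 <- nchar(cf$motifs$terminal5); nt3 <- nchar(cf$motifs$terminal3)
    motif_pos <- c(seq_len(nt5), L - nt3 + seq_len(nt3))
    if (!is.null(cf$motifs$central)) {
      hit <- regexpr(cf$motifs$central, ancestor$residues, fixed = TRUE)
      if (hit > 0) motif_pos <- c(motif_pos, hit + seq_len(attr(hit, "match.length")) - 1L)
    }
  }
  mutable <- setdiff(seq_len(L), motif_pos)
  # DNA letters; pairing assessed at the RNA level (T plays U, GU allowed)
  partners_of <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))

  n_tips <- cf$n_groups * cf$n_species_per_group
  tips <- vector("list", n_tips)
  for (t in seq_len(n_tips)) {
    tip_seed <- derive_seed(cf$seed, 1000L + t)
    tips[[t]] <- withr::with_seed(tip_seed, {
      s <- anc
      nsub <- rpois(1, cf$divergence * L)
      if (nsub > 0) {
        pos <- sample(mutable, nsub, replace = TRUE)
        for (p in pos) {
          new_base <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
          s[p] <- new_base
          q <- partner[p]
          if (q > 0 && !(q %in% motif_pos) &&
              runif(1) < cf$compensatory_fraction) {
            cand <- partners_of[[new_base]]
            s[q] <- if (length(cand) == 1) cand else sample(cand, 1)
          }
        }
      }
      paste(s, collapse = "")
    })
  }
  g <- rep(seq_len(cf$n_groups), each = cf$n_species_per_group)
  t_in_g <- rep(seq_len(cf$n_species_per_group), times = cf$n_groups)
  new_records(sprintf("%s_g%d_t%d", cf$region, g, t_in_g),
              sprintf("species_g%d_t%d", g, t_in_g),
              sprintf("group%d", g), cf$region,
              unlist(tips))
}

#' Generate a complete synthetic family
#'
#' Convenience wrapper: [build_ancestor()] plus [evolve_family()].
#'
#' @param config a [synth_config()].
#' @return list with `records` (the family), `ancestor` and `planted`.
#' @export
synth_family <- function(config) {
  anc <- build_ancestor(config)
  records <- evolve_family(anc$record, anc$structure, config)
  list(records = records, ancestor = anc$record, planted = anc$structure)
}

#' Write a synthetic family to disk
#'
#' Emits FASTA, a metadata sidecar TSV and the planted structure as a
#' dot-bracket file.
#'
#' @param family result of [synth_family()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synth_family <- function(family, dir, prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  sidecar <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  db <- file.path(dir, paste0(prefix, "_planted.db"))
  write_its_fasta(family$records, fasta)
  write.table(family$records[, c("id", "species", "group", "region")],
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  write_dotbracket(family$ancestor$residues, family$planted, db,
                   id = family$ancestor$id)
  invisible(c(fasta = fasta, metadata = sidecar, planted = db))
}
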
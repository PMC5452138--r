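# Folding front-ends: base-pair maximization, MFE folding, suboptimal
# enumeration. The dynamic programming lives in src/fold.cpp; candidate
# suboptimal structures are re-scored with the independent loop-decomposition
# evaluator, so every reported energy is a plain model evaluation of the
# reported structure.

encode_seq <- function(sequence) {
  seq_u <- gsub("T", "U", toupper(sequence), fixed = TRUE)
  ch <- strsplit(seq_u, "")[[1]]
  codes <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  bad <- setdiff(unique(ch), names(codes))
  if (length(bad))
    stop("sequence contains characters outside A/C/G/T/U: ",
         paste(bad, collapse = ", "), " (resolve ambiguity codes first)")
  unname(codes[ch])
}

#' Maximum base-pairing structure (Nussinov)
#'
#' Maximizes the number of mutually non-crossing allowed pairs (`AU, UA, GC,
#' CG, GU, UG`) with a minimum hairpin-loop constraint. Among co-optimal
#' tracebacks, pairing of the outermost candidate is preferred (smallest `i`,
#' then largest `j`). Serves as the small-instance oracle for the energy
#' folder and as a baseline.
#'
#' @param sequence residue string over `A/C/G/T/U` (T read as U).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return list with `max_pairs` (count) and `structure` (an
#'   [rna_structure()], energy `NA`).
#' @export
nussinov_maxpairs <- function(sequence, min_loop = 3) {
  s <- encode_seq(sequence)
  res <- .nussinov_cpp(s, as.integer(min_loop))
  st <- rna_structure(pairs = res$pairs, length = length(s),
                      sequence = toupper(sequence))
  list(max_pairs = res$max_pairs, structure = st)
}

#' Minimum-free-energy structure
#'
#' Zuker-style dynamic programming under the nearest-neighbour model:
#' external recursion plus a pair-closed recursion with hairpin, stacking,
#' bulge/internal loops (total unpaired size capped at
#' `model$max_internal`) and affine multibranch terms. An open chain has
#' energy 0. The returned energy equals [evaluate_energy()] of the returned
#' structure under the same model.
#'
#' @inheritParams nussinov_maxpairs
#' @param model an `energy_model` (shipped defaults if omitted).
#' @return an [rna_structure()] with its free energy in kcal/mol.
#' @export
fold_mfe <- function(sequence, model = default_energy_model()) {
  s <- encode_seq(sequence)
  res <- .zuker_fold_cpp(s, unclass_model(model), NULL)
  rna_structure(pairs = res$pairs, length = length(s), energy = res$energy,
                sequence = toupper(sequence))
}

unclass_model <- function(model) {
  stopifnot(inherits(model, "energy_model"))
  unclass(model)
}

pair_keys <- function(structure) {
  pr <- structure$pairs
  if (nrow(pr) == 0) character(0) else paste(pr[, 1], pr[, 2], sep = ":")
}

pair_distance <- function(a, b) {
  ka <- pair_keys(a); kb <- pair_keys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Enumerate low-energy suboptimal structures
#'
#' Collects distinct structures within `percent_window` percent of the
#' minimum free energy (LES), each differing from every previously kept
#' structure by at least `min_pair_distance` base pairs, up to
#' `max_structures`. The first structure is the [fold_mfe()] optimum.
#'
#' Enumeration is by deterministic pair-penalty refolding: each round adds a
#' small penalty to every base pair seen in earlier candidates and refolds;
#' the candidate is re-scored with the unpenalized model via
#' [evaluate_energy()] and kept if it passes the window and distance filters.
#'
#' @inheritParams fold_mfe
#' @param percent_window energy window as a percentage of the LES (default 10).
#' @param max_structures cap on the number of structures (default 20).
#' @param min_pair_distance minimum base-pair distance between kept
#'   structures (default 3).
#' @return object of class `fold_result`: list with `structures` (ascending
#'   energy, MFE first), `les` (kcal/mol) and `n_structures`.
#' @export
fold_suboptimal <- function(sequence, model = default_energy_model(),
                            percent_window = 10, max_structures = 20,
                            min_pair_distance = 3) {
  stopifnot(percent_window > 0, max_structures >= 1)
  s <- encode_seq(sequence)
  n <- length(s)
  mfe <- fold_mfe(sequence, model)
  les <- mfe$energy
  threshold <- les * (1 - percent_window / 100)  # les <= 0 always
  kept <- list(mfe)
  if (nrow(mfe$pairs) > 0 && max_structures > 1) {
    pen <- matrix(0, n, n)
    pen_step <- 0.3
    seen <- new.env(parent = emptyenv())
    struct_key <- function(st) paste0("s:", paste(pair_keys(st), collapse = ","))
    assign(struct_key(mfe), TRUE, envir = seen)
    bump <- function(st) {
      pr <- st$pairs
      for (k in seq_len(nrow(pr))) {
        pen[pr[k, 1], pr[k, 2]] <<- pen[pr[k, 1], pr[k, 2]] + pen_step
        pen[pr[k, 2], pr[k, 1]] <<- pen[pr[k, 2], pr[k, 1]] + pen_step
      }
    }
    bump(mfe)
    max_rounds <- 3L * max_structures
    streak <- 0L
    mlist <- unclass_model(model)
    for (round in seq_len(max_rounds)) {
      res <- .zuker_fold_cpp(s, mlist, pen)
      cand <- rna_structure(pairs = res$pairs, length = n,
                            sequence = toupper(sequence))
      key <- struct_key(cand)
      if (exists(key, envir = seen, inherits = FALSE)) {
        streak <- streak + 1L
        if (streak >= 6L) break
        bump(cand)
        next
      }
      assign(key, TRUE, envir = seen)
      bump(cand)
      cand$energy <- evaluate_energy(sequence, cand, model)
      ok_energy <- cand$energy <= threshold + 1e-9
      ok_dist <- all(vapply(kept, function(st) pair_distance(st, cand), 0L) >=
                       min_pair_distance)
      if (ok_energy && ok_dist) {
        kept[[length(kept) + 1L]] <- cand
        streak <- 0L
        if (length(kept) >= max_structures) break
      } else {
        streak <- streak + 1L
        if (streak >= 6L) break
      }
    }
  }
  if (length(kept) > 1) {
    rest <- kept[-1]
    ord <- order(vapply(rest, `[[`, 0, "energy"),
                 vapply(rest, `[[`, "", "dotbracket"))
    kept <- c(kept[1], rest[ord])
  }
  structure(list(structures = kept, les = les, n_structures = length(kept)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> LES %.2f kcal/mol, %d structure(s)\n",
              x$les, x$n_structures))
  invisible(x)
}
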
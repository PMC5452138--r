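# Loop-decomposition free-energy evaluation.
#
# Pure-R re-implementation of the energy function, independent of the dynamic
# programming engine: a structure is decomposed into its loops (hairpin,
# stack, bulge/internal, multibranch, exterior) and the model terms are
# summed. Serves as the internal-consistency oracle for the folder and as the
# scorer for suboptimal candidates.

#' Free energy of a given structure under an energy model
#'
#' Decomposes `structure` into loops and sums the model terms: hairpin and
#' bulge/internal penalties by loop size, stacking energies for adjacent
#' pairs, affine multibranch terms (`a + b * branches + c * unpaired`, the
#' closing helix not counted as a branch), zero for the exterior loop.
#'
#' @param sequence residue string over `A/C/G/T/U` (case-insensitive, T
#'   treated as U).
#' @param structure an [rna_structure()] (or a dot-bracket string).
#' @param model an `energy_model`; the shipped defaults if omitted.
#' @return free energy in kcal/mol (0 for an open chain).
#' @export
evaluate_energy <- function(sequence, structure, model = default_energy_model()) {
  if (is.character(structure)) structure <- rna_structure(dotbracket = structure)
  seq_u <- gsub("T", "U", toupper(sequence), fixed = TRUE)
  validate_structure(seq_u, structure, model)
  n <- nchar(seq_u)
  ch <- strsplit(seq_u, "")[[1]]
  partner <- partner_vector(structure, n)

  # children of the loop closed by (i, j); exterior loop = (0, n+1)
  loop_children <- function(i, j) {
    kids <- matrix(integer(0), 0, 2)
    unpaired <- 0L
    k <- i + 1L
    while (k <= j - 1L) {
      if (partner[k] == 0) { unpaired <- unpaired + 1L; k <- k + 1L }
      else if (partner[k] > k) { kids <- rbind(kids, c(k, partner[k])); k <- partner[k] + 1L }
      else stop("inconsistent pairing at position ", k)
    }
    list(kids = kids, unpaired = unpaired)
  }

  total <- 0
  ext <- loop_children(0L, n + 1L)           # exterior contributes 0
  stack_pairs <- ext$kids
  while (nrow(stack_pairs) > 0) {
    i <- stack_pairs[1, 1]; j <- stack_pairs[1, 2]
    stack_pairs <- stack_pairs[-1, , drop = FALSE]
    lp <- loop_children(i, j)
    nb <- nrow(lp$kids)
    if (nb == 0) {
      total <- total + loop_penalty(model$hairpin, j - i - 1L, model$loop_coef)
    } else if (nb == 1) {
      h <- lp$kids[1, 1]; l <- lp$kids[1, 2]
      n1 <- h - i - 1L; n2 <- j - l - 1L
      if (n1 == 0 && n2 == 0) {
        pt_out <- PAIR_NAMES[pair_type_chr(ch[i], ch[j])]
        pt_in <- PAIR_NAMES[pair_type_chr(ch[h], ch[l])]
        total <- total + model$stack[pt_out, pt_in]
      } else if (n1 == 0 || n2 == 0) {
        total <- total + loop_penalty(model$bulge, n1 + n2, model$loop_coef)
      } else {
        total <- total + loop_penalty(model$internal, n1 + n2, model$loop_coef)
      }
    } else {
      total <- total + model$ml_a + model$ml_b * nb + model$ml_c * lp$unpaired
    }
    stack_pairs <- rbind(stack_pairs, lp$kids)
  }
  total
}
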
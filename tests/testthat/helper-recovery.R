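# Shared parameter-recovery simulation for the acceptance suite: 20 seeded
# replicates of a 12-sequences-per-region study at each operating point,
# folded once and reused by the tests that examine constraint flagging and
# hairpin-mode recovery.

.recovery_cache <- new.env(parent = emptyenv())

recovery_replicates <- function(c_frac, div, n_rep = 20) {
  key <- sprintf("c%s_d%s_%d", c_frac, div, n_rep)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  out <- lapply(seq_len(n_rep), function(r) {
    fam1 <- synth_family(synth_config("ITS1", divergence = div,
                                      compensatory_fraction = c_frac,
                                      seed = 2000 + r))
    fam2 <- synth_family(synth_config("ITS2", divergence = div,
                                      compensatory_fraction = c_frac,
                                      seed = 3000 + r))
    recs <- rbind(fam1$records, fam2$records)
    ct <- les_constraint_test(recs, master_seed = 4000 + r)
    list(p = ct$test$p_value,
         mode_its1 = modal_value(ct$real$n_hairpins[ct$real$region == "ITS1"]),
         mode_its2 = modal_value(ct$real$n_hairpins[ct$real$region == "ITS2"]))
  })
  .recovery_cache[[key]] <- out
  out
}
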
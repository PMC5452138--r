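# Pipeline orchestration: features per sequence, group summaries, matched
# null cohort, and the full comparison set, from one config, with logged and
# seeded outputs. Every number in the summary and test tables is recomputable
# from the per-sequence features TSV.

#' Default run configuration
#'
#' @return the default config list; see [run_pipeline()] for the keys.
#' @export
default_run_config <- function() {
  list(
    fasta = list(ITS1 = NULL, ITS2 = NULL),
    metadata = NULL,
    aligned = list(ITS1 = NULL, ITS2 = NULL),
    energy_params = NULL,
    master_seed = 1L,
    suboptimal = list(percent_window = 10, max_structures = 20,
                      min_pair_distance = 3),
    null_mode = "composition",
    out_dir = "itsfold_out",
    max_terminal = 10,
    collapse_tu = FALSE,
    id_whitelist = NULL,
    dump_structures = FALSE
  )
}

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cf <- modifyList(default_run_config(), config)
  cf$master_seed <- as.integer(cf$master_seed)
  cf
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fold a sequence set and extract per-sequence features
#'
#' @param records sequence-set data.frame.
#' @param model an `energy_model`.
#' @param suboptimal list with `percent_window`, `max_structures`,
#'   `min_pair_distance`, or `NULL` to fold the optimal structure only
#'   (`n_structures` is then 1).
#' @return features data.frame, one row per record (see [featurize()]).
#' @export
extract_features <- function(records, model = default_energy_model(),
                             suboptimal = list(percent_window = 10,
                                               max_structures = 20,
                                               min_pair_distance = 3)) {
  rows <- lapply(seq_len(nrow(records)), function(k) {
    rec <- records[k, , drop = FALSE]
    seq_k <- ungap(rec$residues)
    fold <- if (is.null(suboptimal)) fold_mfe(seq_k, model)
    else fold_suboptimal(seq_k, model,
                         percent_window = suboptimal$percent_window,
                         max_structures = suboptimal$max_structures,
                         min_pair_distance = suboptimal$min_pair_distance)
    featurize(fold, rec)
  })
  do.call(rbind, rows)
}

#' Constraint test of real sequences against matched nulls
#'
#' Generates the length- and GC-matched null cohort for `records`, folds both
#' cohorts to their minimum-free-energy structures, and compares the lowest
#' energy states with a two-sided Wilcoxon-Mann-Whitney test. A significantly
#' lower LES in the real sequences is the signature of selective constraint
#' on the fold.
#'
#' @param records sequence-set data.frame (real sequences).
#' @param master_seed integer seed for the null cohort.
#' @param model an `energy_model`.
#' @param mode null-generation mode (see [generate_null_cohort()]).
#' @return list with `test` (an `its_test` on LES), `real` and `null`
#'   feature data.frames.
#' @export
les_constraint_test <- function(records, master_seed,
                                model = default_energy_model(),
                                mode = "composition") {
  nulls <- generate_null_cohort(records, master_seed, mode = mode)
  real_f <- extract_features(records, model, suboptimal = NULL)
  null_f <- extract_features(nulls, model, suboptimal = NULL)
  list(test = mann_whitney_u(real_f$les, null_f$les),
       real = real_f, null = null_f)
}

test_row <- function(comparison, result) {
  data.frame(comparison = comparison, method = result$method,
             statistic = result$statistic, p_value = result$p_value,
             n = paste(result$n_per_group, collapse = "/"),
             p_method = result$p_method, stringsAsFactors = FALSE)
}

summarise_feature_block <- function(features, feature, region, group_label, mask) {
  v <- features[[feature]][mask]
  if (length(v) == 0) return(NULL)
  d <- describe_values(v, label = group_label)
  data.frame(region = region, group = group_label, feature = feature,
             n = d$n, mean = round(d$mean, 1), sd = round(d$sd, 1),
             min = d$min, max = d$max, mode = d$mode, stringsAsFactors = FALSE)
}

#' Run the full constraint-analysis pipeline
#'
#' Reads, labels and filters the input sequences, generates the matched null
#' cohort, folds every sequence (real and random), and writes the analysis
#' artifacts into `config$out_dir`:
#'
#' * `features.tsv` — per-sequence features for real and null sequences
#'   (column `class` is `real` or `random`);
#' * `alignment_stats.tsv` — variable/parsimony-informative site statistics
#'   per group and region (only when aligned inputs are configured);
#' * `summary.tsv` — mean (SD, 1 decimal) of length, LES, number of
#'   structures, hairpins and paired bases per group, per region, pooled, and
#'   for the random cohort;
#' * `tests.tsv` — ITS1 vs ITS2 on each feature; real vs random on LES and
#'   number of structures (combined and per region); Kruskal-Wallis among
#'   groups per region on LES, number of structures and hairpins;
#' * `scatter.tsv` — LES vs number of structures with class `ITS1`, `ITS2`
#'   or `random`;
#' * `hairpin_freq.tsv` — hairpin-count frequencies per region (real
#'   sequences);
#' * `null_provenance.tsv` and `run_log.txt`.
#'
#' Missing inputs cause the affected comparison to be skipped with a logged
#' warning, never silently. Identical config and seed give byte-identical
#' TSV outputs.
#'
#' @param config a config list (see [default_run_config()]) or the path of a
#'   YAML file with the same keys. Keys: `fasta` (per-region FASTA paths),
#'   `metadata` (sidecar TSV), `aligned` (per-region named lists
#'   group -> aligned FASTA), `energy_params`, `master_seed`, `suboptimal`,
#'   `null_mode`, `out_dir`, `max_terminal`, `collapse_tu`, `id_whitelist`,
#'   `dump_structures`.
#' @return invisibly, a list with the artifact paths and the in-memory
#'   `features`, `summary` and `tests` tables.
#' @export
run_pipeline <- function(config) {
  cf <- load_run_config(config)
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("itsfold %s on R %s.%s", packageVersion("itsfold"),
                         R.version$major, R.version$minor),
                 sprintf("master_seed: %d", cf$master_seed),
                 "config:", strsplit(yaml::as.yaml(cf), "\n")[[1]])
  note <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (grepl("^skip", msg)) warning(msg, call. = FALSE)
  }

  model <- if (is.null(cf$energy_params)) default_energy_model()
           else read_energy_model(cf$energy_params)

  # ---- load and filter real sequences per region
  real <- list()
  for (region in REGIONS) {
    path <- cf$fasta[[region]]
    if (is.null(path)) { note(sprintf("skipping %s: no FASTA configured", region)); next }
    recs <- read_its_fasta(path, region = region, metadata = cf$metadata)
    if (!is.null(cf$id_whitelist)) recs <- recs[recs$id %in% cf$id_whitelist, , drop = FALSE]
    recs <- dedupe_identical(recs, collapse_tu = cf$collapse_tu)
    recs <- filter_terminal_missing(recs, cf$max_terminal)
    removed <- attr(recs, "removed")
    if (nrow(removed) > 0)
      note(sprintf("%s: removed %d record(s) for terminal missing data: %s",
                   region, nrow(removed), paste(removed$id, collapse = ", ")))
    note(sprintf("%s: %d records after dedup/filter", region, nrow(recs)))
    real[[region]] <- recs
  }
  if (length(real) == 0) stop("no input sequences configured")
  real_all <- do.call(rbind, unname(real))

  # ---- null cohort (seeded per region for order robustness)
  null_parts <- lapply(seq_along(real), function(k)
    generate_null_cohort(real[[k]], derive_seed(cf$master_seed, 500L + k),
                         mode = cf$null_mode))
  nulls <- do.call(rbind, unname(null_parts))
  prov <- do.call(rbind, unname(lapply(null_parts, attr, "provenance")))

  # ---- fold and featurize
  feats_real <- cbind(class = "real",
                      extract_features(real_all, model, cf$suboptimal),
                      stringsAsFactors = FALSE)
  feats_null <- cbind(class = "random",
                      extract_features(nulls, model, cf$suboptimal),
                      stringsAsFactors = FALSE)
  features <- rbind(feats_real, feats_null)
  paths <- list(features = file.path(cf$out_dir, "features.tsv"))
  write_tsv(features, paths$features)
  write_tsv(prov, file.path(cf$out_dir, "null_provenance.tsv"))

  if (isTRUE(cf$dump_structures)) {
    st_dir <- file.path(cf$out_dir, "structures")
    dir.create(st_dir, showWarnings = FALSE)
    for (k in seq_len(nrow(real_all))) {
      rec <- real_all[k, , drop = FALSE]
      fold <- fold_mfe(ungap(rec$residues), model)
      write_ct(ungap(rec$residues), fold,
               file.path(st_dir, paste0(rec$id, ".ct")), title = rec$id)
      write_dotbracket(ungap(rec$residues), fold,
                       file.path(st_dir, paste0(rec$id, ".db")), id = rec$id)
    }
  }

  # ---- alignment statistics (optional)
  aln_stats <- NULL
  for (region in REGIONS) {
    groups <- cf$aligned[[region]]
    if (is.null(groups)) next
    md <- if (!is.null(cf$metadata)) read.delim(cf$metadata, stringsAsFactors = FALSE) else NULL
    for (g in names(groups)) {
      aln <- read_aligned_fasta(groups[[g]], region = region, group = g)
      sp <- if (!is.null(md)) md$species[match(aln$labels, md$id)] else NULL
      aln_stats <- rbind(aln_stats, variable_and_pi_sites(aln, species = sp))
    }
  }
  if (!is.null(aln_stats)) {
    paths$alignment_stats <- file.path(cf$out_dir, "alignment_stats.tsv")
    write_tsv(aln_stats, paths$alignment_stats)
  } else note("skipping alignment statistics: no aligned inputs configured")

  # ---- summary table (recomputable from features.tsv)
  summary_feats <- c("length", "les", "n_structures", "n_hairpins",
                     "n_paired", "pct_paired")
  summary <- NULL
  for (region in names(real)) {
    fr <- feats_real[feats_real$region == region, ]
    for (f in summary_feats) {
      for (g in unique(fr$group))
        summary <- rbind(summary, summarise_feature_block(fr, f, region, g, fr$group == g))
      summary <- rbind(summary, summarise_feature_block(fr, f, region, "all", rep(TRUE, nrow(fr))))
      fn <- feats_null[feats_null$region == region, ]
      summary <- rbind(summary, summarise_feature_block(fn, f, region, "random", rep(TRUE, nrow(fn))))
    }
  }
  paths$summary <- file.path(cf$out_dir, "summary.tsv")
  write_tsv(summary, paths$summary)

  # ---- tests
  tests <- NULL
  both_regions <- all(REGIONS %in% feats_real$region)
  if (both_regions) {
    f1 <- feats_real[feats_real$region == "ITS1", ]
    f2 <- feats_real[feats_real$region == "ITS2", ]
    for (f in c("les", "n_structures", "n_hairpins", "n_paired", "pct_paired"))
      tests <- rbind(tests, test_row(paste0("ITS1_vs_ITS2_", f),
                                     mann_whitney_u(f1[[f]], f2[[f]])))
  } else note("skipping ITS1 vs ITS2 comparisons: one region missing")
  for (f in c("les", "n_structures")) {
    tests <- rbind(tests, test_row(paste0("ITS_vs_random_", f),
                                   mann_whitney_u(feats_real[[f]], feats_null[[f]])))
    for (region in names(real)) {
      fr <- feats_real[feats_real$region == region, ]
      fn <- feats_null[feats_null$region == region, ]
      tests <- rbind(tests, test_row(sprintf("%s_vs_random_%s", region, f),
                                     mann_whitney_u(fr[[f]], fn[[f]])))
    }
  }
  for (region in names(real)) {
    fr <- feats_real[feats_real$region == region, ]
    grp <- unique(fr$group)
    if (length(grp) < 2) {
      note(sprintf("skipping Kruskal-Wallis for %s: fewer than 2 groups", region))
      next
    }
    for (f in c("les", "n_structures", "n_hairpins")) {
      res <- kruskal_wallis(split(fr[[f]], fr$group))
      tests <- rbind(tests, test_row(sprintf("KW_groups_%s_%s", region, f), res))
    }
  }
  paths$tests <- file.path(cf$out_dir, "tests.tsv")
  write_tsv(tests, paths$tests)

  # ---- figure-style data tables
  scatter <- data.frame(id = features$id, les = features$les,
                        n_structures = features$n_structures,
                        class = ifelse(features$class == "random", "random",
                                       features$region),
                        stringsAsFactors = FALSE)
  paths$scatter <- file.path(cf$out_dir, "scatter.tsv")
  write_tsv(scatter, paths$scatter)

  hp <- NULL
  for (region in names(real)) {
    fr <- feats_real[feats_real$region == region, ]
    tab <- table(factor(fr$n_hairpins, levels = seq(0, max(fr$n_hairpins))))
    hp <- rbind(hp, data.frame(region = region,
                               n_hairpins = as.integer(names(tab)),
                               count = as.integer(tab), stringsAsFactors = FALSE))
  }
  paths$hairpin_freq <- file.path(cf$out_dir, "hairpin_freq.tsv")
  write_tsv(hp, paths$hairpin_freq)

  paths$run_log <- file.path(cf$out_dir, "run_log.txt")
  writeLines(log_lines, paths$run_log)

  invisible(list(paths = paths, features = features, summary = summary,
                 tests = tests, config = cf))
}
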
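library(data.table)

# A small handcrafted transcriptome with 20-nt UTRs, for exact-value tests.
fixture_tx <- function(n = 6L, codons = 80L, seed = 42L) {
  simulate_transcriptome(n, codon_range = c(codons, codons), seed = seed)
}

# Fully controllable config: defaults are uniform dwell weights, unit
# recovery and the canonical digestion distributions.
fixture_config <- function(tx, library_size = 1e4, seed = 7L,
                           codon_weights = NULL, recovery5 = NULL,
                           recovery3 = NULL, d5_probs = NULL,
                           d3_probs = NULL, transcript_probs = NULL) {
  if (is.null(transcript_probs)) {
    transcript_probs <- setNames(rep(1 / nrow(tx), nrow(tx)), tx$transcript)
  }
  if (is.null(codon_weights)) {
    codon_weights <- setNames(rep(1, 61), riboshift:::sense_codons())
  }
  if (is.null(d5_probs)) d5_probs <- c(`14` = 0.2, `15` = 0.6, `16` = 0.2)
  if (is.null(d3_probs)) d3_probs <- c(`9` = 0.2, `10` = 0.6, `11` = 0.2)
  if (is.null(recovery5)) {
    recovery5 <- setNames(rep(1, 64), riboshift:::all_kmers(3))
  }
  if (is.null(recovery3)) {
    recovery3 <- setNames(rep(1, 64), riboshift:::all_kmers(3))
  }
  simulation_config(transcript_probs, codon_weights, d5_probs, d3_probs,
                    recovery5, recovery3, library_size, seed)
}

# Run the full simulate -> featurize -> train -> fit -> correct pipeline for
# one bias scenario. Heavy runs are cached so that several test files (and
# several acceptance checks) can share one computation.
.run_cache <- new.env(parent = emptyenv())

scenario_run <- function(bias_mode, n_tx = 100L, library_size = 5e5,
                         seed = 101L, codon_range = c(150L, 400L),
                         recovery5 = NULL) {
  key <- paste(bias_mode, n_tx, library_size, seed,
               !is.null(recovery5), sep = "_")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  tx <- simulate_transcriptome(n_tx, codon_range = codon_range, seed = seed)
  cfg <- make_default_config(tx, bias_mode, library_size = library_size,
                             seed = seed)
  if (!is.null(recovery5)) {
    cfg$recovery5[] <- recovery5[names(cfg$recovery5)]
  }
  sim <- simulate_library(cfg, tx)
  rules <- true_offset_rules(cfg)
  rec <- aggregate_counts(reads_to_alignments(sim$reads, tx), tx, rules)
  training <- select_training_set(rec, tx, seed = seed)
  full <- materialize_zero_cells(rec, tx, training)
  fit <- suppressWarnings(fit_nb_glm(build_design(full)))
  cm <- correction_model_from_fit(fit, rec)
  corrected <- apply_correction(rec, cm)
  out <- list(tx = tx, cfg = cfg, sim = sim, rules = rules, rec = rec,
              training = training, fit = fit, cm = cm,
              corrected = corrected)
  .run_cache[[key]] <- out
  out
}

# Simulation-parameter vs estimate correlation for one coefficient block,
# both mapped to the block's reference level.
block_recovery_cor <- function(fit, block, truth) {
  b <- coef_block(fit, block)
  ref <- names(b)[1]
  tr <- log(truth / truth[ref])
  common <- intersect(names(b)[!is.na(b)], names(tr))
  cor(exp(b[common]), exp(tr[common]))
}
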
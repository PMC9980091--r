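kmers <- function() riboshift:::all_kmers(3)

null_model <- function() {
  z <- setNames(rep(0, 64), kmers())
  correction_model(z, z, numeric(), numeric(), beta_gc = 0, gbar = 0.5)
}

small_records <- function(n_tx = 3L, codons = 80L, seed = 15L,
                          library_size = 8000) {
  tx <- fixture_tx(n_tx, codons = codons, seed = seed)
  cfg <- fixture_config(tx, library_size = library_size, seed = seed)
  sim <- simulate_library(cfg, tx)
  list(tx = tx, cfg = cfg,
       rec = aggregate_counts(reads_to_alignments(sim$reads, tx), tx,
                              true_offset_rules(cfg)))
}

test_that("a null model leaves counts untouched", {
  rr <- small_records()
  fac <- correction_factor(null_model(), rr$rec)
  # gbar = 0.5 is not the data's mean GC, but beta_gc = 0 makes it moot
  expect_true(all(fac == 1))
  out <- apply_correction(rr$rec, null_model())
  expect_equal(out$corrected_count, out$count)
})

test_that("factors invert the fitted bias on the log scale", {
  z <- setNames(rep(0, 64), kmers())
  b3 <- z
  b3["AAA"] <- log(2)
  m <- correction_model(z, b3, numeric(), numeric(), beta_gc = 0,
                        gbar = 0.5)
  rec <- data.table(transcript = "t", codon_idx = 1L, d5 = 15L, d3 = 10L,
                    f5 = c("ACG", "TTT"), f3 = c("AAA", "CCC"),
                    gc = 0.5, count = c(10, 10))
  fac <- correction_factor(m, rec)
  expect_equal(fac, c(0.5, 1), ignore_attr = TRUE)

  # records at reference-like (all-zero) levels and gc = gbar get factor 1
  m2 <- correction_model(z, z, numeric(), numeric(), beta_gc = 0.7,
                         gbar = 0.4)
  rec2 <- copy(rec)[, gc := 0.4]
  expect_equal(correction_factor(m2, rec2), c(1, 1), ignore_attr = TRUE)
  # ... and a larger fitted bias means a smaller factor
  rec3 <- copy(rec)[, gc := c(0.8, 0.2)]
  fac3 <- correction_factor(m2, rec3)
  expect_lt(fac3[1], fac3[2])
})

test_that("unseen levels contribute neutrally", {
  b5 <- setNames(rnorm(10), kmers()[1:10])  # deliberately partial table
  b3 <- setNames(rep(0, 64), kmers())
  m <- correction_model(b5, b3, numeric(), numeric(), 0, 0.5)
  rec <- data.table(f5 = c(kmers()[1], "TTT"), f3 = "AAA",
                    d5 = 15L, d3 = 10L, gc = 0.5, count = 1)
  fac <- correction_factor(m, rec)
  expect_equal(fac[2], 1)
  expect_equal(fac[1], exp(-b5[[1]]))
  expect_identical(attr(fac, "n_unseen")[["f5"]], 1L)
})

test_that("library size is conserved by every correction call", {
  rr <- small_records(seed = 33)
  set.seed(2)
  m <- correction_model(setNames(rnorm(64, 0, 0.4), kmers()),
                        setNames(rnorm(64, 0, 0.4), kmers()),
                        numeric(), numeric(), beta_gc = 0.3, gbar = 0.45)
  out <- apply_correction(rr$rec, m)
  expect_lt(abs(sum(out$corrected_count) - sum(out$count)) / sum(out$count),
            1e-9)
  # zero raw counts stay zero and factors are positive
  expect_true(all(out$factor > 0 & is.finite(out$factor)))
  expect_true(all(out[count == 0, corrected_count] == 0))
})

test_that("a fit on unbiased data leaves counts essentially alone", {
  run <- scenario_run("none", n_tx = 30L, library_size = 8e4, seed = 301L,
                      codon_range = c(120L, 220L))
  relchg <- abs(run$corrected$corrected_count / run$corrected$count - 1)
  # desk-scale run: coefficient noise alone moves factors by a few percent,
  # but the bulk of records must remain essentially untouched
  expect_lt(median(relchg), 0.1)
})

test_that("monosome factors transfer to disome counts", {
  tx <- fixture_tx(12, codons = 300, seed = 44)
  set.seed(44)
  r5 <- setNames(runif(64, 0.2, 1), kmers())
  r3 <- setNames(runif(64, 0.2, 1), kmers())
  spacing <- 10L
  d5 <- 15L
  d3 <- 10L
  # disome records at every eligible lagging position, with deterministic
  # counts = base * recovery (expected counts under end-sequence bias)
  grid <- CJ(t = tx$transcript, j = 10:270)
  grid[tx, on = c(t = "transcript"), utr5 := i.utr5]
  aln <- grid[, .(qname = paste0("d", .I), transcript = t,
                  pos = utr5 + 3L * j - d5,
                  len = d5 + 3L * spacing + 3L + d3)]
  len <- unique(aln$len)
  rules5 <- offset_rules(len, (-d5) %% 3L, d5, "start")
  rules3 <- offset_rules(len, d3 %% 3L, d3, "stop")
  sq <- tx[aln$transcript, on = "transcript"]$seq
  f5 <- substr(sq, aln$pos + 1L, aln$pos + 3L)
  f3 <- substr(sq, aln$pos + len - 2L, aln$pos + len)
  aln[, weight := 50 * r5[f5] * r3[f3]]
  rec <- aggregate_disome_counts(aln, tx, rules5, rules3)
  expect_true(all(rec$j_lead - rec$codon_idx == spacing))

  # the matched monosome model: true biases on the log scale, referenced
  # to the lexicographically first k-mer as in a fitted block
  mono <- correction_model(log(r5 / r5[["AAA"]]), log(r3 / r3[["AAA"]]),
                           numeric(), numeric(), beta_gc = 0, gbar = 0.5)
  out <- correct_disome(rec, mono)
  expect_lt(abs(sum(out$corrected_count) - sum(out$count)) / sum(out$count),
            1e-9)
  # null model: disome counts unchanged
  out0 <- correct_disome(rec, null_model())
  expect_equal(out0$corrected_count, out0$count)

  # importance around the LEADING A site: the 3' boundary signal (+3/+4)
  # present in raw counts is at least halved after correction
  lead <- copy(as.data.table(out))[, codon_idx := j_lead]
  training <- structure(list(
    transcripts = tx$transcript,
    ranges = data.table(transcript = tx$transcript, first_idx = 15L,
                        last_idx = tx$n_codons - 15L)),
    class = "training_spec")
  imp_raw <- position_importance(
    scale_counts(lead, training, "count"), tx, training)
  imp_cor <- position_importance(
    scale_counts(lead, training, "corrected_count"), tx, training)
  b_raw <- sum(imp_raw[position %in% c(3, 4), importance])
  b_cor <- sum(imp_cor[position %in% c(3, 4), importance])
  expect_gt(b_raw, 0.01)
  expect_lt(b_cor, 0.5 * b_raw)
})

test_that("correction models survive a JSON round trip", {
  rr <- small_records(seed = 51, library_size = 6000)
  training <- select_training_set(rr$rec, rr$tx, min_mean = 0.5,
                                  min_positions = 20, end_trim = 10L,
                                  seed = 3)
  des <- suppressWarnings(build_design(
    materialize_zero_cells(rr$rec, rr$tx, training)))
  fit <- fit_nb_glm(des)
  m <- correction_model_from_fit(fit, rr$rec)
  # gbar equals the count-weighted mean gc, against a direct summation
  expect_equal(m$gbar,
               with(rr$rec, sum(count * gc) / sum(count)))
  path <- tempfile(fileext = ".json")
  write_correction_model(m, path)
  m2 <- read_correction_model(path)
  expect_equal(m2$beta_f5, m$beta_f5)
  expect_equal(m2$beta_d3f3, m$beta_d3f3)
  expect_equal(m2$gbar, m$gbar)
  expect_equal(correction_factor(m2, rr$rec), correction_factor(m, rr$rec),
               ignore_attr = TRUE)
})
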
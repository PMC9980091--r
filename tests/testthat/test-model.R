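library(Matrix)

# small NB datasets for the fitter tests
nb_toy <- function(n = 400L, seed = 99L, phi = 4) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- runif(n)
  g <- factor(sample(c("u", "v", "w"), n, TRUE))
  X <- sparse.model.matrix(~ x1 + x2 + g)
  beta <- c(1.2, 0.5, -0.8, 0.4, -0.3)
  mu <- exp(as.numeric(X %*% beta))
  y <- rnbinom(n, size = phi, mu = mu)
  list(X = X, y = y, beta = beta, df = data.frame(x1, x2, g, y))
}

test_that("design encoding uses reference levels and full one-hot blocks", {
  tx <- fixture_tx(4, codons = 100, seed = 12)
  cfg <- fixture_config(tx, library_size = 2e4, seed = 12)
  sim <- simulate_library(cfg, tx)
  rec <- aggregate_counts(reads_to_alignments(sim$reads, tx), tx,
                          true_offset_rules(cfg))
  training <- select_training_set(rec, tx, min_mean = 1, min_positions = 20,
                                  end_trim = 10L, seed = 2)
  full <- materialize_zero_cells(rec, tx, training)
  des <- suppressWarnings(build_design(full))

  # f5 has 64 levels -> 63 free columns (no N-containing k-mers here)
  expect_identical(sum(des$groups == "f5"), 63L)
  expect_identical(length(des$xlevels$f5), 64L)
  # one-hot blocks: each factor contributes at most one 1 per row
  for (g in c("codA", "f5", "f3", "d5", "d3")) {
    block <- des$X[, des$groups == g, drop = FALSE]
    expect_lte(max(Matrix::rowSums(block)), 1)
  }
  # a record at reference levels everywhere has only intercept + gc
  ref_row <- which(Matrix::rowSums(
    des$X[, !des$groups %in% c("(Intercept)", "gc"), drop = FALSE]) == 0)
  if (length(ref_row)) {
    r <- des$X[ref_row[1], ]
    expect_equal(sum(r != 0), 2L)  # intercept and gc
  }
})

test_that("the fitter matches brute-force likelihood maximization", {
  toy <- nb_toy()
  fit <- fit_nb_glm(list(X = toy$X, y = toy$y))
  expect_true(fit$converged)

  # independent oracle: direct optimization of the NB likelihood written
  # with stats::dnbinom, over (beta, log phi) jointly
  negll <- function(par) {
    mu <- exp(as.numeric(toy$X %*% par[1:5]))
    -sum(stats::dnbinom(toy$y, size = exp(par[6]), mu = mu, log = TRUE))
  }
  opt <- optim(c(rep(0, 5), 0), negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(fit$coefficients - opt$par[1:5])), 1e-4)
  expect_lt(abs(log(fit$phi) - opt$par[6]), 1e-3)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
})

test_that("the fitter agrees with glm.nb on integer data", {
  skip_if_not_installed("MASS")
  toy <- nb_toy(seed = 7)
  fit <- fit_nb_glm(list(X = toy$X, y = toy$y))
  ref <- MASS::glm.nb(y ~ x1 + x2 + g, data = toy$df)
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-4)
  expect_equal(fit$phi, ref$theta, tolerance = 1e-3)
  # Wald SEs match the glm.nb conditional SEs
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-3)
})

test_that("the outer-loop likelihood never decreases", {
  toy <- nb_toy(seed = 3)
  fit <- fit_nb_glm(list(X = toy$X, y = toy$y))
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("estimates are invariant to record order", {
  tx <- fixture_tx(3, codons = 80, seed = 55)
  cfg <- fixture_config(tx, library_size = 8000, seed = 55)
  sim <- simulate_library(cfg, tx)
  rec <- aggregate_counts(reads_to_alignments(sim$reads, tx), tx,
                          true_offset_rules(cfg))
  training <- select_training_set(rec, tx, min_mean = 0.5,
                                  min_positions = 20, end_trim = 10L,
                                  seed = 2)
  full <- materialize_zero_cells(rec, tx, training)
  set.seed(77)
  shuffled <- full[sample(nrow(full))]
  fit1 <- fit_nb_glm(suppressWarnings(build_design(full)))
  fit2 <- fit_nb_glm(suppressWarnings(build_design(shuffled)))
  expect_lt(max(abs(fit1$coefficients - fit2$coefficients)), 1e-10)
  expect_equal(fit1$phi, fit2$phi, tolerance = 1e-8)
})

test_that("dispersion tracks the data-generating distribution", {
  set.seed(17)
  n <- 4000L
  x <- rnorm(n)
  X <- sparse.model.matrix(~ x)
  mu <- exp(1 + 0.6 * x)
  # NB data with phi = 5: recovered phi is near 5 and NB beats Poisson
  y_nb <- rnbinom(n, size = 5, mu = mu)
  fit_nb <- fit_nb_glm(list(X = X, y = y_nb))
  expect_gt(fit_nb$phi, 3.5)
  expect_lt(fit_nb$phi, 7)
  pois <- glm(y_nb ~ x, family = poisson)
  ll_pois <- sum(stats::dpois(y_nb, pois$fitted.values, log = TRUE))
  expect_gt(fit_nb$loglik, ll_pois)

  # Poisson data: 1/phi -> 0 (phi very large)
  y_p <- rpois(n, mu)
  fit_p <- fit_nb_glm(list(X = X, y = y_p))
  expect_lt(1 / fit_p$phi, 1e-2)
})

test_that("coefficient tables carry reference rows and finite SEs", {
  tx <- fixture_tx(3, codons = 80, seed = 14)
  cfg <- fixture_config(tx, library_size = 1.5e4, seed = 14)
  sim <- simulate_library(cfg, tx)
  rec <- aggregate_counts(reads_to_alignments(sim$reads, tx), tx,
                          true_offset_rules(cfg))
  training <- select_training_set(rec, tx, min_mean = 1, min_positions = 20,
                                  end_trim = 10L, seed = 2)
  des <- suppressWarnings(build_design(materialize_zero_cells(rec, tx,
                                                              training)))
  fit <- fit_nb_glm(des)
  tab <- coefficient_table(fit)

  refs <- tab[is.na(se)]
  expect_identical(nrow(refs), length(fit$xlevels))
  expect_true(all(refs$estimate == 0 & refs$exp_estimate == 1))
  free <- tab[!is.na(se)]
  expect_true(all(is.finite(free$se) & free$se > 0))
  # one row per free coefficient plus one reference row per factor
  expect_identical(nrow(tab),
                   length(fit$coefficients) + length(fit$xlevels))
})

test_that("differential occupancy recovers an exact rate ratio", {
  # deterministic check: responses set to their expected values make the
  # MLE land on the generating parameters (the score is zero at the truth)
  tx <- fixture_tx(3, codons = 90, seed = 25)
  cfg <- fixture_config(tx, library_size = 1e4, seed = 25)
  sim <- simulate_library(cfg, tx)
  rec <- aggregate_counts(reads_to_alignments(sim$reads, tx), tx,
                          true_offset_rules(cfg))
  training <- select_training_set(rec, tx, min_mean = 0.1,
                                  min_positions = 10, end_trim = 10L,
                                  seed = 2)
  base <- materialize_zero_cells(rec, tx, training)
  lam <- 6
  r <- 3
  rec_a <- copy(base)[, count := lam]
  rec_b <- copy(base)[, count := lam * ifelse(cod_a == "GCT", r, 1)]
  diff <- suppressWarnings(fit_differential(rec_a, rec_b, tol = 1e-10))
  est <- diff$results[codon == "GCT"]
  expect_equal(est$fold, r, tolerance = 1e-3)
  others <- diff$results[codon != "GCT"]
  expect_lt(max(abs(others$estimate)), 1e-4)
})

test_that("a null contrast yields few false discoveries", {
  run <- scenario_run("none", n_tx = 30L, library_size = 8e4, seed = 301L,
                      codon_range = c(120L, 220L))
  base <- materialize_zero_cells(run$rec, run$tx, run$training)
  cfgb <- run$cfg
  cfgb$seed <- 302L
  simb <- simulate_library(cfgb, run$tx)
  recb <- aggregate_counts(reads_to_alignments(simb$reads, run$tx), run$tx,
                           run$rules)
  fullb <- materialize_zero_cells(recb, run$tx, run$training)
  diff <- suppressWarnings(fit_differential(base, fullb))
  expect_lte(nrow(diff$results[padj < 0.05]), 3L)
})
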
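#' Build the bias-regression design matrix
#'
#' Encodes a count table (including materialized zero cells, see
#' [materialize_zero_cells()]) into a sparse design for the negative
#' binomial regression
#' `log mu = b0 + tx + codA + codP + codE + d5 + d3 + f5 + f3 + d5:f5 +
#' d3:f3 + b_g * gc` (plus, when `condition` is given, a condition indicator
#' and per-codon A-site:condition interactions). All categorical covariates
#' use treatment coding with the lexicographically first observed level as
#' reference; records whose bias k-mers or codons contain N are dropped.
#'
#' @param records featurized count table
#' @param condition optional factor/character of length `nrow(records)`
#'   giving each record's experimental condition (2 levels)
#' @return list with the sparse model matrix `X`, response `y`, `groups`
#'   (term label per column), `xlevels` (factor levels) and the row-filtered
#'   `records`
#' @export
build_design <- function(records, condition = NULL) {
  dt <- as.data.table(records)
  if (!is.null(condition)) dt[, cond := as.character(condition)]
  keep <- !grepl("N", paste0(dt$f5, dt$f3, dt$cod_a, dt$cod_p, dt$cod_e)) &
    !is.na(dt$cod_p) & !is.na(dt$cod_e)
  dt <- dt[keep]
  # canonical row order: estimates must not depend on how records arrive
  setorderv(dt, intersect(c("transcript", "codon_idx", "j_lead", "d5", "d3",
                            "cond"), names(dt)))
  df <- data.frame(
    tx = factor(dt$transcript),
    codA = factor(dt$cod_a), codP = factor(dt$cod_p), codE = factor(dt$cod_e),
    d5 = factor(dt$d5), d3 = factor(dt$d3),
    f5 = factor(dt$f5), f3 = factor(dt$f3),
    gc = dt$gc)
  form <- y ~ tx + codA + codP + codE + d5 + d3 + f5 + f3 + d5:f5 + d3:f3 + gc
  if (!is.null(condition)) {
    df$cond <- factor(dt$cond)
    if (nlevels(df$cond) != 2L) stop("condition must have exactly 2 levels")
    form <- y ~ tx + codA + codP + codE + d5 + d3 + f5 + f3 + d5:f5 + d3:f3 +
      gc + cond + codA:cond
  }
  df$y <- dt$count
  X <- sparse.model.matrix(form, df)
  terms_lab <- c("(Intercept)", attr(stats::terms(form), "term.labels"))
  groups <- terms_lab[attr(X, "assign") + 1L]
  # interaction cells never observed have all-zero columns; they are
  # inestimable and dropped from the design
  nz <- Matrix::colSums(X != 0) > 0
  if (any(!nz)) {
    X <- X[, nz, drop = FALSE]
    groups <- groups[nz]
  }
  # drop aliased (collinear) columns, as lm does for inestimable levels --
  # typically rare interaction cells observed under a single digestion length
  XtX <- as.matrix(Matrix::crossprod(X))
  ch <- suppressWarnings(chol(XtX, pivot = TRUE))
  rank <- attr(ch, "rank")
  if (rank < ncol(X)) {
    bad <- sort(attr(ch, "pivot")[seq.int(rank + 1L, ncol(X))])
    warning("dropping ", length(bad), " aliased design column(s): ",
            paste(head(colnames(X)[bad], 10), collapse = ", "),
            if (length(bad) > 10) ", ...")
    X <- X[, -bad, drop = FALSE]
    groups <- groups[-bad]
  }
  list(X = X, y = dt$count, groups = groups,
       xlevels = lapply(df[, setdiff(names(df), c("y", "gc")),
                           drop = FALSE], levels),
       records = dt)
}

# Negative binomial log-likelihood with dispersion phi (var = mu + mu^2/phi),
# evaluated through the gamma-function continuous extension so fractional
# counts (summed multi-mapping posteriors) are admissible.
nb_loglik <- function(y, mu, phi) {
  sum(lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
        phi * log(phi / (phi + mu)) + y * log(mu / (phi + mu) + (y == 0)))
}

#' Fit the negative binomial bias regression
#'
#' Maximizes the NB log-likelihood (mean `mu`, variance `mu + mu^2/phi`) by
#' alternating iteratively reweighted least squares for the coefficients at
#' fixed dispersion with one-dimensional likelihood maximization of `phi` at
#' fixed coefficients, until the relative log-likelihood change falls below
#' `tol`. Standard errors are Wald errors from the expected information at
#' the optimum (conditional on the fitted dispersion).
#'
#' @param design a design list from [build_design()] (or a list with
#'   elements `X`, `y`, and optionally `groups`)
#' @param tol relative log-likelihood convergence tolerance (default 1e-8)
#' @param max_outer maximum outer (beta, phi) alternations (default 50)
#' @param phi_init starting dispersion (default: method of moments)
#' @param verbose print per-iteration log-likelihoods
#' @return an `nb_fit`: coefficients and SEs (named by design column),
#'   `phi`, `loglik`, `converged`, `iterations`, per-column term `groups`,
#'   `xlevels`, and the log-likelihood trace
#' @export
fit_nb_glm <- function(design, tol = 1e-8, max_outer = 50L, phi_init = NULL,
                       verbose = FALSE) {
  X <- design$X
  y <- design$y
  if (any(y < 0)) stop("response must be non-negative")
  stopifnot(nrow(X) == length(y))

  mu <- pmax(y, 0) + mean(y) / 10 + 1e-4
  eta <- log(mu)
  if (is.null(phi_init)) {
    v <- stats::var(y)
    m <- mean(y)
    phi <- if (v > m * 1.01) m^2 / (v - m) else 1e4
    phi <- min(max(phi, 1e-3), 1e6)
  } else {
    phi <- phi_init
  }

  beta <- NULL
  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_outer)) {
    # IRLS for beta at fixed phi
    for (inner in 1:25) {
      w <- as.numeric(mu / (1 + mu / phi))
      z <- eta + (y - mu) / mu
      XtWX <- as.matrix(Matrix::crossprod(X * sqrt(w)))
      XtWz <- as.numeric(Matrix::crossprod(X, w * z))
      ch <- tryCatch(chol(XtWX), error = function(e) NULL)
      if (is.null(ch)) {
        piv <- chol(XtWX, pivot = TRUE)
        rank <- attr(piv, "rank")
        bad <- colnames(X)[attr(piv, "pivot")][seq.int(rank + 1L, ncol(X))]
        stop("design is singular; aliased column(s): ",
             paste(head(bad, 10), collapse = ", "))
      }
      beta_new <- backsolve(ch, forwardsolve(Matrix::t(ch), XtWz))
      eta_new <- as.numeric(X %*% beta_new)
      eta_new <- pmin(pmax(eta_new, -30), 30)
      mu_new <- exp(eta_new)
      ll_new <- nb_loglik(y, mu_new, phi)
      # step halving if the likelihood worsened
      step <- 1
      while (is.finite(ll) && ll_new < ll - 1e-10 && step > 1e-4 &&
             !is.null(beta)) {
        step <- step / 2
        beta_new <- beta + step * (beta_new - beta)
        eta_new <- pmin(pmax(as.numeric(X %*% beta_new), -30), 30)
        mu_new <- exp(eta_new)
        ll_new <- nb_loglik(y, mu_new, phi)
      }
      done <- !is.null(beta) &&
        abs(ll_new - ll) < tol * (abs(ll_new) + 1) / 10
      beta <- beta_new
      eta <- eta_new
      mu <- mu_new
      ll <- ll_new
      if (done) break
    }
    # 1-D likelihood maximization for phi at fixed mu
    opt <- optimize(function(lp) nb_loglik(y, mu, exp(lp)),
                    interval = c(log(1e-4), log(1e8)),
                    maximum = TRUE, tol = 1e-12)
    phi <- exp(opt$maximum)
    ll_outer <- opt$objective
    trace <- c(trace, ll_outer)
    if (verbose) {
      message(sprintf("outer %d: loglik %.6f, phi %.4g", it, ll_outer, phi))
    }
    if (it > 1L && abs(ll_outer - trace[it - 1L]) <
        tol * (abs(ll_outer) + 1)) {
      converged <- TRUE
      break
    }
    ll <- ll_outer
  }

  w <- as.numeric(mu / (1 + mu / phi))
  XtWX <- as.matrix(Matrix::crossprod(X * sqrt(w)))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, ncol(X)) else sqrt(pmax(diag(cov), 0))

  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    se = setNames(se, colnames(X)),
    phi = phi, loglik = trace[length(trace)], converged = converged,
    iterations = it, trace = trace,
    groups = design$groups %||% rep("", ncol(X)),
    xlevels = design$xlevels, fitted = mu, y = y), class = "nb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(paste0("nb_fit: %d coefficients, phi = %.3g, loglik = %.2f ",
                     "(%s in %d outer iterations)\n"),
              length(x$coefficients), x$phi, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Extract one coefficient block with its reference level at zero
#'
#' @param fit an `nb_fit`
#' @param term term label as used in the design (`"tx"`, `"codA"`, `"codP"`,
#'   `"codE"`, `"d5"`, `"d3"`, `"f5"`, `"f3"`, `"d5:f5"`, `"d3:f3"`, `"gc"`,
#'   `"cond"`, `"codA:cond"`)
#' @return named numeric of coefficients; for simple factor terms the
#'   reference level is included with value 0
#' @export
coef_block <- function(fit, term) {
  sel <- fit$groups == term
  est <- fit$coefficients[sel]
  var <- sub(":.*$", "", term)
  if (!grepl(":", term) && var %in% names(fit$xlevels)) {
    lev <- fit$xlevels[[var]]
    names(est) <- sub(paste0("^", var), "", names(est))
    full <- setNames(rep(NA_real_, length(lev)), lev)
    full[names(est)] <- est
    full[lev[1]] <- 0
    full
  } else {
    est
  }
}

#' Long-format coefficient table
#'
#' One row per coefficient, reference levels included with estimate 0; for
#' each free coefficient the Wald z statistic and two-sided p-value are
#' reported.
#'
#' @param fit an `nb_fit`
#' @return `data.table` with columns `term`, `level`, `estimate`,
#'   `exp_estimate`, `se`, `z`, `p`
#' @export
coefficient_table <- function(fit) {
  out <- data.table(term = fit$groups,
                    level = names(fit$coefficients),
                    estimate = as.numeric(fit$coefficients),
                    se = as.numeric(fit$se))
  # strip the variable prefix from factor levels, e.g. "f5AAC" -> "AAC"
  for (v in names(fit$xlevels)) {
    pre <- paste0("^", v)
    sel <- out$term == v
    out[sel, level := sub(pre, "", level)]
  }
  refs <- rbindlist(lapply(names(fit$xlevels), function(v) {
    if (!any(out$term == v)) return(NULL)
    data.table(term = v, level = fit$xlevels[[v]][1],
               estimate = 0, se = NA_real_)
  }))
  out <- rbind(out, refs)
  out[, exp_estimate := exp(estimate)]
  out[, z := estimate / se]
  out[, p := 2 * pnorm(-abs(z))]
  setorder(out, term, level)
  setcolorder(out, c("term", "level", "estimate", "exp_estimate", "se",
                     "z", "p"))
  out[]
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores coefficients, standard errors, term groups, factor levels, the
#' dispersion and the fit metadata; fitted values and the response are not
#' stored.
#'
#' @param fit an `nb_fit`
#' @param path JSON path
#' @return invisibly `path`; [read_nb_fit()] returns the `nb_fit`
#' @export
write_nb_fit <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
         groups = fit$groups, xlevels = fit$xlevels, phi = fit$phi,
         loglik = fit$loglik, converged = fit$converged,
         iterations = fit$iterations),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nb_fit
#' @export
read_nb_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(x$coefficients), se = unlist(x$se),
                 phi = x$phi, loglik = x$loglik, converged = x$converged,
                 iterations = x$iterations, trace = numeric(),
                 groups = x$groups, xlevels = x$xlevels),
            class = "nb_fit")
}

#' Test differential A-site occupancy between two conditions
#'
#' Jointly fits both libraries with the shared bias model plus a condition
#' indicator (absorbing library size) and per-codon A-site:condition
#' interactions, and reports a Wald test per codon with Benjamini-Hochberg
#' correction across the estimable codons. The interaction's
#' `exp(estimate)` is the fold-change in A-site occupancy of that codon in
#' condition B relative to condition A.
#'
#' @param records_a,records_b identically featurized count tables (use
#'   [materialize_zero_cells()] on each); condition A is the reference
#' @param ... passed to [fit_nb_glm()]
#' @return list with the joint `fit` and `results`, a `data.table` with one
#'   row per codon: `codon`, `estimate`, `fold` (= exp(estimate)), `se`,
#'   `z`, `p`, `padj`
#' @export
fit_differential <- function(records_a, records_b, ...) {
  both <- rbind(as.data.table(records_a), as.data.table(records_b))
  cond <- rep(c("A", "B"), c(nrow(records_a), nrow(records_b)))
  design <- build_design(both, condition = cond)
  fit <- fit_nb_glm(design, ...)
  sel <- fit$groups == "codA:cond"
  est <- fit$coefficients[sel]
  se <- fit$se[sel]
  codon <- sub("^codA(.*):condB$", "\\1", names(est))
  res <- data.table(codon = codon, estimate = as.numeric(est),
                    fold = exp(as.numeric(est)), se = as.numeric(se))
  res[, z := estimate / se]
  res[, p := 2 * pnorm(-abs(z))]
  res[, padj := p.adjust(p, method = "BH")]
  setorder(res, p)
  list(fit = fit, results = res[])
}
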
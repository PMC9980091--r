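#' Build a correction model from a fitted bias regression
#'
#' Extracts exactly the technical coefficient blocks -- 5' and 3' bias
#' sequences, their interactions with digestion length, and the GC slope --
#' together with the count-weighted mean GC content of the observed
#' footprints. These define a per-footprint multiplicative correction factor
#' (see [correction_factor()]) that inverts the fitted technical
#' contribution; biological blocks (transcript, A/P/E codons, digestion
#' main effects) are deliberately left untouched.
#'
#' @param fit a converged `nb_fit` from [fit_nb_glm()]
#' @param records the observed (non-zero-filled) count table the correction
#'   will be applied to; supplies the count-weighted mean GC
#' @return a `correction_model`: lookup tables `beta_f5`, `beta_f3`,
#'   `beta_d5f5`, `beta_d3f3` (keys `"d5|f5"` etc.), scalar `beta_gc`, and
#'   `gbar`
#' @export
correction_model_from_fit <- function(fit, records) {
  if (!isTRUE(fit$converged)) {
    warning("building a correction model from a non-converged fit")
  }
  need <- c("f5", "f3", "gc")
  missing <- setdiff(need, unique(fit$groups))
  if (length(missing)) {
    stop("fit lacks required technical block(s): ",
         paste(missing, collapse = ", "))
  }
  b_f5 <- coef_block(fit, "f5")
  b_f3 <- coef_block(fit, "f3")
  int5 <- fit$coefficients[fit$groups == "d5:f5"]
  int3 <- fit$coefficients[fit$groups == "d3:f3"]
  # "d515:f5AAC" -> key "15|AAC"
  key_of <- function(nm, a, b) {
    m <- regmatches(nm, regexec(paste0("^", a, "([0-9]+):", b, "([ACGT]+)$"),
                                nm))
    vapply(m, function(x) paste(x[2], x[3], sep = "|"), character(1))
  }
  names(int5) <- key_of(names(int5), "d5", "f5")
  names(int3) <- key_of(names(int3), "d3", "f3")
  gbar <- sum(records$count * records$gc) / sum(records$count)
  structure(list(beta_f5 = b_f5, beta_f3 = b_f3,
                 beta_d5f5 = int5, beta_d3f3 = int3,
                 beta_gc = unname(fit$coefficients[fit$groups == "gc"]),
                 gbar = gbar, k5 = unique(nchar(names(b_f5)))),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(paste0("correction_model: %d f5 / %d f3 levels, %d + %d ",
                     "interaction cells, beta_gc = %.4f, mean GC = %.3f\n"),
              length(x$beta_f5), length(x$beta_f3), length(x$beta_d5f5),
              length(x$beta_d3f3), x$beta_gc, x$gbar))
  invisible(x)
}

#' Per-footprint correction factors
#'
#' The factor for a record with end sequences f5/f3, digestion lengths
#' d5/d3 and GC content g is
#' `exp(-(beta_f5[f5] + beta_f3[f3] + beta_d5f5[d5,f5] + beta_d3f3[d3,f3] +
#' beta_gc * (g - gbar)))`:
#' the multiplicative inverse of the fitted technical contribution, with GC
#' centered at the library mean so that an average-GC footprint at
#' reference end sequences is left untouched. Bias-sequence levels unseen in
#' training contribute 0 to the exponent (factor contribution 1); their
#' number is reported in the `n_unseen` attribute.
#'
#' @param model a [correction_model_from_fit()] model
#' @param records featurized count table (same `k5` as the model)
#' @return numeric vector of strictly positive factors, one per record
#' @export
correction_factor <- function(model, records) {
  if (any(nchar(records$f5) != model$k5)) {
    stop("records use a different 5' k-mer length than the model")
  }
  lk <- function(tab, key) {
    v <- tab[key]
    n_unseen <- sum(is.na(v))
    v[is.na(v)] <- 0
    list(v = unname(v), n = n_unseen)
  }
  t1 <- lk(model$beta_f5, records$f5)
  t2 <- lk(model$beta_f3, records$f3)
  t3 <- lk(model$beta_d5f5, paste(records$d5, records$f5, sep = "|"))
  t4 <- lk(model$beta_d3f3, paste(records$d3, records$f3, sep = "|"))
  expo <- t1$v + t2$v + t3$v + t4$v + model$beta_gc * (records$gc - model$gbar)
  out <- exp(-expo)
  # unseen interaction cells include every combination absent from training;
  # only genuinely novel k-mers matter for the main effects
  setattr(out, "n_unseen", c(f5 = t1$n, f3 = t2$n, d5f5 = t3$n, d3f3 = t4$n))
  out
}

#' Apply bias correction to a count table
#'
#' Multiplies each record's count by its correction factor and rescales so
#' the total library size is preserved exactly:
#' `corrected = count * factor * S` with
#' `S = sum(count) / sum(count * factor)`. Zero counts stay zero -- the
#' correction is multiplicative and cannot restore footprints to positions
#' where none were observed.
#'
#' @param records featurized count table
#' @param model a `correction_model`
#' @return the records with added `corrected_count` (and `factor`) columns
#' @export
apply_correction <- function(records, model) {
  fac <- correction_factor(model, records)
  if (!all(is.finite(fac)) || all(fac == 0)) {
    stop("correction factors are degenerate (zero or non-finite)")
  }
  fac <- as.numeric(fac)
  out <- copy(as.data.table(records))
  denom <- sum(out$count * fac)
  if (denom <= 0) stop("all corrected mass is zero; cannot rescale")
  s <- sum(out$count) / denom
  out[, factor_ := fac]
  out[, corrected_count := count * factor_ * s]
  setnames(out, "factor_", "factor")
  for (a in c("k5", "dropped")) setattr(out, a, attr(records, a))
  class(out) <- c("count_records", class(out))
  out[]
}

#' Correct disome counts with a monosome-trained model
#'
#' Disome footprints share the library-preparation chemistry of their
#' matched monosome library, so correction factors learned from abundant
#' monosome footprints transfer to sparse disome counts. Records must carry
#' the disome featurization of [aggregate_disome_counts()]: `d5`/`f5` from
#' the lagging ribosome's 5' end, `d3`/`f3` from the leading ribosome's 3'
#' end. Disome (d5, d3) cells outside the monosome-observed interaction
#' levels contribute neutrally to the exponent; their number is messaged.
#'
#' @param disome_records disome count table
#' @param monosome_model a `correction_model` fitted on the matched
#'   monosome library
#' @return disome records with `corrected_count` (library size preserved)
#' @export
correct_disome <- function(disome_records, monosome_model) {
  fac <- correction_factor(monosome_model, disome_records)
  unseen <- attr(fac, "n_unseen")
  if (sum(unseen[c("d5f5", "d3f3")]) > 0) {
    message(sprintf(paste0("%d disome 5' and %d disome 3' interaction ",
                           "cells outside monosome-observed levels; ",
                           "neutral contribution used"),
                    unseen[["d5f5"]], unseen[["d3f3"]]))
  }
  apply_correction(disome_records, monosome_model)
}

#' Construct a correction model directly
#'
#' Mostly useful for tests and for restoring serialized models; models are
#' normally built from a fit with [correction_model_from_fit()].
#'
#' @param beta_f5,beta_f3 named log-scale coefficients per bias k-mer
#' @param beta_d5f5,beta_d3f3 named interaction coefficients, keys
#'   `"<d>|<kmer>"`
#' @param beta_gc log-scale GC slope
#' @param gbar mean GC content in `[0, 1]`
#' @return a `correction_model`
#' @export
correction_model <- function(beta_f5, beta_f3, beta_d5f5 = numeric(),
                             beta_d3f3 = numeric(), beta_gc = 0, gbar = 0.5) {
  stopifnot(gbar >= 0, gbar <= 1, length(beta_f5) > 0, length(beta_f3) > 0)
  structure(list(beta_f5 = beta_f5, beta_f3 = beta_f3,
                 beta_d5f5 = beta_d5f5, beta_d3f3 = beta_d3f3,
                 beta_gc = as.numeric(beta_gc), gbar = as.numeric(gbar),
                 k5 = unique(nchar(names(beta_f5)))),
            class = "correction_model")
}

#' Serialize / restore a correction model as JSON
#'
#' @param model a `correction_model`
#' @param path JSON path
#' @return invisibly `path`; [read_correction_model()] returns the model
#' @export
write_correction_model <- function(model, path) {
  jsonlite::write_json(
    list(beta_f5 = as.list(model$beta_f5), beta_f3 = as.list(model$beta_f3),
         beta_d5f5 = as.list(model$beta_d5f5),
         beta_d3f3 = as.list(model$beta_d3f3),
         beta_gc = model$beta_gc, gbar = model$gbar, k5 = model$k5),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  correction_model(unlist(x$beta_f5), unlist(x$beta_f3),
                   unlist(x$beta_d5f5), unlist(x$beta_d3f3),
                   x$beta_gc, x$gbar)
}
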
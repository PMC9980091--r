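#' Scale per-position footprint counts by the transcript mean
#'
#' Sums counts over digestion lengths to one value per (transcript, codon
#' position) across the included codon range (positions with no footprints
#' count as zero), then divides by the per-transcript mean so that scaled
#' counts are comparable across transcripts with different mRNA abundances
#' and initiation rates. Transcripts with zero mean are excluded.
#'
#' @param records featurized count table
#' @param training a `training_spec` giving the transcripts and codon ranges
#' @param value_col which column to scale: `"count"` (default) or
#'   `"corrected_count"`
#' @return `data.table` with `transcript`, `codon_idx`, `s` (scaled count);
#'   per transcript, `mean(s) == 1`
#' @export
scale_counts <- function(records, training, value_col = "count") {
  stopifnot(value_col %in% names(records))
  per_pos <- as.data.table(records)[
    , .(value = sum(.SD[[1]])), by = .(transcript, codon_idx),
    .SDcols = value_col]
  grid <- training$ranges[, .(codon_idx = seq.int(first_idx, last_idx)),
                          by = transcript]
  full <- merge(grid, per_pos, by = c("transcript", "codon_idx"),
                all.x = TRUE)
  full[is.na(value), value := 0]
  full[, s := value / mean(value), by = transcript]
  full <- full[is.finite(s)]
  full[, value := NULL]
  full[]
}

#' Position-importance profile of a 13-codon window
#'
#' Quantifies how much the sequence at each position around the A site
#' predicts local footprint density. Scaled counts are regressed on one-hot
#' sequence features of the window positions -6..+6 (codon units, 0 = A
#' site; at nucleotide granularity the corresponding 39 positions); for
#' each position the model is refit without that position's features, and
#' importance(p) is the drop in Pearson correlation between fitted and
#' observed scaled counts, `r_full - r_without_p`, on the fitting data.
#' Ligation biases appear as importance at the footprint boundary positions
#' (-6/-5 and +3/+4 for canonical monosome digestion); the biological
#' decoding signal appears at the A site.
#'
#' @param scaled output of [scale_counts()]
#' @param transcripts a [transcriptome()]
#' @param training the `training_spec` used for scaling (windows must lie
#'   inside the included codon ranges)
#' @param granularity `"codon"` (13 codon factors) or `"nucleotide"`
#'   (39 per-nucleotide factors)
#' @param min_positions minimum usable positions (default 100)
#' @return `data.table` with `position` (-6..+6) and `importance`; the
#'   `r_full` attribute holds the full-model correlation, `granularity` and
#'   `n` the metadata
#' @export
position_importance <- function(scaled, transcripts, training,
                                granularity = c("codon", "nucleotide"),
                                min_positions = 100L) {
  granularity <- match.arg(granularity)
  win <- -6:6
  dat <- as.data.table(scaled)[training$ranges, on = "transcript",
                               nomatch = NULL]
  dat <- dat[codon_idx + win[1] >= first_idx &
               codon_idx + win[length(win)] <= last_idx]
  if (nrow(dat) < min_positions) {
    stop("only ", nrow(dat), " positions have a full in-range window")
  }
  sq <- transcripts[dat$transcript, on = "transcript"]
  a_start <- sq$utr5 + 3L * dat$codon_idx

  # syntactic, sign-safe feature names: "wm5" = codon -5, "wp3" = codon +3
  wname <- function(w) paste0("w", ifelse(w < 0, "m", "p"), abs(w))
  feats <- list()
  if (granularity == "codon") {
    for (w in win) {
      st <- a_start + 3L * w
      feats[[wname(w)]] <- factor(substr(sq$seq, st + 1L, st + 3L))
    }
  } else {
    for (w in win) {
      for (o in 0:2) {
        st <- a_start + 3L * w + o
        feats[[paste0(wname(w), "_", o)]] <-
          factor(substr(sq$seq, st + 1L, st + 1L))
      }
    }
  }
  df <- as.data.frame(feats)
  form <- stats::as.formula(paste("~", paste(names(df), collapse = " + ")))
  X <- sparse.model.matrix(form, df)
  term_lab <- c("(Intercept)", attr(stats::terms(form), "term.labels"))
  col_term <- term_lab[attr(X, "assign") + 1L]
  y <- dat$s

  XtX <- as.matrix(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, y))
  solve_ls <- function(keep) {
    ch <- tryCatch(chol(XtX[keep, keep, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(ch)) {
      stop("singular feature matrix; collinear columns among: ",
           paste(head(unique(col_term[keep]), 10), collapse = ", "))
    }
    b <- backsolve(ch, forwardsolve(t(ch), Xty[keep]))
    as.numeric(X[, keep, drop = FALSE] %*% b)
  }
  r_of <- function(fitv) {
    if (sd(fitv) == 0) 0 else cor(fitv, y)
  }
  r_full <- r_of(solve_ls(seq_len(ncol(X))))
  imp <- vapply(win, function(w) {
    drop_terms <- if (granularity == "codon") wname(w)
                  else paste0(wname(w), "_", 0:2)
    keep <- which(!col_term %in% drop_terms)
    r_full - r_of(solve_ls(keep))
  }, numeric(1))
  out <- data.table(position = win, importance = imp)
  setattr(out, "r_full", r_full)
  setattr(out, "granularity", granularity)
  setattr(out, "n", nrow(dat))
  out[]
}

#' 5'-end metagene profile around the start codon
#'
#' Histogram of footprint 5' ends relative to the start codon (position 0 =
#' 5' end exactly at the A of the AUG), summed across transcripts and
#' optionally restricted to one read length. Accepts either an alignment
#' table (raw reads, weight-summed) or a featurized count table, in which
#' case each record's (corrected) count is redistributed to the 5' position
#' implied by `codon_idx` and `d5`.
#'
#' @param x alignment table or featurized count table
#' @param transcripts a [transcriptome()]
#' @param read_length optional single read length filter (nt)
#' @param value_col for count tables, the column to sum (`"count"` or
#'   `"corrected_count"`)
#' @return `data.table` with `offset_nt` and `count`
#' @export
metagene_5prime <- function(x, transcripts, read_length = NULL,
                            value_col = "count") {
  x <- as.data.table(x)
  if ("pos" %in% names(x)) {  # alignments
    if (!"weight" %in% names(x)) x[, weight := 1]
    if (!is.null(read_length)) x <- x[len == read_length]
    x[transcripts, on = "transcript", utr5 := i.utr5]
    mg <- x[!is.na(utr5), .(count = sum(weight)),
            by = .(offset_nt = pos - utr5)]
  } else {                    # featurized records
    stopifnot(value_col %in% names(x))
    if (!is.null(read_length)) x <- x[d5 + 3L + d3 == read_length]
    mg <- x[, .(count = sum(.SD[[1]])),
            by = .(offset_nt = 3L * codon_idx - d5), .SDcols = value_col]
  }
  setorder(mg, offset_nt)
  mg[]
}

#' Peak-to-background ratio of a metagene profile
#'
#' Compares the metagene count at one offset to the mean count over
#' background offsets in the same reading frame (the 3-nt periodicity of
#' digestion lengths makes off-frame offsets incomparable).
#'
#' @param mg a [metagene_5prime()] table
#' @param at offset of interest (default 0, the start codon)
#' @param background offsets averaged as local background (default
#'   `seq(3, 30, 3)`, downstream in-frame positions clear of the start-edge
#'   truncation)
#' @return the ratio `count[at] / mean(count[background])`
#' @export
metagene_peak_ratio <- function(mg, at = 0L, background = seq(3L, 30L, 3L)) {
  peak <- mg[offset_nt == at, sum(count)]
  bg <- mg[offset_nt %in% background,
           sum(count) / length(background)]
  if (bg <= 0) stop("background is empty or zero")
  peak / bg
}

#' Codon pause scores
#'
#' Mean scaled footprint count over every occurrence of each codon in the
#' A site within the truncated CDS regions. A score of 1 means the codon
#' carries an average ribosome density; slow codons score above 1.
#'
#' @param records featurized count table
#' @param transcripts a [transcriptome()]
#' @param training a `training_spec`
#' @param value_col column to score (`"count"` or `"corrected_count"`)
#' @return `data.table` with `codon`, `score`, `n_occurrences`; codons with
#'   no in-range occurrence are absent
#' @export
codon_pause_scores <- function(records, transcripts, training,
                               value_col = "count") {
  sc <- scale_counts(records, training, value_col = value_col)
  sq <- transcripts[sc$transcript, on = "transcript"]
  sc[, codon := codon_at(sq$seq, sq$utr5, sc$codon_idx)]
  out <- sc[!is.na(codon) & !grepl("N", codon),
            .(score = mean(s), n_occurrences = .N), by = codon]
  setorder(out, codon)
  out[]
}

#' Mean-variance diagnostic across replicate libraries
#'
#' Computes the per-position sample mean and variance of footprint counts
#' across replicate libraries and compares three mean-variance laws by
#' least squares on the (mean, variance) pairs: Poisson (`var = mu`),
#' quasi-Poisson (`var = theta * mu`) and negative binomial
#' (`var = mu + mu^2 / phi`). Overdispersed ribosome profiling counts are
#' expected to favor the quadratic NB law.
#'
#' @param replicates list of >= 3 count tables over the same transcriptome
#'   (replicate libraries); counts are summed per (transcript, codon_idx)
#' @return list with `table` (`data.table` of per-position `mean` and
#'   `variance`), `phi` (NB dispersion estimate), `theta` (quasi-Poisson
#'   scale) and `rss` (named vector of residual sums of squares)
#' @export
mean_variance_diagnostic <- function(replicates) {
  if (length(replicates) < 3L) stop("need at least 3 replicate libraries")
  per <- lapply(seq_along(replicates), function(i) {
    as.data.table(replicates[[i]])[, .(value = sum(count)),
                                   by = .(transcript, codon_idx)][
                                     , rep := i][]
  })
  long <- rbindlist(per)
  wide <- data.table::dcast(long, transcript + codon_idx ~ rep,
                            value.var = "value", fill = 0)
  m <- as.matrix(wide[, -(1:2)])
  tab <- data.table(transcript = wide$transcript,
                    codon_idx = wide$codon_idx,
                    mean = rowMeans(m),
                    variance = apply(m, 1, var))
  mu <- tab$mean
  v <- tab$variance
  theta <- sum(mu * v) / sum(mu^2)
  alpha <- sum(mu^2 * (v - mu)) / sum(mu^4)  # LS slope of (v - mu) on mu^2
  alpha <- max(alpha, 1e-8)
  rss <- c(poisson = sum((v - mu)^2),
           quasipoisson = sum((v - theta * mu)^2),
           nb = sum((v - mu - alpha * mu^2)^2))
  list(table = tab, phi = 1 / alpha, theta = theta, rss = rss)
}
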
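#' Simulation configuration for synthetic ribosome profiling libraries
#'
#' Bundles every parameter of the generative model: per-transcript sampling
#' probabilities, per-codon dwell weights (A-site), digestion-length
#' distributions at both footprint ends, and Bernoulli recovery probabilities
#' for the terminal k-mers (the ligation bias). Footprints are drawn by
#' multinomial sampling of a transcript, then of an A-site codon position with
#' probability proportional to the dwell weight of the codon at that position,
#' then of 5' and 3' digestion lengths; the footprint is retained with
#' probability `recovery5[f5] * recovery3[f3]` where f5/f3 are its terminal
#' k-mers.
#'
#' @param transcript_probs named numeric, probabilities summing to 1
#' @param codon_weights named positive numeric over the 61 sense codons
#' @param d5_probs,d3_probs named numeric (names are digestion lengths in nt),
#'   each summing to 1
#' @param recovery5 named numeric in `[0,1]` over all 5' k-mers (k = 2 or 3)
#' @param recovery3 named numeric in `[0,1]` over all 3-mers
#' @param library_size number of retained footprints to generate
#' @param seed integer seed making the library reproducible
#' @return a `simulation_config` object
#' @export
simulation_config <- function(transcript_probs, codon_weights, d5_probs,
                              d3_probs, recovery5, recovery3,
                              library_size, seed = 1L) {
  cfg <- structure(
    list(transcript_probs = transcript_probs, codon_weights = codon_weights,
         d5_probs = d5_probs, d3_probs = d3_probs,
         recovery5 = recovery5, recovery3 = recovery3,
         library_size = as.integer(library_size), seed = as.integer(seed),
         k5 = unique(nchar(names(recovery5)))),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  chk_prob <- function(p, what) {
    if (is.null(names(p)) || any(names(p) == "")) {
      stop(what, " must be a fully named vector")
    }
    if (abs(sum(p) - 1) > 1e-12) stop(what, " must sum to 1 (within 1e-12)")
    if (any(p < 0)) stop(what, " must be non-negative")
  }
  chk_prob(cfg$transcript_probs, "transcript_probs")
  chk_prob(cfg$d5_probs, "d5_probs")
  chk_prob(cfg$d3_probs, "d3_probs")
  if (any(cfg$codon_weights <= 0)) stop("codon_weights must be positive")
  if (!setequal(names(cfg$codon_weights), sense_codons())) {
    stop("codon_weights must cover exactly the 61 sense codons")
  }
  if (length(cfg$k5) != 1L || !cfg$k5 %in% c(2L, 3L)) {
    stop("recovery5 must be keyed by k-mers of one length, k = 2 or 3")
  }
  if (!setequal(names(cfg$recovery5), all_kmers(cfg$k5))) {
    stop("recovery5 must cover all 4^k 5' k-mers")
  }
  if (!setequal(names(cfg$recovery3), all_kmers(3L))) {
    stop("recovery3 must cover all 64 3-mers")
  }
  if (any(cfg$recovery5 < 0 | cfg$recovery5 > 1) ||
      any(cfg$recovery3 < 0 | cfg$recovery3 > 1)) {
    stop("recovery probabilities must lie in [0, 1]")
  }
  if (cfg$library_size < 1L) stop("library_size must be >= 1")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_config: %d transcripts, library size %d, seed %d\n",
    "  codon dwell range %.2f-%.2f; d5 in {%s}, d3 in {%s}\n",
    "  recovery5 (k=%d) range %.2f-%.2f; recovery3 range %.2f-%.2f\n"),
    length(x$transcript_probs), x$library_size, x$seed,
    min(x$codon_weights), max(x$codon_weights),
    paste(names(x$d5_probs), collapse = ","),
    paste(names(x$d3_probs), collapse = ","),
    x$k5, min(x$recovery5), max(x$recovery5),
    min(x$recovery3), max(x$recovery3)))
  invisible(x)
}

#' Default simulation configuration for the four bias scenarios
#'
#' Builds a [simulation_config()] emulating a typical yeast monosome library:
#' transcript abundances decline log-linearly with transcript length and carry
#' Poisson sampling noise; codon dwell weights are log-normal, rescaled to an
#' 8-fold dynamic range; digestion lengths concentrate at d5 = 15 and d3 = 10
#' with +/-2 nt of spread. The `bias_mode` argument selects which footprint
#' ends carry sequence-dependent recovery: `"none"` sets every recovery
#' probability to 1, `"bias5"`/`"bias3"` vary only the named end, and
#' `"both"` varies both (recovery uniform on `[0.2, 1]` per k-mer).
#'
#' @param transcripts a [transcriptome()] (supplies ids and lengths)
#' @param bias_mode one of `"none"`, `"bias3"`, `"bias5"`, `"both"`
#' @param library_size retained footprints to generate (default 5e5)
#' @param k5 5' bias k-mer length, 2 or 3 (default 3, matching the default
#'   featurization)
#' @param seed integer seed (used both to build the config and, by default,
#'   to draw the library)
#' @return a [simulation_config()]
#' @export
make_default_config <- function(transcripts, bias_mode = c("none", "bias3",
                                                           "bias5", "both"),
                                library_size = 5e5, k5 = 3L, seed = 1L) {
  bias_mode <- match.arg(bias_mode)
  stopifnot(inherits(transcripts, "transcriptome"))
  set.seed(as.integer(seed))

  # abundance ~ exp(-length/1kb) with Poisson noise, never exactly zero
  lens <- nchar(transcripts$seq)
  lam <- 1000 * exp(-lens / 1000)
  counts <- rpois(length(lam), lam) + 1
  tp <- setNames(counts / sum(counts), transcripts$transcript)

  # log-normal dwell weights rescaled to exactly 8-fold range, geo-mean 1
  w <- exp(rnorm(61, 0, 0.5))
  w <- exp((log(w) - min(log(w))) / (max(log(w)) - min(log(w))) * log(8))
  w <- w / exp(mean(log(w)))
  cw <- setNames(w, sense_codons())

  # ragged 5' end (+/-2 nt), tighter 3' end (+/-1 nt): the 5' bias 3-mer
  # then reaches from codon -4 into codon -6 and the 3' one spans +3/+4,
  # while (length, frame) still identifies d5 uniquely for offset rules
  d5p <- setNames(c(0.1, 0.2, 0.4, 0.2, 0.1), 13:17)
  d3p <- c(`9` = 0.2, `10` = 0.6, `11` = 0.2)

  k5mers <- all_kmers(as.integer(k5))
  mers3 <- all_kmers(3L)
  r5 <- setNames(rep(1, length(k5mers)), k5mers)
  r3 <- setNames(rep(1, 64L), mers3)
  if (bias_mode %in% c("bias5", "both")) {
    r5[] <- runif(length(r5), 0.2, 1)
  }
  if (bias_mode %in% c("bias3", "both")) {
    r3[] <- runif(64L, 0.2, 1)
  }
  simulation_config(tp, cw, d5p, d3p, r5, r3, library_size, seed)
}

#' Simulate a ribosome profiling library
#'
#' Draws footprints under the generative model of [simulation_config()] until
#' exactly `cfg$library_size` footprints have been retained, and returns both
#' the retained reads and a ground-truth table of pre-retention and retained
#' counts per (transcript, codon index, d5, d3) cell. Footprints whose sampled
#' extent would overrun the transcript ends are resampled (they appear in
#' neither table; their number is reported in the `diagnostics` attribute),
#' which keeps sampling over interior positions unbiased. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()]
#' @param transcripts a [transcriptome()] containing every id in
#'   `cfg$transcript_probs`
#' @param attempt_cap maximum number of footprint draws before giving up
#'   (guards against configurations whose recovery probabilities are all ~0)
#' @return a list with elements
#'   \describe{
#'     \item{reads}{`data.table` of retained footprints: `read_id`,
#'       `transcript`, `codon_idx`, `d5`, `d3`, `pos` (0-based 5' end),
#'       `len`, `seq`}
#'     \item{truth}{`data.table` keyed by (`transcript`, `codon_idx`, `d5`,
#'       `d3`) with `pre_count` (draws before the Bernoulli retention step)
#'       and `retained_count`; `sum(retained_count) == library_size` and the
#'       `diagnostics` attribute counts resampled out-of-bounds draws}
#'   }
#' @export
simulate_library <- function(cfg, transcripts, attempt_cap = NULL) {
  validate_simulation_config(cfg)
  stopifnot(inherits(transcripts, "transcriptome"))
  ids <- names(cfg$transcript_probs)
  missing <- setdiff(ids, transcripts$transcript)
  if (length(missing)) {
    stop("transcript_probs names absent from transcriptome: ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (is.null(attempt_cap)) attempt_cap <- max(1e6, 400 * cfg$library_size)
  tx <- transcripts[ids, on = "transcript"]
  set.seed(cfg$seed)

  # per-transcript position sampling weights: dwell weight of the codon at
  # each CDS position (codons containing N get weight 0)
  pos_w <- lapply(seq_len(nrow(tx)), function(i) {
    cods <- codon_at(rep(tx$seq[i], tx$n_codons[i]), tx$utr5[i],
                     seq_len(tx$n_codons[i]) - 1L)
    w <- cfg$codon_weights[cods]
    w[is.na(w)] <- 0
    w
  })
  d5v <- as.integer(names(cfg$d5_probs))
  d3v <- as.integer(names(cfg$d3_probs))

  target <- cfg$library_size
  batches <- list()
  n_ret <- 0L
  n_drawn <- 0L
  n_oob <- 0L
  # expected retention under roughly uniform k-mer usage; refined as we go
  est_rate <- max(mean(cfg$recovery5) * mean(cfg$recovery3), 1e-4)
  while (n_ret < target) {
    b <- ceiling(min((target - n_ret) / est_rate * 1.2 + 100, 2e6))
    if (n_drawn + b > attempt_cap) {
      b <- attempt_cap - n_drawn
      if (b <= 0) {
        stop(sprintf(paste0("attempt cap (%d draws) reached with only %d/%d",
                            " footprints retained; recovery probabilities",
                            " may be too small"),
                     attempt_cap, n_ret, target))
      }
    }
    ti <- sample.int(nrow(tx), b, replace = TRUE, prob = cfg$transcript_probs)
    j <- integer(b)
    for (i in unique(ti)) {
      sel <- which(ti == i)
      j[sel] <- sample.int(tx$n_codons[i], length(sel), replace = TRUE,
                           prob = pos_w[[i]]) - 1L
    }
    d5 <- d5v[sample.int(length(d5v), b, replace = TRUE, prob = cfg$d5_probs)]
    d3 <- d3v[sample.int(length(d3v), b, replace = TRUE, prob = cfg$d3_probs)]
    utr5 <- tx$utr5[ti]
    start <- utr5 + 3L * j - d5
    end <- utr5 + 3L * j + 3L + d3
    ok <- start >= 0L & end <= nchar(tx$seq)[ti]
    n_oob <- n_oob + sum(!ok)
    bt <- data.table(ti = ti[ok], codon_idx = j[ok], d5 = d5[ok], d3 = d3[ok],
                     pos = start[ok])
    sq <- tx$seq[bt$ti]
    f5 <- substr(sq, bt$pos + 1L, bt$pos + cfg$k5)
    endp <- bt$pos + bt$d5 + 3L + bt$d3
    f3 <- substr(sq, endp - 2L, endp)
    pr <- unname(cfg$recovery5[f5] * cfg$recovery3[f3])
    pr[is.na(pr)] <- 0  # N-containing end k-mers are never recovered
    bt[, retained := runif(.N) < pr]
    cum <- cumsum(bt$retained)
    if (n_ret + cum[length(cum)] >= target) {
      cut <- which(cum == target - n_ret)[1]
      bt <- bt[seq_len(cut)]
    }
    n_ret <- n_ret + sum(bt$retained)
    n_drawn <- n_drawn + b
    batches[[length(batches) + 1L]] <- bt
    # sharpen the retention-rate estimate for the next batch
    est_rate <- max(n_ret / n_drawn, 1e-4)
  }
  all <- rbindlist(batches)
  all[, transcript := tx$transcript[ti]]

  truth <- all[, .(pre_count = .N, retained_count = sum(retained)),
               by = .(transcript, codon_idx, d5, d3)]
  setkey(truth, transcript, codon_idx, d5, d3)
  setattr(truth, "diagnostics",
          list(n_draws = n_drawn, n_out_of_bounds = n_oob,
               retention_rate = n_ret / max(sum(truth$pre_count), 1L)))

  reads <- all[retained == TRUE,
               .(transcript, codon_idx, d5, d3, pos, ti)]
  reads[, len := d5 + 3L + d3]
  reads[, seq := substr(tx$seq[ti], pos + 1L, pos + len)]
  reads[, ti := NULL]
  reads[, read_id := sprintf("fp%07d|%s|%d|%d|%d", .I, transcript,
                             codon_idx, d5, d3)]
  setcolorder(reads, c("read_id", "transcript", "codon_idx", "d5", "d3",
                       "pos", "len", "seq"))
  list(reads = reads[], truth = truth[])
}

#' Write simulated footprints to FASTQ
#'
#' Standard 4-line records with a constant quality string ("I" = Q40). Read
#' names encode `transcript|codon_idx|d5|d3` after the read serial so that
#' each read can be traced back to its ground-truth cell with
#' [parse_read_ids()].
#'
#' @param reads the `reads` table from [simulate_library()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_fastq <- function(reads, path) {
  stopifnot(nrow(reads) > 0)
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep("I", nchar(reads$seq))
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Offset rules implied by a simulation configuration
#'
#' The ground-truth A-site offset for each (read length, frame) class
#' follows from the digestion-length support of the configuration: a read of
#' length `d5 + 3 + d3` with 5' frame `(-d5) mod 3` has offset `d5`. The
#' support must identify `d5` uniquely per class (it does whenever the d5
#' span is below 6 nt, one full codon on each side).
#'
#' @param cfg a [simulation_config()]
#' @return a start-anchored [offset_rules()] table
#' @export
true_offset_rules <- function(cfg) {
  grid <- CJ(d5 = as.integer(names(cfg$d5_probs)),
             d3 = as.integer(names(cfg$d3_probs)))
  grid[, len := d5 + 3L + d3]
  grid[, frame := ((-d5) %% 3L + 3L) %% 3L]
  cls <- unique(grid[, .(len, frame, offset = d5)])
  if (anyDuplicated(cls, by = c("len", "frame"))) {
    stop("digestion-length support does not identify d5 per (length, frame)")
  }
  offset_rules(cls$len, cls$frame, cls$offset, "start")
}

#' Parse simulated read names back into ground-truth keys
#'
#' @param ids character vector of read names as written by [write_fastq()]
#' @return `data.table` with `read_id`, `transcript`, `codon_idx`, `d5`, `d3`
#' @export
parse_read_ids <- function(ids) {
  parts <- data.table::tstrsplit(ids, "|", fixed = TRUE)
  if (length(parts) != 5L) stop("read ids are not in simulator format")
  data.table(read_id = ids, transcript = parts[[2]],
             codon_idx = as.integer(parts[[3]]), d5 = as.integer(parts[[4]]),
             d3 = as.integer(parts[[5]]))
}

#' Read a FASTQ file of footprints
#'
#' @param path FASTQ path
#' @return `data.table` with `read_id` and `seq`
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = sub("\\s.*$", "", names(seqs)),
             seq = as.character(seqs))
}
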
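#' Featurize assigned footprints and aggregate into a count table
#'
#' Aggregates alignment weights by (transcript, A-site codon index, d5, d3)
#' and attaches the covariates of the bias regression, all drawn from the
#' transcript sequence (never the read, avoiding sequencing errors):
#' \describe{
#'   \item{d5, d3}{digestion lengths; `d5` is the A-site offset and
#'     `d3 = read length - d5 - 3`}
#'   \item{f5, f3}{bias sequences: the first `k5` and last 3 transcript
#'     nucleotides under the footprint}
#'   \item{cod_a, cod_p, cod_e}{codons in the A, P (A-1) and E (A-2) sites}
#'   \item{gc}{GC fraction of the footprint excluding the 9 nt of the
#'     E/P/A codons}
#'   \item{count}{summed alignment weight (fractional weights allowed)}
#' }
#'
#' @param aln alignment table (see [alignments])
#' @param transcripts a [transcriptome()]
#' @param rules start-anchored [offset_rules()] used for A-site assignment
#' @param k5 5' bias k-mer length (2 or 3; default 3)
#' @return a `count_records` `data.table` keyed by
#'   (`transcript`, `codon_idx`, `d5`, `d3`); dropped-alignment tallies are
#'   in the `dropped` attribute and the k-mer length in the `k5` attribute
#' @export
aggregate_counts <- function(aln, transcripts, rules = default_offset_rules(),
                             k5 = 3L) {
  if (!"weight" %in% names(aln)) aln <- copy(as.data.table(aln))[, weight := 1]
  if (any(aln$weight < 0)) stop("negative alignment weights are not allowed")
  asg <- assign_a_site(aln, transcripts, rules)
  dropped <- asg[status != "ok", .(w = sum(weight)), by = status]
  asg <- asg[status == "ok"]
  rec <- asg[, .(count = sum(weight)),
             by = .(transcript, codon_idx, d5 = offset, d3 = len - offset - 3L)]
  count_records(rec, transcripts, k5 = k5,
                dropped = setNames(dropped$w, dropped$status))
}

# Attach sequence-derived covariates to (transcript, codon_idx, d5, d3) keys
# and stamp the count_records class.
count_records <- function(rec, transcripts, k5 = 3L,
                          dropped = c(none = 0)) {
  stopifnot(k5 %in% c(2L, 3L))
  rec <- copy(as.data.table(rec))
  rec[transcripts, on = "transcript", utr5 := i.utr5]
  if (anyNA(rec$utr5)) stop("records reference unknown transcripts")
  sq <- transcripts[rec$transcript, on = "transcript"]$seq
  a_start <- rec$utr5 + 3L * rec$codon_idx
  fp_start <- a_start - rec$d5
  fp_end <- a_start + 3L + rec$d3
  if (any(fp_start < 0L | fp_end > nchar(sq))) {
    stop("footprint interval out of transcript bounds for some records")
  }
  rec[, f5 := substr(sq, fp_start + 1L, fp_start + k5)]
  rec[, f3 := substr(sq, fp_end - 2L, fp_end)]
  rec[, cod_a := substr(sq, a_start + 1L, a_start + 3L)]
  rec[, cod_p := codon_at(sq, rec$utr5, rec$codon_idx - 1L)]
  rec[, cod_e := codon_at(sq, rec$utr5, rec$codon_idx - 2L)]
  # GC over footprint nucleotides outside the E/P/A codons; the exclusion
  # window [A start - 6, A end) is clipped to the footprint extent
  fp <- substr(sq, fp_start + 1L, fp_end)
  ex_lo <- pmax(a_start - 6L, fp_start)
  ex_hi <- pmin(a_start + 3L, fp_end)
  epa <- substr(sq, ex_lo + 1L, ex_hi)
  n_all <- nchar(fp)
  n_epa <- pmax(ex_hi - ex_lo, 0L)
  gc_all <- n_all - nchar(gsub("[GC]", "", fp))
  gc_epa <- n_epa - nchar(gsub("[GC]", "", epa))
  rec[, gc := (gc_all - gc_epa) / pmax(n_all - n_epa, 1L)]
  rec[, utr5 := NULL]
  setcolorder(rec, c("transcript", "codon_idx", "d5", "d3", "f5", "f3",
                     "cod_a", "cod_p", "cod_e", "gc", "count"))
  setkey(rec, transcript, codon_idx, d5, d3)
  setattr(rec, "k5", as.integer(k5))
  setattr(rec, "dropped", dropped)
  class(rec) <- c("count_records", class(rec))
  rec[]
}

#' Select transcripts and codon ranges for model training
#'
#' Transcripts are filtered to those with at least `min_mean` mean footprint
#' counts per codon position (total count / CDS codons) and at least
#' `min_positions` codon positions carrying footprints; survivors are ranked
#' by mean footprint abundance per codon position, the top `n_top` form the
#' candidate pool, and `n_select` of them are sampled uniformly without
#' replacement (seeded). Within each selected transcript the first and last
#' `end_trim` codons are excluded to avoid initiation and termination
#' effects.
#'
#' @param records a count table from [aggregate_counts()]
#' @param transcripts a [transcriptome()]
#' @param n_top size of the high-coverage candidate pool (default 500)
#' @param n_select transcripts sampled from the pool (default 250)
#' @param min_mean minimum mean footprint count per codon position (default 5)
#' @param min_positions minimum codon positions with footprints (default 100)
#' @param end_trim codons trimmed at each CDS end (default 20)
#' @param seed seed for the uniform subsample
#' @return a `training_spec`: list with `transcripts` (selected ids),
#'   `ranges` (`data.table` of included codon index ranges, inclusive) and
#'   the filter parameters
#' @export
select_training_set <- function(records, transcripts, n_top = 500L,
                                n_select = 250L, min_mean = 5,
                                min_positions = 100L, end_trim = 20L,
                                seed = 1L) {
  cov <- records[, .(total = sum(count),
                     n_pos = data.table::uniqueN(codon_idx[count > 0])),
                 by = transcript]
  cov[transcripts, on = "transcript", n_codons := i.n_codons]
  cov[, mean_count := total / n_codons]
  pass <- cov[mean_count >= min_mean & n_pos >= min_positions &
                n_codons >= 2L * end_trim + 1L]
  if (nrow(pass) == 0L) {
    stop(sprintf(paste0("no transcript passes the training filters ",
                        "(best: mean %.2f counts/codon, %d covered ",
                        "positions)"),
                 if (nrow(cov)) max(cov$mean_count) else 0,
                 if (nrow(cov)) max(cov$n_pos) else 0L))
  }
  setorder(pass, -mean_count, transcript)
  pool <- head(pass, n_top)
  set.seed(as.integer(seed))
  sel <- pool[sort(sample.int(nrow(pool), min(n_select, nrow(pool))))]
  ranges <- sel[, .(transcript, first_idx = end_trim,
                    last_idx = n_codons - end_trim - 1L)]
  setkey(ranges, transcript)
  structure(list(transcripts = ranges$transcript, ranges = ranges,
                 n_top = n_top, n_select = n_select, min_mean = min_mean,
                 min_positions = min_positions, end_trim = end_trim,
                 seed = seed),
            class = "training_spec")
}

#' @export
print.training_spec <- function(x, ...) {
  cat(sprintf(paste0("training_spec: %d transcripts (top %d by coverage, ",
                     "%d sampled), %d codons trimmed per end\n"),
              length(x$transcripts), x$n_top, x$n_select, x$end_trim))
  invisible(x)
}

#' Restrict a count table to a training specification
#'
#' @param records count table
#' @param training a `training_spec` from [select_training_set()]
#' @return the records of selected transcripts whose codon index lies in the
#'   included range
#' @export
filter_to_training <- function(records, training) {
  out <- as.data.table(records)[training$ranges, on = "transcript",
                                nomatch = NULL][
    codon_idx >= first_idx & codon_idx <= last_idx]
  out[, c("first_idx", "last_idx") := NULL]
  setkey(out, transcript, codon_idx, d5, d3)
  setattr(out, "k5", attr(records, "k5"))
  class(out) <- c("count_records", class(out))
  out[]
}

#' Materialize zero-count cells for regression
#'
#' The bias regression needs unobserved cells: without zeros, preference for
#' particular end sequences is unidentifiable. The full cross-product of all
#' covariates is intractable, so zeros are materialized only for (d5, d3)
#' combinations observed anywhere in the dataset, crossed with every codon
#' position inside the training ranges of the selected transcripts.
#'
#' @param records count table from [aggregate_counts()]
#' @param transcripts a [transcriptome()]
#' @param training a `training_spec`; the output is restricted to its
#'   transcripts and codon ranges
#' @return a count table over the full (selected transcript, included codon,
#'   observed (d5, d3)) grid, zero-filled where no footprints were observed
#' @export
materialize_zero_cells <- function(records, transcripts, training) {
  combos <- unique(records[, .(d5, d3)])
  grid <- CJ_records(training$ranges, combos)
  obs <- records[, .(transcript, codon_idx, d5, d3, count)]
  full <- merge(grid, obs, by = c("transcript", "codon_idx", "d5", "d3"),
                all.x = TRUE)
  full[is.na(count), count := 0]
  count_records(full, transcripts, k5 = attr(records, "k5"))
}

# cross join: per-transcript codon ranges x (d5, d3) combos
CJ_records <- function(ranges, combos) {
  per_tx <- ranges[, .(codon_idx = seq.int(first_idx, last_idx)),
                   by = transcript]
  per_tx[, combos[, .(d5, d3)], by = .(transcript, codon_idx)]
}

#' Aggregate disome footprints into a count table
#'
#' As [aggregate_counts()], but for disome footprints: the key carries both
#' the lagging (`codon_idx`) and leading (`j_lead`) A-site codon indices,
#' `f5`/`d5` describe the 5' end relative to the lagging ribosome and
#' `f3`/`d3` the 3' end relative to the leading one, and the GC covariate
#' excludes the E/P/A codons of both ribosomes.
#'
#' @param aln disome alignment table
#' @param transcripts a [transcriptome()]
#' @param rules5 start-anchored [offset_rules()] (lagging ribosome)
#' @param rules3 stop-anchored [offset_rules()] (leading ribosome)
#' @param k5 5' bias k-mer length
#' @return a `count_records` table with an extra `j_lead` column; `cod_a`,
#'   `cod_p`, `cod_e` refer to the leading ribosome
#' @export
aggregate_disome_counts <- function(aln, transcripts, rules5, rules3,
                                    k5 = 3L) {
  if (!"weight" %in% names(aln)) aln <- copy(as.data.table(aln))[, weight := 1]
  asg <- assign_disome_sites(aln, transcripts, rules5, rules3)
  dropped <- asg[status != "ok", .(w = sum(weight)), by = status]
  asg <- asg[status == "ok"]
  rec <- asg[, .(count = sum(weight)),
             by = .(transcript, codon_idx, j_lead, d5, d3)]
  rec[transcripts, on = "transcript", utr5 := i.utr5]
  sq <- transcripts[rec$transcript, on = "transcript"]$seq
  lag_start <- rec$utr5 + 3L * rec$codon_idx
  lead_start <- rec$utr5 + 3L * rec$j_lead
  fp_start <- lag_start - rec$d5
  fp_end <- lead_start + 3L + rec$d3
  rec[, f5 := substr(sq, fp_start + 1L, fp_start + k5)]
  rec[, f3 := substr(sq, fp_end - 2L, fp_end)]
  rec[, cod_a := substr(sq, lead_start + 1L, lead_start + 3L)]
  rec[, cod_p := codon_at(sq, rec$utr5, rec$j_lead - 1L)]
  rec[, cod_e := codon_at(sq, rec$utr5, rec$j_lead - 2L)]
  # GC excludes the E/P/A codons of both the lagging and leading ribosome
  fp <- substr(sq, fp_start + 1L, fp_end)
  gc_all <- nchar(fp) - nchar(gsub("[GC]", "", fp))
  n_ex <- 0L
  gc_ex <- 0L
  for (st in list(lag_start, lead_start)) {
    lo <- pmax(st - 6L, fp_start)
    hi <- pmin(st + 3L, fp_end)
    ex <- substr(sq, lo + 1L, hi)
    n_ex <- n_ex + pmax(hi - lo, 0L)
    gc_ex <- gc_ex + (pmax(hi - lo, 0L) - nchar(gsub("[GC]", "", ex)))
  }
  rec[, gc := (gc_all - gc_ex) / pmax(nchar(fp) - n_ex, 1L)]
  rec[, utr5 := NULL]
  setkey(rec, transcript, codon_idx, j_lead, d5, d3)
  setattr(rec, "k5", as.integer(k5))
  setattr(rec, "dropped", setNames(dropped$w, dropped$status))
  class(rec) <- c("count_records", class(rec))
  rec[]
}

#' Write / read a count table as TSV
#'
#' @param records count table
#' @param path TSV path
#' @return invisibly `path` (write) or the count table (read)
#' @export
write_counts <- function(records, path) {
  out <- copy(as.data.table(records))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts
#' @param transcripts a [transcriptome()] (re-derives sequence covariates)
#' @param k5 5' bias k-mer length used when the table was built
#' @export
read_counts <- function(path, transcripts, k5 = 3L) {
  rec <- fread(path)
  need <- c("transcript", "codon_idx", "d5", "d3", "count")
  if (!all(need %in% names(rec))) {
    stop("count TSV must have columns: ", paste(need, collapse = ", "))
  }
  count_records(rec[, need, with = FALSE], transcripts, k5 = k5)
}
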
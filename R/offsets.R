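#' A-site offset rule tables
#'
#' An offset rule table maps a footprint class -- (read length, frame of the
#' anchored end) -- to the distance between that end and the A-site codon.
#' For 5'-anchored ("start") tables the offset is the number of nucleotides
#' from the read 5' end to the first nucleotide of the A-site codon (i.e. the
#' 5' digestion length d5); the frame is `(5' position - utr5_len) mod 3`.
#' For 3'-anchored ("stop") tables, used for the leading ribosome of disome
#' footprints, the offset is the distance from the A-site codon end to the
#' read 3' end (the 3' digestion length d3) and the frame is that of the 3'
#' end. Offsets must place the A-site codon in CDS frame:
#' `(frame + offset) mod 3 == 0` for start-anchored tables,
#' `offset mod 3 == frame` for stop-anchored ones.
#'
#' @param length,frame,offset equal-length integer vectors defining the rules
#' @param anchor `"start"` (5'-anchored) or `"stop"` (3'-anchored)
#' @return an `offset_rules` object (keyed `data.table` with columns
#'   `len`, `frame`, `offset`)
#' @export
offset_rules <- function(length, frame, offset, anchor = c("start", "stop")) {
  anchor <- match.arg(anchor)
  tbl <- data.table(len = as.integer(length), frame = as.integer(frame),
                    offset = as.integer(offset))
  if (any(tbl$frame < 0L | tbl$frame > 2L)) stop("frame must be in {0,1,2}")
  if (any(tbl$offset < 0L | tbl$offset > tbl$len - 3L, na.rm = TRUE)) {
    stop("offset must satisfy 0 <= offset <= length - 3")
  }
  ok <- if (anchor == "start") (tbl$frame + tbl$offset) %% 3L == 0L
        else tbl$offset %% 3L == tbl$frame
  if (any(!ok, na.rm = TRUE)) {
    stop("offset inconsistent with frame for class(es): ",
         paste(sprintf("(%d,%d)", tbl$len[!ok], tbl$frame[!ok]), collapse = " "))
  }
  if (anyDuplicated(tbl, by = c("len", "frame"))) {
    stop("duplicate (length, frame) classes")
  }
  setkey(tbl, len, frame)
  setattr(tbl, "anchor", anchor)
  class(tbl) <- c("offset_rules", class(tbl))
  tbl[]
}

#' Canonical default offset rules
#'
#' The canonical 28-nt, frame-0 footprint gets offset 15 (A-site codon in
#' read nucleotides 16-18). Other classes take the candidate offset in
#' `{12..18}` that satisfies the frame constraint and lies nearest 15,
#' consistent with modest over-/under-digestion: frame 0 -> 15, frame 1 ->
#' 14, frame 2 -> 16, independent of length.
#'
#' @param lengths read lengths to cover
#' @return an [offset_rules()] table (start-anchored)
#' @export
default_offset_rules <- function(lengths = 24:34) {
  grid <- CJ(len = as.integer(lengths), frame = 0:2)
  off <- c(`0` = 15L, `1` = 14L, `2` = 16L)
  offset_rules(grid$len, grid$frame, off[as.character(grid$frame)], "start")
}

#' Infer A-site offset rules from a start (or stop) codon metagene
#'
#' For each (read length, frame) class with at least `min_reads` alignments,
#' candidate offsets are the values in `candidates` compatible with the frame
#' constraint (see [offset_rules()]); the chosen offset maximizes the
#' metagene signal at the start codon -- the number of reads whose implied
#' A site falls on the first or second CDS codon (for `anchor = "stop"`, on
#' the last or second-to-last). Ties are broken toward the canonical offset
#' (15 for start-anchored, 10 for stop-anchored). Classes with insufficient
#' reads are omitted from the table.
#'
#' The default candidate set `{12..18}` spans one codon of over- and
#' under-digestion around the canonical 28-nt/frame-0 offset of 15.
#'
#' @param aln alignment table (see [alignments])
#' @param transcripts a [transcriptome()]
#' @param candidates integer vector of candidate offsets
#' @param anchor `"start"` or `"stop"`
#' @param min_reads minimum alignments per (length, frame) class
#' @return an [offset_rules()] table; the `metagene` attribute holds the
#'   per-class candidate signals for diagnostics
#' @export
infer_offset_rules <- function(aln, transcripts,
                               candidates = if (anchor == "start") 12:18 else 7:13,
                               anchor = c("start", "stop"), min_reads = 50L) {
  anchor <- match.arg(anchor)
  canonical <- if (anchor == "start") 15L else 10L
  a <- aln[transcripts, on = "transcript", nomatch = NULL,
           .(qname, transcript, pos, len, weight, utr5 = i.utr5, cds = i.cds)]
  if (anchor == "start") {
    a[, rel := pos - utr5]
  } else {
    a[, rel := pos + len - (utr5 + cds)]
  }
  a[, frame := ((rel %% 3L) + 3L) %% 3L]
  classes <- a[, .(n = sum(weight)), by = .(len, frame)][n >= min_reads]
  if (nrow(classes) == 0L) {
    stop("no (length, frame) class reaches min_reads = ", min_reads,
         "; total alignments: ", nrow(aln))
  }
  diag <- list()
  picks <- vector("list", nrow(classes))
  for (k in seq_len(nrow(classes))) {
    l <- classes$len[k]
    f <- classes$frame[k]
    cand <- candidates[if (anchor == "start") (f + candidates) %% 3L == 0L
                       else candidates %% 3L == f]
    cand <- cand[cand <= l - 3L & cand >= 0L]
    if (length(cand) == 0L) next
    sub <- a[len == l & frame == f]
    sig <- vapply(cand, function(o) {
      hit <- if (anchor == "start") sub$rel %in% c(-o, 3L - o)
             else sub$rel %in% c(o, o - 3L)
      sum(sub$weight[hit])
    }, numeric(1))
    best <- sig == max(sig)
    pick <- cand[best][which.min(abs(cand[best] - canonical))]
    diag[[sprintf("%d_%d", l, f)]] <- data.table(offset = cand, signal = sig)
    picks[[k]] <- data.table(len = l, frame = f, offset = pick)
  }
  picks <- rbindlist(picks)
  if (nrow(picks) == 0L) {
    stop("no (length, frame) class admits a candidate offset")
  }
  out <- offset_rules(picks$len, picks$frame, picks$offset, anchor)
  setattr(out, "metagene", diag)
  out
}

#' Assign each alignment an A-site codon index
#'
#' Looks up the offset for the alignment's (length, frame) class and places
#' the A site at codon index `(pos - utr5_len + offset) / 3`. Alignments in
#' classes without a rule, shorter than `offset + 3`, or whose A site falls
#' outside the CDS are dropped; drops are categorized, not errors.
#'
#' @param aln alignment table (see [alignments])
#' @param transcripts a [transcriptome()]
#' @param rules a start-anchored [offset_rules()] table
#' @return `data.table`: the alignments plus `codon_idx`, `offset` and
#'   `status` (`"ok"`, `"no_offset_rule"`, `"too_short"`, `"outside_cds"`,
#'   `"unknown_transcript"`)
#' @export
assign_a_site <- function(aln, transcripts, rules = default_offset_rules()) {
  stopifnot(attr(rules, "anchor") == "start")
  out <- copy(as.data.table(aln))
  out[, status := "ok"]
  out[transcripts, on = "transcript",
      `:=`(utr5 = i.utr5, n_codons = i.n_codons)]
  out[is.na(utr5), status := "unknown_transcript"]
  out[, frame := (((pos - utr5) %% 3L) + 3L) %% 3L]
  out[rules, on = c("len", "frame"), offset := i.offset]
  out[status == "ok" & is.na(offset), status := "no_offset_rule"]
  out[status == "ok" & len < offset + 3L, status := "too_short"]
  out[, codon_idx := NA_integer_]
  out[status == "ok", codon_idx := (pos - utr5 + offset) %/% 3L]
  out[status == "ok" & (codon_idx < 0L | codon_idx >= n_codons),
      `:=`(status = "outside_cds", codon_idx = NA_integer_)]
  out[status != "ok", `:=`(codon_idx = NA_integer_, offset = NA_integer_)]
  out[, c("utr5", "n_codons") := NULL]
  out[]
}

#' Assign lagging and leading A sites to disome footprints
#'
#' Disome footprints protect two collided ribosomes. The lagging (5')
#' ribosome's A site is assigned from the read 5' end with a start-anchored
#' rule table (as for monosomes, but with rules learned from the disome
#' library itself); the leading (3') ribosome's A site is assigned from the
#' read 3' end with a stop-anchored table. The resulting `d5` is the
#' 5'-anchored offset and `d3` the 3'-anchored offset, so that the pair
#' matches the (d5, f5)/(d3, f3) featurization of monosome records and
#' monosome-learned correction factors can be transferred.
#'
#' @param aln alignment table of disome reads (see [alignments])
#' @param transcripts a [transcriptome()]
#' @param rules5 start-anchored [offset_rules()] for the lagging ribosome
#' @param rules3 stop-anchored [offset_rules()] for the leading ribosome
#' @return `data.table`: alignments plus `codon_idx` (lagging A site),
#'   `j_lead` (leading A site), `d5`, `d3` and `status` (`"ok"`,
#'   `"no_offset_rule"`, `"no_leading_offset"`, `"outside_cds"`,
#'   `"not_collided"`, `"unknown_transcript"`)
#' @export
assign_disome_sites <- function(aln, transcripts, rules5, rules3) {
  stopifnot(attr(rules5, "anchor") == "start",
            attr(rules3, "anchor") == "stop")
  out <- copy(as.data.table(aln))
  out[, status := "ok"]
  out[transcripts, on = "transcript",
      `:=`(utr5 = i.utr5, cds = i.cds, n_codons = i.n_codons)]
  out[is.na(utr5), status := "unknown_transcript"]
  out[, frame := (((pos - utr5) %% 3L) + 3L) %% 3L]
  out[rules5, on = c("len", "frame"), d5 := i.offset]
  out[status == "ok" & is.na(d5), status := "no_offset_rule"]
  out[, frame3 := (((pos + len - (utr5 + cds)) %% 3L) + 3L) %% 3L]
  out[rules3, on = c("len", frame3 = "frame"), d3 := i.offset]
  out[status == "ok" & is.na(d3), status := "no_leading_offset"]
  out[, `:=`(codon_idx = NA_integer_, j_lead = NA_integer_)]
  out[status == "ok", `:=`(codon_idx = (pos - utr5 + d5) %/% 3L,
                           j_lead = (pos + len - d3 - 3L - utr5) %/% 3L)]
  out[status == "ok" & (codon_idx < 0L | j_lead >= n_codons),
      status := "outside_cds"]
  out[status == "ok" & j_lead <= codon_idx, status := "not_collided"]
  out[status != "ok", `:=`(codon_idx = NA_integer_, j_lead = NA_integer_,
                           d5 = NA_integer_, d3 = NA_integer_)]
  out[, c("utr5", "cds", "n_codons", "frame3") := NULL]
  out[]
}
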
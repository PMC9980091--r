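#' Alignment tables
#'
#' riboshift consumes footprint alignments in transcript space as a plain
#' table with one row per (possibly fractional-weight) alignment:
#' `qname`, `transcript`, `pos` (0-based 5' end on the transcript), `len`
#' (footprint length, nt) and `weight` (non-negative real, default 1;
#' multi-mapping posterior weights are summed downstream as fractional
#' counts). [read_alignments_bam()] builds this table from a BAM file;
#' [reads_to_alignments()] builds it from the simulator output.
#'
#' @name alignments
NULL

#' Read transcript-space footprint alignments from BAM
#'
#' Keeps forward-strand, ungapped primary alignments (transcript-space
#' alignments are sense-strand by construction; reverse-strand and gapped or
#' clipped records are dropped, with counts in the `dropped` attribute).
#' Optional per-alignment weights come from a numeric BAM tag (e.g. the
#' posterior weight emitted by a multi-mapping resolver) or from a sidecar
#' TSV with columns `read_id` and `weight`.
#'
#' @param path BAM file
#' @param weights_tag optional name of a numeric tag holding the alignment
#'   weight (e.g. `"ZW"`)
#' @param weights_tsv optional path to a `read_id  weight` TSV; ignored if
#'   `weights_tag` is given
#' @return alignment `data.table` (see [alignments]) with a `dropped`
#'   attribute counting excluded records
#' @export
read_alignments_bam <- function(path, weights_tag = NULL, weights_tsv = NULL) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  what <- c("qname", "rname", "strand", "pos", "qwidth", "cigar")
  param <- Rsamtools::ScanBamParam(
    what = what,
    tag = if (is.null(weights_tag)) character() else weights_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = NA))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  aln <- data.table(qname = res$qname, transcript = as.character(res$rname),
                    pos = res$pos - 1L, len = res$qwidth, cigar = res$cigar)
  if (!is.null(weights_tag) && !is.null(res$tag[[weights_tag]])) {
    aln[, weight := as.numeric(res$tag[[weights_tag]])]
  } else {
    aln[, weight := 1]
  }
  strand <- as.character(res$strand)
  rev <- strand == "-"
  gapped <- !grepl("^[0-9]+M$", aln$cigar)
  keep <- !rev & !gapped
  dropped <- c(reverse_strand = sum(rev), gapped_or_clipped = sum(gapped & !rev))
  aln <- aln[keep][, cigar := NULL]
  if (is.null(weights_tag) && !is.null(weights_tsv)) {
    w <- fread(weights_tsv)
    if (!all(c("read_id", "weight") %in% names(w))) {
      stop("weights TSV must have columns read_id, weight")
    }
    aln[w, weight := i.weight, on = c(qname = "read_id")]
    aln[is.na(weight), weight := 1]
  }
  if (any(aln$weight < 0)) stop("negative alignment weights are not allowed")
  setattr(aln, "dropped", dropped)
  aln[]
}

#' Turn simulated reads into an alignment table
#'
#' The simulator emits footprints with known transcript coordinates, so no
#' aligner is needed; this converts its `reads` table into the alignment
#' layout, verifying that each read sequence matches the transcript at its
#' recorded position when a transcriptome is supplied.
#'
#' @param reads `reads` table from [simulate_library()]
#' @param transcripts optional [transcriptome()] used to verify sequences
#' @return alignment `data.table` (see [alignments])
#' @export
reads_to_alignments <- function(reads, transcripts = NULL) {
  aln <- reads[, .(qname = read_id, transcript, pos, len, weight = 1)]
  if (!is.null(transcripts)) {
    sq <- transcripts[aln$transcript, on = "transcript"]$seq
    ok <- substr(sq, aln$pos + 1L, aln$pos + aln$len) == reads$seq
    if (!all(ok)) {
      stop(sum(!ok), " read(s) do not match the transcript sequence at ",
           "their recorded position")
    }
  }
  aln[]
}
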
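#' Transcript models: sequence plus UTR5/CDS/UTR3 extents
#'
#' A `transcriptome` is the coordinate authority for all downstream
#' featurization: a table of transcript-space sequences (5'UTR + CDS + 3'UTR)
#' together with the lengths of the three segments. All positions in the
#' package are 0-based, half-open, in transcript coordinates; codon index 0 is
#' the codon at the start AUG.
#'
#' @param id character vector of transcript identifiers (unique)
#' @param seq character vector of nucleotide sequences over \{A,C,G,T,N\}
#' @param utr5_len,cds_len,utr3_len integer segment lengths (nt); must satisfy
#'   `utr5_len + cds_len + utr3_len == nchar(seq)` and `cds_len %% 3 == 0`
#' @return a `transcriptome` object (a keyed `data.table` with columns
#'   `transcript`, `seq`, `utr5`, `cds`, `utr3`, `n_codons`)
#' @export
transcriptome <- function(id, seq, utr5_len, cds_len, utr3_len) {
  tx <- data.table(
    transcript = as.character(id), seq = toupper(as.character(seq)),
    utr5 = as.integer(utr5_len), cds = as.integer(cds_len),
    utr3 = as.integer(utr3_len)
  )
  if (anyDuplicated(tx$transcript)) {
    stop("duplicated transcript ids: ",
         paste(unique(tx$transcript[duplicated(tx$transcript)]), collapse = ", "))
  }
  bad <- validate_tx(tx)
  if (any(bad != "")) {
    stop("invalid transcript model(s): ",
         paste(sprintf("%s (%s)", tx$transcript[bad != ""], bad[bad != ""]),
               collapse = "; "))
  }
  tx[, n_codons := cds %/% 3L]
  setkey(tx, transcript)
  class(tx) <- c("transcriptome", class(tx))
  tx[]
}

# per-row validation message, "" if valid
validate_tx <- function(tx) {
  msg <- character(nrow(tx))
  n <- nchar(tx$seq)
  msg[tx$cds %% 3L != 0L] <- "CDS not multiple of 3"
  bad_len <- tx$utr5 + tx$cds + tx$utr3 != n
  msg[bad_len & msg == ""] <- "segment lengths do not sum to sequence length"
  bad_alpha <- grepl("[^ACGTN]", tx$seq)
  msg[bad_alpha & msg == ""] <- "sequence has characters outside {A,C,G,T,N}"
  msg[tx$cds < 3L & msg == ""] <- "empty CDS"
  msg
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d transcripts, %d-%d CDS codons\n",
              nrow(x), min(x$n_codons), max(x$n_codons)))
  NextMethod()
}

#' Load a transcriptome from FASTA plus segment annotation
#'
#' Reads transcript-space sequences (UTRs included) and an annotation giving
#' the 5'UTR/CDS/3'UTR extent of each transcript. The annotation is either a
#' tab-separated table with columns `transcript`, `utr5_len`, `cds_len`,
#' `utr3_len`, or a GTF file with `five_prime_utr`/`CDS`/`three_prime_utr`
#' features carrying a `transcript_id` attribute (requires the rtracklayer
#' package; segment lengths are summed per transcript).
#'
#' Transcripts failing validation (CDS not a multiple of 3, lengths
#' inconsistent with the sequence) are skipped with a message; annotation ids
#' absent from the FASTA are an error.
#'
#' @param fasta path to a FASTA file of transcript sequences
#' @param annot path to the annotation (TSV or GTF, detected from extension)
#' @return a [transcriptome()] object
#' @export
load_transcriptome <- function(fasta, annot) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  if (!file.exists(annot)) stop("annotation file not found: ", annot)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- if (grepl("\\.gtf(\\.gz)?$", annot, ignore.case = TRUE)) {
    read_annotation_gtf(annot)
  } else {
    read_annotation_tsv(annot)
  }
  missing <- setdiff(ann$transcript, names(seqs))
  if (length(missing)) {
    stop("annotated transcript(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  tx <- data.table(
    transcript = ann$transcript,
    seq = toupper(as.character(seqs[ann$transcript])),
    utr5 = as.integer(ann$utr5_len), cds = as.integer(ann$cds_len),
    utr3 = as.integer(ann$utr3_len)
  )
  msg <- validate_tx(tx)
  if (any(msg != "")) {
    bad <- msg != ""
    message(sprintf("skipping %d transcript(s): %s", sum(bad),
                    paste(sprintf("%s (%s)", tx$transcript[bad], msg[bad]),
                          collapse = "; ")))
    tx <- tx[!bad]
  }
  if (nrow(tx) == 0L) stop("no valid transcripts after validation")
  transcriptome(tx$transcript, tx$seq, tx$utr5, tx$cds, tx$utr3)
}

read_annotation_tsv <- function(path) {
  ann <- fread(path)
  need <- c("transcript", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(ann))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  ann[, need, with = FALSE]
}

read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GTF annotation requires the rtracklayer package; ",
         "use the 4-column TSV format instead")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.table(gr)[, .(type = as.character(type),
                              transcript = as.character(transcript_id),
                              width = width)]
  wide <- df[type %in% c("five_prime_utr", "CDS", "three_prime_utr"),
             .(len = sum(width)), by = .(transcript, type)]
  out <- data.table::dcast(wide, transcript ~ type, value.var = "len", fill = 0L)
  for (col in c("five_prime_utr", "CDS", "three_prime_utr")) {
    if (!col %in% names(out)) out[, (col) := 0L]
  }
  out[, .(transcript, utr5_len = five_prime_utr, cds_len = CDS,
          utr3_len = three_prime_utr)]
}

#' Write a transcriptome to FASTA + TSV annotation
#'
#' @param tx a [transcriptome()]
#' @param fasta,annot output paths
#' @return invisibly, the two paths
#' @export
write_transcriptome <- function(tx, fasta, annot) {
  seqs <- Biostrings::DNAStringSet(setNames(tx$seq, tx$transcript))
  Biostrings::writeXStringSet(seqs, fasta)
  fwrite(data.table(transcript = tx$transcript, utr5_len = tx$utr5,
                    cds_len = tx$cds, utr3_len = tx$utr3),
         annot, sep = "\t")
  invisible(c(fasta, annot))
}

#' Generate a random transcriptome for simulation
#'
#' Draws CDS lengths uniformly over a codon range, prepends an AUG start and
#' appends a stop codon, and pads both ends with random UTRs. Interior CDS
#' codons are drawn uniformly from the 61 sense codons, so in-frame stops
#' occur only at the annotated stop.
#'
#' @param n_transcripts number of transcripts
#' @param codon_range range (min, max) of CDS length in codons, start and stop
#'   codons included
#' @param utr_len length (nt) of both UTRs; 20 nt accommodates footprints at
#'   the start and stop codons
#' @param seed integer seed
#' @return a [transcriptome()]
#' @export
simulate_transcriptome <- function(n_transcripts, codon_range = c(150L, 400L),
                                   utr_len = 20L, seed = 1L) {
  stopifnot(n_transcripts >= 1, codon_range[1] >= 3, utr_len >= 0)
  set.seed(as.integer(seed))
  sense <- sense_codons()
  # sample.int avoids the sample() scalar pitfall when min == max
  n_cod <- codon_range[1] - 1L +
    sample.int(codon_range[2] - codon_range[1] + 1L, n_transcripts,
               replace = TRUE)
  ids <- sprintf("TX%04d", seq_len(n_transcripts))
  seqs <- vapply(n_cod, function(nc) {
    body <- paste0(sample(sense, nc - 2L, replace = TRUE), collapse = "")
    utr5 <- paste0(sample(.nucs, utr_len, replace = TRUE), collapse = "")
    utr3 <- paste0(sample(.nucs, utr_len, replace = TRUE), collapse = "")
    paste0(utr5, "ATG", body, sample(c("TAA", "TAG", "TGA"), 1L), utr3)
  }, character(1))
  transcriptome(ids, seqs, utr_len, 3L * n_cod, utr_len)
}

# codon at CDS codon index j (0-based) of one transcript row; NA outside the
# sequence. Vectorized over j.
codon_at <- function(seq, utr5, j) {
  start <- utr5 + 3L * j
  out <- substring(seq, start + 1L, start + 3L)
  out[start < 0L | start + 3L > nchar(seq)] <- NA_character_
  out
}

# GC fraction of each string (A/C/G/T alphabet), zero-length -> NaN
gc_fraction <- function(s) {
  n <- nchar(s)
  gcn <- n - nchar(gsub("[GCgc]", "", s))
  gcn / n
}
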
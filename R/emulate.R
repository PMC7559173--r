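# Offline emulation of a translated (blastx-style) aligner: six-frame
# translation of each read, k-mer-seeded Smith-Waterman against every
# reference peptide, and emission of standard 12+1-column tabular rows.
# This stands in for an external aligner so the downstream algorithm can be
# exercised end-to-end with no databases or external tools.

#' Emulate translated alignment of reads against reference peptides
#'
#' Translates each mate in all six frames, aligns frames sharing at least
#' one exact amino-acid k-mer with a reference (affine-gap Smith-Waterman,
#' BLOSUM62, gap open 11 / extend 1), keeps the best frame per
#' (mate, reference), and emits blastx-style tabular records. Bitscores are
#' deterministic functions of the raw score (gapped BLOSUM62
#' Karlin-Altschul scale); an error-free read's true origin is therefore
#' always among its best-scoring hits. The two mates of a pair share one
#' query id, so a pair can contribute up to two rows per reference (the
#' tabular parser keeps the better one).
#'
#' @param reads A `read_sim` object, a list with `fwd`/`rev`
#'   `DNAStringSet`s, or a single `DNAStringSet` of reads (names become
#'   query ids; `/1` and `/2` suffixes are stripped).
#' @param reference Named `AAStringSet` of reference peptides.
#' @param min_bitscore Score floor (bits) below which alignments are not
#'   reported.
#' @param k Seed k-mer length (amino acids).
#' @param gap_open,gap_ext Gap penalties (a length-L gap costs
#'   `gap_open + L * gap_ext`).
#' @return data.table of alignment records (columns query, subject, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore, slen) suitable for [alignment_set()] or [write_alignments()].
#' @export
emulate_alignment <- function(reads, reference, min_bitscore = 30, k = 6,
                              gap_open = 11, gap_ext = 1) {
  if (length(reference) == 0) input_error("empty reference set")
  if (is.null(names(reference))) input_error("reference peptides must be named")
  mates <- if (inherits(reads, "read_sim") ||
               (is.list(reads) && !is.null(reads$fwd))) {
    c(reads$fwd, reads$rev)
  } else {
    reads
  }
  qnames <- sub("/[12]$", "", names(mates))
  n <- length(mates)
  widths <- Biostrings::width(mates)

  frames <- character(0)
  rc <- Biostrings::reverseComplement(mates)
  for (strand_set in list(mates, rc)) {
    for (f in 0:2) {
      w <- pmax(0L, 3L * ((widths - f) %/% 3L))
      tr <- Biostrings::translate(
        Biostrings::subseq(strand_set, start = f + 1L, width = w),
        no.init.codon = TRUE, if.fuzzy.codon = "X")
      frames <- c(frames, as.character(tr))
    }
  }

  min_raw <- ceiling(raw_from_bits(min_bitscore))
  hits <- as.data.table(cpp_batch_search(
    frames, as.character(reference), blosum62(), blosum62_alphabet(),
    as.integer(k), min_raw, as.integer(gap_open), as.integer(gap_ext),
    2L, 24L))
  if (nrow(hits) == 0) {
    out <- empty_alignment_records()
    out[, slen := integer()]
    return(out[])
  }

  hits[, mate := (query - 1L) %% n + 1L]
  hits[, block := (query - 1L) %/% n]     # 0..2 forward, 3..5 reverse
  hits[, frame := block %% 3L]
  hits[, minus := block >= 3L]
  setorder(hits, mate, ref, -score, block)
  hits <- hits[!duplicated(hits[, .(mate, ref)])]

  # aa coordinates on the frame -> nt coordinates on the mate
  L <- widths[hits$mate]
  qs_nt <- ifelse(hits$minus,
                  L - (3L * (hits$qstart - 1L) + hits$frame),
                  3L * (hits$qstart - 1L) + 1L + hits$frame)
  qe_nt <- ifelse(hits$minus,
                  L - (3L * hits$qend - 1L + hits$frame),
                  3L * hits$qend + hits$frame)

  bits <- bits_from_raw(hits$score)
  qlen_aa <- pmax(1, floor(L / 3))
  db_aa <- sum(Biostrings::width(reference))
  out <- data.table(
    query = qnames[hits$mate],
    subject = names(reference)[hits$ref],
    pident = round(100 * hits$matches / hits$length, 1),
    length = hits$length,
    mismatch = hits$mismatches,
    gapopen = hits$gapopens,
    qstart = as.integer(qs_nt),
    qend = as.integer(qe_nt),
    sstart = hits$sstart,
    send = hits$send,
    evalue = signif(qlen_aa * db_aa * 2^(-bits), 3),
    bitscore = round(bits, 1),
    slen = Biostrings::width(reference)[hits$ref])
  out[]
}

#' Single-pair local protein alignment (BLOSUM62, affine gaps)
#'
#' Thin wrapper over the package's Smith-Waterman kernel, mainly for
#' inspection and testing.
#'
#' @param a,b Peptide sequences (character).
#' @param gap_open,gap_ext Gap penalties.
#' @return List with raw `score`, `bitscore`, `matches`, `mismatches`,
#'   `gapopens`, `length`, and 1-based alignment coordinates.
#' @export
local_align <- function(a, b, gap_open = 11, gap_ext = 1) {
  res <- cpp_local_align(as.character(a), as.character(b), blosum62(),
                         blosum62_alphabet(), as.integer(gap_open),
                         as.integer(gap_ext))
  res$bitscore <- bits_from_raw(res$score)
  res
}

#' Global identity between two peptides
#'
#' Needleman-Wunsch with affine gaps; identity is matches over alignment
#' columns (end gaps included).
#'
#' @param a,b Peptide sequences.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return Identity fraction in [0, 1].
#' @export
global_identity <- function(a, b, match = 2, mismatch = -1, gap_open = 4,
                            gap_ext = 1) {
  res <- cpp_global_identity(as.character(a), as.character(b),
                             as.integer(match), as.integer(mismatch),
                             as.integer(gap_open), as.integer(gap_ext))
  if (res$columns == 0) return(0)
  res$matches / res$columns
}
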
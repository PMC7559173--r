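# Reading, validation and acceptance filtering of translated-alignment
# tabular files (blastx-style 12-column format, optional column 13 with the
# subject length in amino acids).

#' Column positions for tabular translated alignments
#'
#' Standard blastx tabular order (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), with the subject
#' sequence length optionally in column 13. Pass a modified result to
#' [read_alignments()] for files with rearranged columns; set `slen = NA`
#' when no length column is present and supply a reference FASTA instead.
#'
#' @param qseqid,sseqid,pident,length,mismatch,gapopen,qstart,qend,sstart,send,evalue,bitscore,slen
#'   1-based column positions.
#' @return Named integer vector of column positions.
#' @export
alignment_columns <- function(qseqid = 1, sseqid = 2, pident = 3, length = 4,
                              mismatch = 5, gapopen = 6, qstart = 7, qend = 8,
                              sstart = 9, send = 10, evalue = 11,
                              bitscore = 12, slen = 13) {
  c(qseqid = qseqid, sseqid = sseqid, pident = pident, length = length,
    mismatch = mismatch, gapopen = gapopen, qstart = qstart, qend = qend,
    sstart = sstart, send = send, evalue = evalue, bitscore = bitscore,
    slen = slen)
}

#' Construct an alignment set
#'
#' Bundles alignment records with the subject (reference peptide) lengths and
#' enforces the invariants the downstream algorithm relies on: every subject
#' has a known length, subject coordinates lie inside the subject, and
#' bitscores are positive. When several local alignments link the same read
#' and reference over overlapping subject regions, only the highest-bitscore
#' one is kept; alignments on disjoint regions (typically the two mates of a
#' read pair) are independent coverage evidence and all survive, while the
#' score model still tracks a single candidacy per (query, subject) pair
#' (see [init_scores()]).
#'
#' Mate suffixes (`/1`, `/2`) are stripped from query ids so that the two
#' reads of a pair share one query and are resolved jointly.
#'
#' @param records data.frame/data.table with columns query, subject, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @param subject_lengths Named integer vector (or NULL to take lengths from
#'   a `slen` column of `records`).
#' @param strip_mate_suffix Strip `/1` / `/2` (and ` 1:`/` 2:` Illumina
#'   dialect) suffixes from query ids.
#' @return An object of class `alignment_set`: list with elements `records`
#'   (data.table) and `subject_lengths` (named integer vector).
#' @export
alignment_set <- function(records, subject_lengths = NULL,
                          strip_mate_suffix = TRUE) {
  rec <- as.data.table(records)
  required <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols)) {
    input_error("alignment records lack column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (is.null(subject_lengths)) {
    if (!"slen" %in% names(rec)) {
      input_error("subject_lengths not given and records have no slen column")
    }
    sl <- unique(rec[, .(subject, slen)])
    if (anyDuplicated(sl$subject)) {
      bad <- sl$subject[duplicated(sl$subject)][1]
      input_error("conflicting subject lengths for subject '%s'", bad)
    }
    subject_lengths <- setNames(as.integer(sl$slen), sl$subject)
  }
  rec <- rec[, required, with = FALSE]
  if (strip_mate_suffix) {
    rec[, query := sub("(/[12]| [12]:.*)$", "", query)]
  }

  if (any(!is.finite(rec$bitscore))) {
    input_error("non-numeric bitscore in record %d",
                which(!is.finite(rec$bitscore))[1])
  }
  if (any(rec$bitscore <= 0)) {
    input_error("non-positive bitscore in record %d",
                which(rec$bitscore <= 0)[1])
  }
  if (any(rec$pident < 0 | rec$pident > 100)) {
    input_error("percent identity outside [0, 100] in record %d",
                which(rec$pident < 0 | rec$pident > 100)[1])
  }
  swapped <- rec$sstart > rec$send
  if (any(swapped)) {
    warning(sprintf("%d record(s) had subject_start > subject_end; swapped",
                    sum(swapped)))
    tmp <- rec$sstart[swapped]
    rec[swapped, sstart := send]
    rec[swapped, send := tmp]
  }

  unknown <- setdiff(unique(rec$subject), names(subject_lengths))
  if (length(unknown)) {
    input_error("missing subject length for subject '%s'", unknown[1])
  }
  slen <- subject_lengths[rec$subject]
  over <- which(rec$send > slen)
  if (length(over)) {
    input_error(
      "alignment extends past subject length (query '%s', subject '%s', end %d > %d)",
      rec$query[over[1]], rec$subject[over[1]], rec$send[over[1]],
      slen[over[1]])
  }

  # Exact duplicates are dropped. Within a (query, subject) pair, records
  # whose subject intervals overlap are redundant local alignments of the
  # same evidence and only the highest-bitscore one is kept; records on
  # disjoint subject regions (typically the two mates of a pair) are
  # independent coverage evidence and all survive. Input order is preserved.
  rec[, .orig := .I]
  rec <- unique(rec, by = c("query", "subject", "sstart", "send"))
  setorder(rec, query, subject, -bitscore, .orig)
  rec[, .idx := seq_len(.N), by = .(query, subject)]
  maxn <- if (nrow(rec)) max(rec$.idx) else 0L
  if (maxn > 1L) {
    if (maxn == 2L) {
      # vectorized two-row case: drop row 2 iff it overlaps row 1
      two <- rec[, .N, by = .(query, subject)][N == 2L]
      r1 <- rec[two, on = c("query", "subject")][.idx == 1L]
      r2 <- rec[two, on = c("query", "subject")][.idx == 2L]
      drop <- r2[r1$sstart <= r2$send & r2$sstart <= r1$send]
      if (nrow(drop)) rec <- rec[!drop, on = c("query", "subject", ".idx")]
    } else {
      rec[, .keep := {
        k <- logical(.N)
        for (i in seq_len(.N)) {
          k[i] <- !any(k & sstart[i] <= send & sstart <= send[i])
        }
        k
      }, by = .(query, subject)]
      rec <- rec[(.keep)][, .keep := NULL]
    }
  }
  setorder(rec, .orig)
  rec[, c(".orig", ".idx") := NULL]

  structure(list(records = rec, subject_lengths = subject_lengths),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d alignments, %d queries, %d subjects\n",
              nrow(x$records), length(unique(x$records$query)),
              length(unique(x$records$subject))))
  invisible(x)
}

#' Read a tabular translated-alignment file
#'
#' Parses a tab-separated blastx-style alignment file. Subject lengths (in
#' amino acids) are taken from the `slen` column when present, otherwise
#' from `ref_fasta`. Lines with fewer than the required number of columns are
#' reported by line number.
#'
#' @param path Path to the tab-separated file.
#' @param ref_fasta Optional reference peptide FASTA supplying subject
#'   lengths (required when the file has no length column).
#' @param columns Column map from [alignment_columns()].
#' @param strip_mate_suffix See [alignment_set()].
#' @return An [alignment_set()].
#' @export
read_alignments <- function(path, ref_fasta = NULL,
                            columns = alignment_columns(),
                            strip_mate_suffix = TRUE) {
  if (!file.exists(path)) input_error("alignment file not found: %s", path)
  has_slen <- !is.na(columns["slen"])
  need <- max(columns[setdiff(names(columns), "slen")], na.rm = TRUE)

  nfields <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nfields) == 0) {
    return(alignment_set(empty_alignment_records(),
                         subject_lengths = integer(0)))
  }
  bad <- which(nfields < need)
  if (length(bad)) {
    input_error("line %d has %d columns (expected at least %d)",
                bad[1], nfields[bad[1]], need)
  }
  if (has_slen && any(nfields < columns["slen"])) has_slen <- FALSE

  raw <- fread(path, header = FALSE, sep = "\t", quote = "",
               colClasses = "character", fill = TRUE)
  pick <- function(field) raw[[columns[[field]]]]
  num <- function(field) {
    v <- suppressWarnings(as.numeric(pick(field)))
    badln <- which(is.na(v))
    if (length(badln)) {
      input_error("non-numeric %s on line %d", field, badln[1])
    }
    v
  }
  rec <- data.table(
    query = pick("qseqid"), subject = pick("sseqid"), pident = num("pident"),
    length = as.integer(num("length")), mismatch = as.integer(num("mismatch")),
    gapopen = as.integer(num("gapopen")), qstart = as.integer(num("qstart")),
    qend = as.integer(num("qend")), sstart = as.integer(num("sstart")),
    send = as.integer(num("send")), evalue = num("evalue"),
    bitscore = num("bitscore"))

  subject_lengths <- NULL
  if (has_slen) {
    rec[, slen := as.integer(num("slen"))]
  } else {
    if (is.null(ref_fasta)) {
      input_error(
        "no subject-length column in %s and no reference FASTA supplied", path)
    }
    aa <- Biostrings::readAAStringSet(ref_fasta)
    names(aa) <- sub("\\s.*$", "", names(aa))
    subject_lengths <- setNames(Biostrings::width(aa), names(aa))
  }
  alignment_set(rec, subject_lengths = subject_lengths,
                strip_mate_suffix = strip_mate_suffix)
}

empty_alignment_records <- function() {
  data.table(query = character(), subject = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric())
}

#' Write an alignment set (or emulated alignment table) as tabular text
#'
#' Emits the standard 12 columns plus subject length as column 13, so the
#' file round-trips through [read_alignments()].
#'
#' @param x An `alignment_set` or a data.table of alignment records.
#' @param path Output path.
#' @param subject_lengths Needed only when `x` is a bare record table
#'   without an `slen` column.
#' @export
write_alignments <- function(x, path, subject_lengths = NULL) {
  if (inherits(x, "alignment_set")) {
    rec <- copy(x$records)
    rec[, slen := x$subject_lengths[subject]]
  } else {
    rec <- as.data.table(x)
    if (!"slen" %in% names(rec)) {
      if (is.null(subject_lengths)) {
        input_error("subject_lengths required to write a bare record table")
      }
      rec <- copy(rec)
      rec[, slen := subject_lengths[subject]]
    }
  }
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "slen")
  fwrite(rec[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Keep, per query, only alignments near that query's best
#'
#' With `tolerance_pct = 0` this is the top-hit rule (ties with the best are
#' kept); with `tolerance_pct = 10` it keeps alignments within 10 percentage
#' points of identity of the best alignment for the query (the "top-10"
#' rule). The band is additive on the percent-identity scale; set
#' `by = "bitscore"` to band on bitscore instead (best * (1 - tol/100)).
#'
#' @param alignments An [alignment_set()].
#' @param tolerance_pct Tolerance (percentage points of identity, or percent
#'   of best bitscore), >= 0.
#' @param by Field on which the acceptance band is applied.
#' @return A filtered `alignment_set` preserving input record order.
#' @export
accept_best <- function(alignments, tolerance_pct = 0,
                        by = c("pident", "bitscore")) {
  by <- match.arg(by)
  if (!is.numeric(tolerance_pct) || length(tolerance_pct) != 1 ||
      is.na(tolerance_pct) || tolerance_pct < 0) {
    input_error("tolerance_pct must be a single number >= 0")
  }
  rec <- alignments$records
  if (nrow(rec) == 0) return(alignments)
  keep <- if (by == "pident") {
    rec[, .keep := pident >= max(pident) - tolerance_pct, by = query]$.keep
  } else {
    rec[, .keep := bitscore >= max(bitscore) * (1 - tolerance_pct / 100),
        by = query]$.keep
  }
  rec[, .keep := NULL]
  structure(list(records = rec[keep],
                 subject_lengths = alignments$subject_lengths),
            class = "alignment_set")
}
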
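library(data.table)

# one alignment record with sensible defaults; override fields as needed
aln_row <- function(query, subject, bitscore = 50, pident = 100,
                    sstart = 1, send = 10, length = send - sstart + 1,
                    mismatch = 0, gapopen = 0, qstart = 1,
                    qend = 3 * length, evalue = 1e-10, slen = NA_integer_) {
  data.table(query = query, subject = subject, pident = pident,
             length = as.integer(length), mismatch = as.integer(mismatch),
             gapopen = as.integer(gapopen), qstart = as.integer(qstart),
             qend = as.integer(qend), sstart = as.integer(sstart),
             send = as.integer(send), evalue = evalue, bitscore = bitscore,
             slen = as.integer(slen))
}

# build an alignment_set from aln_row() rows plus a subject length map
tiny_aset <- function(..., lengths) {
  rec <- rbindlist(list(...))
  rec[, slen := NULL]
  alignment_set(rec, subject_lengths = lengths)
}

# dense-matrix mirror of a sparse score table (queries x subjects, NA = absent)
scores_to_matrix <- function(scores) {
  qs <- sort(unique(scores$query))
  ss <- sort(unique(scores$subject))
  m <- matrix(NA_real_, length(qs), length(ss), dimnames = list(qs, ss))
  m[cbind(match(scores$query, qs), match(scores$subject, ss))] <- scores$score
  m
}

matrix_to_scores <- function(m) {
  idx <- which(!is.na(m), arr.ind = TRUE)
  data.table(query = rownames(m)[idx[, 1]], subject = colnames(m)[idx[, 2]],
             score = m[idx])[order(query, subject)]
}

# random sparse bitscore instance: every query has >= 1 subject
random_instance <- function(n_q, n_s, bitscores = c(30, 45, 60, 90)) {
  rows <- list()
  for (q in seq_len(n_q)) {
    subs <- sample.int(n_s, sample.int(n_s, 1))
    rows[[q]] <- data.table(query = sprintf("q%02d", q),
                            subject = sprintf("s%02d", subs),
                            bitscore = sample(bitscores, length(subs),
                                              replace = TRUE))
  }
  rbindlist(rows)
}

random_peptide <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                           "G", "H", "I", "L", "K", "M", "F",
                                           "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# point-mutate a fraction of residues (guaranteed different letter)
mutate_peptide <- function(pep, frac) {
  ch <- strsplit(pep, "")[[1]]
  idx <- sample(length(ch), max(1, round(frac * length(ch))))
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}
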
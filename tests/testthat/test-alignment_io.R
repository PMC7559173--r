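test_that("well-formed 13-column files parse into records with lengths", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\tsubA\t98.8\t80\t1\t0\t1\t240\t11\t90\t1e-40\t160.2\t120",
    "r2\tsubB\t100.0\t83\t0\t0\t1\t249\t5\t87\t1e-44\t171.0\t95"),
    f)
  aset <- read_alignments(f)
  expect_s3_class(aset, "alignment_set")
  expect_equal(nrow(aset$records), 2)
  expect_equal(aset$subject_lengths, c(subA = 120L, subB = 95L))
  expect_equal(aset$records$bitscore, c(160.2, 171.0))
})

test_that("short lines and bad numbers are reported by line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  good <- paste(c("r1", "subA", "98", "80", "1", "0", "1", "240", "11", "90",
                  "1e-40", "160", "120"), collapse = "\t")
  writeLines(c(good, good, paste(rep("x", 11), collapse = "\t")), f)
  expect_error(read_alignments(f), "line 3")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  bad <- sub("160", "notanumber", good)
  writeLines(c(good, bad), f2)
  expect_error(read_alignments(f2), "bitscore on line 2")
})

test_that("subject lengths come from a FASTA when column 13 is absent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("r1", "subA", "98", "80", "1", "0", "1", "240", "11",
                     "90", "1e-40", "160"), collapse = "\t"), f)
  expect_error(read_alignments(f, columns = alignment_columns(slen = NA)),
               "no subject-length column")
  fa <- withr::local_tempfile(fileext = ".faa")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(subA = strrep("M", 120))), fa)
  aset <- read_alignments(f, ref_fasta = fa,
                          columns = alignment_columns(slen = NA))
  expect_equal(unname(aset$subject_lengths["subA"]), 120L)

  # a subject missing from the FASTA is a hard error naming it
  fa2 <- withr::local_tempfile(fileext = ".faa")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(other = strrep("M", 50))), fa2)
  expect_error(read_alignments(f, ref_fasta = fa2,
                               columns = alignment_columns(slen = NA)),
               "subA")
})

test_that("alignment records validate coordinates and scores", {
  expect_error(tiny_aset(aln_row("r1", "A", send = 30),
                         lengths = c(A = 20L)),
               "past subject length")
  expect_error(tiny_aset(aln_row("r1", "A", bitscore = -3),
                         lengths = c(A = 20L)),
               "bitscore")
  expect_error(tiny_aset(aln_row("r1", "A", pident = 101),
                         lengths = c(A = 20L)),
               "identity")
  # swapped subject coordinates are repaired with a warning
  expect_warning(
    a <- tiny_aset(aln_row("r1", "A", sstart = 10, send = 2),
                   lengths = c(A = 20L)),
    "swapped")
  expect_equal(a$records$sstart, 2L)
  expect_equal(a$records$send, 10L)
})

test_that("mates share a query id and redundant local alignments collapse", {
  a <- tiny_aset(aln_row("r1/1", "A", bitscore = 60, sstart = 1, send = 30),
                 aln_row("r1/2", "A", bitscore = 55, sstart = 60, send = 90),
                 lengths = c(A = 100L))
  # disjoint mate alignments both survive under one query id
  expect_equal(unique(a$records$query), "r1")
  expect_equal(nrow(a$records), 2)

  b <- tiny_aset(aln_row("r2", "A", bitscore = 60, sstart = 1, send = 30),
                 aln_row("r2", "A", bitscore = 40, sstart = 10, send = 40),
                 lengths = c(A = 100L))
  # overlapping ones keep only the better-scoring record
  expect_equal(nrow(b$records), 1)
  expect_equal(b$records$bitscore, 60)
})

test_that("alignment files round-trip through write and re-read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  a <- tiny_aset(aln_row("r1", "A", bitscore = 60, sstart = 1, send = 30),
                 aln_row("r1", "B", bitscore = 55, sstart = 2, send = 31),
                 aln_row("r2", "B", bitscore = 71, sstart = 40, send = 70),
                 lengths = c(A = 100L, B = 80L))
  write_alignments(a, f)
  b <- read_alignments(f)
  expect_equal(b$records, a$records)
  expect_equal(b$subject_lengths[sort(names(b$subject_lengths))],
               a$subject_lengths[sort(names(b$subject_lengths))])
  # writing again is a fixed point
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(b, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("accept_best applies the additive identity band per query", {
  a <- tiny_aset(aln_row("r1", "A", pident = 100),
                 aln_row("r1", "B", pident = 95),
                 aln_row("r1", "C", pident = 89),
                 aln_row("r2", "D", pident = 50),
                 lengths = c(A = 20L, B = 20L, C = 20L, D = 20L))
  top10 <- accept_best(a, 10)
  expect_equal(top10$records[query == "r1", subject], c("A", "B"))
  # a single-hit query is always kept, whatever its identity
  expect_equal(top10$records[query == "r2", subject], "D")

  ties <- tiny_aset(aln_row("r1", "A", pident = 97),
                    aln_row("r1", "B", pident = 97),
                    lengths = c(A = 20L, B = 20L))
  expect_equal(nrow(accept_best(ties, 0)$records), 2)

  expect_error(accept_best(a, -1), "tolerance")

  # bitscore variant: the band is relative to the best bitscore
  bb <- tiny_aset(aln_row("r1", "A", bitscore = 100),
                  aln_row("r1", "B", bitscore = 92),
                  aln_row("r1", "C", bitscore = 85),
                  lengths = c(A = 20L, B = 20L, C = 20L))
  expect_equal(accept_best(bb, 10, by = "bitscore")$records$subject,
               c("A", "B"))
})

test_that("accept_best is monotone in tolerance and never empties a query", {
  set.seed(42)
  for (rep in 1:20) {
    rec <- random_instance(4, 5)
    rec[, pident := 70 + 30 * runif(.N)]
    a <- alignment_set(
      rec[, .(query, subject, pident, length = 30L, mismatch = 0L,
              gapopen = 0L, qstart = 1L, qend = 90L, sstart = 1L, send = 30L,
              evalue = 1e-10, bitscore)],
      subject_lengths = setNames(rep(50L, 5), sprintf("s%02d", 1:5)))
    tols <- sort(runif(3, 0, 30))
    prev <- NULL
    for (tol in tols) {
      kept <- accept_best(a, tol)$records
      expect_true(all(kept[, .N, by = query]$N >= 1))
      expect_true(nrow(fsetdiff(kept, a$records)) == 0)
      if (!is.null(prev)) {
        expect_true(nrow(fsetdiff(prev, kept)) == 0)  # prev subset of kept
      }
      prev <- kept
      expect_setequal(unique(kept$query), unique(a$records$query))
    }
  }
})
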
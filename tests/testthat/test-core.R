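test_that("initial scores are bitscore fractions per query", {
  a <- tiny_aset(aln_row("r1", "A", bitscore = 50),
                 aln_row("r2", "A", bitscore = 60, sstart = 11, send = 20),
                 aln_row("r2", "B", bitscore = 40),
                 aln_row("r3", "A", bitscore = 33),
                 aln_row("r3", "B", bitscore = 33, sstart = 5, send = 14),
                 lengths = c(A = 20L, B = 20L))
  s <- init_scores(a)
  expect_equal(s[query == "r1", score], 1.0)
  expect_equal(s[query == "r2"][order(subject), score], c(0.6, 0.4))
  expect_equal(s[query == "r3", score], c(0.5, 0.5))
  expect_error(
    init_scores(data.table(query = "q", subject = "s", bitscore = 0)),
    "zero total bitscore")
})

test_that("reweighting shifts shared reads toward better-supported subjects", {
  # q1 maps only to A; q2 splits evenly between A and B:
  # W(A) = 1.5, W(B) = 0.5, so q2 goes to {A: 0.75, B: 0.25}
  s <- data.table(query = c("q1", "q2", "q2"),
                  subject = c("A", "A", "B"),
                  score = c(1, 0.5, 0.5))
  s2 <- reweight_scores(s)
  expect_equal(s2[query == "q2" & subject == "A", score], 0.75)
  expect_equal(s2[query == "q2" & subject == "B", score], 0.25)
  # single-candidate queries are exact fixed points
  expect_identical(s2[query == "q1", score], 1)
})

test_that("pruning drops candidates below the relative threshold", {
  s <- data.table(query = "q", subject = c("A", "B"), score = c(0.75, 0.25))
  pr <- prune_scores(s, 0.5)
  expect_equal(pr$n_pruned, 1)
  expect_equal(pr$scores$score, 1.0)
  expect_equal(pr$scores$subject, "A")

  tie <- data.table(query = "q", subject = c("A", "B"), score = c(0.5, 0.5))
  pr2 <- prune_scores(tie, 1.0)
  expect_equal(pr2$n_pruned, 0)
  expect_equal(nrow(pr2$scores), 2)

  single <- data.table(query = "q", subject = "A", score = 1.0)
  pr3 <- prune_scores(single, 0.99)
  expect_equal(pr3$n_pruned, 0)
  expect_identical(pr3$scores$score, 1.0)
})

test_that("uniquely mapping reads resolve to themselves in one iteration", {
  a <- tiny_aset(aln_row("r1", "A", sstart = 1, send = 10),
                 aln_row("r2", "B", sstart = 6, send = 15),
                 aln_row("r3", "C", sstart = 1, send = 20),
                 lengths = c(A = 20L, B = 20L, C = 20L))
  res <- run_cdsem(a)
  expect_equal(res$iterations_run, 1L)
  expect_equal(nrow(res$assignments), 3)
  expect_setequal(res$retained_subjects, c("A", "B", "C"))
  expect_length(res$unassigned, 0)
  got <- setNames(res$assignments$subject, res$assignments$query)
  expect_equal(got[c("r1", "r2", "r3")], c(r1 = "A", r2 = "B", r3 = "C"))
})

test_that("exact symmetry is broken deterministically and reruns agree", {
  # two subjects with identical support; the lexicographically smaller id wins
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <-
      aln_row(sprintf("r%d", i), "B", bitscore = 50,
              sstart = 3 * i, send = 3 * i + 9)
    rows[[length(rows) + 1]] <-
      aln_row(sprintf("r%d", i), "A", bitscore = 50,
              sstart = 3 * i, send = 3 * i + 9)
  }
  a <- do.call(tiny_aset, c(rows, list(lengths = c(A = 30L, B = 30L))))
  res1 <- run_cdsem(a)
  res2 <- run_cdsem(a)
  expect_equal(unique(res1$assignments$subject), "A")
  expect_identical(res1$assignments, res2$assignments)
  expect_identical(res1$candidate_counts, res2$candidate_counts)
})

test_that("degenerate inputs give empty results, not errors", {
  empty <- alignment_set(data.table(query = character(),
                                    subject = character(), pident = numeric(),
                                    length = integer(), mismatch = integer(),
                                    gapopen = integer(), qstart = integer(),
                                    qend = integer(), sstart = integer(),
                                    send = integer(), evalue = numeric(),
                                    bitscore = numeric()),
                         subject_lengths = integer(0))
  res <- run_cdsem(empty)
  expect_equal(nrow(res$assignments), 0)
  expect_equal(res$iterations_run, 0L)

  # a single spiked subject: everything is filtered, with a warning
  spiky <- tiny_aset(aln_row("r1", "A", sstart = 1, send = 2),
                     lengths = c(A = 50L))
  expect_warning(res2 <- run_cdsem(spiky), "evenness")
  expect_equal(nrow(res2$assignments), 0)
  expect_equal(res2$unassigned, "r1")
})

test_that("detection summaries match a brute-force coverage overlay", {
  # 10 reads each covering 25 aa of a 100 aa subject, evenly tiled
  rows <- lapply(1:10, function(i) {
    st <- (i - 1) * 8 + 1
    aln_row(sprintf("r%02d", i), "A", sstart = st, send = st + 24)
  })
  a <- do.call(tiny_aset, c(rows, list(lengths = c(A = 100L))))
  res <- run_cdsem(a)
  rep <- summarize_detections(res)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$nreads, 10L)
  expect_equal(rep$length, 100L)

  # independent overlay oracle
  depth <- numeric(100)
  for (i in 1:10) {
    st <- (i - 1) * 8 + 1
    depth[st:(st + 24)] <- depth[st:(st + 24)] + 1
  }
  expect_equal(rep$depth_mean, mean(depth))
  expect_equal(rep$depth_sd, sqrt(mean((depth - mean(depth))^2)))
  expect_equal(rep$coverage_fraction, mean(depth > 0))

  # empty result gives an empty report with the full header
  empty_rep <- summarize_detections(
    structure(list(retained_subjects = character(0),
                   assignments = data.table(query = character(),
                                            subject = character()),
                   coverage = list()),
              class = "cdsem_result"))
  expect_equal(nrow(empty_rep), 0)
  expect_named(empty_rep, c("id", "length", "nreads", "depth_mean",
                            "depth_sd", "coverage_fraction"))
})

test_that("score-weighted coverage feeds the evenness re-check", {
  # a decoy covered only in a shared 10-aa window is removed while the
  # evenly covered truth is retained, and its reads keep their assignment
  rows <- list()
  for (i in 1:8) {
    st <- (i - 1) * 5 + 1
    rows[[length(rows) + 1]] <- aln_row(sprintf("r%d", i), "truth",
                                        bitscore = 60, sstart = st,
                                        send = st + 12)
  }
  # reads 3 and 4 also hit the decoy inside its small shared window
  rows[[length(rows) + 1]] <- aln_row("r3", "decoy", bitscore = 60,
                                      sstart = 20, send = 30)
  rows[[length(rows) + 1]] <- aln_row("r4", "decoy", bitscore = 60,
                                      sstart = 21, send = 31)
  a <- do.call(tiny_aset, c(rows, list(lengths = c(truth = 50L,
                                                   decoy = 50L))))
  res <- run_cdsem(a)
  expect_equal(res$retained_subjects, "truth")
  expect_equal(nrow(res$assignments), 8)
  expect_length(res$unassigned, 0)
})
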
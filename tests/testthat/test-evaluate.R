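test_that("clustering merges near-identical peptides and splits distant ones", {
  set.seed(23)
  base <- random_peptide(200)
  same <- Biostrings::AAStringSet(c(a = base, b = base))
  cl <- cluster_peptides(same)
  expect_length(cl$representatives, 1)
  expect_equal(nrow(cl$membership), 2)
  expect_equal(unique(cl$membership$representative), "a")

  far <- Biostrings::AAStringSet(c(a = base, b = random_peptide(200)))
  cl2 <- cluster_peptides(far)
  expect_length(cl2$representatives, 2)

  # a family of five ~95%-identical homologs collapses to one cluster;
  # the pairwise identities are checked with the independent NW oracle
  fam <- setNames(c(base, vapply(1:4, function(i) mutate_peptide(base, 0.05),
                                 "")), sprintf("h%d", 1:5))
  pids <- combn(5, 2, function(ij) global_identity(fam[ij[1]], fam[ij[2]]))
  expect_true(all(pids >= 0.9))
  cl3 <- cluster_peptides(Biostrings::AAStringSet(fam))
  expect_length(cl3$representatives, 1)
})

test_that("mutual-best-hit classification labels TP, DUP and FP", {
  set.seed(24)
  truth <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) random_peptide(180), ""), sprintf("t%d", 1:4)))

  # perfect detection
  ev <- classify_detections(truth, truth)
  expect_equal(ev$tp, 4)
  expect_equal(ev$fp + ev$dup + ev$fn, 0)

  # one dissimilar detection is an FP, one truth stays undetected (FN)
  det <- Biostrings::AAStringSet(c(truth[1:3],
                                   c(junk = random_peptide(180))))
  ev2 <- classify_detections(det, truth)
  expect_equal(ev2$tp, 3)
  expect_equal(ev2$fp, 1)
  expect_equal(ev2$fn, 1)
  expect_equal(ev2$labels[detected_id == "junk", label], "FP")

  # two detections hitting one truth: full copy is TP, fragment is DUP
  frag <- Biostrings::subseq(truth[[1]], 1, 100)
  det3 <- Biostrings::AAStringSet(c(full = as.character(truth[[1]]),
                                    piece = as.character(frag)))
  ev3 <- classify_detections(det3, truth[1])
  expect_equal(ev3$labels[detected_id == "full", label], "TP")
  expect_equal(ev3$labels[detected_id == "piece", label], "DUP")

  # empty truth set: everything is FP
  ev4 <- classify_detections(det3, Biostrings::AAStringSet())
  expect_equal(ev4$fp, 2)
})

test_that("metrics reproduce the printed formulas and handle empties", {
  fake_eval <- function(tp, fp, dup, fn) {
    structure(list(tp = tp, fp = fp, dup = dup, fn = fn,
                   labels = data.table(detected_id = character(),
                                       label = character(),
                                       best_truth = character()),
                   truth_status = data.table(truth_id = character(),
                                             detected = logical())),
              class = "detection_eval")
  }
  m <- compute_metrics(fake_eval(8, 2, 0, 2))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$uniqueness, 1.0)

  m2 <- compute_metrics(fake_eval(0, 0, 0, 10))
  expect_equal(m2$sensitivity, 0)
  expect_true(is.na(m2$ppv))  # undefined, not zero
})

test_that("depth stratification restricts TP/FN to the bin", {
  set.seed(25)
  truth <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) random_peptide(150), ""), sprintf("t%d", 1:6)))
  det <- truth[c(1, 2, 5)]
  ev <- classify_detections(det, truth)
  depths <- setNames(c(1, 3, 4, 8, 20, 50), names(truth))
  m <- compute_metrics(ev, truth_depths = depths)
  low <- m[stratum == "depth(0,5]"]
  high <- m[stratum == "depth(5,Inf]"]
  # low bin holds t1..t3 (detected t1, t2); high bin t4..t6 (detected t5)
  expect_equal(low$tp, 2)
  expect_equal(low$fn, 1)
  expect_equal(high$tp, 1)
  expect_equal(high$fn, 2)
  expect_equal(low$sensitivity, 2 / 3)
  expect_true(is.na(low$ppv))  # FPs carry no truth depth
})

test_that("classification counts respect the set-level invariants", {
  set.seed(26)
  for (i in 1:5) {
    n_t <- sample(3:6, 1)
    truth <- Biostrings::AAStringSet(setNames(
      vapply(seq_len(n_t), function(i) random_peptide(150), ""),
      sprintf("t%d", seq_len(n_t))))
    pick <- sample(n_t, sample(n_t, 1))
    det <- c(truth[pick],
             Biostrings::AAStringSet(setNames(
               vapply(1:2, function(i) random_peptide(150), ""),
               c("x1", "x2"))))
    ev <- classify_detections(det, truth)
    expect_equal(ev$tp + ev$fp + ev$dup, length(det))
    expect_equal(ev$tp + ev$fn, length(truth))
    expect_lte(ev$tp, min(length(det), length(truth)))
  }
})

test_that("baseline detectors report all-hit and unique-hit subjects", {
  a <- tiny_aset(aln_row("r1", "A", pident = 100, bitscore = 60),
                 aln_row("r1", "B", pident = 100, bitscore = 60),
                 aln_row("r2", "A", pident = 100, bitscore = 55,
                         sstart = 11, send = 20),
                 aln_row("r3", "C", pident = 95, bitscore = 40),
                 lengths = c(A = 30L, B = 30L, C = 30L))
  expect_setequal(detect_all_hits(a), c("A", "B", "C"))
  # r1 ties A/B (not unique); r2 and r3 are unique
  expect_setequal(detect_unique_hits(a), c("A", "C"))
})
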
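# Benchmarking harness: greedy 90%-identity clustering of detected and true
# CDS, mutual-best-hit classification of detections as TP / FP / DUP, and
# sensitivity / PPV / uniqueness metrics, overall and stratified by the
# coverage depth of the true CDS.

#' Greedy clustering of peptides by global identity
#'
#' Sequences are taken longest-first (ties by name for determinism); each
#' sequence joins the earliest-founded representative whose global identity
#' (matches over alignment columns) reaches `identity`, else founds a new
#' cluster -- the CD-HIT strategy. A k-mer prefilter restricts the identity
#' computations to plausible pairs.
#'
#' @param peptides Named `AAStringSet` (or character vector).
#' @param identity Identity threshold (default 0.9).
#' @param k Prefilter k-mer size.
#' @param min_share_frac Minimum fraction of the query's k-mers that must
#'   occur in a representative for it to be compared.
#' @return List with `representatives` (`AAStringSet`) and `membership`
#'   (data.table: id, representative).
#' @export
cluster_peptides <- function(peptides, identity = 0.9, k = 5,
                             min_share_frac = 0.1) {
  if (length(peptides) == 0) input_error("empty peptide set")
  pep <- Biostrings::AAStringSet(peptides)
  if (is.null(names(pep))) names(pep) <- sprintf("seq%05d", seq_along(pep))
  ord <- order(-Biostrings::width(pep), names(pep))
  sorted <- pep[ord]
  rep_idx <- cpp_greedy_cluster(as.character(sorted), identity, as.integer(k),
                                min_share_frac, 2L, -1L, 4L, 1L)
  membership <- data.table(id = names(sorted),
                           representative = names(sorted)[rep_idx])
  reps <- sorted[sort(unique(rep_idx))]
  list(representatives = reps, membership = membership)
}

#' Classify detected CDS against the truly present CDS
#'
#' All-vs-all local protein alignment of detected against true CDS (both
#' sets are expected to be cluster representatives from
#' [cluster_peptides()]). A detected CDS "aligns against" a truth when the
#' local alignment reaches `min_identity` over at least `min_coverage` of
#' the shorter sequence. Each detected CDS keeps its top-hit truth
#' (bitscore-like raw score, ties by identity then id); it is a true
#' positive (TP) iff it is also that truth's best-scoring detected hit
#' (mutual best hit), a duplicate (DUP) if it aligns to some truth without
#' being its best hit, and a false positive (FP) if it aligns to no truth.
#' Every truth without a TP counts as a false negative (FN).
#'
#' @param detected,truth Named `AAStringSet`s.
#' @param min_identity Identity floor (fraction of aligned columns).
#' @param min_coverage Alignment-span floor (fraction of the shorter
#'   sequence).
#' @param k Seed k-mer size for the alignment prefilter.
#' @return Object of class `detection_eval`: `labels` (data.table:
#'   detected_id, label, best_truth), `truth_status` (data.table: truth_id,
#'   detected), and the counts TP/FP/DUP/FN.
#' @export
classify_detections <- function(detected, truth, min_identity = 0.5,
                                min_coverage = 0.5, k = 6) {
  det <- Biostrings::AAStringSet(detected)
  tru <- Biostrings::AAStringSet(truth)
  empty_eval <- function(labels, truth_status) {
    structure(list(labels = labels, truth_status = truth_status,
                   tp = sum(labels$label == "TP"),
                   fp = sum(labels$label == "FP"),
                   dup = sum(labels$label == "DUP"),
                   fn = sum(!truth_status$detected)),
              class = "detection_eval")
  }
  if (length(det) == 0) {
    return(empty_eval(
      data.table(detected_id = character(), label = character(),
                 best_truth = character()),
      data.table(truth_id = names(tru),
                 detected = logical(length(tru)))))
  }
  if (length(tru) == 0) {
    return(empty_eval(
      data.table(detected_id = names(det), label = "FP",
                 best_truth = NA_character_),
      data.table(truth_id = character(), detected = logical(0))))
  }

  hits <- as.data.table(cpp_batch_search(
    as.character(det), as.character(tru), blosum62(), blosum62_alphabet(),
    as.integer(k), 20, 11L, 1L, 2L, 32L))
  if (nrow(hits)) {
    wd <- Biostrings::width(det)[hits$query]
    wt <- Biostrings::width(tru)[hits$ref]
    shorter <- pmin(wd, wt)
    span <- pmin(hits$qend - hits$qstart + 1, hits$send - hits$sstart + 1)
    hits[, identity := matches / length]
    hits <- hits[identity >= min_identity & span / shorter >= min_coverage]
  }

  labels <- data.table(detected_id = names(det), label = "FP",
                       best_truth = NA_character_)
  truth_status <- data.table(truth_id = names(tru),
                             detected = logical(length(tru)))
  if (nrow(hits)) {
    hits[, det_id := names(det)[query]]
    hits[, truth_id := names(tru)[ref]]
    setorder(hits, query, -score, -identity, truth_id)
    top_per_det <- hits[!duplicated(query)]
    setorder(hits, ref, -score, -identity, det_id)
    best_det_of_truth <- hits[!duplicated(ref), .(truth_id, best_det = det_id)]
    cls <- merge(top_per_det[, .(det_id, truth_id, score)],
                 best_det_of_truth, by = "truth_id", all.x = TRUE)
    cls[, label := fifelse(det_id == best_det, "TP", "DUP")]
    labels[match(cls$det_id, detected_id),
           `:=`(label = cls$label, best_truth = cls$truth_id)]
    tp_truths <- cls[label == "TP", truth_id]
    truth_status[truth_id %chin% tp_truths, detected := TRUE]
  }
  empty_eval(labels, truth_status)
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("detection_eval: TP %d, FP %d, DUP %d, FN %d\n",
              x$tp, x$fp, x$dup, x$fn))
  invisible(x)
}

#' Sensitivity, PPV and uniqueness from classified detections
#'
#' Sensitivity = TP / (TP + FN); PPV = TP / (TP + FP); uniqueness =
#' TP / (TP + DUP). When truth depths are supplied, sensitivity and
#' uniqueness are additionally computed within depth bins (default 0-5x and
#' >5x), restricting TP/FN (and DUP via its best truth) to true CDS whose
#' depth falls in the bin; PPV is not stratified because false positives
#' carry no truth depth. Empty denominators yield `NA` (undefined), not 0.
#'
#' @param eval A `detection_eval` from [classify_detections()].
#' @param truth_depths Named numeric vector of per-truth coverage depths
#'   (names matching truth ids), or NULL for overall metrics only.
#' @param depth_bins Increasing break points defining the bins (left-open).
#' @return data.table with one row per stratum ("overall" first):
#'   stratum, tp, fp, dup, fn, sensitivity, ppv, uniqueness.
#' @export
compute_metrics <- function(eval, truth_depths = NULL,
                            depth_bins = c(0, 5, Inf)) {
  stopifnot(inherits(eval, "detection_eval"))
  frac <- function(num, den) {
    if (is.na(den) || den == 0) NA_real_ else num / den
  }
  row <- function(stratum, tp, fp, dup, fn) {
    data.table(stratum = stratum, tp = tp, fp = fp, dup = dup, fn = fn,
               sensitivity = frac(tp, tp + fn), ppv = frac(tp, tp + fp),
               uniqueness = frac(tp, tp + dup))
  }
  out <- row("overall", eval$tp, eval$fp, eval$dup, eval$fn)
  if (!is.null(truth_depths)) {
    ts <- copy(eval$truth_status)
    ts[, depth := truth_depths[truth_id]]
    lb <- eval$labels
    dup_depth <- truth_depths[lb[label == "DUP", best_truth]]
    for (b in seq_len(length(depth_bins) - 1)) {
      lo <- depth_bins[b]
      hi <- depth_bins[b + 1]
      inbin <- ts[!is.na(depth) & depth > lo & depth <= hi]
      dups <- sum(!is.na(dup_depth) & dup_depth > lo & dup_depth <= hi)
      out <- rbind(out, row(sprintf("depth(%g,%g]", lo, hi),
                            tp = sum(inbin$detected), fp = NA_integer_,
                            dup = dups, fn = sum(!inbin$detected)))
    }
    out[is.na(fp), ppv := NA_real_]
  }
  out[]
}

#' Baseline detection strategies
#'
#' `detect_all_hits()` reports every reference with at least one alignment
#' in the set; `detect_unique_hits()` reports references supported by at
#' least one uniquely mapping read -- a read whose top-hit candidate set
#' (ties with its best alignment) contains exactly one reference.
#'
#' @param alignments An [alignment_set()].
#' @return Character vector of detected subject ids.
#' @export
detect_all_hits <- function(alignments) {
  sort(unique(alignments$records$subject))
}

#' @rdname detect_all_hits
#' @export
detect_unique_hits <- function(alignments) {
  top <- accept_best(alignments, tolerance_pct = 0)$records
  uniq_q <- top[, .N, by = query][N == 1, query]
  sort(unique(top[query %chin% uniq_q, subject]))
}
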
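# End-to-end experiments: the three-CDS convergence fixture (a small
# community whose reference set is salted with domain-sharing decoys) and
# the strategy benchmark comparing EM-based detection against the all-hits
# and unique-hits mapping baselines on a full synthetic community.

#' Three-CDS convergence experiment
#'
#' Simulates a fixed number of error-free read pairs from each of
#' `n_truths` CDS, aligns them (emulated translated alignment) against a
#' reference set containing the truths plus `n_decoys_per_truth`
#' domain-sharing decoys per truth (so reads drawn from the conserved
#' domain genuinely multi-map), applies the top-N% acceptance rule and runs
#' the resolution algorithm. Reports how many reads end up assigned to
#' their true origin.
#'
#' @param seed Integer seed.
#' @param n_truths Number of true CDS.
#' @param reads_per_cds Read pairs per true CDS.
#' @param n_decoys_per_truth Decoys sharing each truth's conserved domain.
#' @param domain_length,unique_length Family geometry (aa); see
#'   [make_homolog_family()].
#' @param tolerance_pct Acceptance band applied before the algorithm.
#' @param params Algorithm parameters ([cdsem_params()]).
#' @return List: `result` (`cdsem_result`), `fraction_correct`,
#'   `mean_candidates_per_read` (before any filtering),
#'   `n_retained`, `n_reads`, `alignments` (the accepted
#'   [alignment_set()]), `origins`.
#' @export
convergence_experiment <- function(seed = 1, n_truths = 3,
                                   reads_per_cds = 120,
                                   n_decoys_per_truth = 10,
                                   domain_length = 60, unique_length = 540,
                                   tolerance_pct = 10,
                                   params = cdsem_params()) {
  set.seed(seed)
  fams <- lapply(seq_len(n_truths), function(i) {
    fam <- make_homolog_family(n_decoys_per_truth + 1, domain_length,
                               unique_length)
    names(fam) <- c(sprintf("truth%02d", i),
                    sprintf("truth%02d_decoy%02d", i,
                            seq_len(n_decoys_per_truth)))
    fam
  })
  reference <- do.call(c, fams)
  truths <- reference[sprintf("truth%02d", seq_len(n_truths))]
  reads <- simulate_cds_reads(reverse_translate(truths), reads_per_cds,
                              sim_params())
  tbl <- emulate_alignment(reads, reference)
  aset <- alignment_set(tbl)
  mean_cand <- nrow(aset$records) / length(unique(aset$records$query))
  accepted <- accept_best(aset, tolerance_pct)
  result <- run_cdsem(accepted, params)
  truth_map <- setNames(reads$origins$cds_id, reads$origins$read_id)
  correct <- result$assignments[, subject == truth_map[query]]
  list(result = result,
       fraction_correct = sum(correct) / length(reads$fwd),
       mean_candidates_per_read = mean_cand,
       n_retained = length(result$retained_subjects),
       n_reads = length(reads$fwd),
       alignments = accepted,
       origins = reads$origins)
}

#' Compare detection strategies on one synthetic community
#'
#' Simulates a community ([simulate_community()]), draws reads at the
#' per-genome depths, emulates translated alignment against the full
#' reference database (community CDS plus homolog/decoy entries), applies
#' the top-N% acceptance rule, and detects CDS three ways: the EM-based
#' algorithm ([run_cdsem()]), mapping all-hits, and mapping unique-hits.
#' Detected and true CDS sets are clustered at 90% amino-acid identity and
#' detections are classified as TP/FP/DUP via mutual best hits
#' ([classify_detections()]); sensitivity/PPV/uniqueness are computed
#' overall and for the 0-5x depth stratum.
#'
#' @param params A [sim_params()] object (community structure and depths).
#' @param seed Integer seed for the whole experiment.
#' @param tolerance_pct Acceptance band for the alignment set the
#'   strategies consume.
#' @param cdsem A [cdsem_params()] object.
#' @param depth_bins Depth strata for [compute_metrics()].
#' @return List with `metrics` (named list of data.tables, one per
#'   strategy: `cdsem`, `all_hits`, `unique_hits`), `detected` (named list
#'   of id vectors), `result` (`cdsem_result`), `mean_candidates_per_read`,
#'   `n_read_pairs`, `n_truth_clusters`, and `community`.
#' @export
benchmark_strategies <- function(params = sim_params(), seed = 1,
                                 tolerance_pct = 10,
                                 cdsem = cdsem_params(),
                                 depth_bins = c(0, 5, Inf)) {
  community <- simulate_community(params, seed)
  reads <- simulate_reads(community)
  tbl <- emulate_alignment(reads, community$reference)
  aset <- accept_best(alignment_set(tbl), tolerance_pct)
  mean_cand <- nrow(aset$records) / length(unique(aset$records$query))

  result <- run_cdsem(aset, cdsem)
  detected <- list(cdsem = result$retained_subjects,
                   all_hits = detect_all_hits(aset),
                   unique_hits = detect_unique_hits(aset))

  truth_cl <- cluster_peptides(community$cds_peptides)
  depth_by_cds <- setNames(community$cds_info$depth, community$cds_info$cds_id)
  memb <- copy(truth_cl$membership)
  memb[, depth := depth_by_cds[id]]
  # reads from all members of a cluster pool onto its representative
  rep_depth <- memb[, .(depth = sum(depth)), by = representative]
  truth_depths <- setNames(rep_depth$depth, rep_depth$representative)

  metrics <- lapply(detected, function(ids) {
    if (length(ids) == 0) {
      ev <- classify_detections(Biostrings::AAStringSet(),
                                truth_cl$representatives)
      return(compute_metrics(ev, truth_depths, depth_bins))
    }
    det_cl <- cluster_peptides(community$reference[ids])
    ev <- classify_detections(det_cl$representatives,
                              truth_cl$representatives)
    compute_metrics(ev, truth_depths, depth_bins)
  })

  list(metrics = metrics, detected = detected, result = result,
       mean_candidates_per_read = mean_cand,
       n_read_pairs = length(reads$fwd),
       n_truth_clusters = length(truth_cl$representatives),
       community = community)
}
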
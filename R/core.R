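# The multi-mapping resolution algorithm proper: bitscore-initialized
# per-query scores, iterative weighting/renormalization and pruning, and the
# final evenness re-filter on the deduplicated assignments.

#' Algorithm parameters
#'
#' @param evenness_threshold Coverage-CV threshold for [evenness_filter()]
#'   (default 1.0; references with CV strictly above it are removed).
#' @param prune_ratio Relative pruning threshold in (0, 1]: after each
#'   reweighting, candidates whose score falls below
#'   `prune_ratio * max(score)` for their query are dropped. The per-query
#'   maximum (and ties with it) always survives.
#' @param max_iterations Iteration cap; the loop also stops as soon as an
#'   iteration prunes nothing.
#' @param weighted_first_filter Use score-weighted (rather than unweighted)
#'   coverage for the first evenness pass.
#' @return An object of class `cdsem_params`.
#' @export
cdsem_params <- function(evenness_threshold = 1.0, prune_ratio = 0.5,
                         max_iterations = 10L,
                         weighted_first_filter = FALSE) {
  if (prune_ratio <= 0 || prune_ratio > 1) {
    input_error("prune_ratio must be in (0, 1]")
  }
  if (max_iterations < 1) input_error("max_iterations must be >= 1")
  if (evenness_threshold <= 0) {
    input_error("evenness_threshold must be > 0")
  }
  structure(list(evenness_threshold = evenness_threshold,
                 prune_ratio = prune_ratio,
                 max_iterations = as.integer(max_iterations),
                 weighted_first_filter = isTRUE(weighted_first_filter)),
            class = "cdsem_params")
}

#' Initialize per-query scores from bitscores
#'
#' The initial score of query q coming from subject s is
#' `bitscore(q, s) / sum_s' bitscore(q, s')`, so scores sum to 1 for each
#' query.
#'
#' @param alignments An [alignment_set()] (or its records data.table).
#' @return data.table with columns query, subject, score.
#' @export
init_scores <- function(alignments) {
  rec <- if (inherits(alignments, "alignment_set")) {
    alignments$records
  } else {
    as.data.table(alignments)
  }
  # one candidacy per (query, subject); a pair aligned through both mates
  # contributes the sum of its records' bitscores as evidence
  s <- rec[, .(score = sum(bitscore)), by = .(query, subject)]
  s[, total := sum(score), by = query]
  if (any(s$total <= 0)) {
    input_error("query '%s' has zero total bitscore", s$query[s$total <= 0][1])
  }
  s[, score := score / total][, total := NULL]
  s[]
}

#' One weighting / renormalization step
#'
#' Each subject's weight is the sum of its scores over all queries in the
#' sample; each score is multiplied by its subject's weight and the scores
#' are renormalized to sum to 1 per query. Queries with a single candidate
#' are fixed points (their score stays exactly 1).
#'
#' @param scores data.table (query, subject, score) with per-query sums of 1.
#' @return Updated score table of the same shape.
#' @export
reweight_scores <- function(scores) {
  s <- copy(scores)
  s[, score := score * sum(score), by = subject]
  s[, score := score / sum(score), by = query]
  s[]
}

#' Prune low-likelihood candidates per query
#'
#' Drops, for each query, candidates whose score is strictly below
#' `prune_ratio` times that query's maximum score; survivors are
#' renormalized per query. Ties with the maximum always survive.
#'
#' @param scores data.table (query, subject, score).
#' @param prune_ratio Relative threshold in (0, 1].
#' @return List with `scores` (pruned, renormalized) and `n_pruned`.
#' @export
prune_scores <- function(scores, prune_ratio = 0.5) {
  s <- copy(scores)
  keep <- s[, .keep := score >= prune_ratio * max(score), by = query]$.keep
  s[, .keep := NULL]
  n_pruned <- sum(!keep)
  s <- s[keep]
  if (n_pruned > 0) s[, score := score / sum(score), by = query]
  list(scores = s[], n_pruned = n_pruned)
}

#' Resolve multi-mapped reads to a single reference each
#'
#' The full pipeline: (1) unweighted coverage and evenness filtering of
#' candidate references; (2) bitscore score initialization; (3) iterative
#' weighting/renormalization and pruning until an iteration prunes nothing
#' or `max_iterations` is reached; (4) deterministic final assignment of
#' each query to one subject (highest score, ties broken by higher subject
#' weight, then lexicographically smallest subject id); (5) re-computation
#' of coverage from the deduplicated one-subject-per-query alignments and a
#' final evenness filter. Queries whose final subject fails that last check
#' (or whose every candidate was removed up front) are reported as
#' unassigned rather than silently dropped.
#'
#' @param alignments An [alignment_set()], already acceptance-filtered if
#'   desired (see [accept_best()]).
#' @param params A [cdsem_params()] object.
#' @return Object of class `cdsem_result`: `assignments` (data.table query,
#'   subject), `retained_subjects`, `unassigned` (character vector of
#'   queries), `iterations_run`, `candidate_counts` (candidate (query,
#'   subject) pairs before iterating and after each iteration),
#'   `subjects_after_first_filter`, `coverage` (final per-subject coverage
#'   of retained references) and `subject_lengths`.
#' @export
run_cdsem <- function(alignments, params = cdsem_params()) {
  stopifnot(inherits(alignments, "alignment_set"))
  rec <- alignments$records
  empty <- function(unassigned = character(0), candidate_counts = integer(0),
                    iterations = 0L, n_first = 0L) {
    structure(list(assignments = data.table(query = character(),
                                            subject = character()),
                   retained_subjects = character(0), unassigned = unassigned,
                   iterations_run = iterations,
                   candidate_counts = candidate_counts,
                   subjects_after_first_filter = n_first,
                   coverage = structure(list(), names = character(0)),
                   subject_lengths = alignments$subject_lengths,
                   params = params),
              class = "cdsem_result")
  }
  if (nrow(rec) == 0) return(empty())

  all_queries <- unique(rec$query)

  # steps 2-3: coverage depth and evenness filtering of references
  first_weights <- if (params$weighted_first_filter) init_scores(rec) else NULL
  cov1 <- compute_coverage(alignments, weights = first_weights)
  keep1 <- evenness_filter(cov1, params$evenness_threshold)
  rec <- rec[subject %chin% keep1]
  if (nrow(rec) == 0) {
    warning("all reference subjects were removed by the evenness filter")
    return(empty(unassigned = all_queries, n_first = 0L))
  }
  unassigned_initial <- setdiff(all_queries, unique(rec$query))

  # step 4: initial scores; step 5: iterate weighting + pruning
  scores <- init_scores(rec)
  candidate_counts <- nrow(scores)
  iterations <- 0L
  for (i in seq_len(params$max_iterations)) {
    iterations <- i
    scores <- reweight_scores(scores)
    pr <- prune_scores(scores, params$prune_ratio)
    scores <- pr$scores
    candidate_counts <- c(candidate_counts, nrow(scores))
    if (pr$n_pruned == 0) break
  }

  # final deterministic assignment: score, then sample-wide subject weight,
  # then lexicographically smallest subject id
  s <- copy(scores)
  s[, W := sum(score), by = subject]
  setorder(s, query, -score, -W, subject)
  assign <- s[!duplicated(query), .(query, subject)]

  # repeat the coverage/evenness filtering on the deduplicated alignments
  dedup <- merge(rec, assign, by = c("query", "subject"), sort = FALSE)
  dedup_set <- structure(list(records = dedup,
                              subject_lengths = alignments$subject_lengths),
                         class = "alignment_set")
  cov2 <- compute_coverage(dedup_set)
  keep2 <- evenness_filter(cov2, params$evenness_threshold)
  final <- assign[subject %chin% keep2]
  unassigned_final <- assign[!subject %chin% keep2]$query
  retained <- sort(unique(final$subject))

  structure(list(assignments = final,
                 retained_subjects = retained,
                 unassigned = c(unassigned_initial, unassigned_final),
                 iterations_run = iterations,
                 candidate_counts = candidate_counts,
                 subjects_after_first_filter = length(keep1),
                 coverage = cov2[retained],
                 subject_lengths = alignments$subject_lengths,
                 params = params),
            class = "cdsem_result")
}

#' @export
print.cdsem_result <- function(x, ...) {
  cat(sprintf(
    "cdsem_result: %d reads assigned to %d references (%d unassigned)\n",
    nrow(x$assignments), length(x$retained_subjects), length(x$unassigned)))
  cat(sprintf("  iterations: %d; candidate pairs: %s\n", x$iterations_run,
              paste(x$candidate_counts, collapse = " -> ")))
  invisible(x)
}

#' Per-reference detection summary
#'
#' One row per retained reference: id, length (aa), number of assigned
#' reads, mean and population-SD coverage depth, and the fraction of
#' positions covered by at least one assigned read.
#'
#' @param result A `cdsem_result` from [run_cdsem()].
#' @return data.table with columns id, length, nreads, depth_mean,
#'   depth_sd, coverage_fraction, ordered by decreasing nreads then id.
#' @export
summarize_detections <- function(result) {
  stopifnot(inherits(result, "cdsem_result"))
  if (length(result$retained_subjects) == 0) {
    return(data.table(id = character(), length = integer(),
                      nreads = integer(), depth_mean = numeric(),
                      depth_sd = numeric(), coverage_fraction = numeric()))
  }
  nreads <- result$assignments[, .N, by = subject]
  rows <- rbindlist(lapply(result$coverage, function(cv) {
    data.table(id = cv$subject_id, length = length(cv$depth),
               depth_mean = cv$mean_depth, depth_sd = cv$sd_depth,
               coverage_fraction = mean(cv$depth > 0))
  }))
  out <- merge(rows, nreads, by.x = "id", by.y = "subject")
  setnames(out, "N", "nreads")
  setcolorder(out, c("id", "length", "nreads", "depth_mean", "depth_sd",
                     "coverage_fraction"))
  setorder(out, -nreads, id)
  setkey(out, NULL)
  out[]
}

#' Write a detection report as TSV and/or JSON
#'
#' @param report data.table from [summarize_detections()].
#' @param tsv,json Output paths (either may be NULL).
#' @param config,seed Provenance recorded in the output header.
#' @export
write_detection_report <- function(report, tsv = NULL, json = NULL,
                                   config = list(), seed = NULL) {
  if (!is.null(tsv)) {
    writeLines(provenance_lines(config, seed), tsv)
    fwrite(report, tsv, sep = "\t", append = TRUE, col.names = TRUE)
  }
  if (!is.null(json)) {
    payload <- list(provenance = list(
                      version = as.character(utils::packageVersion("cdsem")),
                      seed = seed, config = config_hash(config)),
                    detections = report)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
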
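# Per-reference amino-acid coverage vectors and the coverage-evenness
# (coefficient-of-variation) filter.

#' Build per-reference coverage vectors
#'
#' Each alignment adds 1 -- or, when `weights` are supplied, its current
#' query-to-subject score -- to every amino-acid position in
#' `[sstart, send]` of its subject. Positions never covered count as zeros
#' in the mean and standard deviation, which run over the full subject
#' length.
#'
#' @param alignments An [alignment_set()].
#' @param weights Optional score table (data.table with columns query,
#'   subject, score, e.g. from [init_scores()]); alignments without a
#'   surviving score are ignored.
#' @return Named list of `coverage_vector` objects (one per subject with at
#'   least one contributing alignment): each has `subject_id`, `depth`
#'   (numeric vector over the full subject length), `mean_depth`, `sd_depth`
#'   (population SD).
#' @export
compute_coverage <- function(alignments, weights = NULL) {
  rec <- alignments$records[, .(query, subject, sstart, send)]
  if (is.null(weights)) {
    rec[, w := 1]
  } else {
    rec <- merge(rec, as.data.table(weights)[, .(query, subject, score)],
                 by = c("query", "subject"), sort = FALSE)
    setnames(rec, "score", "w")
  }
  if (nrow(rec) == 0) return(structure(list(), names = character(0)))
  lens <- alignments$subject_lengths
  groups <- split(rec, by = "subject", keep.by = FALSE)
  out <- lapply(names(groups), function(sid) {
    g <- groups[[sid]]
    L <- lens[[sid]]
    delta <- numeric(L + 1L)
    add <- rowsum(g$w, g$sstart)
    delta[as.integer(rownames(add))] <- add[, 1]
    ends <- pmin(g$send + 1L, L + 1L)
    subp <- rowsum(g$w, ends)
    idx <- as.integer(rownames(subp))
    delta[idx] <- delta[idx] - subp[, 1]
    depth <- cumsum(delta)[seq_len(L)]
    coverage_vector(sid, depth)
  })
  names(out) <- names(groups)
  out
}

#' @rdname compute_coverage
#' @param subject_id Subject identifier.
#' @param depth Numeric depth vector over the full subject length.
#' @export
coverage_vector <- function(subject_id, depth) {
  m <- mean(depth)
  # population SD: the vector is the complete coverage profile, not a sample
  s <- sqrt(mean((depth - m)^2))
  structure(list(subject_id = subject_id, depth = depth,
                 mean_depth = m, sd_depth = s),
            class = "coverage_vector")
}

#' @export
print.coverage_vector <- function(x, ...) {
  cat(sprintf("coverage_vector '%s': length %d, mean %.3f, sd %.3f, CV %.3f\n",
              x$subject_id, length(x$depth), x$mean_depth, x$sd_depth,
              coverage_cv(x)))
  invisible(x)
}

#' Coverage coefficient of variation (SD / mean)
#'
#' @param x A `coverage_vector`.
#' @return CV; `Inf` for an uncovered vector (mean 0), 0 for uniform ones.
#' @export
coverage_cv <- function(x) {
  if (x$mean_depth == 0) return(Inf)
  x$sd_depth / x$mean_depth
}

#' Filter references by coverage evenness
#'
#' Retains a subject iff its coverage coefficient of variation
#' (SD over mean of per-position depth) is at most `threshold`; strictly
#' greater values indicate uneven, domain-only recruitment and are filtered.
#' Subjects with zero mean depth are filtered. The criterion is scale-free:
#' multiplying a coverage vector by a constant does not change the outcome.
#'
#' @param coverage Named list of `coverage_vector`s from [compute_coverage()].
#' @param threshold CV threshold, > 0 (default 1.0).
#' @return Character vector of retained subject ids (in input order).
#' @export
evenness_filter <- function(coverage, threshold = 1.0) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0) {
    input_error("evenness threshold must be a single number > 0")
  }
  keep <- vapply(coverage, function(cv) {
    cv$mean_depth > 0 && cv$sd_depth / cv$mean_depth <= threshold
  }, logical(1))
  names(coverage)[keep]
}

#' Export coverage vectors as per-position TSV (for inspection)
#'
#' @param coverage Named list of `coverage_vector`s.
#' @param path Output path; columns subject, position (1-based aa), depth.
#' @export
export_coverage <- function(coverage, path) {
  dt <- rbindlist(lapply(coverage, function(cv) {
    data.table(subject = cv$subject_id, position = seq_along(cv$depth),
               depth = cv$depth)
  }))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
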
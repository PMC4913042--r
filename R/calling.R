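#' Train the support threshold from labeled scores
#'
#' The threshold separating true from false junctions is placed midway between
#' the lowest-scoring true positive `t` and the highest false positive
#' strictly below it. When no false positive lies below `t` the fallback is
#' `t / 2`. The returned value is always strictly below every true positive,
#' so the training set is called with full sensitivity. Scores are on the
#' `log10(S)` scale.
#'
#' @param labeled tibble (or data frame) with columns `log10_S` and `is_true`.
#' @return numeric threshold.
#' @export
train_threshold <- function(labeled) {
  stopifnot(all(c("log10_S", "is_true") %in% names(labeled)))
  truths <- labeled$log10_S[labeled$is_true]
  truths <- truths[is.finite(truths)]
  if (length(truths) == 0) abort("train_threshold: no true-labeled scores")
  t <- min(truths)
  falses <- labeled$log10_S[!labeled$is_true]
  falses <- falses[is.finite(falses) & falses < t]
  if (length(falses) == 0) return(t / 2)
  (t + max(falses)) / 2
}

#' Caller configuration
#'
#' @param threshold decision threshold on the `log10(S)` scale.
#' @param collapse_window window in bases for collapsing similar calls
#'   (default 500).
#' @param comparison_window window for call-set comparison (default 500).
#' @param use_adjusted compare the coverage-adjusted score against the
#'   threshold (default `FALSE`).
#' @return list of class `st_caller_config`.
#' @export
caller_config <- function(threshold, collapse_window = 500,
                          comparison_window = 500, use_adjusted = FALSE) {
  stopifnot(collapse_window >= 0, comparison_window >= 0)
  structure(list(threshold = threshold, collapse_window = collapse_window,
                 comparison_window = comparison_window,
                 use_adjusted = use_adjusted),
            class = "st_caller_config")
}

#' Threshold scored junctions into SV calls
#'
#' Joins scores back onto their junction records, marks junctions whose
#' (optionally coverage-adjusted) `log10(S)` is at or above the threshold as
#' passed (the comparison is closed: a score exactly at threshold passes), and
#' ranks calls by descending score with coordinate ties broken
#' lexicographically.
#'
#' @param scores score tibble from [score_junctions()].
#' @param junctions junction tibble from [build_junctions()].
#' @param config [caller_config()].
#' @return call tibble: junction columns plus `S`, `log10_S`
#'   (`S_adjusted`/`log10_S_adjusted` when present), `n_reads`, `passed`,
#'   `rank`.
#' @export
call_svs <- function(scores, junctions, config) {
  calls <- left_join(junctions, scores, by = "junction_id")
  if (nrow(calls) == 0) {
    calls$passed <- logical(0); calls$rank <- integer(0)
    return(calls)
  }
  cmp <- if (isTRUE(config$use_adjusted) && "log10_S_adjusted" %in% names(calls))
    calls$log10_S_adjusted else calls$log10_S
  calls$passed <- cmp >= config$threshold
  ord <- order(-cmp, calls$chromA, calls$posA, calls$chromB, calls$posB,
               calls$orientA, calls$orientB)
  calls <- calls[ord, , drop = FALSE]
  calls$rank <- seq_len(nrow(calls))
  calls
}

#' Collapse similar calls into single representatives
#'
#' Calls sharing chromosome pair, SV class and orientation pair whose two
#' breakpoints each lie within `window` bases of another call's corresponding
#' breakpoints are clustered by single linkage; the highest-scoring member
#' (ties to the smallest coordinates) represents the cluster and keeps its own
#' score. The operation is idempotent. Reciprocal-translocation derivatives
#' carry different orientation pairs and therefore never merge.
#'
#' @param calls call tibble from [call_svs()].
#' @param window linkage window in bases (default 500).
#' @return representatives with `cluster_id` and `cluster_size` columns.
#' @export
collapse_calls <- function(calls, window = 500) {
  stopifnot(window >= 0)
  if (nrow(calls) == 0) {
    calls$cluster_id <- character(0); calls$cluster_size <- integer(0)
    return(calls)
  }
  key <- paste(calls$chromA, calls$chromB, calls$sv_class,
               calls$orientA, calls$orientB, sep = "\r")
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (key[i] == key[j] &&
          abs(calls$posA[i] - calls$posA[j]) <= window &&
          abs(calls$posB[i] - calls$posB[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- lapply(split(seq_len(n), root), function(idx) {
    m <- calls[idx, , drop = FALSE]
    ord <- order(-m$log10_S, m$posA, m$posB)
    r <- m[ord[1], , drop = FALSE]
    r$cluster_size <- length(idx)
    r
  })
  out <- bind_rows(reps)
  out$cluster_id <- paste0("c", seq_len(nrow(out)))
  arrange(out, desc(.data$log10_S), .data$chromA, .data$posA)
}

#' Compare two call sets within a breakpoint window
#'
#' A call in set A matches set B when some B call shares its chromosome pair
#' and has both breakpoints within `window` bases. Matching is one-to-one and
#' greedy on total breakpoint distance (deterministic; coordinate ties break
#' lexicographically), so the intersection count is symmetric.
#'
#' @param a,b call tibbles (need `chromA, posA, chromB, posB`).
#' @param window matching window in bases (default 500).
#' @return list: `n_a`, `n_b`, `n_intersect`, `matches` (index pairs with
#'   distances), `only_a`, `only_b` (row indices).
#' @export
compare_call_sets <- function(a, b, window = 500) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chromA[i] == b$chromA[j] && a$chromB[i] == b$chromB[j] &&
          abs(a$posA[i] - b$posA[j]) <= window &&
          abs(a$posB[i] - b$posB[j]) <= window) {
        pairs[[length(pairs) + 1]] <- c(i, j,
                                        abs(a$posA[i] - b$posA[j]) +
                                          abs(a$posB[i] - b$posB[j]))
      }
    }
  }
  matches <- tibble(i = integer(), j = integer(), dist = integer())
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    ord <- order(pm[, 3], pm[, 1], pm[, 2])
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- list()
    for (k in ord) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        keep[[length(keep) + 1]] <- pm[k, ]
      }
    }
    km <- do.call(rbind, keep)
    matches <- tibble(i = km[, 1], j = km[, 2], dist = km[, 3])
  }
  list(n_a = nrow(a), n_b = nrow(b), n_intersect = nrow(matches),
       matches = matches,
       only_a = setdiff(seq_len(nrow(a)), matches$i),
       only_b = setdiff(seq_len(nrow(b)), matches$j))
}

#' Evaluate calls against a planted truth table
#'
#' Passed calls are matched one-to-one to truth junctions (same chromosome
#' pair, both breakpoints within `window`). Sensitivity is matched truths over
#' all truths; PPV is matched passed calls over all passed calls (`NA` when
#' nothing passed).
#'
#' @param calls call tibble (only `passed` rows are evaluated).
#' @param truth truth tibble with `chromA, posA, chromB, posB, sv_class`.
#' @param window matching window in bases (default 500; use 0 to demand exact
#'   breakpoints).
#' @return list: `sensitivity`, `ppv`, `n_truth`, `n_called`, `n_matched`,
#'   `by_class` (per-class tibble), `matches`.
#' @export
evaluate_against_truth <- function(calls, truth, window = 500) {
  if (nrow(truth) == 0) abort("evaluate_against_truth: empty truth table")
  passed <- calls[which(calls$passed), , drop = FALSE]
  cmpr <- compare_call_sets(passed, truth, window)
  matched_truth <- cmpr$matches$j
  by_class <- truth |>
    mutate(matched = seq_len(nrow(truth)) %in% matched_truth) |>
    group_by(.data$sv_class) |>
    summarise(n_truth = n(), n_matched = sum(.data$matched), .groups = "drop")
  list(
    sensitivity = cmpr$n_intersect / nrow(truth),
    ppv = if (nrow(passed) == 0) NA_real_ else cmpr$n_intersect / nrow(passed),
    n_truth = nrow(truth), n_called = nrow(passed),
    n_matched = cmpr$n_intersect,
    by_class = by_class, matches = cmpr$matches
  )
}
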
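#' Targeted structural-variant calling
#'
#' Runs the full stack/tail pipeline over suspected region pairs: extract
#' soft-clipped reads, detect recurrent clip coordinates, pair compatible
#' candidates across the region pairs into a junction library, realign the
#' stacked reads to the library, score each junction with
#' `S = sum(Q * min(l_A, l_B))`, threshold on `log10(S)` and collapse similar
#' passed calls.
#'
#' @param alignments alignment tibble from [read_alignments()] or a SAM/BAM
#'   path.
#' @param reference reference accepted by [fetch_reference()].
#' @param region_pairs tibble from [region_pair()].
#' @param threshold decision threshold on the `log10(S)` scale.
#' @param min_tail minimum soft-clip tail length (default 10).
#' @param min_stack_reads minimum stack size (default 2).
#' @param fuzz clip-clustering slack in bases (default 0).
#' @param flank_len junction flank length; default: longest read + 50, so any
#'   junction-spanning read fits entirely within the candidate sequence.
#' @param max_per_kb optional candidate density cap per 1-kb window.
#' @param scheme [scoring_scheme()].
#' @param collapse_window collapse window in bases (default 500).
#' @param winner_takes_all see [score_junctions()].
#' @return object of class `st_callset`: list with `calls` (collapsed passed
#'   calls), `all_calls` (full ranked table), `scores`, `junctions`,
#'   `candidates`, `clipped`, `config`.
#' @export
sv_call_targeted <- function(alignments, reference, region_pairs, threshold,
                             min_tail = 10, min_stack_reads = 2, fuzz = 0,
                             flank_len = NULL, max_per_kb = NULL,
                             scheme = scoring_scheme(), collapse_window = 500,
                             winner_takes_all = FALSE) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  reference <- as_reference(reference)
  clipped <- extract_clipped_reads(alignments, min_tail = min_tail)
  candidates <- find_breakpoint_candidates(clipped, min_stack_reads, fuzz)
  if (!is.null(max_per_kb)) {
    candidates <- candidate_density_filter(candidates, max_per_kb)
  }
  specs <- suppressWarnings(pair_candidates_targeted(candidates, region_pairs))
  if (is.null(flank_len)) {
    flank_len <- if (nrow(alignments)) max(nchar(alignments$seq)) + 50L else 150L
  }
  junctions <- build_junctions(specs, reference, flank_len)
  sc <- score_junctions(clipped, junctions, scheme, winner_takes_all)
  config <- caller_config(threshold, collapse_window = collapse_window)
  all_calls <- call_svs(sc$scores, junctions, config)
  passed <- all_calls[which(all_calls$passed), , drop = FALSE]
  calls <- collapse_calls(passed, collapse_window)
  structure(list(calls = calls, all_calls = all_calls, scores = sc$scores,
                 contributions = sc$contributions, junctions = junctions,
                 candidates = candidates, clipped = clipped,
                 config = c(config, list(min_tail = min_tail,
                                         min_stack_reads = min_stack_reads,
                                         fuzz = fuzz, flank_len = flank_len,
                                         scheme = scheme, mode = "targeted"))),
            class = "st_callset")
}

#' Whole-genome structural-variant calling
#'
#' Candidate breakpoint pairs come from an external BEDPE (e.g. a paired-end
#' caller's output) or, failing that, from clusters of discordant read pairs.
#' Orientations missing from the input are inferred from discordant pairs
#' within 1 kb (undetermined pairs expand to all four orientations),
#' provisional interval positions are refined against local stacks,
#' excessive-coverage regions are excluded, and scores are adjusted for local
#' coverage before thresholding.
#'
#' @inheritParams sv_call_targeted
#' @param bedpe path to a BEDPE-like candidate file, or `NULL` to derive
#'   candidates from discordant pairs (requires paired-end alignments).
#' @param coverage_k coverage-exclusion multiplier (default 10).
#' @param orientation_window discordant-pair search window (default 1000).
#' @return `st_callset` (see [sv_call_targeted()]); scores carry
#'   `S_adjusted`.
#' @export
sv_call_wgs <- function(alignments, reference, bedpe = NULL, threshold,
                        min_tail = 10, min_stack_reads = 2, fuzz = 0,
                        flank_len = NULL, coverage_k = 10,
                        orientation_window = 1000,
                        scheme = scoring_scheme(), collapse_window = 500) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  reference <- as_reference(reference)
  ref_lengths <- nchar(reference)
  clipped <- extract_clipped_reads(alignments, min_tail = min_tail)
  candidates <- find_breakpoint_candidates(clipped, min_stack_reads, fuzz)
  cov <- compute_coverage(alignments, ref_lengths)
  baseline <- median(unlist(lapply(cov, as.numeric)))
  if (!is.finite(baseline) || baseline <= 0) baseline <- 1

  if (!is.null(bedpe)) {
    specs <- load_external_candidates(bedpe)
  } else {
    if (!any(alignments$is_paired)) {
      abort("whole-genome mode without a candidate BEDPE requires paired-end alignments")
    }
    specs <- discordant_pair_candidates(alignments, window = orientation_window)
    if (nrow(specs) == 0) {
      warn("no discordant-pair candidate clusters found")
    }
  }
  # resolve orientations from discordant pairs where missing
  if (nrow(specs) > 0 && anyNA(specs$orientA)) {
    for (i in which(is.na(specs$orientA))) {
      o <- infer_orientation(alignments, specs$chromA[i], specs$posA[i],
                             specs$chromB[i], specs$posB[i],
                             window = orientation_window)
      if (o$status == "determined") {
        specs$orientA[i] <- o$orientA; specs$orientB[i] <- o$orientB
      }
    }
    specs <- expand_undetermined(specs)
  }
  specs <- refine_positions(specs, candidates)
  specs <- exclude_high_coverage(specs, cov, k = coverage_k,
                                 baseline = baseline)
  if (nrow(specs) > 0) {
    specs$sv_class <- classify_sv(specs$chromA, specs$posA, specs$orientA,
                                  specs$chromB, specs$posB, specs$orientB)
    specs <- canonicalize_specs(specs)
    specs <- distinct(specs, .data$chromA, .data$posA, .data$orientA,
                      .data$chromB, .data$posB, .data$orientB,
                      .keep_all = TRUE)
  }
  if (is.null(flank_len)) {
    flank_len <- if (nrow(alignments)) max(nchar(alignments$seq)) + 50L else 150L
  }
  junctions <- build_junctions(
    specs[, intersect(c("chromA", "posA", "orientA", "chromB", "posB",
                        "orientB", "sv_class", "source", "low_confidence"),
                      names(specs))],
    reference, flank_len)
  # realign only stacked reads near a candidate breakpoint
  near <- rep(FALSE, nrow(clipped))
  for (i in seq_len(nrow(junctions))) {
    near <- near |
      (clipped$chrom == junctions$chromA[i] &
         abs(clipped$clip_pos - junctions$posA[i]) <= orientation_window) |
      (clipped$chrom == junctions$chromB[i] &
         abs(clipped$clip_pos - junctions$posB[i]) <= orientation_window)
  }
  sc <- score_junctions(clipped[near, , drop = FALSE], junctions, scheme)
  local_cov <- map_dbl(seq_len(nrow(junctions)), function(i) {
    mean(c(mean_depth_around(cov, junctions$chromA[i], junctions$posA[i]),
           mean_depth_around(cov, junctions$chromB[i], junctions$posB[i])))
  })
  scores <- adjust_score_for_coverage(sc$scores, local_cov, baseline)
  config <- caller_config(threshold, collapse_window = collapse_window,
                          use_adjusted = TRUE)
  all_calls <- call_svs(scores, junctions, config)
  passed <- all_calls[which(all_calls$passed), , drop = FALSE]
  calls <- collapse_calls(passed, collapse_window)
  structure(list(calls = calls, all_calls = all_calls, scores = scores,
                 contributions = sc$contributions, junctions = junctions,
                 candidates = candidates, clipped = clipped,
                 config = c(config, list(min_tail = min_tail,
                                         min_stack_reads = min_stack_reads,
                                         fuzz = fuzz, flank_len = flank_len,
                                         coverage_k = coverage_k,
                                         baseline_coverage = baseline,
                                         scheme = scheme, mode = "wgs"))),
            class = "st_callset")
}

# cluster discordant read pairs into provisional breakpoint-pair candidates
discordant_pair_candidates <- function(alignments, window = 1000,
                                       min_pairs = 2) {
  a <- alignments[alignments$is_paired & alignments$is_first &
                    !is.na(alignments$mate_chrom), ]
  disc <- a$chrom != a$mate_chrom |
    (!is.na(a$mate_strand) & a$strand == a$mate_strand) |
    abs(a$mate_pos - a$pos) > 10 * window
  a <- a[disc, , drop = FALSE]
  if (nrow(a) == 0) return(mutate(empty_specs(), source = character()))
  # orient each pair canonically, then bin by window
  swap <- a$mate_chrom < a$chrom | (a$mate_chrom == a$chrom & a$mate_pos < a$pos)
  cA <- ifelse(swap, a$mate_chrom, a$chrom)
  pA <- ifelse(swap, a$mate_pos, a$pos)
  cB <- ifelse(swap, a$chrom, a$mate_chrom)
  pB <- ifelse(swap, a$pos, a$mate_pos)
  bin <- paste(cA, pA %/% window, cB, pB %/% window)
  keep <- names(which(table(bin) >= min_pairs))
  rows <- lapply(keep, function(b) {
    sel <- bin == b
    tibble(chromA = cA[sel][1], posA = as.integer(round(median(pA[sel]))),
           orientA = NA_character_,
           chromB = cB[sel][1], posB = as.integer(round(median(pB[sel]))),
           orientB = NA_character_, source = "discordant")
  })
  bind_rows(rows)
}

#' @export
print.st_callset <- function(x, ...) {
  cat(sprintf("Stack/tail call set (%s mode)\n", x$config$mode))
  cat(sprintf("  %d breakpoint candidate(s), %d junction(s) scored\n",
              nrow(x$candidates), nrow(x$junctions)))
  cat(sprintf("  threshold log10(S) >= %.4f: %d passed, %d after collapsing\n",
              x$config$threshold, sum(x$all_calls$passed), nrow(x$calls)))
  if (nrow(x$calls) > 0) {
    print(select(x$calls, all_of(c("chromA", "posA", "chromB", "posB",
                                   "sv_class", "S", "log10_S", "n_reads"))),
          n = 10)
  }
  invisible(x)
}
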
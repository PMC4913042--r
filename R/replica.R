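#' Canonical B-ALL translocation types used by the replica study design
#'
#' Four recurrent interchromosomal translocation types, each joining two of
#' eight captured regions; in the scaled-down replica each region is one
#' synthetic chromosome.
#'
#' @return tibble: `type`, `chromA`, `chromB`.
#' @export
replica_types <- function() {
  tibble(type = c("t(1;19)", "t(4;11)", "t(9;22)", "t(12;21)"),
         chromA = c("chr1", "chr4", "chr9", "chr12"),
         chromB = c("chr19", "chr11", "chr22", "chr21"))
}

#' Lay out a replica study design
#'
#' Each sample carries one translocation of a cycling type; the first
#' `n_reciprocal` samples carry the reciprocal event (two derivative
#' chromosomes, hence two junctions). The default test design — 23 samples,
#' 8 regions, 8 reciprocal events — plants 31 junctions and leaves 153 of the
#' 184 region instances unrearranged.
#'
#' @param n_samples number of samples (default 23).
#' @param n_reciprocal samples with reciprocal translocations (default 8).
#' @return tibble: `sample_id`, `type`, `chromA`, `chromB`, `reciprocal`,
#'   `n_junctions`.
#' @export
replica_design <- function(n_samples = 23, n_reciprocal = 8) {
  stopifnot(n_samples >= 1, n_reciprocal <= n_samples)
  ty <- replica_types()
  idx <- ((seq_len(n_samples) - 1L) %% nrow(ty)) + 1L
  tibble(sample_id = seq_len(n_samples),
         type = ty$type[idx], chromA = ty$chromA[idx], chromB = ty$chromB[idx],
         reciprocal = seq_len(n_samples) <= n_reciprocal,
         n_junctions = ifelse(seq_len(n_samples) <= n_reciprocal, 2L, 1L))
}

#' Bookkeeping counts for a replica design
#'
#' @param design tibble from [replica_design()].
#' @return list: `n_samples`, `n_regions`, `n_region_instances`,
#'   `n_translocated`, `n_normal`.
#' @export
replica_bookkeeping <- function(design) {
  n_regions <- 2L * nrow(replica_types())
  n_instances <- nrow(design) * n_regions
  n_transloc <- sum(design$n_junctions)
  list(n_samples = nrow(design), n_regions = n_regions,
       n_region_instances = n_instances, n_translocated = n_transloc,
       n_normal = n_instances - n_transloc)
}

#' All-pairs region list for the replica's targeted caller run
#'
#' The caller is not told a sample's type: every canonical partner pair is
#' searched in both derivative directions (forward/forward joins A-to-B and
#' B-to-A).
#'
#' @param region_length region (chromosome) length in bases.
#' @return region-pair tibble for [pair_candidates_targeted()].
#' @export
replica_region_pairs <- function(region_length = 10000) {
  ty <- replica_types()
  bind_rows(
    region_pair(ty$chromA, 1, region_length, ty$chromB, 1, region_length),
    region_pair(ty$chromB, 1, region_length, ty$chromA, 1, region_length)
  )
}

#' Run the scaled-down replica of the targeted simulation study
#'
#' Simulates one shared 8 x `region_length` reference, plants each sample's
#' translocation(s) at sample-specific positions, simulates single-end reads
#' (defaults: 250-base reads at 30x, substitution-error-free), emits truth
#' alignments, and runs the full targeted pipeline per sample. When
#' `threshold` is `NULL` it is trained first on a small independent training
#' design (4 samples, 7 junctions) simulated under a shifted seed.
#'
#' @param seed integer seed controlling every random choice.
#' @param design tibble from [replica_design()].
#' @param region_length chromosome length (default 10000).
#' @param read_length read length (default 250).
#' @param coverage depth (default 30).
#' @param error_rate substitution rate (default 0, the clean replica).
#' @param threshold `log10(S)` decision threshold, or `NULL` to train one.
#' @param min_tail,min_stack_reads,fuzz stack-detection parameters.
#' @param match_window truth-matching window in bases (default 500).
#' @return object of class `st_replica`: list with `design`, `threshold`,
#'   `truth`, `calls` (all samples), `per_sample` (tibble with top-call type,
#'   match counts), `evaluation` (sensitivity, PPV, type accuracy),
#'   `labeled_scores`.
#' @export
run_replica <- function(seed = 1, design = replica_design(),
                        region_length = 10000, read_length = 250,
                        coverage = 30, error_rate = 0, threshold = NULL,
                        min_tail = 10, min_stack_reads = 2, fuzz = 0,
                        match_window = 500) {
  ty <- replica_types()
  chroms <- c(rbind(ty$chromA, ty$chromB))
  cfg0 <- sim_config(n_chroms = length(chroms), chrom_length = region_length,
                     read_length = read_length, coverage = coverage,
                     error_rate = error_rate, seed = seed)
  reference <- simulate_reference(cfg0, chrom_names = chroms)
  region_pairs <- replica_region_pairs(region_length)

  if (is.null(threshold)) {
    tr <- run_replica(seed = derive_seed(seed, "other"),
                      design = replica_design(n_samples = 4, n_reciprocal = 3),
                      region_length = region_length, read_length = read_length,
                      coverage = coverage, error_rate = error_rate,
                      threshold = -Inf, min_tail = min_tail,
                      min_stack_reads = min_stack_reads, fuzz = fuzz,
                      match_window = match_window)
    threshold <- train_threshold(tr$labeled_scores)
  }

  truth_all <- list(); calls_all <- list(); labeled <- list()
  per_sample <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    set.seed(derive_seed(seed + d$sample_id, "plan"))
    posA <- sample(seq(region_length * 0.3, region_length * 0.7), 1)
    posB <- sample(seq(region_length * 0.3, region_length * 0.7), 1)
    plan <- sv_plan("translocation", d$chromA, posA, d$chromB, posB,
                    reciprocal = d$reciprocal)
    planted <- plant_svs(reference, plan)
    cfg <- sim_config(n_chroms = length(chroms), chrom_length = region_length,
                      read_length = read_length, coverage = coverage,
                      error_rate = error_rate,
                      seed = derive_seed(seed, "pairs") + d$sample_id)
    reads <- simulate_reads(planted$donor, cfg)
    aln <- emit_truth_alignments(reads, planted$segment_map)
    res <- sv_call_targeted(aln, reference, region_pairs,
                            threshold = threshold, min_tail = min_tail,
                            min_stack_reads = min_stack_reads, fuzz = fuzz)
    truth <- mutate(planted$truth, sample_id = d$sample_id)
    all_calls <- mutate(res$all_calls, sample_id = d$sample_id)
    truth_all[[i]] <- truth
    calls_all[[i]] <- all_calls
    # label every scored junction by truth proximity for threshold training
    lbl <- compare_call_sets(all_calls, truth, window = match_window)
    labeled[[i]] <- tibble(
      log10_S = all_calls$log10_S,
      is_true = seq_len(nrow(all_calls)) %in% lbl$matches$i,
      sample_id = d$sample_id)
    ev <- evaluate_against_truth(all_calls, truth, window = match_window)
    exact <- evaluate_against_truth(all_calls, truth, window = 0)
    top <- all_calls[all_calls$passed, , drop = FALSE]
    top_type <- NA_character_
    if (nrow(top) > 0) {
      tt <- ty$type[(ty$chromA == top$chromA[1] & ty$chromB == top$chromB[1]) |
                      (ty$chromA == top$chromB[1] & ty$chromB == top$chromA[1])]
      if (length(tt) == 1) top_type <- tt
    }
    per_sample[[i]] <- tibble(
      sample_id = d$sample_id, planted_type = d$type,
      n_truth = nrow(truth), n_passed = sum(all_calls$passed),
      n_matched = ev$n_matched, n_exact = exact$n_matched,
      top_type = top_type, type_correct = identical(top_type, d$type))
  }
  truth_all <- bind_rows(truth_all)
  calls_all <- bind_rows(calls_all)
  per_sample <- bind_rows(per_sample)
  evaluation <- list(
    sensitivity = sum(per_sample$n_matched) / nrow(truth_all),
    exact_sensitivity = sum(per_sample$n_exact) / nrow(truth_all),
    ppv = sum(per_sample$n_matched) / max(1, sum(per_sample$n_passed)),
    n_type_correct = sum(per_sample$type_correct),
    n_samples = nrow(per_sample)
  )
  structure(list(design = design, threshold = threshold, truth = truth_all,
                 calls = calls_all, per_sample = per_sample,
                 evaluation = evaluation,
                 labeled_scores = bind_rows(labeled)),
            class = "st_replica")
}

#' @export
print.st_replica <- function(x, ...) {
  ev <- x$evaluation
  cat("Replica study run\n")
  cat(sprintf("  samples: %d  truth junctions: %d\n",
              ev$n_samples, nrow(x$truth)))
  cat(sprintf("  threshold (log10 S): %.6f\n", x$threshold))
  cat(sprintf("  sensitivity: %.3f (exact breakpoints: %.3f)  PPV: %.3f\n",
              ev$sensitivity, ev$exact_sensitivity, ev$ppv))
  cat(sprintf("  sample-level type correct: %d/%d\n",
              ev$n_type_correct, ev$n_samples))
  invisible(x)
}
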
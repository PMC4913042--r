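#' Identify candidate breakpoints as recurrent soft-clip coordinates
#'
#' Clipped reads are grouped by chromosome and clip side, then clustered:
#' the modal clip position (ties broken toward the smaller coordinate) seeds a
#' cluster that absorbs every clip within `fuzz` bases; the process repeats on
#' the remainder. Clusters with at least `min_stack_reads` members become
#' breakpoint candidates located at the modal position, so with `fuzz = 0`
#' the operation is an exact group-by on (chrom, pos, clip_side).
#'
#' @param clipped tibble from [extract_clipped_reads()].
#' @param min_stack_reads minimum stack size (default 2, the weakest reading
#'   of "recurrent").
#' @param fuzz clustering slack in bases (default 0; 2 is a reasonable value
#'   for real data with alignment jitter).
#' @return tibble: `chrom`, `pos`, `clip_side`, `n_reads`, `member_reads`
#'   (list-column of read ids), sorted by (chrom, pos).
#' @export
find_breakpoint_candidates <- function(clipped, min_stack_reads = 2, fuzz = 0) {
  stopifnot(min_stack_reads >= 1, fuzz >= 0)
  if (nrow(clipped) == 0) return(empty_candidates())
  groups <- split(clipped, paste(clipped$chrom, clipped$clip_side, sep = "\r"))
  out <- bind_rows(lapply(groups, function(g) {
    cluster_clips(g, fuzz)
  }))
  out <- out[out$n_reads >= min_stack_reads, , drop = FALSE]
  if (nrow(out) == 0) return(empty_candidates())
  arrange(out, .data$chrom, .data$pos, .data$clip_side)
}

empty_candidates <- function() {
  tibble(chrom = character(), pos = integer(), clip_side = character(),
         n_reads = integer(), member_reads = list())
}

# greedy modal clustering of one (chrom, clip_side) group
cluster_clips <- function(g, fuzz) {
  pos <- g$pos <- g$clip_pos
  remaining <- g
  rows <- list()
  while (nrow(remaining) > 0) {
    tab <- table(remaining$clip_pos)
    best_n <- max(tab)
    modal <- min(as.integer(names(tab)[tab == best_n]))
    member <- abs(remaining$clip_pos - modal) <= fuzz
    m <- remaining[member, , drop = FALSE]
    rows[[length(rows) + 1]] <- tibble(
      chrom = m$chrom[1], pos = as.integer(modal), clip_side = m$clip_side[1],
      n_reads = nrow(m), member_reads = list(m$read_id)
    )
    remaining <- remaining[!member, , drop = FALSE]
  }
  bind_rows(rows)
}

#' Thin dense candidate clusters before pairing
#'
#' Pairing candidates is combinatorial, so regions that shed clips
#' pathologically (repeats, chemistry artifacts) are thinned: wherever a 1-kb
#' window holds more than `max_per_kb` surviving candidates, the
#' lowest-support candidates (ties dropped from the larger coordinate) are
#' removed until the window complies. Windows are processed left to right per
#' chromosome, restarting after each removal, which makes the survivor set
#' deterministic.
#'
#' @param candidates tibble from [find_breakpoint_candidates()].
#' @param max_per_kb maximum candidates tolerated in any 1-kb window.
#' @return filtered candidate tibble.
#' @export
candidate_density_filter <- function(candidates, max_per_kb) {
  stopifnot(max_per_kb > 0)
  if (nrow(candidates) == 0) return(candidates)
  dropped <- 0L
  out <- lapply(split(candidates, candidates$chrom), function(g) {
    g <- arrange(g, .data$pos)
    repeat {
      viol <- find_window_violation(g$pos, max_per_kb)
      if (is.null(viol)) break
      w <- g[viol, , drop = FALSE]
      # drop the weakest member; ties -> largest position goes first
      ord <- order(w$n_reads, -w$pos)
      drop_idx <- viol[ord[1]]
      g <- g[-drop_idx, , drop = FALSE]
      dropped <<- dropped + 1L
    }
    g
  })
  if (dropped > 0) {
    inform(paste0("candidate_density_filter: dropped ", dropped,
                  " candidate(s) in over-dense windows"))
  }
  out <- bind_rows(out)
  arrange(out, .data$chrom, .data$pos, .data$clip_side)
}

# leftmost set of candidate indices inside some 1-kb window exceeding the cap
find_window_violation <- function(pos, max_per_kb) {
  n <- length(pos)
  for (i in seq_len(n)) {
    j <- which(pos >= pos[i] & pos <= pos[i] + 999L)
    if (length(j) > max_per_kb) return(j)
  }
  NULL
}
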
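#' Construct a tibble of region pairs for targeted junction search
#'
#' @param chromA,startA,endA,chromB,startB,endB region coordinates (1-based
#'   inclusive).
#' @param orientA,orientB flank orientations for the junction built from the
#'   pair: `"fwd"` keeps the reference strand, `"rc"` reverse-complements that
#'   flank. A forward A flank ends at its breakpoint and therefore requires
#'   right-side clips; a forward B flank begins at its breakpoint and requires
#'   left-side clips; `"rc"` flips the required side.
#' @return tibble usable as `region_pairs` in [pair_candidates_targeted()].
#' @export
region_pair <- function(chromA, startA, endA, chromB, startB, endB,
                        orientA = "fwd", orientB = "fwd") {
  tibble(chromA = chromA, startA = startA, endA = endA,
         chromB = chromB, startB = startB, endB = endB,
         orientA = orientA, orientB = orientB)
}

#' Pair breakpoint candidates across targeted region pairs
#'
#' Every candidate inside region A whose clip side is compatible with
#' `orientA` is paired with every compatible candidate inside region B: the
#' Cartesian product, canonicalized and deduplicated, forms the junction
#' library specs.
#'
#' @param candidates tibble from [find_breakpoint_candidates()].
#' @param region_pairs tibble from [region_pair()] (rows may be stacked).
#' @return tibble of junction specs: `chromA, posA, orientA, chromB, posB,
#'   orientB, sv_class, source`.
#' @export
pair_candidates_targeted <- function(candidates, region_pairs) {
  specs <- lapply(seq_len(nrow(region_pairs)), function(i) {
    rp <- region_pairs[i, ]
    ca <- candidates[candidates$chrom == rp$chromA &
                       candidates$pos >= rp$startA & candidates$pos <= rp$endA &
                       candidates$clip_side == side_for_A(rp$orientA), ]
    cb <- candidates[candidates$chrom == rp$chromB &
                       candidates$pos >= rp$startB & candidates$pos <= rp$endB &
                       candidates$clip_side == side_for_B(rp$orientB), ]
    if (nrow(ca) == 0 || nrow(cb) == 0) {
      warn(sprintf("region pair %s / %s: no compatible candidates on %s side",
                   rp$chromA, rp$chromB,
                   if (nrow(ca) == 0) "A" else "B"))
      return(NULL)
    }
    grid <- expand.grid(ia = seq_len(nrow(ca)), ib = seq_len(nrow(cb)))
    sp <- tibble(
      chromA = ca$chrom[grid$ia], posA = ca$pos[grid$ia], orientA = rp$orientA,
      chromB = cb$chrom[grid$ib], posB = cb$pos[grid$ib], orientB = rp$orientB,
      source = "targeted"
    )
    # an inversion search can pair a candidate with itself; drop such
    # degenerate self-pairs (same locus, same required clip side)
    sp[!(sp$chromA == sp$chromB & sp$posA == sp$posB &
           side_for_A(sp$orientA) == side_for_B(sp$orientB)), , drop = FALSE]
  })
  specs <- bind_rows(specs)
  if (nrow(specs) == 0) return(empty_specs())
  specs$sv_class <- classify_sv(specs$chromA, specs$posA, specs$orientA,
                                specs$chromB, specs$posB, specs$orientB)
  specs <- canonicalize_specs(specs)
  distinct(arrange(specs, .data$chromA, .data$posA, .data$chromB, .data$posB,
                   .data$orientA, .data$orientB))
}

empty_specs <- function() {
  tibble(chromA = character(), posA = integer(), orientA = character(),
         chromB = character(), posB = integer(), orientB = character(),
         sv_class = character(), source = character())
}

#' Build candidate junction sequences from junction specs
#'
#' For each spec the A flank is the `flank_len` reference bases ending at the
#' A breakpoint (reverse-complemented when `orientA == "rc"`, in which case it
#' is the bases starting at the breakpoint) concatenated with the mirrored
#' construction for the B flank. `breakpoint_offset` is the length of the A
#' flank: bases `1..offset` derive from side A, the rest from side B. Flanks
#' are truncated at chromosome ends; specs whose flank would be empty are
#' skipped with a warning.
#'
#' @param specs tibble of junction specs.
#' @param reference reference accepted by [fetch_reference()].
#' @param flank_len flank length in bases; should be at least the maximum read
#'   length (default heuristic: longest read + 50, supplied by callers).
#' @return tibble: spec columns plus `junction_id`, `seq`,
#'   `breakpoint_offset`, `flankA_len`, `flankB_len`.
#' @export
build_junctions <- function(specs, reference, flank_len) {
  reference <- as_reference(reference)
  if (nrow(specs) == 0) {
    return(mutate(empty_specs(), junction_id = character(), seq = character(),
                  breakpoint_offset = integer(), flankA_len = integer(),
                  flankB_len = integer()))
  }
  lens <- nchar(reference)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    fa <- junction_flank(reference, lens, s$chromA, s$posA, s$orientA, "A",
                         flank_len)
    fb <- junction_flank(reference, lens, s$chromB, s$posB, s$orientB, "B",
                         flank_len)
    if (is.null(fa) || is.null(fb)) {
      warn(sprintf("junction %s:%d|%s:%d skipped: flank outside chromosome",
                   s$chromA, s$posA, s$chromB, s$posB))
      return(NULL)
    }
    mutate(s,
           junction_id = junction_id(s$chromA, s$posA, s$orientA,
                                     s$chromB, s$posB, s$orientB),
           seq = paste0(fa, fb),
           breakpoint_offset = nchar(fa),
           flankA_len = nchar(fa), flankB_len = nchar(fb))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(mutate(empty_specs(), junction_id = character(), seq = character(),
                  breakpoint_offset = integer(), flankA_len = integer(),
                  flankB_len = integer()))
  }
  out
}

# one oriented flank; NULL when fully outside the chromosome.
# A side: fwd -> bases (pos-flank+1)..pos; rc -> revcomp of pos..(pos+flank-1).
# B side: fwd -> bases pos..(pos+flank-1); rc -> revcomp of (pos-flank+1)..pos.
junction_flank <- function(reference, lens, chrom, pos, orient, side, flank) {
  len <- lens[[chrom]]
  ends_at_bp <- (side == "A" & orient == "fwd") | (side == "B" & orient == "rc")
  if (ends_at_bp) {
    start <- max(1L, pos - flank + 1L); end <- pos
  } else {
    start <- pos; end <- min(len, pos + flank - 1L)
  }
  if (start > len || end < 1L || start > end) return(NULL)
  s <- fetch_reference(reference, chrom, start, end)
  if (orient == "rc") revcomp(s) else s
}

#' Load external breakpoint-pair candidates from a BEDPE-like file
#'
#' Expects at least 6 tab-separated columns (chromA, startA, endA, chromB,
#' startB, endB; 0-based half-open starts) with optional name/score and strand
#' columns 9-10 (`+` = fwd, `-` = rc). Interval midpoints become provisional
#' breakpoint positions, to be refined against local stacks; rows without
#' strands get `NA` orientations (expanded to all four pairs downstream).
#' Malformed rows are skipped with a counted warning.
#'
#' @param path BEDPE-like text file.
#' @return tibble of junction specs with `source = "external"` and interval
#'   bounds retained (`startA, endA, startB, endB`, 1-based inclusive).
#' @export
load_external_candidates <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- 0L
  rows <- lapply(fields, function(f) {
    if (length(f) < 6) { bad <<- bad + 1L; return(NULL) }
    num <- suppressWarnings(as.integer(f[c(2, 3, 5, 6)]))
    if (anyNA(num)) { bad <<- bad + 1L; return(NULL) }
    oA <- oB <- NA_character_
    if (length(f) >= 10 && f[9] %in% c("+", "-") && f[10] %in% c("+", "-")) {
      oA <- ifelse(f[9] == "+", "fwd", "rc")
      oB <- ifelse(f[10] == "+", "fwd", "rc")
    }
    tibble(chromA = f[1], startA = num[1] + 1L, endA = num[2],
           posA = as.integer(floor((num[1] + 1L + num[2]) / 2)),
           chromB = f[4], startB = num[3] + 1L, endB = num[4],
           posB = as.integer(floor((num[3] + 1L + num[4]) / 2)),
           orientA = oA, orientB = oB, source = "external")
  })
  if (bad > 0) warn(paste0(bad, " malformed BEDPE row(s) skipped"))
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort(paste0("no parseable BEDPE rows in ", path))
  out$sv_class <- ifelse(is.na(out$orientA), NA_character_,
                         classify_sv(out$chromA, out$posA, out$orientA,
                                     out$chromB, out$posB, out$orientB))
  out
}

#' Infer flank orientations from discordant read pairs
#'
#' Counts discordant pairs whose mates fall within `window` bases of the two
#' provisional breakpoints; the plurality strand combination maps to an
#' orientation pair. With both mates read toward the junction, an FR-like
#' (+/-) combination supports a forward/forward join, while FF (+/+) and RR
#' (-/-) support one reverse-complemented flank. Ties and zero votes return
#' `"undetermined"`.
#'
#' @param alignments tibble with paired reads ([read_alignments()] layout).
#' @param chromA,posA,chromB,posB provisional breakpoints.
#' @param window matching window in bases (default 1000).
#' @return list with `orientA`, `orientB` (or both `NA`), `status`
#'   (`"determined"`/`"undetermined"`) and `votes` (named counts).
#' @export
infer_orientation <- function(alignments, chromA, posA, chromB, posB,
                              window = 1000) {
  a <- alignments[alignments$is_paired &
                    !is.na(alignments$mate_chrom) &
                    alignments$chrom == chromA &
                    abs(alignments$pos - posA) <= window &
                    alignments$mate_chrom == chromB &
                    abs(alignments$mate_pos - posB) <= window, ]
  # keep genuinely discordant pairs: different chromosome, same-strand mates,
  # or an implausible span on one chromosome
  disc <- a$chrom != a$mate_chrom |
    a$strand == a$mate_strand |
    abs(a$mate_pos - a$pos) > 10 * window
  a <- a[disc, ]
  if (nrow(a) == 0) {
    return(list(orientA = NA_character_, orientB = NA_character_,
                status = "undetermined", votes = integer(0)))
  }
  combo <- paste0(a$strand, a$mate_strand)
  votes <- sort(table(combo), decreasing = TRUE)
  if (length(votes) > 1 && votes[1] == votes[2]) {
    return(list(orientA = NA_character_, orientB = NA_character_,
                status = "undetermined", votes = c(votes)))
  }
  map <- list("+-" = c("fwd", "fwd"), "++" = c("fwd", "rc"),
              "--" = c("rc", "fwd"), "-+" = c("rc", "rc"))
  o <- map[[names(votes)[1]]]
  list(orientA = o[1], orientB = o[2], status = "determined", votes = c(votes))
}

# expand specs with NA orientations to all four orientation pairs
expand_undetermined <- function(specs) {
  det <- specs[!is.na(specs$orientA), , drop = FALSE]
  und <- specs[is.na(specs$orientA), , drop = FALSE]
  if (nrow(und) == 0) return(specs)
  combos <- expand.grid(orientA = c("fwd", "rc"), orientB = c("fwd", "rc"),
                        stringsAsFactors = FALSE)
  exp <- bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    mutate(und, orientA = combos$orientA[i], orientB = combos$orientB[i])
  }))
  out <- bind_rows(det, exp)
  out$sv_class <- classify_sv(out$chromA, out$posA, out$orientA,
                              out$chromB, out$posB, out$orientB)
  out
}

#' Compute a per-chromosome depth track from alignments
#'
#' @param alignments tibble from [read_alignments()].
#' @param ref_lengths named integer vector of chromosome lengths.
#' @return named list of [IRanges::Rle] depth vectors, one per chromosome.
#' @export
compute_coverage <- function(alignments, ref_lengths) {
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(alignments$cigar)
  out <- lapply(names(ref_lengths), function(ch) {
    sel <- alignments$chrom == ch
    if (!any(sel)) return(IRanges::Rle(0L, ref_lengths[[ch]]))
    ir <- IRanges::IRanges(start = alignments$pos[sel],
                           width = w[sel])
    IRanges::coverage(ir, width = ref_lengths[[ch]])
  })
  setNames(out, names(ref_lengths))
}

mean_depth_around <- function(coverage, chrom, pos, halfwidth = 500) {
  rle <- coverage[[chrom]]
  if (is.null(rle)) return(0)
  start <- max(1L, pos - halfwidth)
  end <- min(length(rle), pos + halfwidth)
  mean(as.numeric(rle[start:end]))
}

#' Drop junction specs whose breakpoints sit in excessive-coverage regions
#'
#' Highly repetitive loci attract spurious read pile-ups; any spec with either
#' breakpoint inside a region whose mean depth over +/-500 bases exceeds
#' `k` times the baseline (median depth across the genome) is excluded.
#'
#' @param specs junction spec tibble.
#' @param coverage depth track from [compute_coverage()].
#' @param k multiplier over baseline (default 10; must exceed 1).
#' @param baseline optional baseline depth; computed as the median of the
#'   depth track when omitted.
#' @return filtered spec tibble; dropped specs are reported via a message.
#' @export
exclude_high_coverage <- function(specs, coverage, k = 10, baseline = NULL) {
  stopifnot(k > 1)
  if (nrow(specs) == 0) return(specs)
  if (is.null(baseline)) {
    baseline <- median(unlist(lapply(coverage, function(r) {
      as.numeric(IRanges::runValue(r))[rep(seq_along(IRanges::runValue(r)),
                                           pmin(IRanges::runLength(r), 1000L))]
    })))
    if (!is.finite(baseline) || baseline <= 0) baseline <- 1
  }
  depthA <- map_dbl(seq_len(nrow(specs)), function(i)
    mean_depth_around(coverage, specs$chromA[i], specs$posA[i]))
  depthB <- map_dbl(seq_len(nrow(specs)), function(i)
    mean_depth_around(coverage, specs$chromB[i], specs$posB[i]))
  drop <- depthA > k * baseline | depthB > k * baseline
  if (any(drop)) {
    inform(sprintf(
      "exclude_high_coverage: dropped %d spec(s) above %.1fx baseline %.2f",
      sum(drop), k, baseline))
  }
  specs[!drop, , drop = FALSE]
}

#' Refine provisional breakpoint intervals against local stacks
#'
#' External (BEDPE) candidates carry intervals, not base-pair positions. For
#' each side, the strongest breakpoint candidate within +/-`slack` of the
#' interval (with the clip side the orientation requires) replaces the
#' midpoint; specs with no local stack keep the midpoint and are flagged
#' `low_confidence`.
#'
#' @param specs spec tibble from [load_external_candidates()] (orientations
#'   resolved).
#' @param candidates tibble from [find_breakpoint_candidates()].
#' @param slack search slack around the interval in bases (default 500).
#' @return spec tibble with refined `posA`, `posB` and a `low_confidence`
#'   logical column.
#' @export
refine_positions <- function(specs, candidates, slack = 500) {
  if (nrow(specs) == 0) return(mutate(specs, low_confidence = logical(0)))
  refine_one <- function(chrom, lo, hi, side) {
    hit <- candidates[candidates$chrom == chrom & candidates$clip_side == side &
                        candidates$pos >= lo - slack &
                        candidates$pos <= hi + slack, ]
    if (nrow(hit) == 0) return(NA_integer_)
    hit <- arrange(hit, desc(.data$n_reads), .data$pos)
    hit$pos[1]
  }
  pa <- map_int(seq_len(nrow(specs)), function(i)
    refine_one(specs$chromA[i], specs$startA[i] %||% specs$posA[i],
               specs$endA[i] %||% specs$posA[i], side_for_A(specs$orientA[i])))
  pb <- map_int(seq_len(nrow(specs)), function(i)
    refine_one(specs$chromB[i], specs$startB[i] %||% specs$posB[i],
               specs$endB[i] %||% specs$posB[i], side_for_B(specs$orientB[i])))
  specs$low_confidence <- is.na(pa) | is.na(pb)
  specs$posA <- ifelse(is.na(pa), specs$posA, pa)
  specs$posB <- ifelse(is.na(pb), specs$posB, pb)
  specs
}
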
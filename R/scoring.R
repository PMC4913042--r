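#' Alignment scoring scheme
#'
#' Affine-gap local alignment parameters. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match match reward (default 1).
#' @param mismatch mismatch penalty, negative (default -3).
#' @param gap_open gap opening penalty, positive cost (default 5).
#' @param gap_extend per-base gap extension cost (default 2).
#' @param min_align_score alignments scoring below this are discarded
#'   (default 20).
#' @return list of class `st_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -3, gap_open = 5,
                           gap_extend = 2, min_align_score = 20) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_align_score = min_align_score),
            class = "st_scheme")
}

subst_matrix <- function(scheme) {
  Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                           mismatch = scheme$mismatch,
                                           baseOnly = FALSE)
}

#' Align reads locally to one junction sequence
#'
#' Best Smith-Waterman local alignment of each full read (stack plus tail)
#' against the junction, both strands tried; the higher-scoring strand wins
#' and a strand tie goes to `+`. Alignments scoring below
#' `scheme$min_align_score` are dropped.
#'
#' @param reads character vector of read sequences (names become `read_id`;
#'   unnamed reads are numbered).
#' @param junction_seq junction nucleotide string.
#' @param junction_id identifier copied into the result.
#' @param scheme [scoring_scheme()].
#' @return tibble: `read_id`, `junction_id`, `score`, `strand`, `qstart`,
#'   `qend`, `jstart`, `jend` (1-based inclusive alignment intervals on the
#'   read and the junction), `n_matches`, `n_mismatches`, `n_gap_bases`.
#' @export
align_reads_to_junction <- function(reads, junction_seq, junction_id = "J",
                                    scheme = scoring_scheme()) {
  if (length(reads) == 0 || nchar(junction_seq) == 0) return(empty_alignment_tbl())
  ids <- names(reads) %||% as.character(seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  reads <- toupper(reads)
  ok <- nchar(reads) > 0
  if (!any(ok)) return(empty_alignment_tbl())
  reads <- reads[ok]; ids <- ids[ok]
  mat <- subst_matrix(scheme)
  subj <- Biostrings::DNAString(toupper(junction_seq))
  fwd_set <- Biostrings::DNAStringSet(reads)
  rev_set <- Biostrings::reverseComplement(fwd_set)
  aln_f <- Biostrings::pairwiseAlignment(fwd_set, subj, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = scheme$gap_open,
                                         gapExtension = scheme$gap_extend)
  aln_r <- Biostrings::pairwiseAlignment(rev_set, subj, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = scheme$gap_open,
                                         gapExtension = scheme$gap_extend)
  use_rev <- Biostrings::score(aln_r) > Biostrings::score(aln_f)
  pick <- function(f, r) ifelse(use_rev, r, f)
  sc <- pick(Biostrings::score(aln_f), Biostrings::score(aln_r))
  pat_start <- pick(IRanges::start(Biostrings::pattern(aln_f)),
                    IRanges::start(Biostrings::pattern(aln_r)))
  pat_end <- pick(IRanges::end(Biostrings::pattern(aln_f)),
                  IRanges::end(Biostrings::pattern(aln_r)))
  out <- tibble(
    read_id = ids,
    junction_id = junction_id,
    score = sc,
    strand = ifelse(use_rev, "-", "+"),
    qstart = as.integer(pat_start),
    qend = as.integer(pat_end),
    jstart = as.integer(pick(IRanges::start(Biostrings::subject(aln_f)),
                             IRanges::start(Biostrings::subject(aln_r)))),
    jend = as.integer(pick(IRanges::end(Biostrings::subject(aln_f)),
                           IRanges::end(Biostrings::subject(aln_r)))),
    n_matches = as.integer(pick(Biostrings::nmatch(aln_f),
                                Biostrings::nmatch(aln_r))),
    n_mismatches = as.integer(pick(Biostrings::nmismatch(aln_f),
                                   Biostrings::nmismatch(aln_r)))
  )
  out$n_gap_bases <- as.integer(pick(
    Biostrings::nindel(aln_f)@insertion[, 2] + Biostrings::nindel(aln_f)@deletion[, 2],
    Biostrings::nindel(aln_r)@insertion[, 2] + Biostrings::nindel(aln_r)@deletion[, 2]))
  # report read-coordinate intervals on the original (forward) read
  L <- nchar(reads)
  flip <- out$strand == "-"
  qs <- out$qstart; qe <- out$qend
  out$qstart[flip] <- L[flip] - qe[flip] + 1L
  out$qend[flip] <- L[flip] - qs[flip] + 1L
  out[out$score >= scheme$min_align_score, , drop = FALSE]
}

empty_alignment_tbl <- function() {
  tibble(read_id = character(), junction_id = character(), score = numeric(),
         strand = character(), qstart = integer(), qend = integer(),
         jstart = integer(), jend = integer(), n_matches = integer(),
         n_mismatches = integer(), n_gap_bases = integer())
}

#' Alignment quality Q in [0, 1]
#'
#' `Q = score / (match * read_length)`, clipped to `[0, 1]`: a perfect
#' full-length alignment scores 1 and its support contribution is then the
#' tail overlap in bases.
#'
#' @param score local alignment score(s).
#' @param read_length read length(s) in bases.
#' @param scheme [scoring_scheme()].
#' @return numeric vector of qualities.
#' @export
alignment_quality <- function(score, read_length, scheme = scoring_scheme()) {
  q <- score / (scheme$match * read_length)
  pmin(1, pmax(0, q))
}

#' Per-read support contribution for a junction
#'
#' Splits the junction-side alignment interval at the breakpoint offset:
#' `l_A` bases fall on the A side (junction positions `1..offset`), `l_B` on
#' the B side, and the read contributes `Q * min(l_A, l_B)` — a read that does
#' not span the breakpoint contributes zero.
#'
#' @param jstart,jend 1-based inclusive junction alignment interval.
#' @param breakpoint_offset index of the last A-derived junction base.
#' @param junction_len junction length.
#' @param Q alignment quality from [alignment_quality()].
#' @return tibble: `l_A`, `l_B`, `contribution`.
#' @export
read_support <- function(jstart, jend, breakpoint_offset, junction_len, Q) {
  l_A <- pmax(0L, pmin(jend, breakpoint_offset) - pmax(jstart, 1L) + 1L)
  l_B <- pmax(0L, pmin(jend, junction_len) - pmax(jstart, breakpoint_offset + 1L) + 1L)
  tibble(l_A = as.integer(l_A), l_B = as.integer(l_B),
         contribution = Q * pmin(l_A, l_B))
}

#' Score a junction library against a set of clipped reads
#'
#' Realigns every stacked read (each physical read once, even if clipped at
#' both ends) to every junction sequence and accumulates the support statistic
#' `S = sum_i Q_i * min(l_A_i, l_B_i)` per junction. A read aligning to
#' several junctions contributes to each (per-junction evidence);
#' `winner_takes_all = TRUE` instead credits only the junction with the read's
#' best alignment.
#'
#' @param clipped tibble from [extract_clipped_reads()].
#' @param junctions tibble from [build_junctions()].
#' @param scheme [scoring_scheme()].
#' @param winner_takes_all see above (default `FALSE`).
#' @return list with `scores` (tibble: `junction_id`, `S`, `log10_S`,
#'   `n_reads`) and `contributions` (per read-junction tibble).
#' @export
score_junctions <- function(clipped, junctions, scheme = scoring_scheme(),
                            winner_takes_all = FALSE) {
  if (nrow(junctions) == 0) {
    return(list(scores = empty_scores(), contributions = empty_contribs()))
  }
  reads_tbl <- distinct(clipped, .data$read_id, .data$seq)
  reads <- setNames(reads_tbl$seq, reads_tbl$read_id)
  contribs <- lapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    aln <- align_reads_to_junction(reads, j$seq, j$junction_id, scheme)
    if (nrow(aln) == 0) return(NULL)
    Q <- alignment_quality(aln$score, nchar(reads[aln$read_id]), scheme)
    sup <- read_support(aln$jstart, aln$jend, j$breakpoint_offset,
                        nchar(j$seq), Q)
    bind_cols(aln, tibble(Q = Q), sup)
  })
  contribs <- bind_rows(contribs)
  if (nrow(contribs) > 0 && winner_takes_all) {
    contribs <- contribs |>
      group_by(.data$read_id) |>
      filter(.data$score == max(.data$score)) |>
      filter(row_number() == 1) |>
      ungroup()
  }
  scores <- score_table(contribs, junctions$junction_id)
  list(scores = scores, contributions = contribs)
}

empty_contribs <- function() {
  bind_cols(empty_alignment_tbl(),
            tibble(Q = numeric(), l_A = integer(), l_B = integer(),
                   contribution = numeric()))
}

empty_scores <- function() {
  tibble(junction_id = character(), S = numeric(), log10_S = numeric(),
         n_reads = integer())
}

# aggregate contributions into the per-junction score table; junctions with
# no contributions score 0
score_table <- function(contribs, junction_ids) {
  base <- tibble(junction_id = junction_ids)
  if (nrow(contribs) == 0) {
    agg <- tibble(junction_id = character(), S = numeric(), n_reads = integer())
  } else {
    agg <- contribs |>
      group_by(.data$junction_id) |>
      summarise(S = sum(.data$contribution),
                n_reads = sum(.data$contribution > 0), .groups = "drop")
  }
  out <- left_join(base, agg, by = "junction_id")
  out$S[is.na(out$S)] <- 0
  out$n_reads[is.na(out$n_reads)] <- 0L
  out$log10_S <- ifelse(out$S > 0, log10(out$S), -Inf)
  out[, c("junction_id", "S", "log10_S", "n_reads")]
}

#' Score one pre-computed contribution set (the support summation alone)
#'
#' @param contributions tibble with at least `junction_id` and `contribution`.
#' @return tibble: `junction_id`, `S`, `log10_S`, `n_reads`.
#' @export
score_junction <- function(contributions) {
  if (nrow(contributions) > 0 &&
      length(unique(contributions$junction_id)) > 1) {
    abort("score_junction expects contributions for a single junction")
  }
  ids <- unique(contributions$junction_id)
  if (length(ids) == 0) ids <- character(0)
  score_table(contributions, ids)
}

#' Adjust a support score for locally elevated coverage
#'
#' `S_adjusted = S * baseline / max(local, baseline)`: excessive local depth
#' scales the score down proportionally, while depth at or below baseline
#' leaves it unchanged (no up-weighting of thin regions).
#'
#' @param scores score tibble with column `S`.
#' @param local_cov mean depth over both flanks (vectorized).
#' @param baseline_cov genome baseline (median) depth, positive.
#' @return `scores` with columns `S_adjusted` and `log10_S_adjusted` added.
#' @export
adjust_score_for_coverage <- function(scores, local_cov, baseline_cov) {
  stopifnot(baseline_cov > 0)
  bad <- !is.finite(local_cov) | local_cov <= 0
  if (any(bad)) {
    warn(paste0(sum(bad), " junction(s) with non-positive local coverage; ",
                "score left unadjusted"))
    local_cov[bad] <- baseline_cov
  }
  fac <- baseline_cov / pmax(local_cov, baseline_cov)
  scores$S_adjusted <- scores$S * fac
  scores$log10_S_adjusted <- ifelse(scores$S_adjusted > 0,
                                    log10(scores$S_adjusted), -Inf)
  scores
}
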
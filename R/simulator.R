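#' Simulation configuration
#'
#' One seed fixes all randomness; separate RNG substreams are derived for the
#' genome, read positions and sequencing errors so changing the error rate
#' does not shift read placement.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param read_length read length in bases.
#' @param coverage mean sequencing depth.
#' @param error_rate per-base substitution probability (substitution-only
#'   error model; soft-clip boundaries are unaffected by substitutions).
#' @param paired simulate paired-end fragments (default `FALSE`).
#' @param insert_mean,insert_sd fragment-length distribution for paired mode.
#' @param base_quality Phred quality assigned to simulated bases.
#' @param quality_profile `"constant"` or `"linear"` (linear decay of ~15
#'   Phred over the read).
#' @param seed integer seed.
#' @return list of class `st_sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 10000, read_length = 100,
                       coverage = 30, error_rate = 0, paired = FALSE,
                       insert_mean = 500, insert_sd = 50, base_quality = 30,
                       quality_profile = c("constant", "linear"), seed = 1) {
  stopifnot(n_chroms >= 1, chrom_length > 0, read_length > 0, coverage > 0,
            error_rate >= 0, error_rate < 1, base_quality > 0)
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 read_length = read_length, coverage = coverage,
                 error_rate = error_rate, paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_quality = base_quality,
                 quality_profile = match.arg(quality_profile),
                 seed = as.integer(seed)),
            class = "st_sim_config")
}

#' Simulate a random reference genome
#'
#' i.i.d. uniform ACGT chromosomes, deterministic given the seed. Optional
#' tandem-repeat blocks support repeat-failure experiments.
#'
#' @param config [sim_config()].
#' @param chrom_names optional chromosome names (default `chr1..chrN`).
#' @param repeat_blocks optional tibble (`chrom`, `start`, `unit_length`,
#'   `n_copies`) of tandem repeats to plant.
#' @return named character vector of chromosome sequences.
#' @export
simulate_reference <- function(config, chrom_names = NULL,
                               repeat_blocks = NULL) {
  set.seed(derive_seed(config$seed, "genome"))
  nm <- chrom_names %||% paste0("chr", seq_len(config$n_chroms))
  ref <- vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(ref) <- nm
  if (!is.null(repeat_blocks)) {
    for (i in seq_len(nrow(repeat_blocks))) {
      rb <- repeat_blocks[i, ]
      unit <- substr(ref[[rb$chrom]], rb$start, rb$start + rb$unit_length - 1L)
      block <- strrep(unit, rb$n_copies)
      s <- ref[[rb$chrom]]
      end <- rb$start + nchar(block) - 1L
      stopifnot(end <= nchar(s))
      ref[[rb$chrom]] <- paste0(substr(s, 1, rb$start - 1L), block,
                                substr(s, end + 1L, nchar(s)))
    }
  }
  ref
}

#' Describe one structural variant to plant
#'
#' Classes: `"translocation"` joins `chromA[1..posA]` to `chromB[posB..]`
#' (reciprocal adds the complementary derivative); `"deletion"` removes
#' `chrom[(posA+1)..(posB-1)]`; `"duplication"` tandem-duplicates
#' `chrom[posA..posB]`; `"inversion"` reverse-complements `chrom[posA..posB]`
#' (two junction edges).
#'
#' @param sv_class one of the classes above.
#' @param chromA,posA first locus.
#' @param chromB,posB second locus (same chromosome for deletion, duplication
#'   and inversion).
#' @param reciprocal translocations only: emit both derivatives.
#' @return one-row tibble.
#' @export
sv_plan <- function(sv_class, chromA, posA, chromB = chromA, posB,
                    reciprocal = FALSE) {
  stopifnot(sv_class %in% c("translocation", "deletion", "duplication",
                            "inversion"))
  if (sv_class != "translocation") stopifnot(chromA == chromB, posA < posB)
  if (sv_class == "translocation") stopifnot(chromA != chromB)
  tibble(sv_class = sv_class, chromA = chromA, posA = as.integer(posA),
         chromB = chromB, posB = as.integer(posB),
         reciprocal = reciprocal & sv_class == "translocation")
}

#' Plant structural variants into a reference, producing a donor genome
#'
#' Each plan rewrites its chromosome(s) as a list of reference segments; the
#' donor sequence, a donor-to-reference segment map and a truth table of the
#' realized junctions (canonical orientation convention, suitable for
#' [evaluate_against_truth()]) are returned. Plans must touch disjoint
#' chromosomes.
#'
#' @param reference named character vector (or anything
#'   [fetch_reference()] accepts).
#' @param plans tibble of stacked [sv_plan()] rows.
#' @return list: `donor` (named character vector), `segment_map` (tibble:
#'   `donor_chrom, donor_start, donor_end, ref_chrom, ref_start, ref_end,
#'   strand`), `truth` (tibble: `chromA, posA, orientA, chromB, posB, orientB,
#'   sv_class, donor_chrom, donor_pos`).
#' @export
plant_svs <- function(reference, plans) {
  reference <- as_reference(reference)
  used <- c(plans$chromA, plans$chromB[plans$sv_class == "translocation"])
  if (anyDuplicated(used)) {
    dup <- used[duplicated(used)][1]
    abort(paste0("overlapping plans: chromosome ", dup,
                 " appears in more than one plan"))
  }
  lens <- nchar(reference)
  # segment lists per donor chromosome; default = identity
  segs <- lapply(names(reference), function(ch) {
    tibble(ref_chrom = ch, ref_start = 1L, ref_end = lens[[ch]], strand = "+")
  })
  names(segs) <- names(reference)
  truth <- list()
  add_truth <- function(chromA, posA, orientA, chromB, posB, orientB, cls,
                        donor_chrom) {
    sp <- canonicalize_specs(tibble(
      chromA = chromA, posA = as.integer(posA), orientA = orientA,
      chromB = chromB, posB = as.integer(posB), orientB = orientB))
    truth[[length(truth) + 1]] <<- mutate(sp, sv_class = cls,
                                          donor_chrom = donor_chrom)
  }
  for (i in seq_len(nrow(plans))) {
    p <- plans[i, ]
    if (p$sv_class == "translocation") {
      lenA <- lens[[p$chromA]]; lenB <- lens[[p$chromB]]
      stopifnot(p$posA >= 1, p$posA < lenA, p$posB > 1, p$posB <= lenB)
      segs[[p$chromA]] <- tibble(
        ref_chrom = c(p$chromA, p$chromB),
        ref_start = c(1L, p$posB), ref_end = c(p$posA, lenB),
        strand = "+")
      add_truth(p$chromA, p$posA, "fwd", p$chromB, p$posB, "fwd",
                "inter_translocation", p$chromA)
      if (p$reciprocal) {
        segs[[p$chromB]] <- tibble(
          ref_chrom = c(p$chromB, p$chromA),
          ref_start = c(1L, p$posA + 1L), ref_end = c(p$posB - 1L, lenA),
          strand = "+")
        add_truth(p$chromB, p$posB - 1L, "fwd", p$chromA, p$posA + 1L, "fwd",
                  "inter_translocation", p$chromB)
      }
    } else if (p$sv_class == "deletion") {
      len <- lens[[p$chromA]]
      stopifnot(p$posA >= 1, p$posB <= len, p$posB - p$posA >= 2)
      segs[[p$chromA]] <- tibble(
        ref_chrom = p$chromA, ref_start = c(1L, p$posB),
        ref_end = c(p$posA, len), strand = "+")
      add_truth(p$chromA, p$posA, "fwd", p$chromA, p$posB, "fwd",
                "deletion", p$chromA)
    } else if (p$sv_class == "duplication") {
      len <- lens[[p$chromA]]
      stopifnot(p$posA >= 1, p$posB <= len)
      segs[[p$chromA]] <- tibble(
        ref_chrom = p$chromA, ref_start = c(1L, p$posA),
        ref_end = c(p$posB, len), strand = "+")
      add_truth(p$chromA, p$posB, "fwd", p$chromA, p$posA, "fwd",
                "duplication", p$chromA)
    } else if (p$sv_class == "inversion") {
      len <- lens[[p$chromA]]
      stopifnot(p$posA >= 2, p$posB <= len - 1L)
      segs[[p$chromA]] <- tibble(
        ref_chrom = p$chromA,
        ref_start = c(1L, p$posA, p$posB + 1L),
        ref_end = c(p$posA - 1L, p$posB, len),
        strand = c("+", "-", "+"))
      add_truth(p$chromA, p$posA - 1L, "fwd", p$chromA, p$posB, "rc",
                "inversion", p$chromA)
      add_truth(p$chromA, p$posA, "rc", p$chromA, p$posB + 1L, "fwd",
                "inversion", p$chromA)
    }
  }
  # realize donor sequences and donor coordinates
  donor <- character(0)
  seg_map <- list()
  for (ch in names(segs)) {
    sg <- segs[[ch]]
    pieces <- vapply(seq_len(nrow(sg)), function(k) {
      s <- fetch_reference(reference, sg$ref_chrom[k], sg$ref_start[k],
                           sg$ref_end[k])
      if (sg$strand[k] == "-") revcomp(s) else s
    }, character(1))
    w <- nchar(pieces)
    donor_end <- cumsum(w)
    donor_start <- donor_end - w + 1L
    donor[[ch]] <- paste(pieces, collapse = "")
    seg_map[[ch]] <- bind_cols(
      tibble(donor_chrom = ch, donor_start = as.integer(donor_start),
             donor_end = as.integer(donor_end)), sg)
  }
  seg_map <- bind_rows(seg_map)
  truth <- if (length(truth) > 0) bind_rows(truth) else
    tibble(chromA = character(), posA = integer(), orientA = character(),
           chromB = character(), posB = integer(), orientB = character(),
           sv_class = character(), donor_chrom = character())
  # donor junction coordinate = end of the 5' segment within the donor chrom
  if (nrow(truth) > 0) {
    truth$donor_pos <- map_int(seq_len(nrow(truth)), function(k) {
      sm <- seg_map[seg_map$donor_chrom == truth$donor_chrom[k], ]
      if (nrow(sm) < 2) return(NA_integer_)
      sm$donor_end[1]
    })
  } else truth$donor_pos <- integer(0)
  list(donor = donor, segment_map = seg_map, truth = truth)
}

#' Simulate shotgun reads from a donor genome
#'
#' Uniform start positions (both strands), substitution errors at the
#' configured rate, constant or linearly decaying Phred qualities; read count
#' is `round(coverage * total_length / read_length)` (fragment count halved in
#' paired mode, two reads per fragment). Deterministic per seed.
#'
#' @param donor named character vector of donor chromosomes.
#' @param config [sim_config()].
#' @return tibble of reads with donor-forward `seq`/`qual` and origin columns
#'   `donor_chrom, donor_start, donor_end, donor_strand`, plus `fragment_id`,
#'   `mate` (1/2) in paired mode.
#' @export
simulate_reads <- function(donor, config) {
  L <- config$read_length
  lens <- nchar(donor)
  stopifnot(all(lens >= L))
  total <- sum(lens)
  set.seed(derive_seed(config$seed, "positions"))
  qual_str <- simulated_qual(config)
  if (!config$paired) {
    n <- round(config$coverage * total / L)
    chrom <- sample(names(donor), n, replace = TRUE, prob = lens / total)
    start <- floor(runif(n, 1, lens[chrom] - L + 1 + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- tibble(
      read_id = sprintf("read_%06d", seq_len(n)),
      donor_chrom = chrom, donor_start = as.integer(start),
      donor_end = as.integer(start + L - 1L), donor_strand = strand,
      fragment_id = NA_integer_, mate = NA_integer_
    )
  } else {
    n_frag <- round(config$coverage * total / (2 * L))
    flen <- pmax(2L * L, as.integer(round(
      rnorm(n_frag, config$insert_mean, config$insert_sd))))
    chrom <- sample(names(donor), n_frag, replace = TRUE, prob = lens / total)
    flen <- pmin(flen, lens[chrom])
    fstart <- floor(runif(n_frag, 1, lens[chrom] - flen + 1 + 1))
    reads <- bind_rows(
      tibble(read_id = sprintf("frag_%06d/1", seq_len(n_frag)),
             donor_chrom = chrom, donor_start = as.integer(fstart),
             donor_end = as.integer(fstart + L - 1L), donor_strand = "+",
             fragment_id = seq_len(n_frag), mate = 1L),
      tibble(read_id = sprintf("frag_%06d/2", seq_len(n_frag)),
             donor_chrom = chrom,
             donor_start = as.integer(fstart + flen - L),
             donor_end = as.integer(fstart + flen - 1L), donor_strand = "-",
             fragment_id = seq_len(n_frag), mate = 2L)
    )
  }
  reads$seq <- substr(donor[reads$donor_chrom], reads$donor_start,
                      reads$donor_end)
  reads$qual <- qual_str
  reads <- apply_substitution_errors(reads, config)
  reads
}

simulated_qual <- function(config) {
  L <- config$read_length
  q <- if (config$quality_profile == "constant") rep(config$base_quality, L)
  else round(seq(config$base_quality, max(config$base_quality - 15, 2),
                 length.out = L))
  int_to_qual(list(as.integer(q)))[[1]]
}

apply_substitution_errors <- function(reads, config) {
  if (config$error_rate <= 0) return(reads)
  set.seed(derive_seed(config$seed, "errors"))
  L <- config$read_length
  n_err <- stats::rbinom(nrow(reads), L, config$error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(reads$seq[i], "")[[1]]
    pos <- sample.int(L, n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    reads$seq[i] <- paste(s, collapse = "")
  }
  reads
}

#' Map simulated reads back to the reference as truth alignments
#'
#' Each read's donor interval is intersected with the donor-to-reference
#' segment map. Reads inside one segment get a full-match CIGAR; reads
#' crossing a junction are aligned to their longest piece with the remainder
#' soft-clipped, exactly reproducing the stack/tail structure the caller
#' consumes. Reads crossing two junctions are assigned to their longest piece
#' and flagged `multi_junction`. Mate fields make junction-flanking pairs
#' discordant in paired mode.
#'
#' @param reads tibble from [simulate_reads()].
#' @param segment_map from [plant_svs()].
#' @return tibble in the [read_alignments()] layout, coordinate-sorted, with
#'   an extra `multi_junction` column.
#' @export
emit_truth_alignments <- function(reads, segment_map) {
  pieces <- list()
  for (ch in unique(reads$donor_chrom)) {
    r <- reads[reads$donor_chrom == ch, ]
    sm <- segment_map[segment_map$donor_chrom == ch, ]
    for (k in seq_len(nrow(sm))) {
      os <- pmax(r$donor_start, sm$donor_start[k])
      oe <- pmin(r$donor_end, sm$donor_end[k])
      sel <- which(os <= oe)
      if (length(sel) == 0) next
      osk <- os[sel]; oek <- oe[sel]
      if (sm$strand[k] == "+") {
        rs <- sm$ref_start[k] + (osk - sm$donor_start[k])
        re <- sm$ref_start[k] + (oek - sm$donor_start[k])
      } else {
        re <- sm$ref_end[k] - (osk - sm$donor_start[k])
        rs <- sm$ref_end[k] - (oek - sm$donor_start[k])
      }
      pieces[[length(pieces) + 1]] <- tibble(
        row = which(reads$donor_chrom == ch)[sel],
        qs = as.integer(osk - r$donor_start[sel] + 1L),
        qe = as.integer(oek - r$donor_start[sel] + 1L),
        ref_chrom = sm$ref_chrom[k], ref_start = as.integer(rs),
        ref_end = as.integer(re), piece_strand = sm$strand[k]
      )
    }
  }
  pieces <- bind_rows(pieces)
  npieces <- table(pieces$row)
  # primary piece = longest; ties to the smaller query start
  pieces <- arrange(pieces, .data$row, desc(.data$qe - .data$qs),
                    .data$qs)
  primary <- pieces[!duplicated(pieces$row), ]
  primary <- arrange(primary, .data$row)
  r <- reads[primary$row, ]
  L <- nchar(r$seq)
  plus <- primary$piece_strand == "+"
  left_clip <- ifelse(plus, primary$qs - 1L, L - primary$qe)
  right_clip <- ifelse(plus, L - primary$qe, primary$qs - 1L)
  m_len <- primary$qe - primary$qs + 1L
  cigar <- paste0(ifelse(left_clip > 0, paste0(left_clip, "S"), ""),
                  m_len, "M",
                  ifelse(right_clip > 0, paste0(right_clip, "S"), ""))
  seq_out <- ifelse(plus, r$seq, revcomp(r$seq))
  qual_out <- ifelse(plus, r$qual, rev_str(r$qual))
  # reported SAM strand: piece strand composed with the sequenced strand
  sam_rev <- xor(primary$piece_strand == "-", r$donor_strand == "-")
  paired <- !is.na(r$mate)
  aln <- tibble(
    read_id = sub("/[12]$", "", r$read_id),
    chrom = primary$ref_chrom, pos = primary$ref_start,
    mapq = 60L, cigar = cigar,
    strand = ifelse(sam_rev, "-", "+"),
    seq = seq_out, qual = qual_out,
    is_paired = paired,
    is_first = !is.na(r$mate) & r$mate == 1L,
    multi_junction = as.integer(npieces[as.character(primary$row)]) > 2L,
    fragment_id = r$fragment_id
  )
  aln$flag <- ifelse(aln$strand == "-", 16L, 0L)
  if (any(paired)) {
    mate_key <- paste(aln$fragment_id, ifelse(aln$is_first, 2L, 1L))
    self_key <- paste(aln$fragment_id, ifelse(aln$is_first, 1L, 2L))
    idx <- match(mate_key, self_key)
    aln$mate_chrom <- ifelse(paired, aln$chrom[idx], NA_character_)
    aln$mate_pos <- ifelse(paired, aln$pos[idx], NA_integer_)
    aln$mate_strand <- ifelse(paired, aln$strand[idx], NA_character_)
    aln$flag <- aln$flag +
      ifelse(paired, 1L + 2L + ifelse(aln$is_first, 64L, 128L) +
               ifelse(!is.na(aln$mate_strand) & aln$mate_strand == "-",
                      32L, 0L), 0L)
  } else {
    aln$mate_chrom <- NA_character_
    aln$mate_pos <- NA_integer_
    aln$mate_strand <- NA_character_
  }
  aln$fragment_id <- NULL
  arrange(aln, .data$chrom, .data$pos, .data$read_id)
}

#' Write simulated reads to FASTQ (Sanger Phred+33)
#'
#' Reads are written in sequenced orientation: donor-minus reads are
#' reverse-complemented with reversed qualities.
#'
#' @param reads tibble from [simulate_reads()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  minus <- reads$donor_strand == "-"
  seq <- ifelse(minus, revcomp(reads$seq), reads$seq)
  qual <- ifelse(minus, rev_str(reads$qual), reads$qual)
  out <- as.vector(rbind(paste0("@", reads$read_id), seq, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Export a truth table as BEDPE
#' @param truth truth tibble from [plant_svs()].
#' @param path output path.
#' @export
write_truth_bedpe <- function(truth, path) {
  df <- tibble(
    chrom1 = truth$chromA, start1 = truth$posA - 1L, end1 = truth$posA,
    chrom2 = truth$chromB, start2 = truth$posB - 1L, end2 = truth$posB,
    name = truth$sv_class, score = 0,
    strand1 = ifelse(truth$orientA == "fwd", "+", "-"),
    strand2 = ifelse(truth$orientB == "fwd", "+", "-")
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
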
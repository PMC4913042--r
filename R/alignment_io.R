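#' Read primary alignments from a SAM or BAM file into a tibble
#'
#' Secondary, supplementary and (by default) duplicate-flagged records are
#' skipped so each physical read contributes evidence once. SAM input is
#' converted on the fly; a region query requires (and will create) a
#' coordinate-sorted, indexed BAM.
#'
#' @param path SAM or BAM file.
#' @param region optional `"chrom:start-end"` string (1-based inclusive).
#' @param keep_duplicates keep duplicate-flagged records (default `FALSE`).
#' @return tibble with one row per alignment: `read_id`, `flag`, `chrom`,
#'   `pos` (1-based leftmost aligned base), `mapq`, `cigar`, `strand`, `seq`,
#'   `qual` (Phred+33 string), `is_paired`, `is_first`, `mate_chrom`,
#'   `mate_pos`, `mate_strand`.
#' @export
read_alignments <- function(path, region = NULL, keep_duplicates = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) abort(paste0("failed to read SAM file ", path, ": ",
                                       conditionMessage(e)))
    )
  }
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_duplicates) NA else FALSE,
    isUnmappedQuery = FALSE
  )
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "seq", "qual", "mrnm", "mpos")
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort(paste0("malformed region: ", region))
    sorted <- Rsamtools::sortBam(bam, tempfile())
    Rsamtools::indexBam(sorted)
    hdr <- Rsamtools::scanBamHeader(sorted)[[1]]$targets
    if (!m[2] %in% names(hdr)) {
      warn(paste0("region chromosome not in file: ", m[2]))
      return(empty_alignments())
    }
    gr <- GenomicRanges::GRanges(m[2],
                                 IRanges::IRanges(as.numeric(m[3]), as.numeric(m[4])))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = gr)
    res <- Rsamtools::scanBam(sorted, param = param)[[1]]
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
    res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                    error = function(e) abort(paste0("failed to read ", path,
                                                     ": ", conditionMessage(e))))
  }
  alignments_from_scan(res)
}

empty_alignments <- function() {
  tibble(read_id = character(), flag = integer(), chrom = character(),
         pos = integer(), mapq = integer(), cigar = character(),
         strand = character(), seq = character(), qual = character(),
         is_paired = logical(), is_first = logical(),
         mate_chrom = character(), mate_pos = integer(),
         mate_strand = character())
}

alignments_from_scan <- function(res) {
  if (length(res$qname) == 0) return(empty_alignments())
  fl <- res$flag
  tibble(
    read_id = res$qname,
    flag = as.integer(fl),
    chrom = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = as.character(res$cigar),
    strand = as.character(res$strand),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    is_paired = bitwAnd(fl, 1L) > 0L,
    is_first = bitwAnd(fl, 64L) > 0L,
    mate_chrom = as.character(res$mrnm),
    mate_pos = as.integer(res$mpos),
    mate_strand = ifelse(bitwAnd(fl, 1L) == 0L, NA_character_,
                         ifelse(bitwAnd(fl, 32L) > 0L, "-", "+"))
  )
}

#' Extract soft-clipped reads (stack + tail) from alignments
#'
#' A read whose CIGAR starts or ends with a soft clip of at least `min_tail`
#' bases yields one clipped-read row per qualifying end; the aligned portion
#' is the "stack" and the clipped portion the "tail". Tail bases with quality
#' below `min_base_quality` are trimmed from the tail's far end (the end away
#' from the junction) before the length filter. Hard-clipped ends carry no
#' bases and are skipped (one summary warning).
#'
#' Breakpoint convention (1-based): a right clip records the coordinate of the
#' last aligned base; a left clip records the first aligned base.
#'
#' @param alignments tibble from [read_alignments()].
#' @param min_tail minimum tail length in bases (default 10).
#' @param min_base_quality Phred floor for far-end tail trimming (default 3).
#' @return tibble: `read_id`, `chrom`, `clip_side` (`"left"`/`"right"`),
#'   `clip_pos`, `stack_seq`, `tail_seq`, `tail_quals`, `seq`, `qual`, `mapq`.
#' @export
extract_clipped_reads <- function(alignments, min_tail = 10,
                                  min_base_quality = 3) {
  stopifnot(min_tail >= 1)
  if (nrow(alignments) == 0) return(empty_clipped())
  cig <- alignments$cigar
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  first_op <- map_chr(ops, 1)
  last_op <- map_chr(ops, function(x) x[length(x)])
  first_len <- map_int(lens, 1)
  last_len <- map_int(lens, function(x) x[length(x)])
  n_hard <- sum(first_op == "H") + sum(last_op == "H")
  if (n_hard > 0) {
    warn(paste0(n_hard, " hard-clipped read end(s) skipped (bases absent)"))
  }
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)

  rows <- list()
  left_sel <- first_op == "S"
  if (any(left_sel)) {
    a <- alignments[left_sel, ]
    cl <- first_len[left_sel]
    tail_seq <- substr(a$seq, 1L, cl)
    tail_q <- substr(a$qual, 1L, cl)
    # trim low-quality bases at the far (left) end of a left tail
    trimmed <- trim_tail(tail_seq, tail_q, side = "left", floor = min_base_quality)
    keep <- nchar(trimmed$seq) >= min_tail
    if (any(keep)) {
      rows$left <- tibble(
        read_id = a$read_id[keep], chrom = a$chrom[keep],
        clip_side = "left", clip_pos = a$pos[keep],
        stack_seq = substr(a$seq, cl + 1L, nchar(a$seq))[keep],
        tail_seq = trimmed$seq[keep], tail_quals = trimmed$qual[keep],
        seq = a$seq[keep], qual = a$qual[keep], mapq = a$mapq[keep]
      )
    }
  }
  right_sel <- last_op == "S"
  if (any(right_sel)) {
    a <- alignments[right_sel, ]
    cl <- last_len[right_sel]
    L <- nchar(a$seq)
    tail_seq <- substr(a$seq, L - cl + 1L, L)
    tail_q <- substr(a$qual, L - cl + 1L, L)
    trimmed <- trim_tail(tail_seq, tail_q, side = "right", floor = min_base_quality)
    keep <- nchar(trimmed$seq) >= min_tail
    if (any(keep)) {
      rows$right <- tibble(
        read_id = a$read_id[keep], chrom = a$chrom[keep],
        clip_side = "right",
        clip_pos = (a$pos + ref_w[right_sel] - 1L)[keep],
        stack_seq = substr(a$seq, 1L, L - cl)[keep],
        tail_seq = trimmed$seq[keep], tail_quals = trimmed$qual[keep],
        seq = a$seq[keep], qual = a$qual[keep], mapq = a$mapq[keep]
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_clipped())
  arrange(out, .data$chrom, .data$clip_pos, .data$read_id)
}

empty_clipped <- function() {
  tibble(read_id = character(), chrom = character(), clip_side = character(),
         clip_pos = integer(), stack_seq = character(), tail_seq = character(),
         tail_quals = character(), seq = character(), qual = character(),
         mapq = integer())
}

# drop bases below `floor` at the far end of each tail
trim_tail <- function(seq, qual, side, floor) {
  qi <- qual_to_int(qual)
  n_trim <- vapply(qi, function(q) {
    if (length(q) == 0) return(0L)
    v <- if (side == "left") q else rev(q)
    bad <- cumprod(v < floor)
    as.integer(sum(bad))
  }, integer(1))
  L <- nchar(seq)
  if (side == "left") {
    list(seq = substr(seq, n_trim + 1L, L), qual = substr(qual, n_trim + 1L, L))
  } else {
    list(seq = substr(seq, 1L, L - n_trim), qual = substr(qual, 1L, L - n_trim))
  }
}

#' Fetch a reference subsequence
#'
#' @param reference named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return uppercase nucleotide string (N preserved).
#' @export
fetch_reference <- function(reference, chrom, start, end) {
  reference <- as_reference(reference)
  if (!chrom %in% names(reference)) {
    abort(paste0("unknown chromosome: ", chrom))
  }
  len <- nchar(reference[[chrom]])
  if (start < 1 || end > len || start > end) {
    abort(sprintf("requested %s:%d-%d outside 1-%d", chrom, start, end, len))
  }
  toupper(substr(reference[[chrom]], start, end))
}

# normalize the accepted reference representations to a named character vector
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference) && grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(setNames(as.character(ss), names(ss)))
  }
  if (inherits(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  abort("reference must be a named character vector, DNAStringSet, or FASTA path")
}

#' Write a reference to FASTA
#' @param reference named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write alignments to a SAM file
#'
#' Emits a valid coordinate-sortable SAM with `@SQ` lines taken from
#' `ref_lengths`. Records are written sorted by (chrom, pos).
#'
#' @param alignments tibble in the [read_alignments()] layout.
#' @param ref_lengths named integer vector of chromosome lengths.
#' @param path output path ending in `.sam`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  a <- arrange(alignments, .data$chrom, .data$pos)
  rnext <- ifelse(is.na(a$mate_chrom), "*",
                  ifelse(a$mate_chrom == a$chrom, "=", a$mate_chrom))
  pnext <- ifelse(is.na(a$mate_pos), 0L, a$mate_pos)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                 a$read_id, a$flag, a$chrom, a$pos, a$mapq, a$cigar,
                 rnext, pnext, a$seq, a$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a call table to TSV
#'
#' Columns: `chromA, posA, orientA, chromB, posB, orientB, sv_class, S,
#' log10_S, S_adjusted, n_reads, passed, rank, cluster_id, cluster_size`
#' (1-based positions).
#'
#' @param calls tibble of calls (see [call_svs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  keep <- intersect(c("chromA", "posA", "orientA", "chromB", "posB", "orientB",
                      "sv_class", "S", "log10_S", "S_adjusted", "n_reads",
                      "passed", "rank", "cluster_id", "cluster_size"),
                    names(calls))
  readr::write_tsv(calls[, keep], path)
  invisible(path)
}

#' Write calls as BEDPE (0-based half-open intervals of width 1)
#' @inheritParams write_calls_tsv
#' @export
write_calls_bedpe <- function(calls, path) {
  df <- tibble(
    chrom1 = calls$chromA, start1 = calls$posA - 1L, end1 = calls$posA,
    chrom2 = calls$chromB, start2 = calls$posB - 1L, end2 = calls$posB,
    name = paste0(calls$sv_class, "_", seq_len(nrow(calls))),
    score = round(calls$log10_S, 4),
    strand1 = ifelse(calls$orientA == "fwd", "+", "-"),
    strand2 = ifelse(calls$orientB == "fwd", "+", "-")
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Export breakpoint candidates as BED (0-based half-open)
#' @param candidates tibble from [find_breakpoint_candidates()].
#' @param path output path.
#' @export
write_candidates_bed <- function(candidates, path) {
  df <- tibble(chrom = candidates$chrom, start = candidates$pos - 1L,
               end = candidates$pos, name = candidates$clip_side,
               score = candidates$n_reads)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write calls in VCF breakend (BND) notation
#'
#' One BND record per breakpoint side; ALT encodes the partner locus and the
#' join orientation per VCF 4.2.
#'
#' @inheritParams write_calls_tsv
#' @param reference reference (for the REF base at each breakend).
#' @export
write_calls_vcf <- function(calls, reference, path) {
  reference <- as_reference(reference)
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=BND,Description=\"Breakend\">",
           "##INFO=<ID=SVCLASS,Number=1,Type=String,Description=\"SV class\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Float,Description=\"Support score S\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
           sprintf("##contig=<ID=%s,length=%d>", names(reference),
                   nchar(reference)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  for (i in seq_len(nrow(calls))) {
    cA <- calls$chromA[i]; pA <- calls$posA[i]; oA <- calls$orientA[i]
    cB <- calls$chromB[i]; pB <- calls$posB[i]; oB <- calls$orientB[i]
    refA <- fetch_reference(reference, cA, pA, pA)
    refB <- fetch_reference(reference, cB, pB, pB)
    idA <- sprintf("bnd_%d_A", i); idB <- sprintf("bnd_%d_B", i)
    # A side: sequence continues into B; fwd A flank ends at posA
    altA <- if (oB == "fwd") sprintf("%s[%s:%d[", refA, cB, pB)
            else sprintf("%s]%s:%d]", refA, cB, pB)
    altB <- if (oA == "fwd") sprintf("]%s:%d]%s", cA, pA, refB)
            else sprintf("[%s:%d[%s", cA, pA, refB)
    info <- sprintf("SVCLASS=%s;SUPPORT=%.4f", calls$sv_class[i], calls$S[i])
    recs <- c(recs,
              sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s;MATEID=%s",
                      cA, pA, idA, refA, altA, info, idB),
              sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s;MATEID=%s",
                      cB, pB, idB, refB, altB, info, idA))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
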
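# Independent oracles used by the tests. These are deliberately separate
# implementations from the package code paths they check.

# Affine-gap local alignment by a plain three-state R dynamic program
# (gap of length L costs open + L * extend). Returns the best score.
sw_oracle <- function(p, s, match = 1, mismatch = -3, open = 5, extend = 2) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(pc); m <- length(sc)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      sub <- if (pc[i - 1] == sc[j - 1]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + sub)
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Threshold training by a direct scan over the sorted labeled scores.
threshold_oracle <- function(labeled) {
  scores <- labeled$log10_S
  truths <- scores[labeled$is_true & is.finite(scores)]
  t <- min(truths)
  below <- scores[!labeled$is_true & is.finite(scores) & scores < t]
  if (length(below) == 0) return(t / 2)
  srt <- sort(below, decreasing = TRUE)
  (t + srt[1]) / 2
}

# Single-linkage clustering of calls by breadth-first closure over the
# pairwise within-window relation.
collapse_oracle <- function(calls, window) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  linked <- function(i, j) {
    calls$chromA[i] == calls$chromA[j] && calls$chromB[i] == calls$chromB[j] &&
      calls$sv_class[i] == calls$sv_class[j] &&
      calls$orientA[i] == calls$orientA[j] &&
      calls$orientB[i] == calls$orientB[j] &&
      abs(calls$posA[i] - calls$posA[j]) <= window &&
      abs(calls$posB[i] - calls$posB[j]) <= window
  }
  cluster <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    cl <- cl + 1L
    queue <- i
    cluster[i] <- cl
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in seq_len(n)) {
        if (is.na(cluster[v]) && linked(u, v)) {
          cluster[v] <- cl
          queue <- c(queue, v)
        }
      }
    }
  }
  cluster
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# minimal SAM writer for hand-built fixtures
write_fixture_sam <- function(path, records,
                              sq = c(chr1 = 10000L, chr2 = 10000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos, cigar, seq,
                       qual = strrep("I", nchar(seq)), mapq = 60) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, chrom, pos, mapq, cigar, seq, qual)
}

# a small shared simulation: reciprocal translocation, clean reads
small_sim <- function(seed = 11, coverage = 20, read_length = 100,
                      error_rate = 0, paired = FALSE) {
  cfg <- sim_config(n_chroms = 2, chrom_length = 10000,
                    read_length = read_length, coverage = coverage,
                    error_rate = error_rate, paired = paired, seed = seed)
  ref <- simulate_reference(cfg)
  plan <- sv_plan("translocation", "chr1", 5000, "chr2", 4000,
                  reciprocal = TRUE)
  planted <- plant_svs(ref, plan)
  reads <- simulate_reads(planted$donor, cfg)
  aln <- emit_truth_alignments(reads, planted$segment_map)
  list(cfg = cfg, ref = ref, planted = planted, reads = reads, aln = aln)
}
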
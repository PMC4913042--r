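test_that("local alignment of exact and near-exact substrings scores as specified", {
  set.seed(101)
  j <- rand_dna(200)
  r <- substr(j, 31, 70) # 40-mer
  aln <- align_reads_to_junction(c(x = r), j)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$score, 40)
  expect_equal(c(aln$jstart, aln$jend), c(31L, 70L))
  expect_equal(c(aln$qstart, aln$qend), c(1L, 40L))
  expect_equal(aln$strand, "+")
  # one mismatch in the middle: 39 matches + 1 mismatch = 36
  r2 <- r
  b <- substr(r2, 20, 20)
  substr(r2, 20, 20) <- setdiff(c("A", "C", "G", "T"), b)[1]
  aln2 <- align_reads_to_junction(c(x = r2), j)
  expect_equal(aln2$score, 36)
  # reverse-complement read aligns on the minus strand with the same score
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  aln3 <- align_reads_to_junction(c(x = rc), j)
  expect_equal(aln3$score, 40)
  expect_equal(aln3$strand, "-")
  expect_equal(c(aln3$jstart, aln3$jend), c(31L, 70L))
})

test_that("random reads do not reach the alignment score floor", {
  set.seed(202)
  hits <- vapply(1:25, function(i) {
    nrow(align_reads_to_junction(c(x = rand_dna(40)), rand_dna(200)))
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("optimal local score matches an independent affine-gap dynamic program", {
  set.seed(303)
  scheme <- scoring_scheme(min_align_score = 5)
  n_checked <- 0
  for (case in 1:120) {
    jlen <- sample(15:30, 1)
    rlen <- sample(6:12, 1)
    j <- rand_dna(jlen)
    r <- if (case %% 3 == 0) {
      # plant a (possibly mutated) substring so high-score cases occur
      s <- sample(1:(jlen - rlen + 1), 1)
      x <- substr(j, s, s + rlen - 1)
      if (case %% 6 == 0) {
        p <- sample(rlen, 1)
        substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      x
    } else rand_dna(rlen)
    oracle <- max(sw_oracle(r, j),
                  sw_oracle(as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(r))), j))
    got <- align_reads_to_junction(c(x = r), j, scheme = scheme)
    if (oracle >= 5) {
      expect_equal(got$score, oracle, info = paste("case", case))
      n_checked <- n_checked + 1
    } else {
      expect_true(nrow(got) == 0 || got$score == oracle)
    }
  }
  expect_gt(n_checked, 20)
})

test_that("alignment quality is the score fraction of a perfect full-length alignment", {
  expect_equal(alignment_quality(40, 40), 1.0)
  expect_equal(alignment_quality(36, 40), 0.9)
  expect_equal(alignment_quality(20, 40), 0.5)
  expect_equal(alignment_quality(-10, 40), 0)   # clipped at 0
  expect_equal(alignment_quality(80, 40), 1.0)  # clipped at 1
})

test_that("support contributions take Q times the lesser flank overlap", {
  # interval covering 10 bases left and 25 right of offset 100 on a 200-bp junction
  s <- read_support(jstart = 91, jend = 125, breakpoint_offset = 100,
                    junction_len = 200, Q = 1.0)
  expect_equal(c(s$l_A, s$l_B), c(10L, 25L))
  expect_equal(s$contribution, 10.0)
  s2 <- read_support(71, 130, 100, 200, Q = 0.5)
  expect_equal(c(s2$l_A, s2$l_B), c(30L, 30L))
  expect_equal(s2$contribution, 15.0)
  # entirely on side A: no support
  s3 <- read_support(10, 50, 100, 200, Q = 1.0)
  expect_equal(s3$l_B, 0L)
  expect_equal(s3$contribution, 0.0)
  # vectorized and bounded by min(l_A, l_B)
  set.seed(1)
  js <- sample(1:150, 50, replace = TRUE)
  je <- pmin(200L, js + sample(10:80, 50, replace = TRUE))
  q <- runif(50)
  sv <- read_support(js, je, 100, 200, q)
  expect_true(all(sv$contribution <= pmin(sv$l_A, sv$l_B) + 1e-12))
  expect_true(all(sv$l_A + sv$l_B == je - js + 1))
})

test_that("junction support sums contributions additively and permutation-invariantly", {
  contribs <- tibble::tibble(junction_id = "J", read_id = c("a", "b"),
                             contribution = c(10, 15))
  sc <- score_junction(contribs)
  expect_equal(sc$S, 25)
  expect_equal(sc$log10_S, log10(25), tolerance = 1e-6)
  expect_equal(round(sc$log10_S, 5), 1.39794)
  expect_equal(sc$n_reads, 2L)
  # permutation invariance
  sc2 <- score_junction(contribs[2:1, ])
  expect_equal(sc2$S, sc$S)
  # empty input scores zero
  sc0 <- score_junction(contribs[0, ])
  expect_equal(nrow(sc0), 0)
  # adding a read never decreases S
  sc3 <- score_junction(dplyr::bind_rows(
    contribs, tibble::tibble(junction_id = "J", read_id = "c",
                             contribution = 3)))
  expect_gte(sc3$S, sc$S)
  # mixed junction ids are a programming error
  expect_error(score_junction(tibble::tibble(junction_id = c("J", "K"),
                                             contribution = 1)), "single")
})

test_that("error-free spanning reads reproduce the brute-force support sum", {
  set.seed(404)
  jseq <- rand_dna(400)
  offset <- 200L
  junction <- tibble::tibble(
    chromA = "chrA", posA = 200L, orientA = "fwd",
    chromB = "chrB", posB = 1L, orientB = "fwd",
    sv_class = "inter_translocation", source = "targeted",
    junction_id = "J", seq = jseq, breakpoint_offset = offset,
    flankA_len = 200L, flankB_len = 200L)
  # 30 perfect reads of length 100 crossing the offset at varied phases
  starts <- as.integer(round(seq(105, 195, length.out = 30)))
  clipped <- tibble::tibble(
    read_id = paste0("r", seq_along(starts)),
    chrom = "chrA", clip_side = "right", clip_pos = 200L,
    stack_seq = "", tail_seq = "", tail_quals = "",
    seq = substr(rep(jseq, length(starts)), starts, starts + 99L),
    qual = strrep("I", 100), mapq = 60L)
  sc <- score_junctions(clipped, junction)
  # brute force from the planted start positions: Q = 1, contribution =
  # min(bases left of offset, bases right of offset)
  l_A <- offset - starts + 1L
  l_B <- (starts + 99L) - offset
  expect_equal(sc$scores$S, sum(pmin(l_A, l_B)))
  expect_equal(sc$scores$n_reads, 30L)
})

test_that("support is symmetric under reverse complement of junction and reads", {
  set.seed(505)
  jseq <- rand_dna(300)
  offset <- 120L
  mk_junction <- function(seq, off) tibble::tibble(
    chromA = "c", posA = 1L, orientA = "fwd", chromB = "d", posB = 1L,
    orientB = "fwd", sv_class = "inter_translocation", source = "t",
    junction_id = "J", seq = seq, breakpoint_offset = off,
    flankA_len = off, flankB_len = nchar(seq) - off)
  starts <- c(71, 91, 101, 111)
  reads <- substr(rep(jseq, 4), starts, starts + 79)
  mk_clip <- function(seqs) tibble::tibble(
    read_id = paste0("r", seq_along(seqs)), chrom = "c", clip_side = "right",
    clip_pos = 1L, stack_seq = "", tail_seq = "", tail_quals = "",
    seq = seqs, qual = strrep("I", 80), mapq = 60L)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  s1 <- score_junctions(mk_clip(reads), mk_junction(jseq, offset))
  s2 <- score_junctions(mk_clip(rc(reads)),
                        mk_junction(rc(jseq), nchar(jseq) - offset))
  expect_equal(s1$scores$S, s2$scores$S)
  expect_equal(s1$scores$n_reads, s2$scores$n_reads)
})

test_that("a half-correct junction gains no support from its wrong partner side", {
  set.seed(606)
  flankA <- rand_dna(150)
  flankB <- rand_dna(150)
  flankWrong <- rand_dna(150)
  true_junction <- paste0(flankA, flankB)
  # reads spanning the true junction
  starts <- c(101, 111, 121, 131)
  reads <- substr(rep(true_junction, 4), starts, starts + 79)
  clipped <- tibble::tibble(
    read_id = paste0("r", 1:4), chrom = "c", clip_side = "right",
    clip_pos = 1L, stack_seq = "", tail_seq = "", tail_quals = "",
    seq = reads, qual = strrep("I", 80), mapq = 60L)
  wrong <- tibble::tibble(
    chromA = "c", posA = 150L, orientA = "fwd", chromB = "e", posB = 1L,
    orientB = "fwd", sv_class = "inter_translocation", source = "t",
    junction_id = "W", seq = paste0(flankA, flankWrong),
    breakpoint_offset = 150L, flankA_len = 150L, flankB_len = 150L)
  true_j <- dplyr::mutate(wrong, junction_id = "T", seq = true_junction)
  sc_wrong <- score_junctions(clipped, wrong)
  sc_true <- score_junctions(clipped, true_j)
  # alignments stop at the shared flank (barring chance single-base
  # extensions): support collapses relative to the true junction
  expect_true(all(sc_wrong$contributions$l_B <= 5))
  expect_lt(sc_wrong$scores$S, 0.05 * sc_true$scores$S)
  expect_equal(sc_true$scores$n_reads, 4L)
})

test_that("coverage adjustment scales scores down but never up", {
  scores <- tibble::tibble(junction_id = c("a", "b", "c"),
                           S = c(100, 100, 100),
                           log10_S = 2, n_reads = 10L)
  adj <- adjust_score_for_coverage(scores, local_cov = c(30, 60, 15),
                                   baseline_cov = 30)
  expect_equal(adj$S_adjusted, c(100, 50, 100))
  expect_warning(
    adj0 <- adjust_score_for_coverage(scores[1, ], local_cov = 0,
                                      baseline_cov = 30),
    "non-positive")
  expect_equal(adj0$S_adjusted, 100)
})
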
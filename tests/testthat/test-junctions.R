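cand_row <- function(chrom, pos, side, n = 3L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), clip_side = side,
                 n_reads = n, member_reads = list(paste0("r", pos)))
}

test_that("targeted pairing is the side-compatible Cartesian product", {
  cand <- dplyr::bind_rows(
    cand_row("chrA", c(100, 200), "right"),
    cand_row("chrB", c(300, 400, 500), "left")
  )
  rp <- region_pair("chrA", 1, 1000, "chrB", 1, 1000)
  specs <- pair_candidates_targeted(cand, rp)
  expect_equal(nrow(specs), 6) # 2 x 3
  # wrong clip side is excluded: a left clip in A cannot join forward
  cand2 <- dplyr::bind_rows(cand, cand_row("chrA", 150, "left"))
  specs2 <- pair_candidates_targeted(cand2, rp)
  expect_equal(nrow(specs2), 6)
  expect_false(150 %in% specs2$posA)
  # empty side warns and returns empty
  expect_warning(
    empty <- pair_candidates_targeted(cand_row("chrA", 100, "right"), rp),
    "no compatible")
  expect_equal(nrow(empty), 0)
})

test_that("an inversion search pairs right-clip candidates with each other", {
  cand <- cand_row("chr1", c(1000, 3000), "right")
  rp <- region_pair("chr1", 1, 5000, "chr1", 1, 5000,
                    orientA = "fwd", orientB = "rc")
  specs <- pair_candidates_targeted(cand, rp)
  # compatible side pairs: right x right, minus self-pairs, canonicalized
  expect_equal(nrow(specs), 1)
  expect_equal(specs$sv_class, "inversion")
  expect_equal(c(specs$posA, specs$posB), c(1000L, 3000L))
})

test_that("junction sequences are oriented reference flank concatenations", {
  ref <- c(chr1 = rand_dna(2000), chr2 = rand_dna(1000))
  spec <- tibble::tibble(chromA = "chr1", posA = 1050L, orientA = "fwd",
                         chromB = "chr2", posB = 500L, orientB = "fwd",
                         sv_class = "inter_translocation", source = "targeted")
  j <- build_junctions(spec, ref, flank_len = 100)
  expect_equal(nchar(j$seq), 200)
  expect_equal(j$breakpoint_offset, 100L)
  expect_equal(substr(j$seq, 1, 100), fetch_reference(ref, "chr1", 951, 1050))
  expect_equal(substr(j$seq, 101, 200), fetch_reference(ref, "chr2", 500, 599))
  expect_equal(j$sv_class, "inter_translocation")
})

test_that("same-chromosome geometries classify as deletion and inversion", {
  ref <- c(chr1 = rand_dna(20000))
  del <- tibble::tibble(chromA = "chr1", posA = 2000L, orientA = "fwd",
                        chromB = "chr1", posB = 7000L, orientB = "fwd",
                        sv_class = classify_sv("chr1", 2000, "fwd", "chr1", 7000, "fwd"),
                        source = "targeted")
  expect_equal(del$sv_class, "deletion")
  inv <- tibble::tibble(chromA = "chr1", posA = 2000L, orientA = "fwd",
                        chromB = "chr1", posB = 7000L, orientB = "rc",
                        sv_class = classify_sv("chr1", 2000, "fwd", "chr1", 7000, "rc"),
                        source = "targeted")
  expect_equal(inv$sv_class, "inversion")
  j <- build_junctions(inv, ref, flank_len = 80)
  # reverse-complemented B flank: bases after the offset equal the reverse
  # complement of the reference flank ending at posB
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fetch_reference(ref, "chr1", 6921, 7000))))
  expect_equal(substr(j$seq, 81, 160), rc)
})

test_that("junction construction is invertible and canonically stable", {
  ref <- c(chr1 = rand_dna(5000), chr2 = rand_dna(5000))
  spec <- tibble::tibble(chromA = "chr2", posA = 900L, orientA = "fwd",
                         chromB = "chr1", posB = 2500L, orientB = "fwd",
                         sv_class = "inter_translocation", source = "targeted")
  can <- stacktail:::canonicalize_specs(spec)
  # swapped input yields the mirrored canonical representation
  expect_equal(can$chromA, "chr1")
  expect_equal(can$posA, 2500L)
  expect_equal(can$orientA, "rc")
  expect_equal(can$orientB, "rc")
  j <- build_junctions(can, ref, flank_len = 60)
  # both flanks locate exactly in the reference (or its reverse complement)
  flankA <- substr(j$seq, 1, j$breakpoint_offset)
  flankB <- substr(j$seq, j$breakpoint_offset + 1, nchar(j$seq))
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(rc(flankA), fetch_reference(ref, "chr1", 2500, 2559))
  expect_equal(rc(flankB), fetch_reference(ref, "chr2", 841, 900))
  # the mirrored junction sequence is the reverse complement of the original
  mirror <- tibble::tibble(chromA = "chr2", posA = 900L, orientA = "fwd",
                           chromB = "chr1", posB = 2500L, orientB = "fwd",
                           sv_class = "inter_translocation", source = "targeted")
  jm <- build_junctions(mirror, ref, flank_len = 60)
  expect_equal(rc(jm$seq), j$seq)
})

test_that("flanks truncate at chromosome ends and fully-outside specs are skipped", {
  ref <- c(chr1 = rand_dna(300), chr2 = rand_dna(300))
  spec <- tibble::tibble(chromA = "chr1", posA = 30L, orientA = "fwd",
                         chromB = "chr2", posB = 280L, orientB = "fwd",
                         sv_class = "inter_translocation", source = "targeted")
  j <- build_junctions(spec, ref, flank_len = 100)
  expect_equal(j$flankA_len, 30L)
  expect_equal(j$flankB_len, 21L)
  expect_equal(j$breakpoint_offset, 30L)
})

test_that("BEDPE candidates load with midpoints, strands, and malformed-row warnings", {
  path <- tempfile(fileext = ".bedpe")
  writeLines(c(
    "chr1\t100\t200\tchr2\t300\t400\tsv1\t0\t+\t+",
    "chr1\t500\t600\tchr2\t700\t800",
    "chr1\tXYZ\t600\tchr2\t700\t800",
    "chr3\t1000\t1100\tchr4\t1200\t1300\tsv2\t0\t+\t-",
    "chr5\t10\t20\tchr6\t30\t40",
    "chr7\t1\t2\tchr8\t3\t4"
  ), path)
  expect_warning(specs <- load_external_candidates(path), "1 malformed")
  expect_equal(nrow(specs), 5)
  expect_equal(specs$posA[1], 150L) # midpoint of 1-based 101..200
  expect_equal(specs$orientA[1], "fwd")
  expect_equal(specs$orientB[3], "rc") # row 4 of the file, after the skip
  expect_true(is.na(specs$orientA[2]))
  writeLines("garbage", path)
  expect_error(suppressWarnings(load_external_candidates(path)), "no parseable")
})

test_that("simulator truth BEDPE round-trips into matching junction specs", {
  sim <- small_sim(seed = 33)
  path <- tempfile(fileext = ".bedpe")
  write_truth_bedpe(sim$planted$truth, path)
  specs <- load_external_candidates(path)
  expect_equal(nrow(specs), nrow(sim$planted$truth))
  expect_equal(specs$posA, sim$planted$truth$posA)
  expect_equal(specs$posB, sim$planted$truth$posB)
  expect_equal(specs$orientA, sim$planted$truth$orientA)
})

test_that("discordant-pair orientation votes map strand combinations to joins", {
  mk_pair <- function(n, strand, mate_strand, chrom = "chr1", mchrom = "chr2") {
    tibble::tibble(read_id = paste0("p", seq_len(n)), flag = 1L,
                   chrom = chrom, pos = 5000L, mapq = 60L, cigar = "100M",
                   strand = strand, seq = strrep("A", 100),
                   qual = strrep("I", 100), is_paired = TRUE, is_first = TRUE,
                   mate_chrom = mchrom, mate_pos = 4000L,
                   mate_strand = mate_strand)
  }
  un <- infer_orientation(mk_pair(10, "+", "-"), "chr1", 5000, "chr2", 4000)
  expect_equal(un$status, "determined")
  expect_equal(c(un$orientA, un$orientB), c("fwd", "fwd"))
  ff <- infer_orientation(mk_pair(10, "+", "+"), "chr1", 5000, "chr2", 4000)
  expect_equal(c(ff$orientA, ff$orientB), c("fwd", "rc"))
  none <- infer_orientation(mk_pair(2, "+", "-")[0, ], "chr1", 5000, "chr2", 4000)
  expect_equal(none$status, "undetermined")
  # undetermined specs expand to all four orientation pairs
  spec <- tibble::tibble(chromA = "chr1", posA = 5000L, orientA = NA_character_,
                         chromB = "chr2", posB = 4000L, orientB = NA_character_,
                         source = "external")
  ex <- stacktail:::expand_undetermined(spec)
  expect_equal(nrow(ex), 4)
  expect_setequal(paste(ex$orientA, ex$orientB),
                  c("fwd fwd", "fwd rc", "rc fwd", "rc rc"))
})

test_that("a simulated inversion's discordant pairs recover the rc orientation", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 30000, read_length = 100,
                    coverage = 30, paired = TRUE, insert_mean = 500,
                    insert_sd = 40, seed = 13)
  ref <- simulate_reference(cfg)
  plan <- sv_plan("inversion", "chr1", 10000, "chr1", 20000)
  planted <- plant_svs(ref, plan)
  reads <- simulate_reads(planted$donor, cfg)
  aln <- emit_truth_alignments(reads, planted$segment_map)
  tr <- planted$truth[1, ] # left inversion edge: fwd / rc
  o <- infer_orientation(aln, tr$chromA, tr$posA, tr$chromB, tr$posB,
                         window = 1000)
  # both inversion edges share these loci, so the vote sees same-strand (FF/RR)
  # pairs only: every vote implies one reverse-complemented flank, and a
  # determined outcome must name exactly one rc side
  expect_true(length(o$votes) > 0)
  expect_true(all(names(o$votes) %in% c("++", "--")))
  if (o$status == "determined") {
    expect_equal(sum(c(o$orientA, o$orientB) == "rc"), 1)
  }
})

test_that("excessive-coverage breakpoints are excluded against a brute-force depth scan", {
  set.seed(5)
  n <- 2000
  aln <- tibble::tibble(
    read_id = paste0("r", 1:n), flag = 0L, chrom = "chr1",
    pos = c(sample(1:19900, n - 500, replace = TRUE),
            sample(9950:10050, 500, replace = TRUE)),
    mapq = 60L, cigar = "100M", strand = "+", seq = strrep("A", 100),
    qual = strrep("I", 100), is_paired = FALSE, is_first = FALSE,
    mate_chrom = NA_character_, mate_pos = NA_integer_,
    mate_strand = NA_character_)
  cov <- compute_coverage(aln, c(chr1 = 20000L))
  specs <- tibble::tibble(
    chromA = "chr1", posA = c(10000L, 3000L), orientA = "fwd",
    chromB = "chr1", posB = c(15000L, 5000L), orientB = "fwd",
    sv_class = "deletion", source = "external")
  baseline <- median(as.numeric(cov$chr1))
  kept <- suppressMessages(exclude_high_coverage(specs, cov, k = 5,
                                                 baseline = baseline))
  # brute force: mean depth +/-500 from the raw position lists
  depth_at <- function(p) {
    win <- (p - 500):(p + 500)
    mean(vapply(win, function(x) sum(aln$pos <= x & aln$pos + 99 >= x),
                numeric(1)))
  }
  keep_bf <- vapply(seq_len(nrow(specs)), function(i) {
    depth_at(specs$posA[i]) <= 5 * baseline &&
      depth_at(specs$posB[i]) <= 5 * baseline
  }, logical(1))
  expect_equal(nrow(kept), sum(keep_bf))
  expect_equal(kept$posA, specs$posA[keep_bf])
  # all depths near baseline with a generous k leaves specs unchanged
  expect_equal(nrow(exclude_high_coverage(specs[2, ], cov, k = 50,
                                          baseline = baseline)), 1)
})

test_that("donor sequence around each truth junction equals the built junction", {
  sim <- small_sim(seed = 35)
  tr <- sim$planted$truth
  j <- build_junctions(
    dplyr::mutate(tr[, c("chromA", "posA", "orientA", "chromB", "posB",
                         "orientB", "sv_class")], source = "truth"),
    sim$ref, flank_len = 80)
  for (k in seq_len(nrow(tr))) {
    donor_seq <- sim$planted$donor[[tr$donor_chrom[k]]]
    around <- substr(donor_seq, tr$donor_pos[k] - 79, tr$donor_pos[k] + 80)
    jseq <- j$seq[k]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(jseq)))
    expect_true(around == jseq || around == rc)
  }
})
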
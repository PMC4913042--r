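#' @import tibble
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join row_number n desc across rename all_of
#'   distinct
#' @importFrom purrr map map2 pmap map_chr map_int map_dbl map_lgl
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils head tail
NULL

# reverse complement of a plain character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# flip an orientation label
flip_orient <- function(o) ifelse(o == "fwd", "rc", "fwd")

# clip side required on the A (5') flank for a given orientation
side_for_A <- function(orient) ifelse(orient == "fwd", "right", "left")
# clip side required on the B (3') flank
side_for_B <- function(orient) ifelse(orient == "fwd", "left", "right")

# reverse each string in a character vector
rev_str <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Phred+33 helpers
qual_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}
int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

#' Classify a junction geometry into a structural-variant class
#'
#' The class is read off the chromosome pair, the orientation pair and the
#' breakpoint order: different chromosomes give an inter-chromosomal
#' translocation; on one chromosome a forward/forward join with `posA < posB`
#' skips sequence (deletion), the mirrored configuration duplicates it
#' (tandem-duplication / insertion-like), and any mixed orientation is an
#' inversion edge.
#'
#' @param chromA,chromB chromosome names.
#' @param posA,posB 1-based breakpoint coordinates.
#' @param orientA,orientB flank orientations, `"fwd"` or `"rc"`.
#' @return character vector of classes: `"deletion"`, `"duplication"`,
#'   `"inversion"`, or `"inter_translocation"`.
#' @export
classify_sv <- function(chromA, posA, orientA, chromB, posB, orientB) {
  dplyr::case_when(
    chromA != chromB ~ "inter_translocation",
    orientA != orientB ~ "inversion",
    orientA == "fwd" & posA < posB ~ "deletion",
    orientA == "rc" & posA < posB ~ "duplication",
    orientA == "fwd" ~ "duplication",
    TRUE ~ "deletion"
  )
}

# Canonicalize junction specs: a junction and its mirror
# (bpB, flip(orientB), bpA, flip(orientA)) describe the same adjacency; keep
# the representation whose (chrom, pos) key sorts first. Class is computed
# before swapping so it is representation-invariant.
canonicalize_specs <- function(specs) {
  if (nrow(specs) == 0) return(specs)
  swap <- (specs$chromB < specs$chromA) |
    (specs$chromB == specs$chromA & specs$posB < specs$posA)
  out <- specs
  out$chromA[swap] <- specs$chromB[swap]
  out$posA[swap] <- specs$posB[swap]
  out$orientA[swap] <- flip_orient(specs$orientB[swap])
  out$chromB[swap] <- specs$chromA[swap]
  out$posB[swap] <- specs$posA[swap]
  out$orientB[swap] <- flip_orient(specs$orientA[swap])
  out
}

junction_id <- function(chromA, posA, orientA, chromB, posB, orientB) {
  paste0(chromA, ":", posA, ":", orientA, "|", chromB, ":", posB, ":", orientB)
}

# deterministic per-purpose RNG substreams derived from one user seed
derive_seed <- function(seed, purpose) {
  offsets <- c(genome = 11, plan = 101, positions = 211, errors = 307,
               pairs = 401, other = 503)
  as.integer((as.numeric(seed) * 1009 + offsets[[purpose]]) %% 2147483587)
}
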
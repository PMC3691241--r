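#' @importFrom Biostrings DNAStringSet oligonucleotideFrequency mkAllStrings
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Split a masked sequence into valid segments
#'
#' A valid segment is a maximal run of uppercase `A`, `C`, `G`, `T`.
#' Soft-masked (lowercase) bases and undefined bases (`N`) both break runs:
#' every sequence feature in this package is computed on the non-repetitive,
#' defined part of the window only, so repeat-derived CpG-rich decoys (Alu
#' and friends) cannot masquerade as promoter signal.
#'
#' @param seq A single sequence string.
#' @return Character vector of segments in left-to-right order (possibly
#'   empty).
#' @export
valid_segments <- function(seq) {
  m <- gregexpr("[ACGT]+", seq)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(seq, list(m))[[1]]
}

# Total overlapping occurrences of each k-mer across segments, in
# lexicographic k-mer order. Returns an all-zero vector when no segment
# reaches length k.
kmer_counts <- function(segments, k) {
  words <- Biostrings::mkAllStrings(DNA_BASES, k)
  segments <- segments[nchar(segments) >= k]
  if (length(segments) == 0L)
    return(stats::setNames(numeric(length(words)), words))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(segments), width = k)
  colSums(counts)[words]
}

#' n-mer frequency features (NM family)
#'
#' Overlapping occurrence counts of every word of length 1 to 4, summed
#' across valid segments and normalised by the total valid length of the
#' window. 4 + 16 + 64 + 256 = 340 features; a fully masked window yields
#' all zeros.
#'
#' @param seq A single sequence string.
#' @param ks Word lengths to include.
#' @return Named numeric vector; names follow `NM_k<k>_<word>`.
#' @export
nmer_features <- function(seq, ks = 1:4) {
  segs <- valid_segments(seq)
  L <- sum(nchar(segs))
  out <- lapply(ks, function(k) {
    cnt <- kmer_counts(segs, k)
    v <- if (L > 0L) cnt / L else cnt * 0
    stats::setNames(v, sprintf("NM_k%d_%s", k, names(cnt)))
  })
  unlist(out)
}

# The 16 length-4 reverse-complement palindromes, one per choice of the
# first two bases, lexicographically ordered.
palindromic_4mers <- function() {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  p <- as.vector(outer(DNA_BASES, DNA_BASES, function(a, b)
    paste0(a, b, comp[b], comp[a])))
  sort(p)
}

# Count windows of length 2h within one segment that equal their own
# reverse complement. Vectorised over window start positions.
count_palindromes <- function(chars, comp_chars, h) {
  w <- 2L * h
  n <- length(chars)
  if (n < w) return(0L)
  m <- n - w + 1L
  ok <- rep(TRUE, m)
  for (i in 0:(h - 1L))
    ok <- ok & (chars[seq_len(m) + i] == comp_chars[seq_len(m) + w - 1L - i])
  sum(ok)
}

#' Reverse-complement palindrome features (PL family)
#'
#' Two blocks: (a) the per-pattern normalised frequency of each of the 16
#' length-4 palindromes (a word equal to its own reverse complement), and
#' (b) one aggregate normalised count of all palindromic windows for each
#' half-length in `half_lengths`. Counting is overlapping, restricted to
#' valid segments, and normalised by total valid length. Defaults give
#' 16 + 4 = 20 features.
#'
#' @param seq A single sequence string.
#' @param half_lengths Palindrome half-lengths for the aggregate block.
#' @return Named numeric vector (`PL_<pattern>`, `PL_agg_h<h>`).
#' @export
palindrome_features <- function(seq, half_lengths = 2:5) {
  segs <- valid_segments(seq)
  L <- sum(nchar(segs))
  pats <- palindromic_4mers()
  per_pattern <- kmer_counts(segs, 4L)[pats]
  agg <- vapply(half_lengths, function(h) {
    sum(vapply(segs, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      comp_chars <- chartr("ACGT", "TGCA", s)
      comp_chars <- strsplit(comp_chars, "", fixed = TRUE)[[1]]
      count_palindromes(chars, comp_chars, h)
    }, numeric(1)))
  }, numeric(1))
  vals <- c(per_pattern, agg)
  vals <- if (L > 0L) vals / L else vals * 0
  stats::setNames(vals, c(sprintf("PL_%s", pats),
                          sprintf("PL_agg_h%d", half_lengths)))
}

SPECIAL_PATTERNS <- c("G**G" = "G..G",
                      "G**G**G" = "G..G..G",
                      "GC**GC**GC" = "GC..GC..GC")

# Overlapping regex matches via zero-width lookahead.
count_overlapping <- function(x, pattern) {
  m <- gregexpr(sprintf("(?=%s)", pattern), x, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Promoter-associated wildcard motif features (S family)
#'
#' Normalised overlapping occurrence counts of the three over-represented
#' promoter patterns `G**G`, `G**G**G` and `GC**GC**GC`, where `*` matches
#' any single base. Counted within valid segments, normalised by total
#' valid length.
#'
#' @param seq A single sequence string.
#' @return Named numeric vector of length 3 (`S_<pattern>`).
#' @export
special_features <- function(seq) {
  segs <- valid_segments(seq)
  L <- sum(nchar(segs))
  cnt <- vapply(SPECIAL_PATTERNS, function(p)
    sum(vapply(segs, count_overlapping, integer(1), pattern = p)),
    numeric(1))
  vals <- if (L > 0L) cnt / L else cnt * 0
  stats::setNames(vals, sprintf("S_%s", names(SPECIAL_PATTERNS)))
}

#' CpG and base counts of a window, repeat-excluded
#'
#' Counts are restricted to uppercase bases: a CpG dinucleotide is counted
#' only when both its C and G are unmasked and adjacent, and `L` is the
#' number of unmasked, defined bases — the length of the non-repetitive
#' sequence actually analysed.
#'
#' @param seq A single sequence string (typically one tile of a window).
#' @return List with `n_cpg`, `n_c`, `n_g`, `L`.
#' @export
window_counts <- function(seq) {
  list(n_cpg = count_overlapping(seq, "CG"),
       n_c = nchar(gsub("[^C]", "", seq)),
       n_g = nchar(gsub("[^G]", "", seq)),
       L = nchar(gsub("[^ACGT]", "", seq)))
}

cpg_oe <- function(wc) {
  if (wc$L == 0L || wc$n_c * wc$n_g == 0) return(0)
  wc$n_cpg * wc$L / (wc$n_c * wc$n_g)
}

gc_content <- function(wc) {
  if (wc$L == 0L) return(0)
  (wc$n_c + wc$n_g) / wc$L
}

# Non-overlapping tiling; a trailing partial tile is dropped.
tile_sequence <- function(seq, width) {
  n <- nchar(seq) %/% width
  if (n == 0L) return(character(0))
  starts <- (seq_len(n) - 1L) * width + 1L
  substring(seq, starts, starts + width - 1L)
}

#' CpG-island features (CI family)
#'
#' For each tiling window length, the sequence is cut into non-overlapping
#' tiles and the CpG observed/expected ratio
#' `O/E = n_CpG * L / (n_C * n_G)` and G+C content `(n_C + n_G) / L` are
#' computed per tile on the non-repetitive bases; the feature reported per
#' length is the maximum over tiles (a promoter CpG island shows up as a
#' peak tile), or the mean if `aggregate = "mean"`. Degenerate tiles
#' (`L = 0` or no C or no G) contribute 0. Defaults give 2 features for
#' each of the four lengths, 8 in total.
#'
#' @param seq A single sequence string.
#' @param window_lengths Tile lengths in bp.
#' @param aggregate `"max"` (default) or `"mean"` over tiles.
#' @return Named numeric vector (`CI_<len>_OE`, `CI_<len>_GC`).
#' @export
cpg_island_features <- function(seq, window_lengths = c(125L, 250L, 500L, 1000L),
                                aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "max") max else mean
  if (any(window_lengths > nchar(seq)))
    abort_validation("CI window length exceeds sequence length %d", nchar(seq))
  out <- lapply(window_lengths, function(w) {
    tiles <- tile_sequence(seq, w)
    wcs <- lapply(tiles, window_counts)
    c(agg_fun(vapply(wcs, cpg_oe, numeric(1))),
      agg_fun(vapply(wcs, gc_content, numeric(1))))
  })
  stats::setNames(unlist(out),
                  as.vector(rbind(sprintf("CI_%d_OE", window_lengths),
                                  sprintf("CI_%d_GC", window_lengths))))
}

#' Concatenate feature families into one vector
#'
#' Families are concatenated in the fixed order NM, PL, S, CI, MT. The
#' default configuration yields 385 features with 14 methylome tracks
#' (340 + 20 + 3 + 8 + 14) and 371 without the MT block.
#'
#' @param nm,pl,s,ci Named numeric vectors from the corresponding
#'   extractors.
#' @param mt Optional named numeric vector of methylation features.
#' @return Named numeric vector.
#' @export
assemble_features <- function(nm, pl, s, ci, mt = NULL) {
  v <- c(nm, pl, s, ci, mt)
  dup <- duplicated(names(v))
  if (any(dup))
    abort_validation("duplicate feature name(s): %s",
                     paste(unique(names(v)[dup]), collapse = ", "))
  v
}
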
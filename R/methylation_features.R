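#' Configuration for methylation (MT) feature scoring
#'
#' @param coverage_halfsat Read coverage at which the confidence weight
#'   `r / (r + coverage_halfsat)` reaches one half. Small values trust
#'   low-coverage calls; large values demand deep coverage.
#' @param island_oe_min,island_gc_min Gardiner-Garden thresholds a tile
#'   must reach (CpG O/E >= 0.6 and G+C >= 0.5 by default) to count as
#'   island-like when tallying CpG islands in a window.
#' @param island_window Tile width in bp for island detection.
#' @return A list of class `mt_config`.
#' @export
mt_config <- function(coverage_halfsat = 10, island_oe_min = 0.6,
                      island_gc_min = 0.5, island_window = 125L) {
  stopifnot(coverage_halfsat > 0, island_oe_min > 0, island_gc_min > 0,
            island_window > 0)
  structure(list(coverage_halfsat = coverage_halfsat,
                 island_oe_min = island_oe_min,
                 island_gc_min = island_gc_min,
                 island_window = as.integer(island_window)),
            class = "mt_config")
}

#' Count CpG islands in a window
#'
#' The window is tiled with non-overlapping tiles of `cfg$island_window` bp;
#' a tile is island-like when its repeat-excluded CpG O/E and G+C both reach
#' the configured thresholds. Each maximal run of consecutive island-like
#' tiles counts as one island.
#'
#' @param seq A single sequence string.
#' @param cfg An [mt_config()].
#' @return Integer island count (>= 0).
#' @export
count_cpg_islands <- function(seq, cfg = mt_config()) {
  tiles <- tile_sequence(seq, cfg$island_window)
  if (length(tiles) == 0L) return(0L)
  island <- vapply(tiles, function(t) {
    wc <- window_counts(t)
    cpg_oe(wc) >= cfg$island_oe_min && gc_content(wc) >= cfg$island_gc_min
  }, logical(1))
  r <- rle(island)
  sum(r$values)
}

#' Coverage-weighted methylation score of a region for one methylome
#'
#' Each methylation site inside the region contributes its methylation
#' probability damped by a saturating read-coverage confidence weight, and
#' the sum is normalised by the number of CpG islands in the region:
#' `score = (1 / max(n, 1)) * sum_s p_s * r_s / (r_s + c)` with `c` the
#' coverage half-saturation. High methylation probability raises the score;
#' low read coverage discounts it.
#'
#' @param region List with `chrom`, `start`, `end` (0-based half-open).
#' @param track A methylome track (see [read_methylation_track()]).
#' @param n_islands CpG-island count of the region, from
#'   [count_cpg_islands()].
#' @param cfg An [mt_config()].
#' @return Non-negative numeric score; 0 when no site falls in the region.
#' @export
methylation_score <- function(region, track, n_islands, cfg = mt_config()) {
  s <- track$sites
  inside <- s$chrom == region$chrom & s$pos >= region$start & s$pos < region$end
  if (!any(inside)) return(0)
  p <- s$p[inside]
  r <- s$r[inside]
  sum(p * r / (r + cfg$coverage_halfsat)) / max(n_islands, 1L)
}

#' Methylation features (MT family)
#'
#' One feature per methylome track, all sharing the island count computed
#' once from the window sequence.
#'
#' @param region Genomic span of the window (`chrom`, `start`, `end`).
#' @param seq The window sequence (for island counting).
#' @param tracks List of methylome tracks with unique `sample_id`s.
#' @param cfg An [mt_config()].
#' @return Named numeric vector (`MT_<sample_id>`), one value per track.
#' @export
methylation_features <- function(region, seq, tracks, cfg = mt_config()) {
  if (length(tracks) == 0L) return(stats::setNames(numeric(0), character(0)))
  ids <- vapply(tracks, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    abort_validation("duplicate track sample_id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- count_cpg_islands(seq, cfg)
  vals <- vapply(tracks, methylation_score, numeric(1),
                 region = region, n_islands = n, cfg = cfg)
  stats::setNames(vals, sprintf("MT_%s", ids))
}
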
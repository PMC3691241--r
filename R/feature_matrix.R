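#' Construct a labeled feature matrix
#'
#' The central container of the pipeline: one row per sample window, one
#' column per named feature, plus a binary label (1 = TSS-positive,
#' 0 = negative).
#'
#' @param values Numeric matrix (samples x features) with column names.
#' @param labels Integer/numeric vector of 0/1 labels, one per row.
#' @param sample_ids Optional sample identifiers; defaults to row names.
#' @return An object of class `feature_matrix`: a list with `values`,
#'   `labels`, `sample_ids`, `feature_names`.
#' @export
feature_matrix <- function(values, labels, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    abort_validation("feature matrix must have feature names")
  if (length(labels) != nrow(values))
    abort_validation("labels length (%d) != number of samples (%d)",
                     length(labels), nrow(values))
  if (!all(labels %in% c(0L, 1L)))
    abort_validation("labels must be 0 or 1")
  if (any(!is.finite(values)))
    abort_validation("non-finite feature value(s)")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  structure(list(values = values, labels = as.integer(labels),
                 sample_ids = sample_ids, feature_names = colnames(values)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write a feature matrix to TSV
#'
#' Layout: header row of feature names with `sample_id` first and `label`
#' last; one row per sample.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample_id = fm$sample_ids, fm$values,
                   label = fm$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path Path to a TSV written by [write_feature_matrix()].
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) abort_validation("feature matrix not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  cn <- colnames(dt)
  if (cn[1] != "sample_id" || cn[length(cn)] != "label")
    abort_validation("feature matrix TSV must start with sample_id and end with label")
  vals <- as.matrix(dt[, -c(1, length(cn)), drop = FALSE])
  feature_matrix(vals, dt$label, sample_ids = dt$sample_id)
}

#' Extract all feature families for one window
#'
#' @param window A window as returned by [extract_window()].
#' @param tracks List of methylome tracks (possibly empty) for the MT block.
#' @param ci_window_lengths Tile lengths for the CI family.
#' @param pl_half_lengths Palindrome half-lengths for the PL aggregates.
#' @param mt_cfg An [mt_config()].
#' @param include_mt Set `FALSE` to omit the MT block even when tracks are
#'   supplied.
#' @return Named numeric feature vector (385 values at defaults with 14
#'   tracks; 371 without MT).
#' @export
window_features <- function(window, tracks = list(),
                            ci_window_lengths = c(125L, 250L, 500L, 1000L),
                            pl_half_lengths = 2:5,
                            mt_cfg = mt_config(), include_mt = TRUE) {
  seq <- window$seq
  mt <- if (include_mt && length(tracks))
    methylation_features(window$region, seq, tracks, mt_cfg)
  else NULL
  assemble_features(nm = nmer_features(seq),
                    pl = palindrome_features(seq, pl_half_lengths),
                    s = special_features(seq),
                    ci = cpg_island_features(seq, ci_window_lengths),
                    mt = mt)
}

#' Extract the feature matrix for a set of TSS loci
#'
#' Runs strand-aware window extraction for every BED locus and assembles
#' the full feature vector per window. Out-of-bounds loci abort the run,
#' listing every offending record.
#'
#' @param genome Named character vector of chromosomes ([read_fasta()]).
#' @param regions Data frame of loci ([read_bed()]).
#' @param tracks List of methylome tracks.
#' @param labels Optional 0/1 labels per locus (defaults to all 0; join
#'   with a truth table for supervised work).
#' @param upstream,total_len Window geometry (see [extract_window()]).
#' @inheritParams window_features
#' @return A [feature_matrix()].
#' @export
extract_feature_matrix <- function(genome, regions, tracks = list(),
                                   labels = NULL,
                                   upstream = 500L, total_len = 1000L,
                                   ci_window_lengths = c(125L, 250L, 500L, 1000L),
                                   pl_half_lengths = 2:5,
                                   mt_cfg = mt_config(), include_mt = TRUE) {
  if (is.null(labels)) labels <- rep(0L, nrow(regions))
  errs <- character(0)
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    w <- tryCatch(extract_window(genome, regions[i, ], upstream, total_len),
                  mirtss_validation_error = function(e) e)
    if (inherits(w, "error")) {
      errs <- c(errs, conditionMessage(w))
      next
    }
    rows[[i]] <- window_features(w, tracks, ci_window_lengths,
                                 pl_half_lengths, mt_cfg, include_mt)
  }
  if (length(errs))
    abort_validation("window extraction failed for %d record(s):\n%s",
                     length(errs), paste(errs, collapse = "\n"))
  feature_matrix(do.call(rbind, rows), labels, sample_ids = regions$name)
}
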
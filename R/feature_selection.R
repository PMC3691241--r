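#' Two-class F-score of a single feature
#'
#' Ratio of between-class separation to pooled within-class variance:
#' \deqn{F = \frac{(\bar{x}^{+}-\bar{x})^2 + (\bar{x}^{-}-\bar{x})^2}
#'            {\frac{1}{n_{+}-1}\sum_k (x^{+}_k-\bar{x}^{+})^2 +
#'             \frac{1}{n_{-}-1}\sum_k (x^{-}_k-\bar{x}^{-})^2}}
#' where \eqn{\bar{x}} is the grand mean over all samples. Larger is more
#' discriminative. A zero numerator gives 0; a positive numerator over a
#' zero denominator (a perfect separator with no within-class variance)
#' gives `Inf`, which sorts ahead of every finite score.
#'
#' @param pos_values,neg_values Feature values of the positive / negative
#'   samples (at least two each).
#' @return Non-negative numeric (possibly `Inf`).
#' @export
f_score <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L)
    abort_validation("F-score needs at least 2 samples per class")
  grand <- mean(c(pos_values, neg_values))
  num <- (mean(pos_values) - grand)^2 + (mean(neg_values) - grand)^2
  den <- sum((pos_values - mean(pos_values))^2) / (length(pos_values) - 1L) +
         sum((neg_values - mean(neg_values))^2) / (length(neg_values) - 1L)
  if (num == 0) return(0)
  if (den == 0) return(Inf)
  num / den
}

selection_result <- function(features, scores, method) {
  structure(data.frame(rank = seq_along(features), feature = features,
                       score = scores, stringsAsFactors = FALSE),
            method = method, class = c("selection_result", "data.frame"))
}

#' Rank all features by F-score
#'
#' Descending F-score; ties (including multiple `Inf` sentinels) are broken
#' by feature name so the ranking is fully deterministic.
#'
#' @param fm A [feature_matrix()].
#' @return A `selection_result` data frame with columns `rank`, `feature`,
#'   `score`.
#' @export
rank_by_fscore <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  pos <- fm$labels == 1L
  scores <- apply(fm$values, 2L, function(v) f_score(v[pos], v[!pos]))
  ord <- order(-scores, names(scores))
  selection_result(names(scores)[ord], unname(scores[ord]), "fscore")
}

#' Equal-frequency discretisation
#'
#' Bins values into `n_bins` states at the empirical quantiles. Values
#' tied with a bin boundary fall into the lower bin; constant input
#' collapses to a single state 0. Heavily zero-inflated features (most
#' k-mer frequencies) therefore land their zero mass in one state rather
#' than spreading it across bins.
#'
#' @param values Numeric vector.
#' @param n_bins Number of states (>= 2).
#' @return Integer vector of states in `0:(n_bins-1)`.
#' @export
discretize <- function(values, n_bins = 3L) {
  stopifnot(n_bins >= 2L)
  qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  inner <- qs[-c(1L, length(qs))]
  if (length(inner) == 0L) return(rep(0L, length(values)))
  as.integer(cut(values, breaks = c(-Inf, inner, Inf), right = TRUE,
                 labels = FALSE)) - 1L
}

#' Normalised mutual information of two discrete variables
#'
#' Plug-in mutual information over the empirical joint distribution,
#' normalised by the geometric mean of the marginal entropies (natural
#' logs): `NI(X;Y) = I(X;Y) / sqrt(H(X) H(Y))`, bounded in \[0, 1\],
#' symmetric, and defined as 0 when either variable is constant.
#'
#' @param x,y Equal-length vectors of discrete states.
#' @return Numeric in \[0, 1\].
#' @export
normalized_mi <- function(x, y) {
  if (length(x) != length(y))
    abort_validation("normalized_mi: lengths differ (%d vs %d)",
                     length(x), length(y))
  tab <- table(x, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  pp <- as.vector(pxy)
  pe <- as.vector(outer(px, py))
  keep <- pp > 0
  mi <- sum(pp[keep] * log(pp[keep] / pe[keep]))
  min(max(mi / sqrt(hx * hy), 0), 1)
}

#' Greedy VWMRmR feature selection
#'
#' Variable-weighted maximal-relevance minimal-redundancy selection on
#' discretised features. The first feature maximises the normalised mutual
#' information (NMI) with the class label; thereafter, with `m` features
#' already in the selected set `S`, the next feature maximises
#' `J(f) = NI(f; c) - w(m) * mean_{g in S} NI(f; g)`. The class-relevance
#' weight is fixed at 1 while the redundancy weight `w(m)` grows with the
#' size of the selected set; the default schedule `w(m) = m / (m + 1)`
#' starts near the classic mRMR balance and approaches parity. Setting
#' `redundancy_weight = function(m) 0` recovers pure relevance ranking,
#' `function(m) 1` recovers mRMR with NMI.
#'
#' @param fm A [feature_matrix()].
#' @param k Number of features to select (1 to d).
#' @param n_bins Discretisation states (see [discretize()]).
#' @param redundancy_weight Function of the current selected-set size `m`
#'   returning the redundancy weight `w(m)`.
#' @return A `selection_result` in selection order; `score` holds the
#'   criterion value `J` at the step each feature was picked.
#' @export
vwmrmr_select <- function(fm, k, n_bins = 3L,
                          redundancy_weight = function(m) m / (m + 1)) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- ncol(fm$values)
  if (k < 1L || k > d)
    abort_validation("k must be in 1..%d, got %d", d, k)
  disc <- apply(fm$values, 2L, discretize, n_bins = n_bins)
  feats <- colnames(fm$values)
  relevance <- vapply(seq_len(d), function(j)
    normalized_mi(disc[, j], fm$labels), numeric(1))
  names(relevance) <- feats
  # pairwise NMI between features, filled lazily as candidates are scored
  red <- matrix(NA_real_, d, d, dimnames = list(feats, feats))
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(d)
  for (step in seq_len(k)) {
    if (length(selected) == 0L) {
      j_vals <- relevance[remaining]
    } else {
      w <- redundancy_weight(length(selected))
      for (s in selected) {
        todo <- remaining[is.na(red[remaining, s])]
        for (f in todo) {
          red[f, s] <- red[s, f] <- normalized_mi(disc[, f], disc[, s])
        }
      }
      mean_red <- rowMeans(red[remaining, selected, drop = FALSE])
      j_vals <- relevance[remaining] - w * mean_red
    }
    # round before ordering so criteria that are equal up to floating-point
    # noise tie and fall through to the deterministic name order
    pick <- remaining[order(-round(j_vals, 10L), feats[remaining])[1]]
    selected <- c(selected, pick)
    scores <- c(scores, j_vals[[match(pick, remaining)]])
    remaining <- setdiff(remaining, pick)
  }
  selection_result(feats[selected], scores, "vwmrmr")
}

FEATURE_CATEGORIES <- c("NM", "NM-CG", "NM-1", "NM-2", "NM-3", "NM-4",
                        "CI", "PL", "S", "MT")

# Category membership derived from the feature-name scheme. A feature may
# belong to several categories (every NM_k2_* is NM and NM-2, and NM-CG too
# if its word contains CG).
feature_categories <- function(feature) {
  if (grepl("^NM_k[1-4]_", feature)) {
    k <- sub("^NM_k([1-4])_.*$", "\\1", feature)
    word <- sub("^NM_k[1-4]_", "", feature)
    cats <- c("NM", paste0("NM-", k))
    if (grepl("CG", word, fixed = TRUE)) cats <- c(cats, "NM-CG")
    return(cats)
  }
  if (startsWith(feature, "CI_")) return("CI")
  if (startsWith(feature, "PL_")) return("PL")
  if (startsWith(feature, "S_")) return("S")
  if (startsWith(feature, "MT_")) return("MT")
  abort_validation("feature '%s' does not match any category", feature)
}

#' Per-category rank summary of a feature ranking
#'
#' Summarises where each feature family lands in a ranked list: minimum,
#' maximum and average 1-based rank per category. The n-mer family is
#' additionally split into NM-1..NM-4 by word length and NM-CG (words
#' containing `CG` as a substring); categories overlap by design.
#'
#' @param result A `selection_result` from [rank_by_fscore()] or
#'   [vwmrmr_select()].
#' @return Data frame with columns `category`, `n_features`, `min_rank`,
#'   `max_rank`, `avg_rank`, one row per non-empty category in the fixed
#'   display order NM, NM-CG, NM-1..NM-4, CI, PL, S, MT.
#' @export
category_rank_summary <- function(result) {
  stopifnot(is.data.frame(result), all(c("rank", "feature") %in% names(result)))
  cats <- lapply(result$feature, feature_categories)
  rows <- lapply(FEATURE_CATEGORIES, function(cat) {
    ranks <- result$rank[vapply(cats, function(cc) cat %in% cc, logical(1))]
    if (length(ranks) == 0L) return(NULL)
    data.frame(category = cat, n_features = length(ranks),
               min_rank = min(ranks), max_rank = max(ranks),
               avg_rank = mean(ranks), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a selection result (and its rank summary) to TSV
#'
#' @param result A `selection_result`.
#' @param path Output TSV for the ranked list (`rank`, `feature`, `score`).
#' @param summary_path Optional output TSV for the per-category rank
#'   summary.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path, summary_path = NULL) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  if (!is.null(summary_path))
    data.table::fwrite(category_rank_summary(result), summary_path, sep = "\t")
  invisible(path)
}
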
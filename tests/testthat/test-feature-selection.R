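test_that("F-score matches hand-computed and degenerate cases", {
  expect_equal(f_score(c(1, 0), c(0, 1)), 0)
  expect_equal(f_score(c(2, 0), c(1, -1)), 0.125)
  expect_identical(f_score(c(1, 1), c(0, 0)), Inf)
  expect_error(f_score(1, c(0, 1)), class = "mirtss_validation_error")
})

test_that("F-score is shift-invariant and scale-invariant", {
  set.seed(19)
  for (trial in 1:20) {
    pos <- rnorm(8); neg <- rnorm(11, mean = 0.5)
    f <- f_score(pos, neg)
    expect_equal(f_score(pos + 3.7, neg + 3.7), f)
    expect_equal(f_score(pos * -2.5, neg * -2.5), f)
  }
})

test_that("F-score ranking sorts descending with lexicographic ties", {
  vals <- cbind(f1 = c(1, 2, 0, 1), f2 = c(0, 1, 0, 1), f3 = c(5, 6, 0, 1))
  labels <- c(1, 1, 0, 0)
  fm <- feature_matrix(vals, labels)
  r <- rank_by_fscore(fm)
  scores <- sapply(colnames(vals), function(f)
    oracle_fscore(vals[labels == 1, f], vals[labels == 0, f]))
  expect_equal(r$feature, names(sort(-scores)))
  # exact tie -> name order
  tied <- feature_matrix(cbind(b_feat = c(0, 1, 0, 1), a_feat = c(0, 1, 0, 1)),
                         labels)
  # degenerate: identical columns, equal scores, a_feat must come first
  expect_equal(rank_by_fscore(tied)$feature[1], "a_feat")
})

test_that("F-score ranking agrees with brute force on random matrices", {
  set.seed(23)
  for (trial in 1:10) {
    fm <- rand_feature_matrix(n = 30, d = 10, informative = 3)
    r <- rank_by_fscore(fm)
    pos <- fm$labels == 1
    scores <- sapply(colnames(fm$values), function(f)
      oracle_fscore(fm$values[pos, f], fm$values[!pos, f]))
    expect_equal(r$feature, names(scores)[order(-scores, names(scores))])
    expect_equal(r$score, unname(sort(scores, decreasing = TRUE)))
  }
})

test_that("equal-frequency discretisation follows the quantile rule", {
  expect_identical(discretize(1:6, 3), c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_identical(discretize(c(5, 5, 5), 3), c(0L, 0L, 0L))
  expect_identical(discretize(c(0, 1, 0, 1, 1, 0), 2), c(0L, 1L, 0L, 1L, 1L, 0L))
})

test_that("normalised MI is symmetric, bounded and matches plug-in arithmetic", {
  x <- c(0, 0, 1, 1)
  expect_equal(normalized_mi(x, x), 1)
  expect_equal(normalized_mi(x, c(0, 1, 0, 1)), 0)
  # joint counts [[2,1],[1,2]]
  a <- c(0, 0, 0, 1, 1, 1)
  b <- c(0, 0, 1, 0, 1, 1)
  expect_equal(normalized_mi(a, b), oracle_nmi(a, b))
  hand <- (2 * (2 / 6) * log((2 / 6) / 0.25) +
           2 * (1 / 6) * log((1 / 6) / 0.25)) / log(2)
  expect_equal(normalized_mi(a, b), hand)
  set.seed(29)
  for (trial in 1:20) {
    x <- sample(0:2, 40, replace = TRUE)
    y <- sample(0:3, 40, replace = TRUE)
    v <- normalized_mi(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, normalized_mi(y, x))
    expect_equal(v, oracle_nmi(x, y))
  }
  expect_equal(normalized_mi(rep(1, 10), sample(0:1, 10, replace = TRUE)), 0)
  expect_error(normalized_mi(1:3, 1:4), class = "mirtss_validation_error")
})

test_that("redundant copies of the best feature are penalised", {
  set.seed(37)
  labels <- rep(c(1L, 0L), each = 15)
  f1 <- labels + rnorm(30, sd = 0.01)
  vals <- cbind(f1 = f1, f2 = f1, f3 = rnorm(30))
  fm <- feature_matrix(vals, labels)
  # under the default growing schedule the order matches the oracle at
  # every step (the duplicate still outranks pure noise at w(1) = 1/2)
  sel <- vwmrmr_select(fm, 3)
  expect_equal(sel$feature, oracle_vwmrmr(vals, labels, 3))
  expect_lt(sel$score[sel$feature == "f2"], sel$score[sel$feature == "f1"])
  # a strong constant redundancy weight defers the duplicate behind noise
  heavy <- vwmrmr_select(fm, 3, redundancy_weight = function(m) 2)
  expect_equal(heavy$feature, c("f1", "f3", "f2"))
  expect_equal(vwmrmr_select(fm, 1)$feature, "f1")
  expect_error(vwmrmr_select(fm, 4), class = "mirtss_validation_error")
})

test_that("zero redundancy weight reduces to pure relevance ranking", {
  set.seed(41)
  fm <- rand_feature_matrix(n = 40, d = 8, informative = 3)
  sel0 <- vwmrmr_select(fm, 8, redundancy_weight = function(m) 0)
  rel <- sapply(colnames(fm$values), function(f)
    oracle_nmi(oracle_discretize(fm$values[, f]), fm$labels))
  expect_equal(sel0$feature, names(rel)[order(-rel, names(rel))])
})

test_that("every greedy step matches the independent oracle", {
  set.seed(43)
  for (trial in 1:10) {
    d <- sample(3:8, 1)
    fm <- rand_feature_matrix(n = sample(16:40, 1), d = d,
                              informative = sample(0:2, 1))
    expect_equal(vwmrmr_select(fm, d)$feature,
                 oracle_vwmrmr(fm$values, fm$labels, d))
  }
})

test_that("category summaries use the feature-name scheme", {
  res <- structure(data.frame(rank = 1:3,
                              feature = c("S_a", "CI_b", "S_c"),
                              score = c(3, 2, 1)),
                   class = c("selection_result", "data.frame"))
  s <- category_rank_summary(res)
  srow <- s[s$category == "S", ]
  expect_equal(c(srow$min_rank, srow$max_rank, srow$avg_rank), c(1, 3, 2))
  cirow <- s[s$category == "CI", ]
  expect_equal(c(cirow$min_rank, cirow$max_rank, cirow$avg_rank), c(2, 2, 2))

  expect_true("NM-CG" %in% feature_categories("NM_k2_CG"))
  expect_true("NM-CG" %in% feature_categories("NM_k4_ACGT"))
  expect_false("NM-CG" %in% feature_categories("NM_k4_AAAA"))
  expect_error(category_rank_summary(
    data.frame(rank = 1, feature = "XX_odd", score = 1)),
    class = "mirtss_validation_error")
})

test_that("NM-CG membership equals brute-force enumeration over 385 names", {
  set.seed(47)
  seq <- rand_dna(1000L)
  mt <- stats::setNames(runif(14), sprintf("MT_ctrl%02d", 1:14))
  feats <- assemble_features(nmer_features(seq), palindrome_features(seq),
                             special_features(seq), cpg_island_features(seq), mt)
  ranking <- structure(data.frame(rank = seq_along(feats),
                                  feature = sample(names(feats)),
                                  score = 0),
                       class = c("selection_result", "data.frame"))
  s <- category_rank_summary(ranking)
  enum <- sum(vapply(1:4, function(k)
    sum(grepl("CG", all_words(k), fixed = TRUE)), integer(1)))
  expect_equal(s$n_features[s$category == "NM-CG"], enum)
  expect_equal(s$n_features[s$category == "NM"], 340L)
  expect_equal(s$n_features[s$category == "MT"], 14L)
  expect_true(all(s$min_rank <= s$avg_rank & s$avg_rank <= s$max_rank))
})
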
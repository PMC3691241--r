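# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive and shares no code path with the package internals.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, probs = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# Random window with soft-masked (lowercase) blocks and N runs inserted.
rand_masked_window <- function(n = 200L) {
  chars <- sample(BASES, n, replace = TRUE)
  n_blocks <- sample(0:3, 1)
  for (b in seq_len(n_blocks)) {
    len <- sample(5:40, 1)
    start <- sample(n - len, 1)
    if (runif(1) < 0.5) {
      chars[start:(start + len - 1)] <- tolower(chars[start:(start + len - 1)])
    } else {
      chars[start:(start + len - 1)] <- "N"
    }
  }
  paste(chars, collapse = "")
}

soft_to_hard_mask <- function(seq) gsub("[acgtn]", "N", seq)

naive_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# Maximal uppercase-ACGT runs by character walk.
naive_segments <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  ok <- chars %in% BASES
  segs <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    if (ok[i]) {
      cur <- paste0(cur, chars[i])
    } else if (nzchar(cur)) {
      segs <- c(segs, cur); cur <- ""
    }
  }
  if (nzchar(cur)) segs <- c(segs, cur)
  segs
}

# All overlapping substrings of length k of one segment.
naive_windows <- function(seg, k) {
  n <- nchar(seg)
  if (n < k) return(character(0))
  substring(seg, 1:(n - k + 1), k:n)
}

all_words <- function(k) {
  w <- ""
  for (i in seq_len(k)) w <- as.vector(outer(w, BASES, paste0))
  sort(w)
}

naive_nmer <- function(seq, ks = 1:4) {
  segs <- naive_segments(seq)
  L <- sum(nchar(segs))
  out <- numeric(0)
  for (k in ks) {
    words <- all_words(k)
    cnt <- stats::setNames(numeric(length(words)), words)
    for (seg in segs) {
      tab <- table(naive_windows(seg, k))
      cnt[names(tab)] <- cnt[names(tab)] + as.numeric(tab)
    }
    v <- if (L > 0) cnt / L else cnt
    names(v) <- sprintf("NM_k%d_%s", k, words)
    out <- c(out, v)
  }
  out
}

naive_palindrome_aggregate <- function(seq, h) {
  segs <- naive_segments(seq)
  L <- sum(nchar(segs))
  cnt <- 0
  for (seg in segs) {
    wins <- naive_windows(seg, 2 * h)
    cnt <- cnt + sum(vapply(wins, function(w) w == naive_revcomp(w), logical(1)))
  }
  if (L > 0) cnt / L else 0
}

naive_special <- function(seq) {
  segs <- naive_segments(seq)
  L <- sum(nchar(segs))
  count_fixed <- function(seg, width, spec) {
    wins <- naive_windows(seg, width)
    sum(vapply(wins, function(w) {
      all(vapply(seq_along(spec), function(i)
        is.na(spec[i]) || substring(w, i, i) == spec[i], logical(1)))
    }, logical(1)))
  }
  specs <- list(c("G", NA, NA, "G"),
                c("G", NA, NA, "G", NA, NA, "G"),
                c("G", "C", NA, NA, "G", "C", NA, NA, "G", "C"))
  cnt <- vapply(specs, function(sp)
    sum(vapply(segs, count_fixed, numeric(1), width = length(sp), spec = sp)),
    numeric(1))
  if (L > 0) cnt / L else cnt * 0
}

# --- feature-selection oracles -------------------------------------------

oracle_fscore <- function(pos, neg) {
  xb_p <- sum(pos) / length(pos)
  xb_n <- sum(neg) / length(neg)
  xb <- sum(c(pos, neg)) / (length(pos) + length(neg))
  num <- (xb_p - xb)^2 + (xb_n - xb)^2
  den <- sum((pos - xb_p)^2) / (length(pos) - 1) +
         sum((neg - xb_n)^2) / (length(neg) - 1)
  if (num == 0) 0 else if (den == 0) Inf else num / den
}

oracle_nmi <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  mi <- 0
  for (a in ux) for (b in uy) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (sum(x == a) / n * sum(y == b) / n))
  }
  ent <- function(v, u) {
    p <- vapply(u, function(a) sum(v == a) / n, numeric(1))
    -sum(p * log(p))
  }
  hx <- ent(x, ux); hy <- ent(y, uy)
  if (hx == 0 || hy == 0) 0 else mi / sqrt(hx * hy)
}

oracle_discretize <- function(v, bins = 3L) {
  breaks <- stats::quantile(v, (1:(bins - 1)) / bins, type = 7, names = FALSE)
  vapply(v, function(x) sum(x > breaks), numeric(1))
}

# Independent greedy VWMRmR: explicit loops, no caching.
oracle_vwmrmr <- function(values, labels, k, bins = 3L,
                          w = function(m) m / (m + 1)) {
  feats <- colnames(values)
  disc <- lapply(feats, function(f) oracle_discretize(values[, f], bins))
  names(disc) <- feats
  rel <- vapply(feats, function(f) oracle_nmi(disc[[f]], labels), numeric(1))
  sel <- character(0)
  for (step in seq_len(k)) {
    rest <- setdiff(feats, sel)
    j <- vapply(rest, function(f) {
      if (length(sel) == 0) return(rel[[f]])
      redun <- mean(vapply(sel, function(g) oracle_nmi(disc[[f]], disc[[g]]),
                           numeric(1)))
      rel[[f]] - w(length(sel)) * redun
    }, numeric(1))
    sel <- c(sel, rest[order(-round(j, 10), rest)[1]])
  }
  sel
}

rand_feature_matrix <- function(n, d, informative = 0L, shift = 2) {
  labels <- rep(c(1L, 0L), length.out = n)
  vals <- matrix(rnorm(n * d), n, d,
                 dimnames = list(NULL, sprintf("S_f%02d", seq_len(d))))
  for (j in seq_len(informative))
    vals[labels == 1L, j] <- vals[labels == 1L, j] + shift
  feature_matrix(vals, labels)
}

# Small on-disk genome + loci fixture.
write_toy_genome <- function(dir, chroms) {
  fa <- file.path(dir, "toy.fa")
  write_fasta(chroms, fa)
  fa
}

.acceptance_cache <- new.env(parent = emptyenv())
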
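#' @importFrom stats rbeta rpois runif setNames quantile
NULL

#' Simulation configuration
#'
#' Defines the statistical structure of the synthetic study: positive
#' windows carry a centred CpG-island block, promoter motifs and
#' hypomethylated high-coverage CpG sites; negative windows are CpG-depleted
#' genomic background, optionally carrying a soft-masked CpG-rich repeat
#' decoy, with hypermethylated sites. Defaults follow a 26% positive class
#' (52 positive, 148 negative windows of 1 kb) observed over 14 control
#' brain methylomes.
#'
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param seq_len Window length in bp.
#' @param n_tracks Number of methylome tracks.
#' @param island_len Length of the centred CpG-island block in positives.
#' @param island_gc,island_oe Target G+C content and CpG O/E of the island
#'   block (in expectation).
#' @param background_cpg_depletion Probability that a background CpG
#'   dinucleotide is retained; genomic background is CpG-poor.
#' @param motif_boost Multiplier on the background occurrence rate of the
#'   three promoter motifs in positive windows; 1 plants nothing.
#' @param pos_meth_beta,neg_meth_beta Beta(a, b) parameters of per-site
#'   methylation probabilities in positive / negative windows (defaults:
#'   promoters hypomethylated, mean 0.1; background hypermethylated,
#'   mean 0.9).
#' @param coverage_mean Mean read coverage; coverage is 1 + Poisson.
#' @param repeat_decoy_prob Probability that a negative window carries a
#'   soft-masked CpG-rich Alu-like decoy block.
#' @param seed Integer seed; every output is a pure function of the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pos = 52L, n_neg = 148L, seq_len = 1000L,
                       n_tracks = 14L, island_len = 250L,
                       island_gc = 0.6, island_oe = 0.9,
                       background_cpg_depletion = 0.25,
                       motif_boost = 3, pos_meth_beta = c(1, 9),
                       neg_meth_beta = c(9, 1), coverage_mean = 20,
                       repeat_decoy_prob = 0.5, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, seq_len >= 1L,
            island_len <= seq_len, n_tracks >= 0L,
            background_cpg_depletion > 0, background_cpg_depletion <= 1,
            motif_boost >= 1, repeat_decoy_prob >= 0, repeat_decoy_prob <= 1,
            coverage_mean >= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seq_len = as.integer(seq_len), n_tracks = as.integer(n_tracks),
                 island_len = as.integer(island_len),
                 island_gc = island_gc, island_oe = island_oe,
                 background_cpg_depletion = background_cpg_depletion,
                 motif_boost = motif_boost,
                 pos_meth_beta = pos_meth_beta, neg_meth_beta = neg_meth_beta,
                 coverage_mean = coverage_mean,
                 repeat_decoy_prob = repeat_decoy_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Null simulation configuration
#'
#' Removes every planted difference between classes: the "island" block is
#' drawn from the background distribution, no motifs are planted, no decoys
#' inserted, and both classes share one methylation distribution. Classes
#' are balanced so chance accuracy is 50%.
#'
#' @param n_pos,n_neg,seed As in [sim_config()].
#' @return A `sim_config`.
#' @export
null_sim_config <- function(n_pos = 100L, n_neg = 100L, seed = 1L) {
  sim_config(n_pos = n_pos, n_neg = n_neg,
             island_gc = 0.4, island_oe = 0.25, motif_boost = 1,
             repeat_decoy_prob = 0,
             pos_meth_beta = c(3, 3), neg_meth_beta = c(3, 3),
             seed = seed)
}

# Background base probabilities (A, C, G, T): mildly AT-rich, like bulk
# mammalian genome.
BACKGROUND_PROBS <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)

sample_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Thin CG dinucleotides down to `keep_prob` of their occurrence rate by
# rewriting the G of a removed CpG to A or T (which cannot create a new
# CpG, so one pass suffices).
deplete_cpg <- function(chars, keep_prob) {
  if (keep_prob >= 1 || length(chars) < 2L) return(chars)
  n <- length(chars)
  cg <- which(chars[-n] == "C" & chars[-1L] == "G")
  drop <- cg[runif(length(cg)) > keep_prob]
  if (length(drop))
    chars[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
  chars
}

# CpG-island-like block: i.i.d. bases at the target G+C, CpG rate adjusted
# toward `oe` (depleted below 1, extra CpGs planted above 1).
island_chars <- function(len, gc, oe) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample_bases(len, probs)
  if (oe < 1) {
    chars <- deplete_cpg(chars, oe)
  } else if (oe > 1 && len >= 2L) {
    target <- round(oe * (gc / 2)^2 * (len - 1L))
    current <- sum(chars[-len] == "C" & chars[-1L] == "G")
    extra <- target - current
    if (extra > 0L) {
      slots <- seq(1L, len - 1L, by = 2L)
      plant <- sample(slots, min(extra, length(slots)))
      chars[plant] <- "C"
      chars[plant + 1L] <- "G"
    }
  }
  chars
}

background_chars <- function(len, cfg) {
  deplete_cpg(sample_bases(len, BACKGROUND_PROBS), cfg$background_cpg_depletion)
}

# Fixed letters of the three promoter motifs: offset -> base, 0-based
# within the motif; wildcard positions are left as they are.
MOTIF_TEMPLATES <- list(
  "G**G" = c("0" = "G", "3" = "G"),
  "G**G**G" = c("0" = "G", "3" = "G", "6" = "G"),
  "GC**GC**GC" = c("0" = "G", "1" = "C", "4" = "G", "5" = "C",
                   "8" = "G", "9" = "C")
)

# Background per-position match rates of the motifs under BACKGROUND_PROBS.
motif_background_rate <- function(template) {
  prod(c(C = BACKGROUND_PROBS[["C"]],
         G = BACKGROUND_PROBS[["G"]])[template])
}

# Plant Poisson-many extra motif instances (rate (boost - 1) x background)
# at uniform positions inside the allowed ranges, overwriting only the
# motifs' fixed letters. Planting is kept CpG-neutral: a background C
# immediately before a planted G (or background G after a planted C) is
# rewritten to A/T, so motif insertion does not leak into the CpG-island
# feature family.
plant_motifs <- function(chars, ranges, boost) {
  if (boost <= 1) return(chars)
  span <- sum(vapply(ranges, function(r) r[2] - r[1] + 1L, integer(1)))
  for (nm in names(MOTIF_TEMPLATES)) {
    tmpl <- MOTIF_TEMPLATES[[nm]]
    w <- max(as.integer(names(tmpl))) + 1L
    lambda <- (boost - 1) * motif_background_rate(tmpl) * span
    n_extra <- rpois(1L, lambda)
    if (n_extra == 0L) next
    starts <- unlist(lapply(ranges, function(r)
      if (r[2] - w + 1L >= r[1]) seq.int(r[1], r[2] - w + 1L) else integer(0)))
    if (length(starts) == 0L) next
    pos <- sample(starts, n_extra, replace = TRUE)
    offs <- as.integer(names(tmpl))
    for (p in pos) {
      fixed <- p + offs
      chars[fixed] <- unname(tmpl)
      before_g <- fixed[tmpl == "G"] - 1L
      before_g <- setdiff(before_g[before_g >= 1L], fixed)
      hit <- before_g[chars[before_g] == "C"]
      after_c <- fixed[tmpl == "C"] + 1L
      after_c <- setdiff(after_c[after_c <= length(chars)], fixed)
      hit <- c(hit, after_c[chars[after_c] == "G"])
      if (length(hit))
        chars[hit] <- sample(c("A", "T"), length(hit), replace = TRUE)
    }
  }
  chars
}

#' Generate one positive (promoter-like) window
#'
#' CpG-depleted background with a centred CpG-island block and promoter
#' motifs planted in the flanks at `motif_boost` times their background
#' rate. Fully uppercase. Uses the current RNG state; seed via
#' `set.seed()` or use [generate_dataset()].
#'
#' @param cfg A [sim_config()].
#' @return A sequence string of length `cfg$seq_len`.
#' @export
generate_positive_window <- function(cfg = sim_config()) {
  chars <- background_chars(cfg$seq_len, cfg)
  start <- (cfg$seq_len - cfg$island_len) %/% 2L + 1L
  end <- start + cfg$island_len - 1L
  chars[start:end] <- island_chars(cfg$island_len, cfg$island_gc, cfg$island_oe)
  ranges <- list()
  if (start > 1L) ranges <- c(ranges, list(c(1L, start - 1L)))
  if (end < cfg$seq_len) ranges <- c(ranges, list(c(end + 1L, cfg$seq_len)))
  if (length(ranges))
    chars <- plant_motifs(chars, ranges, cfg$motif_boost)
  paste(chars, collapse = "")
}

# Alu-sized decoy length.
DECOY_LEN <- 300L

#' Generate one negative (background) window
#'
#' CpG-depleted background; with probability `cfg$repeat_decoy_prob` a
#' soft-masked (lowercase) CpG-rich Alu-like decoy block is inserted. A
#' correct feature extractor must ignore the decoy's bases entirely.
#'
#' @param cfg A [sim_config()].
#' @return A sequence string of length `cfg$seq_len`.
#' @export
generate_negative_window <- function(cfg = sim_config()) {
  chars <- background_chars(cfg$seq_len, cfg)
  if (cfg$repeat_decoy_prob > 0 && runif(1L) < cfg$repeat_decoy_prob &&
      cfg$seq_len >= DECOY_LEN) {
    start <- sample.int(cfg$seq_len - DECOY_LEN + 1L, 1L)
    decoy <- tolower(island_chars(DECOY_LEN, gc = 0.55, oe = 0.9))
    chars[start:(start + DECOY_LEN - 1L)] <- decoy
  }
  paste(chars, collapse = "")
}

#' Generate one methylome track over a set of labeled windows
#'
#' Every unmasked CpG site in every window receives a methylation
#' probability drawn from the class-specific Beta distribution
#' (hypomethylated in positives, hypermethylated in negatives at defaults)
#' and a read coverage of 1 + Poisson(`coverage_mean` - 1).
#'
#' @param cfg A [sim_config()].
#' @param windows List of windows, each a list with `region` (`chrom`,
#'   `start`, `end`), `seq` (genome-oriented sequence of the span) and
#'   `label` (1/0).
#' @param sample_id Track identifier.
#' @return A methylome track (same shape as [read_methylation_track()]).
#' @export
generate_track <- function(cfg, windows, sample_id) {
  site_list <- lapply(windows, function(w) {
    m <- gregexpr("CG", w$seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    beta <- if (w$label == 1L) cfg$pos_meth_beta else cfg$neg_meth_beta
    k <- length(m)
    data.frame(chrom = w$region$chrom,
               pos = w$region$start + as.integer(m) - 1L,
               p = rbeta(k, beta[1], beta[2]),
               r = 1L + rpois(k, cfg$coverage_mean - 1),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        p = numeric(0), r = integer(0))
  list(sample_id = sample_id, sites = sites)
}

SPACER_LEN <- 200L

# Build the window set, embed it in one synthetic chromosome with N
# spacers, and derive BED loci and methylome tracks. Strand-aware: a
# window assigned the minus strand is embedded as its reverse complement,
# so extraction recovers the original sequence.
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  labels <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
  n <- length(labels)
  ids <- sprintf("s%04d", seq_len(n))
  seqs <- vapply(labels, function(lab)
    if (lab == 1L) generate_positive_window(cfg)
    else generate_negative_window(cfg), character(1))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  spacer <- strrep("N", SPACER_LEN)
  offsets <- SPACER_LEN + (seq_len(n) - 1L) * (cfg$seq_len + SPACER_LEN)
  embedded <- ifelse(strands == "-",
                     vapply(seqs, reverse_complement, character(1)), seqs)
  chrom <- paste0(spacer, paste(embedded, collapse = spacer), spacer)
  upstream <- cfg$seq_len %/% 2L
  tss <- ifelse(strands == "+", offsets + upstream,
                offsets + cfg$seq_len - upstream - 1L)
  bed <- data.frame(chrom = "chrS", start = tss, end = tss + 1L,
                    name = ids, score = 0L, strand = strands,
                    stringsAsFactors = FALSE)
  windows <- lapply(seq_len(n), function(i)
    list(name = ids[i],
         region = list(chrom = "chrS", start = offsets[i],
                       end = offsets[i] + cfg$seq_len, strand = strands[i]),
         seq = embedded[i], label = labels[i]))
  tracks <- lapply(seq_len(cfg$n_tracks), function(t)
    generate_track(cfg, windows, sprintf("ctrl%02d", t)))
  truth <- data.frame(sample_id = ids, label = labels, strand = strands,
                      stringsAsFactors = FALSE)
  planted <- c(sprintf("CI_%d_OE", c(125L, 250L)),
               sprintf("CI_%d_GC", c(125L, 250L)),
               sprintf("S_%s", names(MOTIF_TEMPLATES)),
               sprintf("MT_ctrl%02d", seq_len(cfg$n_tracks)))
  list(genome = c(chrS = chrom), bed = bed, tracks = tracks,
       windows = windows, truth = truth, planted = planted,
       upstream = upstream, total_len = cfg$seq_len, cfg = cfg)
}

#' Generate a complete synthetic dataset on disk
#'
#' Windows are embedded into one synthetic chromosome separated by runs of
#' `N`, so the full file path — FASTA parsing, BED parsing, strand-aware
#' extraction, track lookup — is exercised end to end. Writes
#' `genome.fa`, `loci.bed`, one `track_<id>.tsv` per methylome (1-based
#' positions), `truth.tsv` (sample, label, strand) and
#' `planted_features.tsv` (names of the feature columns the generator
#' makes informative). Output is byte-identical for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the in-memory study
#'   (`$study`).
#' @export
generate_dataset <- function(cfg = sim_config(), out_dir) {
  study <- simulate_study(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                bed = file.path(out_dir, "loci.bed"),
                truth = file.path(out_dir, "truth.tsv"),
                planted = file.path(out_dir, "planted_features.tsv"),
                tracks = vapply(study$tracks, function(t)
                  file.path(out_dir, sprintf("track_%s.tsv", t$sample_id)),
                  character(1)))
  write_fasta(study$genome, paths$genome)
  data.table::fwrite(study$bed, paths$bed, sep = "\t", col.names = FALSE)
  for (i in seq_along(study$tracks)) {
    t <- study$tracks[[i]]
    out <- data.frame(chrom = t$sites$chrom, pos = t$sites$pos + 1L,
                      p = t$sites$p, r = t$sites$r)
    data.table::fwrite(out, paths$tracks[i], sep = "\t", col.names = FALSE)
  }
  data.table::fwrite(study$truth, paths$truth, sep = "\t")
  data.table::fwrite(data.frame(feature = study$planted), paths$planted,
                     sep = "\t")
  invisible(c(paths, list(study = study)))
}

#' Simulate a study and extract its feature matrix in memory
#'
#' Convenience wrapper running the generator and the feature extractor
#' without touching the file system; the windows used are exactly the ones
#' [generate_dataset()] would write.
#'
#' @param cfg A [sim_config()].
#' @param include_mt Include the MT block.
#' @param mt_cfg An [mt_config()].
#' @return A [feature_matrix()] (385 columns at defaults; 371 without MT).
#' @export
simulate_feature_matrix <- function(cfg = sim_config(), include_mt = TRUE,
                                    mt_cfg = mt_config()) {
  study <- simulate_study(cfg)
  rows <- lapply(study$windows, function(w) {
    oriented <- if (w$region$strand == "-") reverse_complement(w$seq) else w$seq
    window_features(list(region = w$region, seq = oriented),
                    tracks = study$tracks, mt_cfg = mt_cfg,
                    include_mt = include_mt)
  })
  feature_matrix(do.call(rbind, rows), study$truth$label,
                 sample_ids = study$truth$sample_id)
}
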
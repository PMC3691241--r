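#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the pipeline. A YAML config
#' file (see [load_config()]) overrides any subset of these; command-line
#' flags override the file.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    window = list(upstream = 500L, total_len = 1000L),
    ci = list(window_lengths = c(125L, 250L, 500L, 1000L)),
    pl = list(half_lengths = 2:5),
    mt = list(coverage_halfsat = 10, island_oe_min = 0.6,
              island_gc_min = 0.5, island_window = 125L),
    selection = list(n_bins = 3L, k = 100L),
    rf = list(num_trees = 100L, num_features = NULL),
    cv = list(folds = 5L, repeats = 10L),
    sim = list(n_pos = 52L, n_neg = 148L, n_tracks = 14L),
    seed = 1L
  ), class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; values are validated against the owning
#' module's preconditions at load time.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file (e.g. a
#'   `--seed` flag).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_validation("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      abort_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg <- merge_config(cfg, user)
  }
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (window$upstream < 0L || window$upstream >= window$total_len)
      abort_validation("window: need 0 <= upstream < total_len")
    if (any(ci$window_lengths < 1L) || any(ci$window_lengths > window$total_len))
      abort_validation("ci: window lengths must be in 1..total_len")
    if (any(pl$half_lengths < 1L))
      abort_validation("pl: half lengths must be positive")
    if (mt$coverage_halfsat <= 0)
      abort_validation("mt: coverage_halfsat must be positive")
    if (selection$n_bins < 2L || selection$k < 1L)
      abort_validation("selection: need n_bins >= 2 and k >= 1")
    if (rf$num_trees < 1L)
      abort_validation("rf: num_trees must be >= 1")
    if (cv$folds < 2L || cv$repeats < 1L)
      abort_validation("cv: need folds >= 2 and repeats >= 1")
    if (sim$n_pos < 1L || sim$n_neg < 1L)
      abort_validation("sim: need n_pos >= 1 and n_neg >= 1")
  })
  invisible(cfg)
}

config_mt <- function(cfg) {
  mt_config(coverage_halfsat = cfg$mt$coverage_halfsat,
            island_oe_min = cfg$mt$island_oe_min,
            island_gc_min = cfg$mt$island_gc_min,
            island_window = cfg$mt$island_window)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[mirtss %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

log_provenance <- function(cfg) {
  pipeline_log("mirtss %s, config hash %s",
               as.character(utils::packageVersion("mirtss")),
               substr(rlang_free_hash(cfg), 1, 12))
}

# Content hash without extra dependencies: serialize deterministically.
rlang_free_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  paste(format(as.hexmode(as.integer(raw[seq_len(min(64L, length(raw)))])),
               width = 2), collapse = "")
}

#' Pipeline commands
#'
#' Thin wrappers tying the stages together; the shell entry point
#' (`inst/cli/mirtss.R`) dispatches to these. Validation failures raise
#' `mirtss_validation_error`, mapped to exit code 2 by the CLI.
#'
#' @param cfg A `pipeline_config` from [load_config()].
#' @param out_dir,out Output locations.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(cfg, out_dir) {
  log_provenance(cfg)
  sim <- sim_config(n_pos = cfg$sim$n_pos, n_neg = cfg$sim$n_neg,
                    seq_len = cfg$window$total_len,
                    n_tracks = cfg$sim$n_tracks, seed = cfg$seed)
  res <- generate_dataset(sim, out_dir)
  pipeline_log("wrote %d loci, %d tracks to %s",
               nrow(res$study$bed), length(res$tracks), out_dir)
  invisible(res)
}

#' @rdname pipeline-commands
#' @param genome_path,bed_path,track_paths Input files.
#' @param labels_path Optional truth table TSV (sample_id, label) used to
#'   label rows; unlabeled rows default to 0.
#' @param include_mt Set `FALSE` (CLI: `--no-mt`) to omit the MT block.
#' @export
cmd_extract <- function(genome_path, bed_path, track_paths = character(0),
                        cfg = default_config(), out, include_mt = TRUE,
                        labels_path = NULL) {
  log_provenance(cfg)
  genome <- read_fasta(genome_path)
  regions <- read_bed(bed_path)
  tracks <- lapply(track_paths, function(p)
    read_methylation_track(p, sub("^track_", "", sub("\\.tsv$", "", basename(p)))))
  labels <- rep(0L, nrow(regions))
  if (!is.null(labels_path)) {
    truth <- data.table::fread(labels_path, sep = "\t", data.table = FALSE)
    labels <- truth$label[match(regions$name, truth$sample_id)]
    labels[is.na(labels)] <- 0L
  }
  fm <- extract_feature_matrix(
    genome, regions, tracks, labels = labels,
    upstream = cfg$window$upstream, total_len = cfg$window$total_len,
    ci_window_lengths = cfg$ci$window_lengths,
    pl_half_lengths = cfg$pl$half_lengths,
    mt_cfg = config_mt(cfg), include_mt = include_mt)
  write_feature_matrix(fm, out)
  pipeline_log("extracted %d x %d feature matrix -> %s",
               nrow(fm$values), ncol(fm$values), out)
  invisible(fm)
}

#' @rdname pipeline-commands
#' @param matrix_path Feature-matrix TSV.
#' @param method `"fscore"` or `"vwmrmr"`.
#' @param k Number of features `vwmrmr` selects (`fscore` always ranks all).
#' @param summary_out Optional path for the per-category rank-summary TSV.
#' @export
cmd_select <- function(matrix_path, method = c("fscore", "vwmrmr"),
                       k = NULL, cfg = default_config(), out,
                       summary_out = NULL) {
  method <- match.arg(method)
  log_provenance(cfg)
  fm <- read_feature_matrix(matrix_path)
  if (is.null(k)) k <- min(cfg$selection$k, ncol(fm$values))
  res <- if (method == "fscore") rank_by_fscore(fm)
         else vwmrmr_select(fm, k, n_bins = cfg$selection$n_bins)
  write_selection(res, out, summary_out)
  pipeline_log("%s ranked %d features -> %s", method, nrow(res), out)
  invisible(res)
}

#' @rdname pipeline-commands
#' @param model_path Model file.
#' @export
cmd_train <- function(matrix_path, cfg = default_config(), model_path) {
  log_provenance(cfg)
  fm <- read_feature_matrix(matrix_path)
  model <- train_rf(fm, rf_config(cfg$rf$num_trees, cfg$rf$num_features,
                                  seed = cfg$seed))
  save_model(model, model_path)
  pipeline_log("trained %d-tree forest on %d x %d -> %s",
               cfg$rf$num_trees, nrow(fm$values), ncol(fm$values), model_path)
  invisible(model)
}

#' @rdname pipeline-commands
#' @export
cmd_evaluate <- function(matrix_path, cfg = default_config(), out) {
  log_provenance(cfg)
  fm <- read_feature_matrix(matrix_path)
  cv <- cross_validate(fm, folds = cfg$cv$folds, repeats = cfg$cv$repeats,
                       cfg = rf_config(cfg$rf$num_trees, cfg$rf$num_features,
                                       seed = cfg$seed))
  data.table::fwrite(as.data.frame(cv), out, sep = "\t")
  pipeline_log("%d-fold x %d-repeat CV -> %s", cfg$cv$folds, cfg$cv$repeats, out)
  invisible(cv)
}

#' @rdname pipeline-commands
#' @export
cmd_predict <- function(model_path, matrix_path, out) {
  model <- load_model(model_path)
  fm <- read_feature_matrix(matrix_path)
  pred <- predict(model, fm)
  res <- data.frame(sample_id = fm$sample_ids, predicted = pred)
  data.table::fwrite(res, out, sep = "\t")
  pipeline_log("predicted %d samples -> %s", nrow(res), out)
  invisible(res)
}
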
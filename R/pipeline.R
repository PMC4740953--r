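# Orchestration of the generate -> fit -> compare/correlate stages.  Each
# stage writes exactly one JSON manifest carrying the config hash and seed
# so every downstream number is traceable to its inputs.

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension).  Recognized top-level sections: `cohort`
#' (fields of [cohort_config()]), `sampler` (fields of [sampler_config()]),
#' `min_rt`.  Unknown fields in a section are a config error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list with `cohort`, `sampler`, `min_rt`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) abort_config("config must be a mapping")
  cohort_args <- raw$cohort %||% list()
  bad <- setdiff(names(cohort_args), names(formals(cohort_config)))
  if (length(bad) > 0)
    abort_config(sprintf("unknown cohort config fields: %s", paste(bad, collapse = ", ")))
  sampler_args <- raw$sampler %||% list()
  bad <- setdiff(names(sampler_args), names(formals(sampler_config)))
  if (length(bad) > 0)
    abort_config(sprintf("unknown sampler config fields: %s", paste(bad, collapse = ", ")))
  list(cohort = do.call(cohort_config, cohort_args),
       sampler = do.call(sampler_config, sampler_args),
       min_rt = raw$min_rt %||% 0.150)
}

#' Pipeline stage: generate a synthetic cohort
#'
#' Runs [generate_cohort()] and writes its tables and manifest to a run
#' directory.
#'
#' @param config a [cohort_config()].
#' @param outdir run directory to create/populate.
#' @return `outdir`, invisibly.
#' @export
pipeline_generate <- function(config = cohort_config(), outdir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, outdir)
  invisible(outdir)
}

#' Persist / reload posterior draws
#'
#' Draws are stored as a gzip-compressed columnar table
#' (`chain, iteration, parameter, value`) next to a JSON sidecar carrying
#' the parameter index, subject-group map and sampler settings.
#'
#' @param draws an `lba_draws` object.
#' @param path output path, conventionally ending in `.csv.gz`.
#' @return `save_draws` returns `path` invisibly; `load_draws` the
#'   reconstructed `lba_draws`.
#' @export
save_draws <- function(draws, path) {
  d <- dim(draws$values)
  ids <- dimnames(draws$values)[[3]]
  long <- data.table::data.table(
    chain = rep(seq_len(d[1]), times = d[2] * d[3]),
    iteration = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(ids, each = d[1] * d[2]),
    value = as.vector(draws$values))
  data.table::fwrite(long, path, compress = "gzip")
  side <- list(index = draws$index, subjects = draws$subjects,
               groups = draws$groups,
               subj_group = as.list(draws$subj_group),
               config = unclass(draws$config),
               acceptance = draws$acceptance,
               dim = d)
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_draws
#' @export
load_draws <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("draws file not found: %s", path))
  side <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  con <- gzfile(path)
  long <- utils::read.csv(con)
  d <- as.integer(side$dim)
  ids <- side$index$id
  values <- array(long$value, dim = d, dimnames = list(NULL, NULL, ids))
  cfg <- side$config
  config <- sampler_config(cfg$n_chains, cfg$n_samples, cfg$burn_in,
                           cfg$gamma, cfg$jitter_b0, cfg$migration_prob,
                           cfg$seed)
  structure(list(values = values, index = side$index,
                 subjects = side$subjects, groups = side$groups,
                 subj_group = unlist(side$subj_group),
                 config = config, acceptance = side$acceptance),
            class = "lba_draws")
}

#' Pipeline stage: fit the hierarchical model
#'
#' Reads the trial table of a run directory, applies the RT validity
#' filter, fits the model with [run_sampler()], and persists draws,
#' convergence diagnostics and a manifest.  Non-convergence (any R-hat
#' above `rhat_warn`) logs a warning but is not a failure.
#'
#' @param run_dir run directory produced by [pipeline_generate()] (or
#'   containing a compatible `trials.tsv`).
#' @param config a [sampler_config()].
#' @param priors a [hyperprior_config()].
#' @param min_rt RT validity threshold in seconds.
#' @param rhat_warn warning threshold on split R-hat.
#' @param quiet suppress progress messages.
#' @return the fitted `lba_draws`, invisibly.
#' @export
pipeline_fit <- function(run_dir, config = sampler_config(),
                         priors = hyperprior_config(), min_rt = 0.150,
                         rhat_warn = 1.1, quiet = FALSE) {
  trials_path <- file.path(run_dir, "trials.tsv")
  if (!file.exists(trials_path))
    abort_data(sprintf("missing trial table: %s", trials_path))
  trials <- read_trials(trials_path)
  trials <- filter_valid(trials, min_rt)
  if (nrow(trials) == 0)
    abort_data(sprintf("no trials left after the %g s validity filter", min_rt))
  if (!quiet)
    message(sprintf("fitting %d subjects, %d valid trials (%d chains x %d samples)",
                    length(unique(trials$subject_id)), nrow(trials),
                    config$n_chains, config$n_samples))
  draws <- run_sampler(trials, priors = priors, config = config)
  diag <- convergence_diagnostics(draws)
  if (any(diag$rhat > rhat_warn, na.rm = TRUE))
    warning(sprintf("%d parameter(s) with split R-hat > %.2f (max %.3f)",
                    sum(diag$rhat > rhat_warn, na.rm = TRUE), rhat_warn,
                    max(diag$rhat, na.rm = TRUE)))
  save_draws(draws, file.path(run_dir, "draws.csv.gz"))
  utils::write.table(diag, file.path(run_dir, "diagnostics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(stage = "fit",
                   seed = config$seed,
                   config = unclass(config),
                   config_hash = config_hash(unclass(config)),
                   acceptance = draws$acceptance,
                   rhat_max = max(diag$rhat, na.rm = TRUE),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(run_dir, "fit_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(draws)
}

#' Pipeline stage: group comparison and brain-behavior correlation
#'
#' Loads the persisted draws and ROI table of a run directory, computes the
#' oriented odds ratio on the correct FACE drift hyperdistributions between
#' groups, and the within-group Spearman correlations of per-subject
#' posterior medians against every region in the ROI table.  Results go
#' into `results.json`.
#'
#' @param run_dir run directory containing `draws.csv.gz` and `roi.tsv`.
#' @param parameter drift parameter to compare, default `"v_c_face"`.
#' @param mode odds-ratio mode, see [compare_groups()].
#' @return list with `odds_ratio` (an `or_result`) and `correlations`
#'   (data frame), invisibly.
#' @export
pipeline_compare_correlate <- function(run_dir, parameter = "v_c_face",
                                       mode = "hyper_mean") {
  draws_path <- file.path(run_dir, "draws.csv.gz")
  roi_path <- file.path(run_dir, "roi.tsv")
  if (!file.exists(draws_path)) abort_data(sprintf("missing draws: %s", draws_path))
  if (!file.exists(roi_path)) abort_data(sprintf("missing ROI table: %s", roi_path))
  draws <- load_draws(draws_path)
  roi <- read_roi(roi_path)
  or <- compare_groups(draws, parameter = parameter, mode = mode)
  med <- posterior_medians(draws, parameter = parameter)
  cors <- roi_correlations(med, roi, draws$subj_group)
  results <- list(
    stage = "compare_correlate",
    parameter = parameter,
    mode = mode,
    odds_ratio = list(count = or$count, odds_ratio = or$odds_ratio,
                      direction = or$direction, n_pairs = or$n_pairs,
                      infinite = or$infinite),
    correlations = cors,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(results, file.path(run_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(odds_ratio = or, correlations = cors))
}
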
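#' Default generating hyperparameters for the synthetic cohort
#'
#' Calibrated so a simulated cohort lands on the behavioral scale of the
#' emulated study design: roughly 80% accuracy and a 2.2 s mean RT on FACE
#' trials, with OVAL (sensorimotor control) trials slightly easier and
#' faster.  The MDD group's correct-drift mean carries a small positive
#' offset over HCL, so the expected group effect is weak — commensurate
#' with a near-null group comparison.
#'
#' @return named list of [group_hypers()] for `MDD` and `HCL`.
#' @export
default_true_hypers <- function() {
  sigma <- c(A = 0.2, k = 0.4, t0 = 0.06, v_c_face = 0.35, v_e_face = 0.3,
             v_c_oval = 0.35, v_e_oval = 0.3)
  mu_hcl <- c(A = 1, k = 3, t0 = 0.35, v_c_face = 2.28, v_e_face = 1.0,
              v_c_oval = 2.6, v_e_oval = 0.9)
  mu_mdd <- mu_hcl
  mu_mdd["v_c_face"] <- 2.32
  list(MDD = group_hypers("MDD", mu_mdd, sigma),
       HCL = group_hypers("HCL", mu_hcl, sigma))
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the emulated study design: 26 MDD and 37 HCL
#' subjects, one run of 60 FACE + 20 OVAL trials at 6 s per trial plus a
#' 10 s terminal blank (490 s total), subject parameters drawn from
#' group-specific positive-truncated normal hyperdistributions, and a
#' per-subject percent-signal-change value for one region with a controlled
#' negative rank association to the true correct-drift parameter within the
#' MDD group (none in HCL).
#'
#' @param n_mdd,n_hcl subject counts.
#' @param n_face,n_oval FACE and OVAL trials per run.
#' @param trial_duration trial length in seconds.
#' @param terminal_blank terminal blank-screen duration in seconds.
#' @param true_hypers named list of [group_hypers()] used as ground truth.
#' @param roi_assoc named numeric vector (per group) of target Spearman
#'   correlation between true `v_c_face` and psc; magnitudes must be < 1.
#' @param roi_name region label for the generated ROI table.
#' @param psc_mean named numeric vector (per group) of mean percent signal
#'   change.
#' @param noise_sd scale of psc variation around the group mean, `> 0`.
#' @param min_rt validity threshold (seconds) used to flag trials.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_mdd = 26, n_hcl = 37, n_face = 60, n_oval = 20,
                          trial_duration = 6.0, terminal_blank = 10.0,
                          true_hypers = default_true_hypers(),
                          roi_assoc = c(MDD = -0.45, HCL = 0),
                          roi_name = "L_fusiform",
                          psc_mean = c(MDD = 0.32, HCL = 0.77),
                          noise_sd = 0.35, min_rt = 0.150, seed = 1L) {
  for (nm in c("n_mdd", "n_hcl", "n_face"))
    if (!is_count(get(nm))) abort_config(sprintf("%s must be a positive integer", nm))
  if (!is.numeric(n_oval) || n_oval < 0 || n_oval != floor(n_oval))
    abort_config("n_oval must be a non-negative integer")
  if (trial_duration <= 0 || terminal_blank < 0)
    abort_config("durations must be positive (terminal blank non-negative)")
  if (any(abs(roi_assoc) >= 1))
    abort_config("|roi_assoc| must be < 1 (a rank correlation of +-1 is not reachable with noise)")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    abort_config("noise_sd must be > 0")
  if (min_rt < 0) abort_config("min_rt must be >= 0")
  if (!all(c("MDD", "HCL") %in% names(true_hypers)))
    abort_config("true_hypers must cover groups MDD and HCL")
  structure(list(n_mdd = as.integer(n_mdd), n_hcl = as.integer(n_hcl),
                 n_face = as.integer(n_face), n_oval = as.integer(n_oval),
                 trial_duration = trial_duration,
                 terminal_blank = terminal_blank,
                 true_hypers = true_hypers, roi_assoc = roi_assoc,
                 roi_name = roi_name, psc_mean = psc_mean,
                 noise_sd = noise_sd, min_rt = min_rt,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Build the ordered trial schedule of one run
#'
#' FACE trials decompose into 1.5 s cue text + 3.0 s morph + 0.8 s hold +
#' 0.7 s blank (6 s); OVAL trials are 6 s control trials.  Emotions are
#' assigned to FACE trials in counterbalanced fixed blocks (a mirrored
#' block order, not a shuffle), so the schedule is fully deterministic.
#'
#' @param config a [cohort_config()].
#' @return data frame with columns `trial, condition, emotion, onset,
#'   duration` and attribute `total_duration` (equal to
#'   `n_trials * trial_duration + terminal_blank`).
#' @export
build_schedule <- function(config = cohort_config()) {
  emotions <- c("FEAR", "HAPPY", "SAD")
  n_emo <- floor(config$n_face / 3) + (seq_len(3) <= config$n_face %% 3)
  names(n_emo) <- emotions
  # mirrored halves: FEAR HAPPY SAD OVAL | OVAL SAD HAPPY FEAR
  half1 <- unlist(lapply(emotions, function(e) rep(e, ceiling(n_emo[e] / 2))))
  half1 <- c(half1, rep("OVAL", ceiling(config$n_oval / 2)))
  half2 <- unlist(lapply(rev(emotions), function(e) rep(e, floor(n_emo[e] / 2))))
  half2 <- c(rep("OVAL", floor(config$n_oval / 2)), half2)
  lab <- c(half1, half2)
  condition <- ifelse(lab == "OVAL", "OVAL", "FACE")
  n <- length(lab)
  sched <- data.frame(trial = seq_len(n), condition = condition,
                      emotion = ifelse(condition == "OVAL", NA_character_, lab),
                      onset = (seq_len(n) - 1) * config$trial_duration,
                      duration = config$trial_duration)
  attr(sched, "total_duration") <- n * config$trial_duration + config$terminal_blank
  sched
}

#' Draw one subject's parameters from group hypers
#'
#' Each of the seven subject-level parameters is drawn independently from
#' its positive-truncated normal hyperdistribution, so the result always
#' satisfies the parameter invariants (strict positivity, `b > A`).  Uses
#' the current RNG.
#'
#' @param hypers a [group_hypers()] object.
#' @return a [subject_params()] object.
#' @export
sample_subject_params <- function(hypers) {
  x <- rtruncnorm_pos(7, hypers$mu, hypers$sigma)
  names(x) <- .param_names
  subject_params(x["A"], x["k"], x["t0"], x["v_c_face"], x["v_e_face"],
                 x["v_c_oval"], x["v_e_oval"])
}

# Gaussian-copula mixer: expected Spearman rho_s between psc and the true
# scores corresponds to latent normal correlation r = 2 sin(pi rho_s / 6)
roi_psc_from_scores <- function(v_true, rho_s, center, scale) {
  n <- length(v_true)
  if (n == 0) return(numeric(0))
  z <- qnorm((rank(v_true, ties.method = "average") - 0.5) / n)
  r <- 2 * sin(pi * rho_s / 6)
  latent <- r * z + sqrt(1 - r^2) * rnorm(n)
  center + scale * latent
}

#' Generate a complete synthetic study cohort
#'
#' Produces (i) a trial-level behavioral table simulated trial-by-trial
#' from the LBA forward model on the run schedule, for every subject of
#' both groups, (ii) a per-subject ROI table whose percent-signal-change
#' values have a controlled rank association to the subjects' *true*
#' correct FACE drift (estimation noise will attenuate any downstream
#' estimate-based correlation), and (iii) the full ground truth.  Entirely
#' reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list of class `lba_cohort` with elements `trials`, `roi`,
#'   `truth` (subject parameters, hypers, realized latent correlations) and
#'   `schedule`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  sched <- build_schedule(config)
  groups <- c(rep("MDD", config$n_mdd), rep("HCL", config$n_hcl))
  ids <- c(sprintf("MDD%02d", seq_len(config$n_mdd)),
           sprintf("HCL%02d", seq_len(config$n_hcl)))
  params_rows <- list()
  trial_rows <- list()
  for (i in seq_along(ids)) {
    p <- sample_subject_params(config$true_hypers[[groups[i]]])
    params_rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                                   as.data.frame(p[.param_names]))
    beh <- simulate_trials(p, sched$condition)
    trial_rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                                  condition = sched$condition,
                                  emotion = sched$emotion,
                                  correct = beh$correct, rt = beh$rt,
                                  valid = beh$rt >= config$min_rt)
  }
  truth_params <- do.call(rbind, params_rows)
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL

  roi_rows <- list()
  latent_r <- c()
  for (g in c("MDD", "HCL")) {
    sel <- truth_params$group == g
    rho <- unname(config$roi_assoc[g])
    psc <- roi_psc_from_scores(truth_params$v_c_face[sel], rho,
                               unname(config$psc_mean[g]), config$noise_sd)
    latent_r[g] <- 2 * sin(pi * rho / 6)
    roi_rows[[g]] <- data.frame(subject_id = truth_params$subject_id[sel],
                                roi = config$roi_name, psc = psc)
  }
  roi <- do.call(rbind, roi_rows)
  rownames(roi) <- NULL

  structure(list(trials = trials, roi = roi,
                 truth = list(params = truth_params,
                              hypers = config$true_hypers,
                              latent_r = latent_r),
                 config = config, schedule = sched),
            class = "lba_cohort")
}

#' @export
print.lba_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d MDD + %d HCL subjects, %d trials each\n",
              x$config$n_mdd, x$config$n_hcl, nrow(x$schedule)))
  cat(sprintf("Run duration %g s; ROI '%s' target association %s\n",
              attr(x$schedule, "total_duration"), x$config$roi_name,
              paste(sprintf("%s=%g", names(x$config$roi_assoc),
                            x$config$roi_assoc), collapse = ", ")))
  invisible(x)
}

#' Write a generated cohort to a run directory
#'
#' Writes `trials.tsv`, `roi.tsv`, `ground_truth.tsv` and `manifest.json`
#' (configuration + seed) under `dir`.
#'
#' @param cohort an `lba_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(cohort$trials, file.path(dir, "trials.tsv"))
  write_roi(cohort$roi, file.path(dir, "roi.tsv"))
  utils::write.table(cohort$truth$params, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  manifest <- list(
    stage = "generate",
    seed = cfg$seed,
    config = config_as_list(cfg),
    config_hash = config_hash(config_as_list(cfg)),
    latent_r = as.list(cohort$truth$latent_r),
    n_trials = nrow(cohort$trials),
    total_duration = attr(cohort$schedule, "total_duration"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# plain-list view of a cohort_config for hashing / serialization
config_as_list <- function(cfg) {
  hy <- lapply(cfg$true_hypers, function(h)
    list(group = h$group, mu = as.list(h$mu), sigma = as.list(h$sigma)))
  list(n_mdd = cfg$n_mdd, n_hcl = cfg$n_hcl, n_face = cfg$n_face,
       n_oval = cfg$n_oval, trial_duration = cfg$trial_duration,
       terminal_blank = cfg$terminal_blank, true_hypers = hy,
       roi_assoc = as.list(cfg$roi_assoc), roi_name = cfg$roi_name,
       psc_mean = as.list(cfg$psc_mean), noise_sd = cfg$noise_sd,
       min_rt = cfg$min_rt, seed = cfg$seed)
}
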
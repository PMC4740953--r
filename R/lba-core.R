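#' Subject-level LBA parameter vector
#'
#' Bundles the parameters of the Linear Ballistic Accumulator for one
#' subject.  The response threshold is parameterized as an offset `k` above
#' the start-point range `A` (so `b = A + k > A` holds by construction), and
#' drift rates are condition-specific: a correct-response and an
#' error-response drift mean for FACE trials and for OVAL trials.  The
#' between-trial drift standard deviation `s` is fixed at 1 by convention
#' (it sets the evidence scale) unless overridden.
#'
#' @param A start-point range (evidence units); start points are drawn
#'   uniformly on `[0, A]`.
#' @param k threshold offset (evidence units); threshold `b = A + k`.
#' @param t0 non-decision time in seconds.
#' @param v_c_face,v_e_face mean drift rates (evidence/s) of the correct and
#'   error accumulators on FACE trials.
#' @param v_c_oval,v_e_oval drift means on OVAL trials; default to the FACE
#'   values.
#' @param s between-trial drift standard deviation; fixed at 1 by default.
#' @return an object of class `subject_params`.
#' @examples
#' p <- subject_params(A = 1, k = 3, t0 = 0.35, v_c_face = 2.3, v_e_face = 1)
#' p$b
#' @export
subject_params <- function(A, k, t0, v_c_face, v_e_face,
                           v_c_oval = v_c_face, v_e_oval = v_e_face, s = 1) {
  vals <- c(A = A, k = k, t0 = t0, v_c_face = v_c_face, v_e_face = v_e_face,
            v_c_oval = v_c_oval, v_e_oval = v_e_oval)
  if (!all(is.finite(vals)) || !is.finite(s))
    abort_param("all LBA parameters must be finite")
  if (A <= 0) abort_param("start-point range A must be > 0")
  if (k <= 0) abort_param("threshold offset k must be > 0 (so that b > A)")
  if (t0 <= 0) abort_param("non-decision time t0 must be > 0")
  if (s <= 0) abort_param("drift standard deviation s must be > 0")
  structure(list(A = A, k = k, t0 = t0, b = A + k,
                 v_c_face = v_c_face, v_e_face = v_e_face,
                 v_c_oval = v_c_oval, v_e_oval = v_e_oval, s = s),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("LBA subject parameters (s =", x$s, ")\n")
  print(unlist(x[.param_names]))
  invisible(x)
}

# named numeric vector in canonical order
param_vector <- function(params) {
  if (inherits(params, "subject_params")) return(unlist(params[.param_names]))
  if (is.numeric(params) && length(params) == length(.param_names))
    return(setNames(as.numeric(params), .param_names))
  abort_param("params must be a subject_params object or a length-7 numeric vector")
}

check_node_params <- function(A, b, s) {
  for (nm in c("A", "b", "s")) stopifnot_scalar_num(get(nm), nm)
  if (A <= 0) abort_param("A must be > 0")
  if (s <= 0) abort_param("s must be > 0")
  if (b < A) abort_param("threshold b must be >= start-point range A")
}

#' First-passage CDF of a single LBA accumulator
#'
#' Probability that an accumulator with start point uniform on `[0, A]`,
#' drift drawn from `Normal(v, s)` and threshold `b` has reached threshold
#' by decision time `t`.  The limit as `t -> Inf` is `pnorm(v / s)`: trials
#' on which the sampled drift is negative never cross.
#'
#' @param t decision time(s) in seconds, `>= 0` (time after `t0`).
#' @param A start-point range, `> 0`.
#' @param b response threshold, `>= A`.
#' @param v mean drift rate.
#' @param s between-trial drift standard deviation, `> 0`.
#' @return vector of probabilities, same length as `t`.
#' @seealso [lba_pdf()]
#' @export
lba_cdf <- function(t, A, b, v, s = 1) {
  check_node_params(A, b, s)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    abort_param("t must be finite and >= 0")
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (A < 1e-6) {
    # A -> 0 limit: first-passage time is b / drift
    out[pos] <- pnorm((v - b / tp) / s)
  } else {
    ts <- tp * s
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    out[pos] <- 1 + ((b - A - tp * v) / A) * pnorm(z1) -
      ((b - tp * v) / A) * pnorm(z2) + (ts / A) * (dnorm(z1) - dnorm(z2))
  }
  pmin(pmax(out, 0), 1)
}

# survival 1 - F computed directly (no cancellation near F = 1)
lba_survival <- function(t, A, b, v, s = 1) {
  check_node_params(A, b, s)
  out <- rep(1, length(t))
  pos <- t > 0
  tp <- t[pos]
  if (A < 1e-6) {
    out[pos] <- pnorm((b / tp - v) / s)
  } else {
    ts <- tp * s
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    out[pos] <- -((b - A - tp * v) / A) * pnorm(z1) +
      ((b - tp * v) / A) * pnorm(z2) - (ts / A) * (dnorm(z1) - dnorm(z2))
  }
  pmin(pmax(out, 0), 1)
}

#' First-passage density of a single LBA accumulator
#'
#' Density (per second) of the threshold-crossing time of one accumulator.
#' Integrates to `pnorm(v / s)` over `(0, Inf)` — the defective mass equals
#' the probability of a positive sampled drift.
#'
#' @inheritParams lba_cdf
#' @param t decision time(s) in seconds, `> 0` (density is 0 at `t <= 0`).
#' @return vector of densities, same length as `t`.
#' @export
lba_pdf <- function(t, A, b, v, s = 1) {
  check_node_params(A, b, s)
  if (!is.numeric(t) || any(!is.finite(t)))
    abort_param("t must be finite")
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (A < 1e-6) {
    out[pos] <- (b / (s * tp^2)) * dnorm((b / tp - v) / s)
  } else {
    ts <- tp * s
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    out[pos] <- (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) / A
  }
  pmax(out, 0)
}

#' Defective log likelihood of observed two-choice trials
#'
#' For each trial the likelihood is the winner's first-passage density times
#' the loser's survivor function at decision time `rt - t0`: correct choices
#' race the correct-drift accumulator (`v_c`) against the error one (`v_e`),
#' error choices the reverse, with condition-specific drifts.  The density
#' is left defective: the event that both sampled drifts are negative (no
#' response) carries the missing mass `pnorm(-v_c/s) * pnorm(-v_e/s)` and is
#' not renormalized.  Densities are floored at 1e-300 before the log;
#' `rt <= t0` gives `-Inf` exactly.
#'
#' @param trials data frame with columns `rt` (seconds), `correct` (0/1 or
#'   logical) and `condition` (`"FACE"` or `"OVAL"`).
#' @param params a [subject_params()] object.
#' @return numeric vector of per-trial log densities.
#' @export
trial_loglik <- function(trials, params) {
  params <- as_subject_params(params)
  if (!all(c("rt", "correct", "condition") %in% names(trials)))
    abort_data("trials must have columns rt, correct, condition")
  rt <- as.numeric(trials$rt)
  if (any(!is.finite(rt)) || any(rt <= 0)) abort_data("all rt must be finite and > 0")
  correct <- as.logical(trials$correct)
  face <- trials$condition == "FACE"
  vc <- ifelse(face, params$v_c_face, params$v_c_oval)
  ve <- ifelse(face, params$v_e_face, params$v_e_oval)
  vw <- ifelse(correct, vc, ve)
  vl <- ifelse(correct, ve, vc)
  t <- rt - params$t0
  out <- rep(-Inf, length(rt))
  pos <- t > 0
  # only four (winner, loser) drift combinations exist; vectorize per combo
  combo <- paste(vw, vl)
  for (cb in unique(combo[pos])) {
    idx <- which(pos & combo == cb)
    dens <- lba_pdf(t[idx], params$A, params$b, vw[idx][1], params$s) *
      lba_survival(t[idx], params$A, params$b, vl[idx][1], params$s)
    out[idx] <- log(pmax(dens, 1e-300))
  }
  out
}

as_subject_params <- function(params) {
  if (inherits(params, "subject_params")) return(params)
  v <- param_vector(params)
  subject_params(v["A"], v["k"], v["t0"], v["v_c_face"], v["v_e_face"],
                 v["v_c_oval"], v["v_e_oval"])
}

#' Simulate two-choice LBA trials
#'
#' Forward simulation of the race: per trial, start points are drawn
#' uniformly on `[0, A]` and drifts from `Normal(v, s)` for each
#' accumulator; the accumulator reaching `b` first determines choice and
#' decision time, and `rt = t0 + decision time`.  If both sampled drifts are
#' non-positive both are redrawn (the task forces a response), a deliberate,
#' O(`pnorm(-v_c) * pnorm(-v_e)`) mismatch with the defective likelihood of
#' [trial_loglik()].  Uses R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param params a [subject_params()] object.
#' @param condition character vector of `"FACE"` / `"OVAL"`, one per trial.
#' @return data frame with columns `condition`, `correct` (integer 0/1) and
#'   `rt` (seconds).
#' @export
simulate_trials <- function(params, condition) {
  params <- as_subject_params(params)
  if (!all(condition %in% c("FACE", "OVAL")))
    abort_data("condition entries must be 'FACE' or 'OVAL'")
  n <- length(condition)
  face <- condition == "FACE"
  vc <- ifelse(face, params$v_c_face, params$v_c_oval)
  ve <- ifelse(face, params$v_e_face, params$v_e_oval)
  start_c <- runif(n, 0, params$A)
  start_e <- runif(n, 0, params$A)
  dc <- rnorm(n, vc, params$s)
  de <- rnorm(n, ve, params$s)
  bad <- dc <= 0 & de <= 0
  while (any(bad)) {
    dc[bad] <- rnorm(sum(bad), vc[bad], params$s)
    de[bad] <- rnorm(sum(bad), ve[bad], params$s)
    bad <- dc <= 0 & de <= 0
  }
  tc <- ifelse(dc > 0, (params$b - start_c) / dc, Inf)
  te <- ifelse(de > 0, (params$b - start_e) / de, Inf)
  data.frame(condition = condition,
             correct = as.integer(tc < te),
             rt = params$t0 + pmin(tc, te))
}

#' Read / write trial-level behavioral tables
#'
#' Delimited-text round trip for trial tables.  On disk the columns are
#' `subject_id, group, condition, emotion, correct, rt_sec, valid`; in
#' memory the RT column is named `rt`.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @param trials in-memory trial data frame.
#' @return `read_trials` returns the trial data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("trial table not found: %s", path))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "emotion", "correct", "rt_sec", "valid")
  if (!all(need %in% names(df)))
    abort_data(sprintf("trial table missing columns: %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  names(df)[names(df) == "rt_sec"] <- "rt"
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  df <- trials
  names(df)[names(df) == "rt"] <- "rt_sec"
  need <- c("subject_id", "group", "condition", "emotion", "correct", "rt_sec", "valid")
  if (!all(need %in% names(df)))
    abort_data("trials lack the canonical columns")
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df[need], path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
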
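#' Log density of the positive-truncated normal
#'
#' Density `dnorm((x - mu)/sigma) / (sigma * pnorm(mu/sigma))` for `x > 0`,
#' zero otherwise — the hyperdistribution family used for every
#' subject-level parameter.  Normalizing constant is evaluated on the log
#' scale so extreme `mu/sigma` ratios stay finite.
#'
#' @param x quantile(s).
#' @param mu,sigma location and scale of the parent normal; `sigma > 0`.
#' @return log density, `-Inf` for `x <= 0`.
#' @export
truncnorm_logpdf <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    abort_param("sigma must be finite and > 0")
  out <- dnorm(x, mu, sigma, log = TRUE) -
    pnorm(mu / sigma, log.p = TRUE)
  out[x <= 0] <- -Inf
  out
}

#' Draw from the positive-truncated normal by inverse-CDF
#'
#' @param n number of draws.
#' @param mu,sigma parent normal location and scale.
#' @return `n` strictly positive draws.
#' @export
rtruncnorm_pos <- function(n, mu, sigma) {
  if (any(sigma <= 0)) abort_param("sigma must be > 0")
  plo <- pnorm(0, mu, sigma)
  x <- qnorm(runif(n, plo, 1), mu, sigma)
  pmax(x, .Machine$double.xmin)
}

#' Group-level hyperparameters
#'
#' One positive-truncated normal `(mu, sigma)` per subject-level parameter,
#' for one group.  Groups are modelled with disjoint hypers (estimated
#' separately, as when each group is fitted on its own).
#'
#' @param group group label, e.g. `"MDD"` or `"HCL"`.
#' @param mu,sigma named numeric vectors over the seven subject-level
#'   parameters `A, k, t0, v_c_face, v_e_face, v_c_oval, v_e_oval` (a
#'   partial set is completed against `mu`'s defaults only if full).
#' @return object of class `group_hypers`.
#' @export
group_hypers <- function(group, mu, sigma) {
  mu <- mu[.param_names]
  sigma <- sigma[.param_names]
  if (any(is.na(mu)) || any(is.na(sigma)))
    abort_param(sprintf("mu and sigma must be named over: %s",
                        paste(.param_names, collapse = ", ")))
  if (any(!is.finite(mu))) abort_param("all hyper means must be finite")
  if (any(sigma <= 0)) abort_param("all hyper sigmas must be > 0")
  structure(list(group = as.character(group),
                 mu = setNames(as.numeric(mu), .param_names),
                 sigma = setNames(as.numeric(sigma), .param_names)),
            class = "group_hypers")
}

#' @export
print.group_hypers <- function(x, ...) {
  cat("Group hypers:", x$group, "\n")
  print(rbind(mu = x$mu, sigma = x$sigma))
  invisible(x)
}

#' Hyperprior configuration
#'
#' Priors over the hyperparameters themselves: every `mu_p` and `sigma_p`
#' gets a positive-truncated normal prior.  Defaults are weakly informative
#' on the scale fixed by `s = 1`: location 1, scale 3 for the accumulator
#' geometry (`A`, `k`) and all drift means; location 0.3, scale 0.3 for
#' `t0` (seconds); `sigma_p ~ TN+(0, 1)` throughout.
#'
#' @param mu_loc,mu_scale,sigma_loc,sigma_scale optional named numeric
#'   vectors (over the seven parameter names) overriding the defaults.
#' @return data frame with one row per subject-level parameter and columns
#'   `mu_loc, mu_scale, sigma_loc, sigma_scale`, class `hyperprior_config`.
#' @export
hyperprior_config <- function(mu_loc = NULL, mu_scale = NULL,
                              sigma_loc = NULL, sigma_scale = NULL) {
  cfg <- data.frame(
    row.names = .param_names,
    mu_loc = c(1, 1, 0.3, 1, 1, 1, 1),
    mu_scale = c(3, 3, 0.3, 3, 3, 3, 3),
    sigma_loc = rep(0, 7),
    sigma_scale = rep(1, 7))
  override <- list(mu_loc = mu_loc, mu_scale = mu_scale,
                   sigma_loc = sigma_loc, sigma_scale = sigma_scale)
  for (nm in names(override)) {
    ov <- override[[nm]]
    if (is.null(ov)) next
    if (is.null(names(ov)) || !all(names(ov) %in% .param_names))
      abort_config("hyperprior overrides must be named by parameter")
    cfg[names(ov), nm] <- ov
  }
  if (any(cfg$mu_scale <= 0) || any(cfg$sigma_scale <= 0))
    abort_config("hyperprior scales must be > 0")
  class(cfg) <- c("hyperprior_config", "data.frame")
  cfg
}

# log density of the hyperprior for one group's hypers
hyperprior_logdens <- function(hypers, priors) {
  sum(truncnorm_logpdf(hypers$mu, priors$mu_loc, priors$mu_scale)) +
    sum(truncnorm_logpdf(hypers$sigma, priors$sigma_loc, priors$sigma_scale))
}

#' Joint log posterior of the two-group hierarchical LBA model
#'
#' Sums (i) the defective trial log likelihoods of every subject, (ii) the
#' positive-truncated normal log densities of every subject-level parameter
#' under its group's hypers, and (iii) the hyperprior log densities.  Any
#' `-Inf` component propagates.  This is the reference (pure R)
#' implementation; the sampler evaluates the same quantity in compiled code.
#'
#' @param theta numeric matrix of subject-level parameters, one row per
#'   subject (rownames = subject ids), columns the seven canonical
#'   parameter names.
#' @param hypers named list of [group_hypers()], one per group.
#' @param trials trial data frame with columns `subject_id, group,
#'   condition, correct, rt`; may have zero rows (prior only).
#' @param priors a [hyperprior_config()].
#' @param s drift standard deviation (fixed scale), default 1.
#' @return scalar log posterior density (unnormalized).
#' @export
joint_log_posterior <- function(theta, hypers, trials,
                                priors = hyperprior_config(), s = 1) {
  if (is.null(rownames(theta)))
    abort_param("theta must have subject ids as rownames")
  subj_group <- NULL
  ll <- 0
  if (nrow(trials) > 0) {
    missing <- setdiff(unique(trials$subject_id), rownames(theta))
    if (length(missing) > 0)
      abort_consistency(sprintf("subjects in data without a parameter state: %s",
                                paste(missing, collapse = ", ")))
    for (sid in unique(trials$subject_id)) {
      tr <- trials[trials$subject_id == sid, , drop = FALSE]
      p <- theta[sid, ]
      if (any(p[c("A", "k", "t0")] <= 0)) return(-Inf)
      ll_s <- sum(trial_loglik(tr, subject_params(
        p["A"], p["k"], p["t0"], p["v_c_face"], p["v_e_face"],
        p["v_c_oval"], p["v_e_oval"], s = s)))
      if (!is.finite(ll_s)) return(-Inf)
      ll <- ll + ll_s
    }
    subj_group <- trials$group[match(rownames(theta), trials$subject_id)]
  }
  # subject-level prior terms require a group for each subject; when there
  # are no trials, subjects are matched to groups via a 'group' attribute
  # on theta or, failing that, the single group in hypers
  if (is.null(subj_group) || any(is.na(subj_group)))
    subj_group <- attr(theta, "group") %||% subj_group
  lp <- 0
  for (i in seq_len(nrow(theta))) {
    g <- subj_group[i]
    if (is.na(g) || is.null(hypers[[g]]))
      abort_consistency(sprintf("no hypers for group of subject %s", rownames(theta)[i]))
    h <- hypers[[g]]
    lp_i <- sum(truncnorm_logpdf(theta[i, .param_names], h$mu, h$sigma))
    if (!is.finite(lp_i)) return(-Inf)
    lp <- lp + lp_i
  }
  hp <- sum(vapply(hypers, hyperprior_logdens, numeric(1), priors = priors))
  if (!is.finite(hp)) return(-Inf)
  ll + lp + hp
}

#' Serialize / read a full parameter state
#'
#' Long-format delimited text with columns
#' `level, group, subject_id, parameter, value` covering every subject-level
#' parameter and every hyperparameter.
#'
#' @param theta,hypers as in [joint_log_posterior()].
#' @param subj_group named character vector mapping subject id to group.
#' @param path output path (tab-separated).
#' @return `write_param_state` returns `path` invisibly; `read_param_state`
#'   returns a list with elements `theta`, `hypers`, `subj_group`.
#' @export
write_param_state <- function(theta, hypers, subj_group, path) {
  rows <- list()
  for (sid in rownames(theta)) {
    rows[[length(rows) + 1]] <- data.frame(
      level = "subject", group = unname(subj_group[sid]), subject_id = sid,
      parameter = .param_names, value = as.numeric(theta[sid, .param_names]))
  }
  for (h in hypers) {
    rows[[length(rows) + 1]] <- data.frame(
      level = "hyper", group = h$group, subject_id = NA,
      parameter = c(paste0("mu.", .param_names), paste0("sigma.", .param_names)),
      value = c(unname(h$mu), unname(h$sigma)))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_param_state
#' @export
read_param_state <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sub <- df[df$level == "subject", ]
  ids <- unique(sub$subject_id)
  theta <- matrix(NA_real_, length(ids), length(.param_names),
                  dimnames = list(ids, .param_names))
  for (i in seq_len(nrow(sub)))
    theta[sub$subject_id[i], sub$parameter[i]] <- sub$value[i]
  subj_group <- setNames(sub$group[match(ids, sub$subject_id)], ids)
  hyp <- df[df$level == "hyper", ]
  hypers <- list()
  for (g in unique(hyp$group)) {
    hg <- hyp[hyp$group == g, ]
    mu <- setNames(hg$value[match(paste0("mu.", .param_names), hg$parameter)], .param_names)
    sigma <- setNames(hg$value[match(paste0("sigma.", .param_names), hg$parameter)], .param_names)
    hypers[[g]] <- group_hypers(g, mu, sigma)
  }
  list(theta = theta, hypers = hypers, subj_group = subj_group)
}
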
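#' Sampler configuration
#'
#' Settings for the blocked DE-MCMC sampler.  Defaults follow common
#' practice for hierarchical evidence-accumulation fits: 20 interacting
#' chains, 5000 retained samples per chain, the first half of the run
#' discarded as burn-in, crossover factor `2.38 / sqrt(2 d)` per block of
#' dimension `d`, uniform jitter of half-width 0.001 on every proposal
#' coordinate, and migration (chain-state rotation) with probability 0.1
#' per iteration during burn-in only.
#'
#' @param n_chains number of chains, at least 3 (the crossover proposal
#'   needs two distinct partner chains).
#' @param n_samples retained iterations per chain.
#' @param burn_in iterations discarded before retention.
#' @param gamma crossover jump factor; `NULL` means `2.38 / sqrt(2 d)` with
#'   `d` the block dimension.
#' @param jitter_b0 half-width of the uniform proposal jitter, `>= 0`.
#' @param migration_prob probability of a migration step per burn-in
#'   iteration.
#' @param seed integer RNG seed; every source of randomness in the run is
#'   derived from it.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 20, n_samples = 5000,
                           burn_in = 2500, gamma = NULL,
                           jitter_b0 = 0.001, migration_prob = 0.1,
                           seed = 1L) {
  if (!is_count(n_chains) || n_chains < 3)
    abort_config("n_chains must be an integer >= 3")
  if (!is_count(n_samples)) abort_config("n_samples must be a positive integer")
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in != floor(burn_in))
    abort_config("burn_in must be a non-negative integer")
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma < 0))
    abort_config("gamma must be >= 0 or NULL")
  if (!is.numeric(jitter_b0) || jitter_b0 < 0)
    abort_config("jitter_b0 must be >= 0")
  if (!is.numeric(migration_prob) || migration_prob < 0 || migration_prob > 1)
    abort_config("migration_prob must be in [0, 1]")
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), gamma = gamma,
                 jitter_b0 = jitter_b0, migration_prob = migration_prob,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

default_gamma <- function(d) 2.38 / sqrt(2 * d)

#' Differential-evolution crossover proposal
#'
#' Proposes `current + gamma * (partner_a - partner_b) + eps` with
#' `eps ~ Uniform(-jitter_b0, jitter_b0)` per coordinate.  The proposal is
#' symmetric, so the Metropolis ratio needs no correction term.
#'
#' @param current numeric state vector of the updating chain.
#' @param partner_a,partner_b state vectors of two other chains.
#' @param gamma jump factor; default `2.38 / sqrt(2 d)`.
#' @param jitter_b0 half-width of the uniform jitter.
#' @param partner_ids optional integer vector `c(self, a, b)` of chain
#'   indices; supplying duplicated indices is a sampler-logic error.
#' @return proposed state vector.
#' @export
de_propose <- function(current, partner_a, partner_b,
                       gamma = default_gamma(length(current)),
                       jitter_b0 = 0.001, partner_ids = NULL) {
  if (!is.null(partner_ids) && anyDuplicated(partner_ids))
    abort_sampler("crossover partners must be two distinct chains, distinct from the current chain")
  if (length(partner_a) != length(current) || length(partner_b) != length(current))
    abort_sampler("partner states must match the dimension of the current state")
  current + gamma * (partner_a - partner_b) +
    runif(length(current), -jitter_b0, jitter_b0)
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(log_post_proposed -
#' log_post_current))`.  A `-Inf` proposal is never accepted; a `NaN` log
#' density is surfaced as an error rather than silently rejected.
#'
#' @param log_post_current,log_post_proposed log posterior densities of the
#'   current and proposed states (same data, same block conditioning).
#' @return logical accept flag.
#' @export
metropolis_accept <- function(log_post_current, log_post_proposed) {
  if (is.nan(log_post_current) || is.nan(log_post_proposed))
    abort_numeric("NaN log posterior density in Metropolis step")
  if (log_post_proposed == -Inf) return(FALSE)
  delta <- log_post_proposed - log_post_current
  delta >= 0 || log(runif(1)) < delta
}

#' Generic DE-MCMC on an arbitrary log target
#'
#' Plain (unblocked) differential-evolution MCMC over a d-dimensional log
#' density, built from [de_propose()] and [metropolis_accept()], with the
#' same migration scheme as the hierarchical sampler.  Used for analytic
#' validation targets; the hierarchical model runs through [run_sampler()].
#'
#' @param log_target function mapping a length-d numeric vector to a log
#'   density.
#' @param init numeric matrix `n_chains x d` of starting states, or a
#'   function `function(chain)` returning a length-d vector.
#' @param d target dimension.
#' @param config a [sampler_config()].
#' @return list with `draws` (array `chain x iteration x dim` of retained
#'   states) and `accept_rate`.
#' @export
de_mcmc <- function(log_target, init, d = 1, config = sampler_config()) {
  nc <- config$n_chains
  set.seed(config$seed)
  state <- matrix(NA_real_, nc, d)
  if (is.function(init)) {
    for (c in seq_len(nc)) state[c, ] <- init(c)
  } else {
    state <- matrix(init, nc, d)
  }
  lp <- apply(state, 1, log_target)
  if (any(!is.finite(lp))) abort_sampler("non-finite log target at initialization")
  if (d > 1 && all(apply(state, 2, var) == 0))
    abort_sampler("degenerate initialization: all chains identical")
  if (d == 1 && var(state[, 1]) == 0)
    abort_sampler("degenerate initialization: all chains identical")
  gamma <- config$gamma %||% default_gamma(d)
  n_iter <- config$burn_in + config$n_samples
  draws <- array(NA_real_, c(nc, config$n_samples, d))
  accept <- 0L
  tries <- 0L
  for (iter in seq_len(n_iter)) {
    for (c in seq_len(nc)) {
      mn <- sample(seq_len(nc)[-c], 2)
      prop <- de_propose(state[c, ], state[mn[1], ], state[mn[2], ],
                         gamma = gamma, jitter_b0 = config$jitter_b0,
                         partner_ids = c(c, mn))
      lp_prop <- log_target(prop)
      if (is.nan(lp_prop)) abort_numeric("NaN log target")
      tries <- tries + 1L
      if (metropolis_accept(lp[c], lp_prop)) {
        state[c, ] <- prop
        lp[c] <- lp_prop
        accept <- accept + 1L
      }
    }
    if (iter <= config$burn_in && config$migration_prob > 0 &&
        runif(1) < config$migration_prob) {
      k <- sample.int(nc, 1)
      idx <- sample.int(nc, k)
      snap_state <- state[idx, , drop = FALSE]
      snap_lp <- lp[idx]
      for (j in seq_len(k)) {
        donor <- if (j == 1) k else j - 1
        if (metropolis_accept(snap_lp[j], snap_lp[donor])) {
          state[idx[j], ] <- snap_state[donor, ]
          lp[idx[j]] <- snap_lp[donor]
        }
      }
    }
    if (iter > config$burn_in)
      draws[, iter - config$burn_in, ] <- state
  }
  list(draws = draws, accept_rate = accept / tries)
}

#' Fit the hierarchical LBA model by blocked DE-MCMC
#'
#' Per iteration and chain, each subject's 7-parameter block is updated by
#' a crossover proposal conditional on the chain's current hypers, then each
#' group's 14-dimensional hyper block conditional on its subject
#' parameters; migration rotates whole chain states during burn-in.
#' Proposals outside the support (non-positive parameters, `rt <= t0`) are
#' rejected through a `-Inf` posterior, never clamped.  The compiled
#' sampler evaluates the same joint density as [joint_log_posterior()].
#'
#' @param trials trial data frame (`subject_id, group, condition, correct,
#'   rt`); normally pre-filtered with [filter_valid()].
#' @param priors a [hyperprior_config()].
#' @param config a [sampler_config()].
#' @param s fixed drift standard deviation.
#' @param init `"heuristic"` (default; moderate truncated-normal start
#'   distributions with `t0` started below each subject's fastest RT) or
#'   `"hyperprior"` (chains started at hyperprior draws); either way up to
#'   100 redraws per chain to reach a finite posterior.
#' @param store_subject keep subject-level draws (set `FALSE` to retain
#'   only hyperparameters and save memory).
#' @return an object of class `lba_draws`; see [posterior_medians()],
#'   [hyper_mean_draws()], [convergence_diagnostics()].
#' @export
run_sampler <- function(trials, priors = hyperprior_config(),
                        config = sampler_config(), s = 1,
                        init = c("heuristic", "hyperprior"),
                        store_subject = TRUE) {
  init <- match.arg(init)
  if (is.null(trials) || nrow(trials) == 0)
    abort_data("no trials to fit (is everything below the validity threshold?)")
  need <- c("subject_id", "group", "condition", "correct", "rt")
  if (!all(need %in% names(trials)))
    abort_data(sprintf("trials must have columns: %s", paste(need, collapse = ", ")))
  trials <- trials[order(trials$subject_id), , drop = FALSE]
  subjects <- unique(trials$subject_id)
  n_subj <- length(subjects)
  groups <- sort(unique(as.character(trials$group)))
  subj_group_chr <- as.character(trials$group[match(subjects, trials$subject_id)])
  subj_group <- match(subj_group_chr, groups) - 1L
  subj_off <- c(0L, cumsum(as.integer(table(factor(trials$subject_id, levels = subjects)))))
  cond <- ifelse(trials$condition == "FACE", 0L, 1L)
  correct <- as.integer(as.logical(trials$correct))
  rt <- as.numeric(trials$rt)
  min_rt <- vapply(seq_len(n_subj),
                   function(i) min(rt[(subj_off[i] + 1):subj_off[i + 1]]),
                   numeric(1))

  set.seed(config$seed)
  nc <- config$n_chains
  init_theta <- array(NA_real_, c(7, n_subj, nc))
  init_hyper <- array(NA_real_, c(14, length(groups), nc))
  pr <- as.matrix(priors[, c("mu_loc", "mu_scale", "sigma_loc", "sigma_scale")])
  for (ch in seq_len(nc)) {
    for (gi in seq_along(groups)) {
      ok <- FALSE
      for (try in seq_len(100)) {
        if (init == "hyperprior") {
          mu <- rtruncnorm_pos(7, pr[, "mu_loc"], pr[, "mu_scale"])
          sigma <- rtruncnorm_pos(7, pr[, "sigma_loc"], pr[, "sigma_scale"])
        } else {
          mu <- c(runif(1, 0.5, 1.5), runif(1, 1, 4),
                  runif(1, 0.15, max(0.2, 0.7 * min(min_rt))),
                  runif(4, 0.8, 3.2))
          sigma <- runif(7, 0.1, 0.5)
        }
        sel <- which(subj_group == gi - 1L)
        th <- matrix(rtruncnorm_pos(7 * length(sel), rep(mu, length(sel)),
                                    rep(sigma, length(sel))), nrow = 7)
        if (init == "heuristic")
          th[3, ] <- pmin(th[3, ], 0.9 * min_rt[sel])
        ll <- vapply(seq_along(sel), function(j) {
          i <- sel[j]
          cpp_subject_loglik(th[, j], rt[(subj_off[i] + 1):subj_off[i + 1]],
                             correct[(subj_off[i] + 1):subj_off[i + 1]],
                             cond[(subj_off[i] + 1):subj_off[i + 1]], s)
        }, numeric(1))
        if (all(is.finite(ll)) && all(th > 0)) {
          init_theta[, sel, ch] <- th
          init_hyper[, gi, ch] <- c(mu, sigma)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        abort_sampler(sprintf("could not find a finite-posterior start for chain %d after 100 redraws", ch))
    }
  }

  gamma_subj <- config$gamma %||% default_gamma(7)
  gamma_hyper <- config$gamma %||% default_gamma(2)  # (mu_p, sigma_p) pair blocks
  res <- cpp_run_sampler(rt, correct, cond, as.integer(subj_off), subj_group,
                         length(groups), pr,
                         as.numeric(init_theta), as.numeric(init_hyper),
                         nc, config$n_samples, config$burn_in,
                         gamma_subj, gamma_hyper,
                         config$jitter_b0, config$migration_prob, s,
                         store_subject)

  hyper_ids <- as.vector(outer(c(paste0("mu.", .param_names),
                                 paste0("sigma.", .param_names)),
                               groups, function(p, g) paste(g, p, sep = ".")))
  hyper_arr <- array(res$hyper, c(14 * length(groups), config$n_samples, nc))
  values <- aperm(hyper_arr, c(3, 2, 1))
  ids <- hyper_ids
  index <- data.frame(
    id = hyper_ids, level = "hyper",
    group = rep(groups, each = 14), subject_id = NA_character_,
    parameter = rep(c(paste0("mu.", .param_names), paste0("sigma.", .param_names)),
                    times = length(groups)),
    stringsAsFactors = FALSE)
  if (store_subject) {
    subj_ids <- as.vector(outer(.param_names, subjects,
                                function(p, s) paste(s, p, sep = ".")))
    theta_arr <- array(res$theta, c(7 * n_subj, config$n_samples, nc))
    values <- array(c(aperm(theta_arr, c(3, 2, 1)), values),
                    c(nc, config$n_samples, 7 * n_subj + length(hyper_ids)))
    ids <- c(subj_ids, hyper_ids)
    index <- rbind(data.frame(
      id = subj_ids, level = "subject",
      group = rep(subj_group_chr, each = 7),
      subject_id = rep(subjects, each = 7),
      parameter = rep(.param_names, times = n_subj),
      stringsAsFactors = FALSE), index)
  }
  dimnames(values) <- list(NULL, NULL, ids)
  structure(list(values = values, index = index,
                 subjects = subjects, groups = groups,
                 subj_group = setNames(subj_group_chr, subjects),
                 config = config,
                 acceptance = list(subject = res$accept_subject,
                                   hyper = res$accept_hyper,
                                   migration = res$accept_migration)),
            class = "lba_draws")
}

#' @export
print.lba_draws <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Posterior draws: %d chains x %d iterations x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("Groups: %s; subjects: %d\n", paste(x$groups, collapse = ", "),
              length(x$subjects)))
  cat(sprintf("Acceptance: subject blocks %.2f, hyper blocks %.2f\n",
              x$acceptance$subject, x$acceptance$hyper))
  invisible(x)
}

# retained draws of one parameter id as a chains x iterations matrix
draws_matrix <- function(draws, id) {
  if (!id %in% dimnames(draws$values)[[3]])
    abort_lookup(sprintf("unknown parameter id: %s", id))
  draws$values[, , id]
}

#' Rank-normalized split R-hat
#'
#' Chains are split in half, all draws rank-normalized with the inverse
#' normal transform, and the classic potential-scale-reduction statistic
#' computed on the result.  Values near 1 (conventionally < 1.05) indicate
#' between-chain agreement.
#'
#' @param x numeric matrix, chains in rows and iterations in columns.
#' @return scalar R-hat.
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  half <- floor(n / 2)
  splits <- rbind(x[, seq_len(half), drop = FALSE],
                  x[, (n - half + 1):n, drop = FALSE])
  z <- qnorm((rank(splits) - 3 / 8) / (length(splits) + 1 / 4))
  z <- matrix(z, nrow = nrow(splits))
  m <- nrow(z)
  nn <- ncol(z)
  chain_means <- rowMeans(z)
  w <- mean(apply(z, 1, var))
  b <- nn * var(chain_means)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# effective sample size via Geyer's initial positive sequence, chains pooled
# after centering
ess_basic <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- nrow(x)
  n <- ncol(x)
  centered <- x - rowMeans(x)
  rho <- rep(0, n - 1)
  for (c in seq_len(m)) {
    if (var(centered[c, ]) == 0) next  # stuck chain: no autocorrelation info
    a <- acf(centered[c, ], lag.max = min(n - 1, 200), plot = FALSE,
             demean = FALSE)$acf[-1]
    rho[seq_along(a)] <- rho[seq_along(a)] + a / m
  }
  rho[!is.finite(rho)] <- 0
  tau <- 1
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  m * n / tau
}

#' Convergence diagnostics for every retained parameter
#'
#' @param draws an `lba_draws` object.
#' @return data frame with columns `id, rhat, ess`.
#' @export
convergence_diagnostics <- function(draws) {
  ids <- dimnames(draws$values)[[3]]
  rhat <- vapply(ids, function(id) split_rhat(draws$values[, , id]), numeric(1))
  ess <- vapply(ids, function(id) ess_basic(draws$values[, , id]), numeric(1))
  data.frame(id = ids, rhat = unname(rhat), ess = unname(ess),
             row.names = NULL, stringsAsFactors = FALSE)
}
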
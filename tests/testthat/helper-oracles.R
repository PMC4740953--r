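# independent oracles used across test files

# O(N^2) exhaustive strict cross-pair count (the reference for odds_ratio)
naive_pair_count <- function(a, b) {
  n_gt <- 0L
  n_tie <- 0L
  for (x in a) {
    n_gt <- n_gt + sum(x > b)
    n_tie <- n_tie + sum(x == b)
  }
  list(count = n_gt / (length(a) * length(b)),
       ties = n_tie / (length(a) * length(b)))
}

# numeric conditional CDF of RTs for one choice, by cumulative trapezoid on
# a fine grid over the defective density
numeric_choice_cdf <- function(params, condition = "FACE", correct = 1,
                               t_max = 60, n_grid = 24000) {
  grid <- seq(params$t0 + 1e-9, t_max, length.out = n_grid)
  dens <- exp(trial_loglik(
    data.frame(rt = grid, correct = correct, condition = condition), params))
  cum <- cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(grid))
  total <- cum[length(cum)]
  list(
    prob = total,  # choice probability (defective mass of this choice)
    cdf = stats::approxfun(grid[-1], cum / total, yleft = 0, yright = 1)
  )
}

# defective-mass identity target: total response probability
total_response_mass <- function(params, condition = "FACE") {
  vc <- if (condition == "FACE") params$v_c_face else params$v_c_oval
  ve <- if (condition == "FACE") params$v_e_face else params$v_e_oval
  1 - pnorm(-vc / params$s) * pnorm(-ve / params$s)
}

# random plausible parameter sets for property loops
random_params <- function() {
  subject_params(A = runif(1, 0.2, 1.5), k = runif(1, 0.2, 3),
                 t0 = runif(1, 0.1, 0.5),
                 v_c_face = runif(1, 0.5, 3.5), v_e_face = runif(1, 0.1, 2),
                 v_c_oval = runif(1, 0.5, 3.5), v_e_oval = runif(1, 0.1, 2))
}

# minimal hand-built lba_draws object for group_compare / brain_behavior
# tests that do not need a real fit
fake_draws <- function(values_list, subjects = character(0),
                       subj_group = character(0), groups = c("HCL", "MDD")) {
  ids <- names(values_list)
  n_chain <- nrow(values_list[[1]])
  n_iter <- ncol(values_list[[1]])
  arr <- array(NA_real_, c(n_chain, n_iter, length(ids)),
               dimnames = list(NULL, NULL, ids))
  for (id in ids) arr[, , id] <- values_list[[id]]
  structure(list(values = arr, subjects = subjects, groups = groups,
                 subj_group = subj_group, config = NULL, acceptance = NULL),
            class = "lba_draws")
}
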
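test_that("positive-truncated normal log density is correct and normalized", {
  expect_identical(truncnorm_logpdf(-0.1, 0, 1), -Inf)
  expect_identical(truncnorm_logpdf(0, 2, 0.5), -Inf)
  # hand value: log(dnorm(1) / 0.5)
  expect_equal(truncnorm_logpdf(1, 0, 1), log(dnorm(1) / 0.5), tolerance = 1e-12)
  q <- integrate(function(x) exp(truncnorm_logpdf(x, 2, 0.5)), 0, 50,
                 rel.tol = 1e-10)$value
  expect_equal(q, 1, tolerance = 1e-6)
  expect_error(truncnorm_logpdf(1, 0, -1), class = "hlba_param_error")
})

test_that("truncated-normal sampler matches its closed-form mean and support", {
  set.seed(5)
  x <- rtruncnorm_pos(2e5, 0.5, 1)
  expect_true(all(x > 0))
  expect_equal(mean(x), truncnorm_mean(0.5, 1), tolerance = 3 * sd(x) / sqrt(length(x)))
  # deep truncation still positive and finite
  y <- rtruncnorm_pos(1e4, -3, 0.5)
  expect_true(all(y > 0 & is.finite(y)))
})

test_that("joint log posterior decomposes into its parts", {
  hypers <- list(
    MDD = group_hypers("MDD",
      mu = c(A = 1, k = 1, t0 = 0.3, v_c_face = 2, v_e_face = 1,
             v_c_oval = 2, v_e_oval = 1),
      sigma = c(A = 0.3, k = 0.3, t0 = 0.1, v_c_face = 0.5, v_e_face = 0.5,
                v_c_oval = 0.5, v_e_oval = 0.5)))
  priors <- hyperprior_config()
  theta <- matrix(c(0.8, 0.9, 0.25, 2.1, 0.9, 1.8, 1.1), 1, 7,
                  dimnames = list("S1", c("A", "k", "t0", "v_c_face",
                                          "v_e_face", "v_c_oval", "v_e_oval")))
  attr(theta, "group") <- "MDD"
  empty <- data.frame(subject_id = character(0), group = character(0),
                      condition = character(0), correct = integer(0),
                      rt = numeric(0))
  # zero trials: hierarchical prior density alone
  prior_only <- sum(truncnorm_logpdf(theta[1, ], hypers$MDD$mu, hypers$MDD$sigma)) +
    sum(truncnorm_logpdf(hypers$MDD$mu, priors$mu_loc, priors$mu_scale)) +
    sum(truncnorm_logpdf(hypers$MDD$sigma, priors$sigma_loc, priors$sigma_scale))
  expect_equal(joint_log_posterior(theta, hypers, empty, priors), prior_only)

  # one subject, one trial: independent summation of all addends
  tr <- data.frame(subject_id = "S1", group = "MDD", condition = "FACE",
                   correct = 1L, rt = 0.9)
  p <- subject_params(0.8, 0.9, 0.25, 2.1, 0.9, 1.8, 1.1)
  expected <- sum(trial_loglik(tr, p)) + prior_only
  expect_equal(joint_log_posterior(theta, hypers, tr, priors), expected)

  # duplicating every trial doubles exactly the likelihood portion
  tr2 <- rbind(tr, tr)
  expect_equal(joint_log_posterior(theta, hypers, tr2, priors),
               expected + sum(trial_loglik(tr, p)))

  # subject present in data but absent from the state
  tr_bad <- transform(tr, subject_id = "S9")
  expect_error(joint_log_posterior(theta, hypers, tr_bad, priors),
               class = "hlba_consistency_error")
})

test_that("joint posterior is exchangeable in subjects and separable across groups", {
  set.seed(21)
  cfg <- cohort_config(n_mdd = 3, n_hcl = 3, n_face = 6, n_oval = 2, seed = 2)
  coh <- generate_cohort(cfg)
  trials <- coh$trials
  ids <- unique(trials$subject_id)
  theta <- as.matrix(coh$truth$params[, c("A", "k", "t0", "v_c_face",
                                          "v_e_face", "v_c_oval", "v_e_oval")])
  rownames(theta) <- coh$truth$params$subject_id
  hypers <- coh$truth$hypers
  priors <- hyperprior_config()

  base <- joint_log_posterior(theta, hypers, trials, priors)
  # permuting subject (row) order changes nothing
  perm <- sample(nrow(theta))
  trials_perm <- trials[order(match(trials$subject_id, rownames(theta)[perm])), ]
  expect_equal(joint_log_posterior(theta[perm, ], hypers, trials_perm, priors), base)

  # the MDD hyper portion is blind to HCL data: changing HCL trials shifts
  # the joint by the same amount under different MDD hypers
  trials_mod <- trials
  hcl_rows <- which(trials_mod$group == "HCL")[1:4]
  trials_mod$rt[hcl_rows] <- trials_mod$rt[hcl_rows] + 0.3
  hypers2 <- hypers
  hypers2$MDD$mu["v_c_face"] <- hypers2$MDD$mu["v_c_face"] + 0.7
  d1 <- joint_log_posterior(theta, hypers, trials_mod, priors) - base
  d2 <- joint_log_posterior(theta, hypers2, trials_mod, priors) -
    joint_log_posterior(theta, hypers2, trials, priors)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("hyperprior draws always generate valid subject parameters", {
  set.seed(77)
  priors <- hyperprior_config()
  for (i in 1:100) {
    mu <- rtruncnorm_pos(7, priors$mu_loc, priors$mu_scale)
    sigma <- rtruncnorm_pos(7, priors$sigma_loc, priors$sigma_scale)
    names(mu) <- names(sigma) <- rownames(priors)
    h <- group_hypers("MDD", mu, sigma)
    p <- sample_subject_params(h)
    expect_s3_class(p, "subject_params")
    expect_true(all(unlist(p[c("A", "k", "t0")]) > 0))
  }
})

test_that("parameter states round-trip through the long text format", {
  theta <- matrix(c(0.8, 0.9, 0.25, 2.1, 0.9, 1.8, 1.1,
                    1.1, 1.2, 0.31, 2.4, 1.1, 2.0, 0.8),
                  2, 7, byrow = TRUE,
                  dimnames = list(c("M1", "H1"),
                                  c("A", "k", "t0", "v_c_face", "v_e_face",
                                    "v_c_oval", "v_e_oval")))
  hypers <- default_true_hypers()
  sg <- c(M1 = "MDD", H1 = "HCL")
  path <- tempfile(fileext = ".tsv")
  write_param_state(theta, hypers, sg, path)
  back <- read_param_state(path)
  expect_equal(back$theta, theta)
  expect_equal(back$subj_group, sg)
  expect_equal(back$hypers$MDD$mu, hypers$MDD$mu)
  expect_equal(back$hypers$HCL$sigma, hypers$HCL$sigma)
})
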
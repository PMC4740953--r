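test_that("accumulator CDF matches limits and a Monte-Carlo first-passage oracle", {
  expect_equal(lba_cdf(0, A = 1, b = 2, v = 1), 0)
  # symmetry: half of sampled drifts are positive when v = 0
  expect_equal(lba_cdf(1e6, A = 1, b = 2, v = 0, s = 1), 0.5, tolerance = 1e-5)
  # limit t -> Inf equals P(drift > 0)
  expect_equal(lba_cdf(1e7, A = 0.5, b = 1, v = 1.3, s = 1), pnorm(1.3),
               tolerance = 1e-6)

  # Monte-Carlo oracle: fraction of (start, drift) draws crossing by t
  set.seed(101)
  n <- 1e6
  start <- runif(n, 0, 1)
  drift <- rnorm(n, 1, 1)
  mc <- mean(drift > 0 & (2 - start) / drift <= 2)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(lba_cdf(2, A = 1, b = 2, v = 1, s = 1) - mc), 3 * se)

  # monotone nondecreasing in t
  tt <- seq(0, 10, by = 0.05)
  expect_true(all(diff(lba_cdf(tt, A = 1, b = 2, v = 1)) >= 0))

  expect_error(lba_cdf(1, A = -1, b = 2, v = 1), class = "hlba_param_error")
  expect_error(lba_cdf(1, A = 1, b = 0.5, v = 1), class = "hlba_param_error")
  expect_error(lba_cdf(1, A = 1, b = 2, v = 1, s = 0), class = "hlba_param_error")
})

test_that("accumulator density integrates to the positive-drift mass and differentiates the CDF", {
  # unreachable threshold in vanishing time
  expect_lt(lba_pdf(1e-12, A = 0.5, b = 1, v = 2), 1e-12)
  # quadrature equals Phi(v/s)
  q <- integrate(function(t) lba_pdf(t, 0.5, 1, 1.5, 1), 0, Inf)$value
  expect_equal(q, pnorm(1.5), tolerance = 1e-4)
  # central difference of the CDF reproduces the density
  h <- 1e-6
  fd <- (lba_cdf(1 + h, 1, 2, 1) - lba_cdf(1 - h, 1, 2, 1)) / (2 * h)
  expect_lt(abs(fd - lba_pdf(1, 1, 2, 1)), 1e-5)
})

test_that("CDF/PDF consistency holds on a time grid for random parameter sets", {
  set.seed(7)
  h <- 1e-6
  for (i in 1:5) {
    p <- random_params()
    tt <- seq(0.05, 5, by = 0.05)
    fd <- (lba_cdf(tt + h, p$A, p$b, p$v_c_face) -
             lba_cdf(tt - h, p$A, p$b, p$v_c_face)) / (2 * h)
    expect_lt(max(abs(fd - lba_pdf(tt, p$A, p$b, p$v_c_face))), 1e-5)
  }
})

test_that("trial log likelihood is the defective race density", {
  p <- subject_params(A = 0.5, k = 0.5, t0 = 0.2, v_c_face = 2, v_e_face = 1)
  # response before non-decision time has probability zero
  expect_identical(trial_loglik(data.frame(rt = 0.1, correct = 1,
                                           condition = "FACE"), p), -Inf)
  # symmetric race: equal drifts make correct and error equally likely
  ps <- subject_params(A = 0.5, k = 0.5, t0 = 0.2, v_c_face = 1.5, v_e_face = 1.5)
  ll_c <- trial_loglik(data.frame(rt = 0.8, correct = 1, condition = "FACE"), ps)
  ll_e <- trial_loglik(data.frame(rt = 0.8, correct = 0, condition = "FACE"), ps)
  expect_equal(ll_c, ll_e)
  # joint mass of both defective densities
  fc <- integrate(function(rt) exp(trial_loglik(
    data.frame(rt = rt, correct = 1, condition = "FACE"), p)), 0.2, Inf)$value
  fe <- integrate(function(rt) exp(trial_loglik(
    data.frame(rt = rt, correct = 0, condition = "FACE"), p)), 0.2, Inf)$value
  expect_equal(fc + fe, 1 - pnorm(-2) * pnorm(-1), tolerance = 1e-4)

  expect_error(subject_params(A = 0, k = 1, t0 = 0.2, v_c_face = 2, v_e_face = 1),
               class = "hlba_param_error")
  expect_error(trial_loglik(data.frame(rt = -1, correct = 1, condition = "FACE"), p),
               class = "hlba_data_error")
})

test_that("mass conservation holds across random parameter sets", {
  set.seed(42)
  for (i in 1:10) {
    p <- random_params()
    mass <- integrate(function(rt) exp(trial_loglik(
        data.frame(rt = rt, correct = 1, condition = "FACE"), p)),
        p$t0, Inf, rel.tol = 1e-9)$value +
      integrate(function(rt) exp(trial_loglik(
        data.frame(rt = rt, correct = 0, condition = "FACE"), p)),
        p$t0, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, total_response_mass(p), tolerance = 1e-4)
  }
})

test_that("log likelihood is finite whenever rt > t0 and params are valid", {
  set.seed(8)
  for (i in 1:20) {
    p <- random_params()
    rt <- p$t0 + runif(1, 1e-4, 30)
    ll <- trial_loglik(data.frame(rt = rt, correct = sample(0:1, 1),
                                  condition = sample(c("FACE", "OVAL"), 1)), p)
    expect_true(is.finite(ll))
  }
})

test_that("compiled and R density paths agree", {
  set.seed(12)
  for (i in 1:5) {
    p <- random_params()
    tr <- data.frame(rt = p$t0 + runif(20, 0.05, 4),
                     correct = sample(0:1, 20, replace = TRUE),
                     condition = sample(c("FACE", "OVAL"), 20, replace = TRUE))
    r_sum <- sum(trial_loglik(tr, p))
    cpp_sum <- hlba:::cpp_subject_loglik(
      unlist(p[c("A", "k", "t0", "v_c_face", "v_e_face", "v_c_oval", "v_e_oval")]),
      tr$rt, as.integer(tr$correct),
      ifelse(tr$condition == "FACE", 0L, 1L), 1)
    expect_equal(r_sum, cpp_sum, tolerance = 1e-10)
  }
})

test_that("simulator reaches the ballistic limit and matches the likelihood", {
  # deterministic limit: A ~ 0, s ~ 0 -> rt = b/v + t0 exactly, always correct
  p0 <- subject_params(A = 1e-9, k = 1, t0 = 0.2, v_c_face = 1, v_e_face = -1,
                       s = 1e-9)
  set.seed(3)
  sim0 <- simulate_trials(p0, rep("FACE", 100))
  expect_true(all(sim0$correct == 1))
  expect_equal(sim0$rt, rep(1.2, 100), tolerance = 1e-6)

  # choice probability and conditional RT distribution vs quadrature
  p <- subject_params(A = 0.5, k = 0.5, t0 = 0.2, v_c_face = 2, v_e_face = 1)
  set.seed(99)
  n <- 2e4
  sim <- simulate_trials(p, rep("FACE", n))
  oracle <- numeric_choice_cdf(p, "FACE", correct = 1)
  # simulator renormalizes the no-response event, the density does not
  p_correct_theory <- oracle$prob / total_response_mass(p)
  se <- sqrt(p_correct_theory * (1 - p_correct_theory) / n)
  expect_lt(abs(mean(sim$correct) - p_correct_theory), 3 * se)
  rts <- sort(sim$rt[sim$correct == 1])
  emp <- seq_along(rts) / length(rts)
  ks <- max(abs(emp - oracle$cdf(rts)))
  expect_lt(ks, 0.02)
})

test_that("trial tables round-trip through delimited text", {
  tr <- data.frame(subject_id = c("S1", "S1", "S2"), group = c("MDD", "MDD", "HCL"),
                   condition = c("FACE", "OVAL", "FACE"),
                   emotion = c("FEAR", NA, "SAD"),
                   correct = c(1L, 0L, 1L), rt = c(1.25, 2.5, 0.875),
                   valid = c(TRUE, TRUE, TRUE))
  path <- tempfile(fileext = ".tsv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$rt, tr$rt)
  expect_equal(back$subject_id, tr$subject_id)
  expect_equal(as.logical(back$valid), tr$valid)
  path2 <- tempfile(fileext = ".csv")
  write_trials(back, path2)
  expect_equal(read_trials(path2)$rt, tr$rt)
})
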
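make_trials <- function(rt, subject = "S1", group = "MDD",
                        condition = "FACE", emotion = "FEAR", correct = 1) {
  data.frame(subject_id = subject, group = group, condition = condition,
             emotion = ifelse(condition == "OVAL", NA, emotion),
             correct = correct, rt = rt, valid = NA)
}

test_that("validity filter keeps the >= threshold boundary and is idempotent", {
  tr <- make_trials(c(0.100, 0.150, 0.200))
  kept <- filter_valid(tr, 0.150)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$rt, c(0.150, 0.200))
  expect_true(all(kept$valid))
  expect_equal(nrow(filter_valid(tr, 0)), 3)
  expect_equal(filter_valid(kept, 0.150), kept)
  expect_error(filter_valid(tr, -0.1), class = "hlba_config_error")
})

test_that("behavioral summaries aggregate subject means with SEM", {
  tr <- rbind(make_trials(c(1, 2, 3), subject = "S1"),
              make_trials(c(2, 2), subject = "S2", correct = c(1, 0)))
  s <- summarize_behavior(tr, by = "condition")
  expect_equal(s$mean_rt, mean(c(2, 2)))  # subject means 2 and 2
  expect_equal(s$accuracy_pct, mean(c(100, 50)))
  expect_equal(s$n_subjects, 2L)
  # all-correct trials give 100%
  s1 <- summarize_behavior(make_trials(c(1, 2)), by = "condition")
  expect_equal(s1$accuracy_pct, 100)
  # a group with no trials is explicit missing, not zero
  s2 <- summarize_behavior(tr, by = "condition", groups = c("MDD", "HCL"))
  hcl <- s2[s2$group == "HCL", ]
  expect_equal(nrow(hcl), 1)
  expect_true(is.na(hcl$mean_rt) && is.na(hcl$accuracy_pct))
  expect_equal(hcl$n_subjects, 0L)
})

test_that("simulated group mean RT matches the analytic defective-density mean", {
  # the race RT density has a t^-2 tail (winner with a vanishing drift while
  # the loser's drift is negative), so the unconditional mean diverges;
  # compare means within a finite window instead
  p <- subject_params(A = 1, k = 3, t0 = 0.35, v_c_face = 2.3, v_e_face = 1)
  t_max <- 10
  dens <- function(rt)
    exp(trial_loglik(data.frame(rt = rt, correct = 1, condition = "FACE"), p)) +
    exp(trial_loglik(data.frame(rt = rt, correct = 0, condition = "FACE"), p))
  mass <- integrate(dens, p$t0, t_max, rel.tol = 1e-9)$value
  mean_rt_theory <- integrate(function(rt) rt * dens(rt), p$t0, t_max,
                              rel.tol = 1e-9)$value / mass
  set.seed(33)
  sim <- simulate_trials(p, rep("FACE", 4e4))
  rts <- sim$rt[sim$rt <= t_max]
  expect_lt(abs(mean(rts) - mean_rt_theory), 3 * sd(rts) / sqrt(length(rts)))
})

test_that("posterior medians are per-subject and robust", {
  vals <- list("S1.v_c_face" = matrix(2.5, 2, 5),
               "S2.v_c_face" = matrix(c(1, 2, 100, 2, 2, 1, 2, 2, 1, 2), 2, 5))
  draws <- fake_draws(vals, subjects = c("S1", "S2"),
                      subj_group = c(S1 = "MDD", S2 = "MDD"))
  med <- posterior_medians(draws, "v_c_face")
  expect_equal(unname(med["S1"]), 2.5)
  expect_equal(unname(med["S2"]), 2)
  expect_error(posterior_medians(draws, "v_c_face", subjects = "S3"),
               class = "hlba_lookup_error")
  # sampling check: median of many standard-normal draws is near 0
  set.seed(55)
  big <- fake_draws(list("S1.t0" = matrix(rnorm(1e4), 4, 2500)),
                    subjects = "S1", subj_group = c(S1 = "MDD"))
  expect_lt(abs(posterior_medians(big, "t0")["S1"]), 0.03)
})

test_that("Spearman correlation matches hand enumeration and its invariances", {
  # classic d^2 example: ranks (1,2,3,4) vs (2,1,4,3)
  x <- c(10, 20, 30, 40)
  y <- c(5, 2, 90, 60)
  res <- spearman_cor(x, y)
  expect_equal(res$rho, 0.6)
  # perfect monotone association
  expect_equal(spearman_cor(1:5, c(2, 4, 9, 16, 33))$rho, 1)
  expect_equal(spearman_cor(1:5, -c(2, 4, 9, 16, 33))$rho, -1)
  expect_equal(spearman_cor(1:5, c(2, 4, 9, 16, 33))$p_two_sided, 0)
  # invariance under strictly monotone transforms and argument swap
  set.seed(41)
  a <- rnorm(30)
  b <- 0.5 * a + rnorm(30)
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(b, a)$rho)
  expect_error(spearman_cor(a, b[-1]), class = "hlba_data_error")
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), class = "hlba_data_error")
  expect_error(spearman_cor(a[1:2], b[1:2]), class = "hlba_data_error")
})

test_that("permutation p-values agree with the t-approximation at moderate n", {
  set.seed(47)
  x <- rnorm(40)
  y <- 0.45 * x + rnorm(40)
  pt <- spearman_cor(x, y, method = "t")$p_two_sided
  pp <- spearman_cor(x, y, method = "permutation", n_perm = 4000)$p_two_sided
  expect_lt(abs(pt - pp), 0.03)
})

test_that("ROI correlations run within group and flag subject mismatches", {
  set.seed(3)
  med <- setNames(rnorm(12, 2), sprintf("S%02d", 1:12))
  sg <- setNames(rep(c("MDD", "HCL"), each = 6), names(med))
  roi <- data.frame(subject_id = names(med), roi = "L_fusiform", psc = unname(med))
  res <- roi_correlations(med, roi, sg)
  # psc identical to the medians: rho = 1 within each group
  expect_equal(res$rho, c(1, 1))
  expect_equal(sort(res$group), c("HCL", "MDD"))
  roi_bad <- roi[-1, ]
  expect_error(roi_correlations(med, roi_bad, sg), "S01",
               class = "hlba_consistency_error")
})

test_that("ROI tables round-trip through delimited text", {
  roi <- data.frame(subject_id = c("A1", "A2"), roi = "L_fusiform",
                    psc = c(0.321, 0.77))
  path <- tempfile(fileext = ".tsv")
  write_roi(roi, path)
  expect_equal(read_roi(path)$psc, roi$psc)
})
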
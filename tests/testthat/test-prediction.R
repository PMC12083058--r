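test_that("b-sampler reduces to the conjugate Gaussian when associations are zero", {
  # with alpha = 0 the survival factor is constant in b, so the sampler's
  # stationary law is the closed-form longitudinal conditional
  p <- default_params()
  for (k in 1:2) for (j in 1:2)
    p$causes[[k]]$association[[j]]$coefficient <- 0
  post <- posterior_from_params(p)
  set.seed(5)
  tt <- c(0, 0.25, 0.5, 0.75, 1.0)
  subj <- subject_truth("c", c(0.5, 0.05, -0.5, -0.02), 20)
  recs <- rbind(
    data.frame(subject_id = "c", outcome = "troponin", time_years = tt,
               value = linear_predictor(p, subj$random_effects, "troponin",
                                        tt) + rnorm(5, 0, 0.2114)),
    data.frame(subject_id = "c", outcome = "ntprobnp", time_years = tt,
               value = linear_predictor(p, subj$random_effects, "ntprobnp",
                                        tt) + rnorm(5, 0, 0.4105)))
  hist <- patient_history("c", recs, 20, t = 1.0)
  bs <- sample_conditional_random_effects(
    post, hist, mc_control(n_theta = 1, n_b = 1500, mh_steps = 6000))
  cond <- bs$conditional
  expect_gt(bs$acceptance, 0.1)
  # exact Gaussian moments
  mu <- cond$Mu[1, ]; C <- cond$C[, , 1]
  m_hat <- colMeans(bs$pairs)
  # generous MC tolerance for autocorrelated MH draws
  expect_lt(max(abs(m_hat - mu) / sqrt(diag(C))), 0.25)
  C_hat <- stats::cov(bs$pairs)
  expect_lt(sqrt(sum((C_hat - C)^2)) / sqrt(sum(C^2)), 0.25)
})

test_that("with no data the sampler recovers the random-effects prior", {
  p <- default_params()
  for (k in 1:2) for (j in 1:2)
    p$causes[[k]]$association[[j]]$coefficient <- 0
  post <- posterior_from_params(p)
  set.seed(6)
  hist <- empty_history(0, w = 20)
  bs <- sample_conditional_random_effects(
    post, hist, mc_control(n_theta = 1, n_b = 1200, mh_steps = 5000))
  D <- p$re_covariance
  expect_lt(max(abs(colMeans(bs$pairs)) / sqrt(diag(D))), 0.25)
  expect_lt(sqrt(sum((stats::cov(bs$pairs) - D)^2)) / sqrt(sum(D^2)), 0.3)
})

test_that("long event-free survival shifts risk-driving effects downward", {
  p <- default_params()
  # strengthen the troponin association so the survival factor is informative
  p$causes[[1]]$association[[1]]$coefficient <- 2.0
  post <- posterior_from_params(p)
  set.seed(7)
  hist <- empty_history(10, w = 20)  # event-free 10 years, no measurements
  bs <- sample_conditional_random_effects(
    post, hist, mc_control(n_theta = 1, n_b = 800, mh_steps = 3000))
  # longitudinal-only conditional mean is 0; survival conditioning must
  # pull the troponin intercept (hazard-increasing) below it
  expect_lt(mean(bs$pairs[, 1]), -0.1)
})

test_that("degenerate-posterior prediction equals the true conditional CIF", {
  p <- default_params()
  p$re_covariance <- diag(1e-8, 4)
  post <- posterior_from_params(p)
  subj <- subject_truth("d", rep(0, 4), 20, true_event_time = 20,
                        true_cause = 0L)
  hist <- empty_history(0.5, w = 20)
  set.seed(8)
  for (k in 1:2) {
    pr <- predict_cif(post, hist, k, s = 1.5,
                      mc = mc_control(n_theta = 2, n_b = 2, mh_steps = 4))
    expect_equal(pr$point_estimate, true_conditional_cif(p, subj, k, 0.5, 1.5),
                 tolerance = 2e-4)
    expect_lt(pr$upper95 - pr$lower95, 1e-6)
  }
})

test_that("prediction matches the constant-hazard closed form and limits", {
  pc <- const_hazard_params(c(10, 1e9), sigma = 1e-6)
  post <- posterior_from_params(pc)
  hist <- empty_history(2)
  set.seed(9)
  pr <- predict_cif(post, hist, 1, s = 3,
                    mc = mc_control(n_theta = 1, n_b = 1, mh_steps = 3))
  expect_equal(pr$point_estimate, 1 - exp(-0.1), tolerance = 1e-4)
  # empty window
  pr0 <- predict_cif(post, hist, 1, s = 2 + 1e-9,
                     mc = mc_control(n_theta = 1, n_b = 1, mh_steps = 3))
  expect_lt(pr0$point_estimate, 1e-8)
  # one cause, huge horizon: conservation to 1
  p1 <- const_hazard_params(c(2, 1e12), sigma = 1e-6)
  post1 <- posterior_from_params(p1)
  set.seed(10)
  cv <- predict_cif_curve(post1, hist, 1, s_grid = c(3, 10, 60),
                          mc = mc_control(1, 1, 3, grid_step = 0.05))
  expect_equal(cv$point[3], 1, tolerance = 1e-3)
})

test_that("shared-draw curves are monotone draw-by-draw and consistent", {
  sm <- fit_small_cached()
  hist <- patient_history(
    "t1", sm$dataset$test$longitudinal[
      sm$dataset$test$longitudinal$subject_id ==
        sm$dataset$test$survival$subject_id[1], ],
    sm$dataset$test$survival$maggic[1], t = 0.5)
  set.seed(11)
  s_grid <- 0.5 + seq(0.05, 1, by = 0.05)
  cv <- predict_cif_curve(sm$fit, hist, 1, s_grid,
                          mc = mc_control(n_theta = 50, n_b = 3,
                                          mh_steps = 15))
  expect_true(all(diff(t(cv$pair_draws)) >= -1e-12))
  expect_true(all(diff(cv$point) >= -1e-12))
  expect_true(all(cv$pair_draws >= 0 & cv$pair_draws <= 1))
  expect_true(all(cv$lower95 <= cv$point + 1e-12) &&
                all(cv$point <= cv$upper95 + 1e-12))

  # a matched-seed scalar call reproduces the curve at the same horizon
  set.seed(11)
  pr <- predict_cif_curve(sm$fit, hist, 1, s_grid,
                          mc = mc_control(n_theta = 50, n_b = 3,
                                          mh_steps = 15))
  expect_identical(cv$point, pr$point)
})

test_that("Monte-Carlo error of the point estimate shrinks with the budget", {
  p <- default_params()
  post <- posterior_from_params(p)
  hist <- empty_history(0.5, w = 20)
  sds <- vapply(c(3, 12, 48), function(nb) {
    reps <- vapply(1:24, function(r) {
      set.seed(1000 + 17 * r + nb)
      predict_cif(post, hist, 1, s = 1.5,
                  mc = mc_control(n_theta = 1, n_b = nb,
                                  mh_steps = 150))$point_estimate
    }, 0)
    stats::sd(reps)
  }, 0)
  # SE drops with the number of kept draws; autocorrelation of the MH
  # states keeps the decay below the ideal 1/sqrt(n)
  expect_lt(sds[2], sds[1])
  expect_lt(sds[3], sds[1] / 1.4)
})

test_that("plug-in predictions at baseline are calibrated against simulation", {
  # cohort-level self-consistency: group subjects by predicted 1-year risk
  # quantile (degenerate posterior at the truth, prediction from baseline
  # covariates only) and compare with realized cause-1 incidence
  p <- default_params()
  cfg <- simulation_config(n_train = 2500L, n_test = 1L)
  ds <- generate_dataset(p, cfg, seed = 2718)
  post <- posterior_from_params(p)
  truths <- ds$train$truths
  set.seed(12)
  pred <- vapply(truths, function(s) {
    hist <- empty_history(0, w = s$baseline_covariates)
    predict_cif(post, hist, 1, s = 1,
                mc = mc_control(n_theta = 1, n_b = 40, mh_steps = 80,
                                grid_step = 0.05))$point_estimate
  }, 0)
  obs <- vapply(truths, function(s)
    as.numeric(s$true_event_time <= 1 && s$true_cause == 1L), 0)
  qs <- cut(pred, stats::quantile(pred, seq(0, 1, 0.25)),
            include.lowest = TRUE)
  for (g in levels(qs)) {
    sel <- qs == g
    n <- sum(sel); phat <- mean(obs[sel]); pbar <- mean(pred[sel])
    expect_lt(abs(phat - pbar), 3 * sqrt(max(pbar * (1 - pbar), 1e-4) / n))
  }
})
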
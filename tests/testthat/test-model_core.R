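test_that("linear predictor reproduces fixed-effect arithmetic", {
  p <- default_params()
  expect_equal(linear_predictor(p, rep(0, 4), "troponin", 0), 2.8788)
  expect_equal(linear_predictor(p, rep(0, 4), "troponin", 1),
               2.8788 + 0.0537)
  # random effects shift intercept and slope additively
  b <- c(0.3, -0.02, 0, 0)
  expect_equal(linear_predictor(p, b, "troponin", 2),
               2.8788 + 0.3 + (0.0537 - 0.02) * 2)
  # cancelling the intercepts gives zero at t = 0
  b_cancel <- c(-2.8788, 0, -4.6624, 0)
  expect_equal(linear_predictor(p, b_cancel, "ntprobnp", 0), 0)
  expect_error(linear_predictor(p, rep(0, 4), "crp", 1),
               class = "jmsched_unknown_outcome")
})

test_that("cause-specific hazard matches Weibull and association arithmetic", {
  pe <- const_hazard_params(c(1, 1))
  s <- zero_subject()
  expect_equal(cause_specific_hazard(pe, s, 1, c(0.1, 1, 7)), rep(1, 3))
  # shape 2, scale 1: h(t) = 2t
  pw <- joint_model_params(
    list(longitudinal_spec("troponin", c(0, 0), 0.1),
         longitudinal_spec("ntprobnp", c(0, 0), 0.1)),
    diag(1e-8, 4), list(cause_spec(1, 2, 1)), character())
  expect_equal(cause_specific_hazard(pw, s, 1, 0.5), 1.0)
  expect_equal(cause_specific_hazard(pw, s, 1, 0), 0)  # continuity, shape > 1
  ps <- joint_model_params(
    list(longitudinal_spec("troponin", c(0, 0), 0.1),
         longitudinal_spec("ntprobnp", c(0, 0), 0.1)),
    diag(1e-8, 4), list(cause_spec(1, 0.5, 1)), character())
  expect_error(cause_specific_hazard(ps, s, 1, 0),
               class = "jmsched_hazard_origin")

  # value association: h = h0 * exp(alpha * eta(t)), scalar oracle
  p <- default_params()
  b <- c(0.2, 0.01, -0.1, 0.005)
  subj <- subject_truth("a", b, 20)
  t <- 1.7
  eta_tr <- 2.8788 + 0.2 + (0.0537 + 0.01) * t
  eta_nt <- 4.6624 - 0.1 + (0.0472 + 0.005) * t
  h0 <- 1 / 244304
  expect_equal(cause_specific_hazard(p, subj, 1, t),
               h0 * exp(0.0112 * 20 + 0.5080 * eta_tr + 0.9957 * eta_nt),
               tolerance = 1e-10)
})

test_that("slope and area association forms use the trajectory functionals", {
  mk <- function(form, coef) joint_model_params(
    list(longitudinal_spec("troponin", c(1.0, 0.4), 0.1),
         longitudinal_spec("ntprobnp", c(0, 0), 0.1)),
    diag(1e-8, 4),
    list(cause_spec(1, 1, 1,
                    association = list(association_term("troponin", form,
                                                        coef)))),
    character())
  s <- zero_subject()
  t <- 2.0
  expect_equal(cause_specific_hazard(mk("value", 0.3), s, 1, t),
               exp(0.3 * (1.0 + 0.4 * t)))
  expect_equal(cause_specific_hazard(mk("slope", 0.3), s, 1, t),
               exp(0.3 * 0.4))
  expect_equal(cause_specific_hazard(mk("area", 0.3), s, 1, t),
               exp(0.3 * (1.0 * t + 0.4 * t^2 / 2)))
  # slope/area reduce to value when eta is flat: eta = c0 constant
  mkflat <- function(form, coef) joint_model_params(
    list(longitudinal_spec("troponin", c(1.0, 0), 0.1),
         longitudinal_spec("ntprobnp", c(0, 0), 0.1)),
    diag(1e-8, 4),
    list(cause_spec(1, 1, 1,
                    association = list(association_term("troponin", form,
                                                        coef)))),
    character())
  # value with alpha and area with alpha/t give identical hazard at time t
  expect_equal(cause_specific_hazard(mkflat("area", 0.3 / t), s, 1, t),
               cause_specific_hazard(mkflat("value", 0.3), s, 1, t))
})

test_that("cumulative hazard, survival and conditional CIF match closed forms", {
  # two constant cause hazards 0.3 and 0.7
  p <- const_hazard_params(c(1 / 0.3, 1 / 0.7))
  s <- zero_subject()
  expect_equal(cumulative_overall_hazard(p, s, 0), 0)
  expect_equal(cumulative_overall_hazard(p, s, 2), 2.0, tolerance = 1e-10)
  expect_equal(overall_survival(p, s, 0), 1)
  expect_equal(overall_survival(p, s, 1), exp(-1), tolerance = 1e-10)

  # Weibull shape 2 closed form (t/scale)^shape
  pw <- joint_model_params(
    list(longitudinal_spec("troponin", c(0, 0), 0.1),
         longitudinal_spec("ntprobnp", c(0, 0), 0.1)),
    diag(1e-8, 4), list(cause_spec(1, 2, 1)), character())
  expect_equal(cumulative_overall_hazard(pw, s, 1.5), 2.25,
               tolerance = 1e-6)

  # quadrature vs closed form with a covariate-like multiplier via
  # association on a flat trajectory
  pa <- joint_model_params(
    list(longitudinal_spec("troponin", c(2, 0), 0.1),
         longitudinal_spec("ntprobnp", c(0, 0), 0.1)),
    diag(1e-8, 4),
    list(cause_spec(1, 2, 1, association = list(
      association_term("troponin", "value", 0.5)))), character())
  expect_equal(cumulative_overall_hazard(pa, s, 1.5), 2.25 * exp(1),
               tolerance = 1e-6)

  # conditional CIF closed forms
  ph <- const_hazard_params(c(2, 2))   # h1 = h2 = 0.5
  expect_equal(true_conditional_cif(ph, s, 1, 0, 0), 0)
  expect_equal(true_conditional_cif(ph, s, 1, 0, 1),
               0.5 * (1 - exp(-1)), tolerance = 1e-8)
  # conservation: sum over causes at long horizon -> 1
  tot <- true_conditional_cif(ph, s, 1, 0, 40) +
    true_conditional_cif(ph, s, 2, 0, 40)
  expect_equal(tot, 1, tolerance = 1e-8)
  # conditioning on survival to t: memoryless for constant hazards
  expect_equal(true_conditional_cif(ph, s, 1, 3, 4),
               true_conditional_cif(ph, s, 1, 0, 1), tolerance = 1e-8)
})

test_that("conditional CIF is monotone in s and bounded for realistic subjects", {
  p <- default_params()
  set.seed(42)
  cfg <- simulation_config()
  for (r in 1:5) {
    subj <- draw_subject(p, cfg, paste0("s", r))
    sgrid <- c(0.5, 1, 2, 4, 8, 15)
    vals <- vapply(sgrid, function(s2)
      true_conditional_cif(p, subj, 1, 0.5, s2), 0)
    expect_true(all(diff(vals) >= -1e-12))
    tot <- true_conditional_cif(p, subj, 1, 0.5, 15) +
      true_conditional_cif(p, subj, 2, 0.5, 15)
    expect_true(tot >= 0 && tot <= 1)
  }
})

test_that("grid-based truth computation agrees with panel quadrature", {
  p <- default_params()
  set.seed(7)
  subj <- draw_subject(p, simulation_config(), "g")
  gr <- jmsched:::subject_risk_grid(p, subj, 12, step = 0.005)
  # cumulative hazard and survival
  i6 <- which.min(abs(gr$times - 6))
  expect_equal(gr$H[i6], cumulative_overall_hazard(p, subj, gr$times[i6]),
               tolerance = 1e-5)
  # window risk CIF(t, t+1)
  wr <- jmsched:::grid_window_risk(gr, 1, 1.0)
  i3 <- which.min(abs(gr$times - 3))
  expect_equal(wr[i3], true_conditional_cif(p, subj, 1, gr$times[i3],
                                            gr$times[i3] + 1),
               tolerance = 1e-5)
})

test_that("parameter containers validate their invariants", {
  expect_error(longitudinal_spec("x", c(1, 2), -0.1),
               class = "jmsched_spec_error")
  expect_error(cause_spec(1, -1, 1), class = "jmsched_spec_error")
  expect_error(association_term("x", "value", "a"),
               class = "jmsched_spec_error")
  # D must be symmetric PSD with matching dimension
  bad <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  expect_error(joint_model_params(
    list(longitudinal_spec("a", c(0, 0), 1),
         longitudinal_spec("b", c(0, 0), 1)),
    bad, list(cause_spec(1, 1, 1)), character()),
    class = "jmsched_spec_error")
  D <- diag(4); D[1, 1] <- -1
  expect_error(joint_model_params(
    list(longitudinal_spec("a", c(0, 0), 1),
         longitudinal_spec("b", c(0, 0), 1)),
    D, list(cause_spec(1, 1, 1)), character()),
    class = "jmsched_spec_error")
  # association must reference declared outcomes
  expect_error(joint_model_params(
    list(longitudinal_spec("a", c(0, 0), 1),
         longitudinal_spec("b", c(0, 0), 1)),
    diag(4),
    list(cause_spec(1, 1, 1, association = list(
      association_term("zz", "value", 1)))), character()),
    class = "jmsched_spec_error")
})
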
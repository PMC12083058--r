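# shared in-code fixtures for the test suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-outcome skeleton with flat trajectories and constant cause-specific
# hazards h_k = 1/scale_k (Weibull shape 1, no covariates, no association)
const_hazard_params <- function(scales, sigma = 0.1, D = diag(1e-8, 4)) {
  joint_model_params(
    longitudinal = list(
      longitudinal_spec("troponin", beta = c(0, 0), residual_sd = sigma),
      longitudinal_spec("ntprobnp", beta = c(0, 0), residual_sd = sigma)),
    re_covariance = D,
    causes = lapply(seq_along(scales), function(k)
      cause_spec(k, shape = 1, scale = scales[k])),
    baseline_covariate_names = character())
}

zero_subject <- function(T = NA_real_, cause = NA_integer_, b = rep(0, 4))
  subject_truth("s", b, numeric(), true_event_time = T, true_cause = cause)

empty_history <- function(t, w = numeric())
  patient_history("s", data.frame(outcome = character(),
                                  time_years = numeric(), value = numeric()),
                  w, t)

# small cohort + laplace fit, cached across tests within a session
fit_small_cached <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      p <- default_params()
      cfg <- simulation_config(n_train = 120L, n_test = 5L)
      ds <- generate_dataset(p, cfg, seed = 2024L)
      fit <- fit_joint_model(ds$train$longitudinal, ds$train$survival,
                             method = "laplace", seed = 1L)
      memo <<- list(params = p, config = cfg, dataset = ds, fit = fit)
    }
    memo
  }
})
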
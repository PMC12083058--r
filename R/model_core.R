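#' Specification of one longitudinal biomarker submodel
#'
#' Defines a Gaussian linear mixed submodel for one log-scale biomarker with
#' fixed and random design terms drawn from \code{"intercept"} and
#' \code{"time"} (random intercepts and slopes, the canonical case).
#'
#' @param outcome Character label, e.g. \code{"troponin"}.
#' @param beta Numeric vector of fixed-effect coefficients, one per element of
#'   \code{fixed_design}.
#' @param residual_sd Positive residual standard deviation on the log scale.
#' @param fixed_design Character vector of basis labels for the fixed effects.
#' @param random_design Character vector of basis labels for the random
#'   effects; must be a subset of \code{fixed_design}.
#' @return An object of class \code{"longitudinal_spec"}.
#' @export
longitudinal_spec <- function(outcome, beta, residual_sd,
                              fixed_design = c("intercept", "time"),
                              random_design = c("intercept", "time")) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  allowed <- c("intercept", "time")
  if (!length(fixed_design) || !all(fixed_design %in% allowed))
    stop_jmsched("fixed_design must be a non-empty subset of {intercept, time}",
                 "jmsched_spec_error")
  if (!length(random_design) || !all(random_design %in% fixed_design))
    stop_jmsched("random_design must be a non-empty subset of fixed_design",
                 "jmsched_spec_error")
  if (length(beta) != length(fixed_design))
    stop_jmsched("beta length must match fixed_design", "jmsched_spec_error")
  if (!is_number(residual_sd) || residual_sd < 0)
    stop_jmsched("residual_sd must be a single non-negative number",
                 "jmsched_spec_error")
  structure(list(outcome = outcome, beta = as.numeric(beta),
                 residual_sd = residual_sd,
                 fixed_design = fixed_design, random_design = random_design),
            class = "longitudinal_spec")
}

#' Association between a biomarker trajectory and a cause-specific hazard
#'
#' @param outcome Label of a declared longitudinal outcome.
#' @param form One of \code{"value"} (current level of the linear predictor),
#'   \code{"slope"} (its derivative) or \code{"area"} (its integral from 0).
#' @param coefficient Association coefficient; a single number, or a function
#'   of time for a time-varying (generative-only) association.
#' @return An object of class \code{"association_term"}.
#' @export
association_term <- function(outcome, form = c("value", "slope", "area"),
                             coefficient) {
  form <- match.arg(form)
  if (!(is_number(coefficient) || is.function(coefficient)))
    stop_jmsched("coefficient must be a number or a function of time",
                 "jmsched_spec_error")
  structure(list(outcome = outcome, form = form, coefficient = coefficient),
            class = "association_term")
}

#' Specification of one cause-specific hazard
#'
#' Weibull baseline hazard \eqn{h_0(t) = (a/s)(t/s)^{a-1}} (shape \eqn{a},
#' scale \eqn{s}) multiplied by \eqn{\exp(\gamma'w + \sum_j \alpha_j f_j(t))}
#' where the \eqn{f_j} are association functionals of the biomarker linear
#' predictors.
#'
#' @param cause Integer cause code (1-based).
#' @param shape,scale Positive Weibull parameters.
#' @param baseline_coefficients Named or plain numeric vector of log hazard
#'   ratios for the baseline covariates.
#' @param association List of [association_term()] objects.
#' @return An object of class \code{"cause_spec"}.
#' @export
cause_spec <- function(cause, shape, scale, baseline_coefficients = numeric(),
                       association = list()) {
  if (!is_number(shape) || shape <= 0) stop_jmsched("shape must be > 0",
                                                    "jmsched_spec_error")
  if (!is_number(scale) || scale <= 0) stop_jmsched("scale must be > 0",
                                                    "jmsched_spec_error")
  stopifnot(all(vapply(association, inherits, TRUE, "association_term")))
  structure(list(cause = as.integer(cause), shape = shape, scale = scale,
                 baseline_coefficients = as.numeric(baseline_coefficients),
                 association = association),
            class = "cause_spec")
}

#' Full parameter set of the joint model
#'
#' Bundles the longitudinal submodels, the random-effects covariance matrix
#' \code{D} (stacked per outcome in declaration order, within outcome in
#' design order: here troponin intercept, troponin slope, NT-proBNP
#' intercept, NT-proBNP slope), and the cause-specific hazard submodels.
#'
#' @param longitudinal List of [longitudinal_spec()] objects.
#' @param re_covariance Symmetric positive-semidefinite matrix over the
#'   stacked random effects.
#' @param causes List of [cause_spec()] objects with cause codes 1..K.
#' @param baseline_covariate_names Character labels of baseline covariates,
#'   matching the length of each cause's \code{baseline_coefficients}.
#' @return An object of class \code{"joint_model_params"}.
#' @export
joint_model_params <- function(longitudinal, re_covariance, causes,
                               baseline_covariate_names = character()) {
  stopifnot(length(longitudinal) >= 1L,
            all(vapply(longitudinal, inherits, TRUE, "longitudinal_spec")),
            length(causes) >= 1L,
            all(vapply(causes, inherits, TRUE, "cause_spec")))
  D <- as.matrix(re_covariance)
  q <- sum(vapply(longitudinal, function(s) length(s$random_design), 1L))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop_jmsched("re_covariance must be symmetric", "jmsched_spec_error")
  if (nrow(D) != q)
    stop_jmsched("re_covariance dimension must equal total random-design size",
                 "jmsched_spec_error")
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_jmsched("re_covariance must be positive semi-definite",
                 "jmsched_spec_error")
  out_names <- vapply(longitudinal, `[[`, "", "outcome")
  for (cs in causes) {
    refs <- vapply(cs$association, `[[`, "", "outcome")
    if (!all(refs %in% out_names))
      stop_jmsched("association terms reference undeclared outcomes",
                   "jmsched_spec_error")
    for (at in cs$association)
      if (is.function(at$coefficient) && !is.null(attr(at, "fitted")))
        stop_jmsched("time-varying association only allowed generatively",
                     "jmsched_spec_error")
    if (length(cs$baseline_coefficients) != length(baseline_covariate_names))
      stop_jmsched("baseline_coefficients length must match covariate names",
                   "jmsched_spec_error")
  }
  names(longitudinal) <- out_names
  structure(list(longitudinal = longitudinal, re_covariance = D,
                 causes = causes,
                 baseline_covariate_names = baseline_covariate_names),
            class = "joint_model_params")
}

#' Latent truth for one simulated subject
#'
#' @param subject_id Label.
#' @param random_effects Numeric vector \code{b} in the stacked ordering of
#'   the random-effects covariance.
#' @param baseline_covariates Numeric vector (here the MAGGIC score).
#' @param true_event_time Observed event/censoring time in years (optional
#'   until sampled).
#' @param true_cause Integer 0..K; 0 means censored.
#' @return An object of class \code{"subject_truth"}.
#' @export
subject_truth <- function(subject_id, random_effects, baseline_covariates,
                          true_event_time = NA_real_, true_cause = NA_integer_) {
  structure(list(subject_id = subject_id,
                 random_effects = as.numeric(random_effects),
                 baseline_covariates = as.numeric(baseline_covariates),
                 true_event_time = true_event_time,
                 true_cause = as.integer(true_cause)),
            class = "subject_truth")
}

# ---- internal: linear representation of eta ---------------------------------

# index of each outcome's random effects within the stacked b vector
re_index <- function(params) {
  sizes <- vapply(params$longitudinal, function(s) length(s$random_design), 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  stats::setNames(Map(seq.int, starts, ends),
                  vapply(params$longitudinal, `[[`, "", "outcome"))
}

# eta_p(t) = c0 + c1 * t ; returns c(c0, c1) for one outcome given stacked b
eta_coefs <- function(params, b, outcome) {
  spec <- params$longitudinal[[outcome]]
  if (is.null(spec))
    stop_jmsched(sprintf("unknown outcome '%s'", outcome),
                 "jmsched_unknown_outcome")
  idx <- re_index(params)[[outcome]]
  brand <- as.numeric(b)[idx]
  c0 <- 0; c1 <- 0
  for (j in seq_along(spec$fixed_design)) {
    if (spec$fixed_design[j] == "intercept") c0 <- c0 + spec$beta[j]
    else c1 <- c1 + spec$beta[j]
  }
  for (j in seq_along(spec$random_design)) {
    if (spec$random_design[j] == "intercept") c0 <- c0 + brand[j]
    else c1 <- c1 + brand[j]
  }
  c(c0, c1)
}

#' Subject-specific linear predictor of a longitudinal outcome
#'
#' Evaluates \eqn{\eta_p(t) = x(t)'\beta_p + z(t)'b_p} for one declared
#' outcome; vectorized over \code{t}.
#'
#' @param params A [joint_model_params()] object.
#' @param b Stacked random-effects vector.
#' @param outcome Outcome label.
#' @param t Time(s) in years, non-negative.
#' @return Numeric vector of linear-predictor values.
#' @export
linear_predictor <- function(params, b, outcome, t) {
  stopifnot(all(t >= 0))
  cf <- eta_coefs(params, b, outcome)
  cf[1] + cf[2] * t
}

# association functional value f_j(t) for linear eta, vectorized over t
assoc_value <- function(at, params, b, t) {
  cf <- eta_coefs(params, b, at$outcome)
  switch(at$form,
         value = cf[1] + cf[2] * t,
         slope = rep(cf[2], length(t)),
         area  = cf[1] * t + cf[2] * t^2 / 2)
}

assoc_coef_at <- function(at, t) {
  if (is.function(at$coefficient)) at$coefficient(t)
  else rep(at$coefficient, length(t))
}

# log cause-specific hazard at times t (vectorized); t > 0 (or t = 0 handled
# by continuity upstream)
log_hazard_vec <- function(params, subject, cause_spec, t) {
  a <- cause_spec$shape; s <- cause_spec$scale
  lh <- log(a / s) + (a - 1) * log(t / s)
  if (length(cause_spec$baseline_coefficients))
    lh <- lh + sum(cause_spec$baseline_coefficients * subject$baseline_covariates)
  for (at in cause_spec$association)
    lh <- lh + assoc_coef_at(at, t) * assoc_value(at, params, subject$random_effects, t)
  lh
}

#' Cause-specific hazard for a subject
#'
#' \eqn{h_k(t) = h_{k0}(t)\exp(\gamma_k'w + \sum_j \alpha_{kj} f_{kj}(t))}
#' with Weibull baseline. At \eqn{t=0} the hazard is defined by continuity
#' (0 for shape > 1, \eqn{\exp(\cdot)/scale} for shape = 1) and is an error
#' for shape < 1 (unbounded).
#'
#' @inheritParams linear_predictor
#' @param subject A [subject_truth()] object.
#' @param cause Cause code in 1..K.
#' @param t Time(s) in years.
#' @return Non-negative hazard value(s).
#' @export
cause_specific_hazard <- function(params, subject, cause, t) {
  cs <- find_cause(params, cause)
  out <- numeric(length(t))
  zero <- t == 0
  if (any(zero)) {
    if (cs$shape < 1)
      stop_jmsched("hazard unbounded at t = 0 for Weibull shape < 1",
                   "jmsched_hazard_origin")
    out[zero] <- if (cs$shape > 1) 0 else {
      exp(log_hazard_zero_shape1(params, subject, cs))
    }
  }
  if (any(!zero)) out[!zero] <- exp(log_hazard_vec(params, subject, cs, t[!zero]))
  out
}

log_hazard_zero_shape1 <- function(params, subject, cs) {
  lh <- -log(cs$scale)
  if (length(cs$baseline_coefficients))
    lh <- lh + sum(cs$baseline_coefficients * subject$baseline_covariates)
  for (at in cs$association)
    lh <- lh + assoc_coef_at(at, 0) * assoc_value(at, params, subject$random_effects, 0)
  lh
}

find_cause <- function(params, cause) {
  for (cs in params$causes) if (cs$cause == cause) return(cs)
  stop_jmsched(sprintf("unknown cause %s", cause), "jmsched_unknown_cause")
}

# total hazard at times t (vectorized over t)
total_hazard_vec <- function(params, subject, t) {
  h <- numeric(length(t))
  for (cs in params$causes) h <- h + exp(log_hazard_vec(params, subject, cs, t))
  h
}

#' Cumulative overall hazard
#'
#' \eqn{H(t) = \sum_k \int_0^t h_k(u)\,du} by composite Gauss-Legendre
#' quadrature (15 nodes per panel, panels at most half a year wide).
#'
#' @inheritParams cause_specific_hazard
#' @return Non-negative cumulative hazard; \code{H(0) = 0}.
#' @export
cumulative_overall_hazard <- function(params, subject, t) {
  stopifnot(length(t) == 1L, t >= 0)
  if (t == 0) return(0)
  q <- panel_gl(0, t)
  sum(q$weights * total_hazard_vec(params, subject, q$nodes))
}

#' Overall survival function
#'
#' \eqn{S(t) = \exp(-H(t))}, the probability of remaining free of all K
#' events through time \code{t}.
#'
#' @inheritParams cumulative_overall_hazard
#' @return Probability in (0, 1]; \code{S(0) = 1}.
#' @export
overall_survival <- function(params, subject, t) {
  exp(-cumulative_overall_hazard(params, subject, t))
}

#' True conditional cumulative incidence over a window
#'
#' \eqn{[\int_t^s h_k(u) S(u)\,du] / S(t)}: the probability of a cause-k
#' event in \eqn{(t, s]} given event-free survival to \code{t}, computed from
#' the generative parameters by quadrature.
#'
#' @inheritParams cause_specific_hazard
#' @param t Window start (years).
#' @param s Window end (years), \code{s >= t}.
#' @return Probability in [0, 1]; 0 when \code{s == t}.
#' @export
true_conditional_cif <- function(params, subject, cause, t, s) {
  stopifnot(t >= 0, s >= t)
  if (s == t) return(0)
  cs <- find_cause(params, cause)
  St <- overall_survival(params, subject, t)
  if (St < 1e-300)
    stop_jmsched("S(t) underflow in conditional CIF", "jmsched_survival_underflow")
  # integrate h_k(u) exp(-(H(u) - H(t))) over (t, s]; the inner cumulative
  # hazard increment is built up panel-by-panel so each node's survival
  # factor is itself a panel-GL integral from the window start
  br <- panel_breaks(t, s, 0.5)
  rule <- gl_rule(15L)
  acc <- 0
  H_inc <- 0   # H(u) - H(t) at current panel start
  for (p in seq_len(length(br) - 1L)) {
    a <- br[p]; bnd <- br[p + 1L]
    w <- bnd - a
    nodes <- a + w * rule$x
    htot <- total_hazard_vec(params, subject, nodes)
    hk <- exp(log_hazard_vec(params, subject, cs, nodes))
    # cumulative hazard increment from panel start to each node (nested GL)
    Hin <- vapply(seq_along(nodes), function(j) {
      inner <- gl_rule(15L)
      nn <- a + (nodes[j] - a) * inner$x
      (nodes[j] - a) * sum(inner$w * total_hazard_vec(params, subject, nn))
    }, 0)
    acc <- acc + w * sum(rule$w * hk * exp(-(H_inc + Hin)))
    H_inc <- H_inc + w * sum(rule$w * htot)
  }
  min(max(acc, 0), 1)
}

# Fine-grid truth computation for one subject: hazards, cumulative overall
# hazard (trapezoid), survival, and cumulative cause-specific incidence
# A_k(t) = int_0^t h_k S du on a uniform grid. Used where the panel-GL
# scalar functions above would be called thousands of times (calibration,
# optimal-interruption search); a test checks agreement between the two.
subject_risk_grid <- function(params, subject, t_max, step = 0.01) {
  times <- seq(0, t_max, by = step)
  if (times[length(times)] < t_max) times <- c(times, t_max)
  nt <- length(times)
  K <- length(params$causes)
  h <- matrix(0, nt, K)
  for (k in seq_len(K)) {
    cs <- params$causes[[k]]
    h[-1, k] <- exp(log_hazard_vec(params, subject, cs, times[-1]))
    h[1, k] <- cause_specific_hazard(params, subject, cs$cause, 0)
  }
  htot <- rowSums(h)
  dt <- diff(times)
  H <- c(0, cumsum(dt * (htot[-nt] + htot[-1]) / 2))
  S <- exp(-H)
  A <- matrix(0, nt, K)
  for (k in seq_len(K)) {
    g <- h[, k] * S
    A[, k] <- c(0, cumsum(dt * (g[-nt] + g[-1]) / 2))
  }
  list(times = times, hazard = h, H = H, S = S, A = A)
}

# conditional window risk CIF_k(t, t+delta) for all grid t (vectorized),
# from a subject_risk_grid object; linear interpolation between grid points
grid_window_risk <- function(gr, cause, delta) {
  A_shift <- stats::approx(gr$times, gr$A[, cause], pmin(gr$times + delta,
                                                         max(gr$times)),
                           rule = 2)$y
  (A_shift - gr$A[, cause]) / gr$S
}
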
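#' Simulation configuration
#'
#' Study-design settings of the synthetic stable-CHF cohort: 381 training and
#' 50 test patients, quarterly training visits, administrative censoring at
#' 20 years, and the choice of generative scenario.
#'
#' @param n_train,n_test Cohort sizes.
#' @param maggic_mean,maggic_sd Gaussian parameters of the baseline MAGGIC
#'   score (assumed values; see methods vignette).
#' @param censor_time Administrative censoring horizon in years.
#' @param scenario \code{"well_specified"} or \code{"misspecified"}; the
#'   latter draws NT-proBNP residuals from a centered, variance-matched
#'   exponential and makes the troponin association with HF hospitalization
#'   increase over time.
#' @param training_visit_interval Spacing of training-arm visits in years.
#' @param max_followup_train Cap on training-arm visit times (defaults to the
#'   censoring horizon).
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_train = 381L, n_test = 50L,
                              maggic_mean = default_maggic()$mean,
                              maggic_sd = default_maggic()$sd,
                              censor_time = 20,
                              scenario = c("well_specified", "misspecified"),
                              training_visit_interval = 0.25,
                              max_followup_train = censor_time) {
  scenario <- match.arg(scenario)
  stopifnot(n_train >= 1L, n_test >= 1L, censor_time > 0,
            training_visit_interval > 0, maggic_sd >= 0)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 maggic_mean = maggic_mean, maggic_sd = maggic_sd,
                 censor_time = censor_time, scenario = scenario,
                 training_visit_interval = training_visit_interval,
                 max_followup_train = max_followup_train),
            class = "simulation_config")
}

#' Draw one subject's latent state
#'
#' Random effects \eqn{b \sim N(0, D)} and baseline MAGGIC score
#' \eqn{\sim N(\mu, \sigma^2)}; the event time is left unset until
#' [sample_event_time()].
#'
#' @param params A [joint_model_params()] object.
#' @param config A [simulation_config()] object.
#' @param subject_id Label for the new subject.
#' @return A [subject_truth()] object.
#' @export
draw_subject <- function(params, config, subject_id = "s1") {
  D <- params$re_covariance
  b <- if (all(D == 0)) rep(0, nrow(D)) else
    as.numeric(MASS::mvrnorm(1, mu = rep(0, nrow(D)), Sigma = D))
  maggic <- stats::rnorm(1, config$maggic_mean, config$maggic_sd)
  subject_truth(subject_id, b, maggic)
}

#' Sample the event time and cause for a subject
#'
#' Inverse-transform sampling of the overall event time: draw
#' \eqn{U \sim \mathrm{Unif}(0,1)}, solve \eqn{H(T^*) = -\log(1-U)} by
#' bracketing and bisection on the cumulative overall hazard, censor
#' administratively at the configured horizon, and otherwise assign the
#' cause by a trial with probabilities proportional to the cause-specific
#' hazards at \eqn{T^*}.
#'
#' @inheritParams draw_subject
#' @param subject A [subject_truth()] with random effects and covariates drawn.
#' @return The subject with \code{true_event_time} and \code{true_cause} set.
#' @export
sample_event_time <- function(params, subject, config) {
  U <- stats::runif(1)
  target <- -log1p(-U)
  H_cens <- cumulative_overall_hazard(params, subject, config$censor_time)
  if (H_cens <= target) {
    subject$true_event_time <- config$censor_time
    subject$true_cause <- 0L
    return(subject)
  }
  f <- function(t) cumulative_overall_hazard(params, subject, t) - target
  lo <- 1e-6; hi <- config$censor_time
  if (f(lo) > 0) {
    tstar <- lo
  } else {
    tstar <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }
  h <- vapply(params$causes,
              function(cs) exp(log_hazard_vec(params, subject, cs, tstar)), 0)
  if (!all(is.finite(h)) || sum(h) <= 0)
    stop_jmsched("degenerate cause-assignment hazards at sampled time",
                 "jmsched_cause_assignment")
  cause <- sample(vapply(params$causes, `[[`, 1L, "cause"), 1, prob = h / sum(h))
  subject$true_event_time <- tstar
  subject$true_cause <- as.integer(cause)
  subject
}

#' Observe noisy biomarker values at given visit times
#'
#' Adds measurement error to the subject-specific linear predictors. Under
#' the well-specified scenario errors are Gaussian for both outcomes; under
#' the misspecified scenario the NT-proBNP error is \eqn{\sigma(E - 1)} with
#' \eqn{E \sim \mathrm{Exp}(1)} (mean 0, variance \eqn{\sigma^2}, skewness 2).
#'
#' @inheritParams sample_event_time
#' @param visit_times Strictly increasing times, all before the subject's
#'   observed event/censoring time (later ones are dropped with a warning).
#' @return A data frame with columns \code{subject_id}, \code{outcome},
#'   \code{time_years}, \code{value} (long format).
#' @export
observe_biomarkers <- function(params, subject, visit_times, config) {
  stopifnot(!is.unsorted(visit_times, strictly = TRUE) || length(visit_times) <= 1L)
  if (!is.na(subject$true_event_time)) {
    keep <- visit_times < subject$true_event_time
    if (!all(keep)) {
      warning(sprintf("dropping %d visit(s) at or after the observed time for %s",
                      sum(!keep), subject$subject_id))
      visit_times <- visit_times[keep]
    }
  }
  if (!length(visit_times))
    return(data.frame(subject_id = character(), outcome = character(),
                      time_years = numeric(), value = numeric()))
  out <- lapply(params$longitudinal, function(spec) {
    eta <- linear_predictor(params, subject$random_effects, spec$outcome,
                            visit_times)
    n <- length(visit_times)
    eps <- if (config$scenario == "misspecified" && spec$outcome == "ntprobnp") {
      spec$residual_sd * (stats::rexp(n) - 1)
    } else {
      stats::rnorm(n, 0, spec$residual_sd)
    }
    data.frame(subject_id = subject$subject_id, outcome = spec$outcome,
               time_years = visit_times, value = eta + eps)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Training subjects receive quarterly visits from baseline until their
#' observed event/censoring time; test subjects receive latent truths plus
#' warm-up visits only (their later visits are produced by the scheduler).
#'
#' @inheritParams draw_subject
#' @param warmup_visits Warm-up visit times for the test arm.
#' @param seed Optional integer seed; when given, the dataset is reproducible.
#' @return A list with elements \code{train} (list of \code{longitudinal},
#'   \code{survival} data frames and \code{truths}), and \code{test} (list of
#'   \code{truths} and warm-up \code{longitudinal} records).
#' @export
generate_dataset <- function(params, config, warmup_visits = c(0, 0.25, 0.5),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_train + config$n_test
  ids <- sprintf("p%03d", seq_len(n))
  role <- rep(c("train", "test"), c(config$n_train, config$n_test))

  truths <- vector("list", n)
  long <- vector("list", n)
  surv <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- draw_subject(params, config, ids[i])
    subj <- sample_event_time(params, subj, config)
    truths[[i]] <- subj
    sv <- data.frame(subject_id = ids[i],
                     time_years = subj$true_event_time,
                     event_code = subj$true_cause)
    for (j in seq_along(params$baseline_covariate_names))
      sv[[params$baseline_covariate_names[j]]] <- subj$baseline_covariates[j]
    surv[[i]] <- sv
    vt <- if (role[i] == "train") {
      seq(0, min(subj$true_event_time, config$max_followup_train),
          by = config$training_visit_interval)
    } else {
      warmup_visits
    }
    vt <- vt[vt < subj$true_event_time]
    long[[i]] <- if (length(vt))
      observe_biomarkers(params, subj, vt, config)
    else
      data.frame(subject_id = character(), outcome = character(),
                 time_years = numeric(), value = numeric())
  }
  tr <- role == "train"
  list(
    train = list(longitudinal = do.call(rbind, long[tr]),
                 survival = do.call(rbind, surv[tr]),
                 truths = truths[tr]),
    test = list(truths = truths[!tr],
                longitudinal = do.call(rbind, long[!tr]),
                survival = do.call(rbind, surv[!tr]))
  )
}

#' Calibrate Weibull baseline scales to target event fractions
#'
#' Holds the per-cause Weibull shapes fixed and solves for the scales such
#' that the Monte-Carlo expected fraction of subjects experiencing each
#' cause over follow-up (to the censoring horizon) matches the targets.
#' Expectations are computed by averaging each drawn subject's true
#' cumulative incidence (quadrature, not resimulation), so the solver sees a
#' smooth deterministic function of the scales for a fixed set of subject
#' draws; the fixed point is found by multiplicative rate updates.
#'
#' @inheritParams draw_subject
#' @param target_event_fractions Numeric vector, one entry per cause, each in
#'   (0,1) and summing to less than 1 (e.g. \code{c(90, 14)/381}).
#' @param n_subjects Number of Monte-Carlo subject draws used for the
#'   expectation.
#' @param shapes Fixed Weibull shapes (default exponential).
#' @param tol Absolute tolerance on each cause's event fraction.
#' @param max_iter Maximum fixed-point iterations.
#' @param seed Optional seed for the subject draws.
#' @return List with \code{shape}, \code{scale}, achieved \code{fractions},
#'   and \code{iterations}.
#' @export
calibrate_weibull <- function(params, target_event_fractions, config,
                              n_subjects = 400L, shapes = NULL,
                              tol = 0.01, max_iter = 40L, seed = NULL) {
  K <- length(params$causes)
  stopifnot(length(target_event_fractions) == K,
            all(target_event_fractions > 0), sum(target_event_fractions) < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(shapes)) shapes <- vapply(params$causes, `[[`, 0, "shape")
  subjects <- lapply(seq_len(n_subjects), function(i)
    draw_subject(params, config, sprintf("cal%04d", i)))

  scales <- vapply(params$causes, `[[`, 0, "scale")
  horizon <- config$censor_time
  fr <- NULL
  for (it in seq_len(max_iter)) {
    cand <- params
    for (k in seq_len(K)) {
      cand$causes[[k]]$shape <- shapes[k]
      cand$causes[[k]]$scale <- scales[k]
    }
    cif <- matrix(0, n_subjects, K)
    for (i in seq_len(n_subjects)) {
      gr <- subject_risk_grid(cand, subjects[[i]], horizon, step = 0.05)
      cif[i, ] <- gr$A[length(gr$times), ]
    }
    fr <- colMeans(cif)
    if (all(abs(fr - target_event_fractions) <= tol)) {
      for (k in seq_len(K)) {
        params$causes[[k]]$shape <- shapes[k]
        params$causes[[k]]$scale <- scales[k]
      }
      return(list(shape = shapes, scale = scales, fractions = fr,
                  iterations = it, params = params))
    }
    # rate_k ~ scale_k^{-shape_k}: update rates multiplicatively toward the
    # target fractions (damped to stabilize the competing-risks coupling)
    ratio <- pmin(pmax(target_event_fractions / pmax(fr, 1e-8), 0.05), 20)
    scales <- scales / ratio^(0.8 / shapes)
  }
  stop_jmsched(sprintf(
    "Weibull calibration did not converge in %d iterations (last fractions %s)",
    max_iter, paste(signif(fr, 4), collapse = ", ")),
    "jmsched_calibration_failure")
}
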
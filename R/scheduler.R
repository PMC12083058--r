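# Visit-scheduling strategies. At every decision visit t the Delta-horizon
# risk pi(t, t+Delta) is estimated once; monitoring is interrupted when its
# point estimate reaches kappa, and otherwise the next visit is placed at
# t + u where u solves pi(t, t+u) = lambda on the shared-draw monotone risk
# curve (regular rule), on its upper 95% limit (conservative rule), at the
# minimum across endpoints (multi rule), or at a fixed interval.

#' Configuration of a scheduling strategy
#'
#' @param kind One of \code{"fixed"}, \code{"risk_based"},
#'   \code{"risk_based_conservative"}, \code{"risk_based_multi"}.
#' @param fixed_interval Visit spacing in years (fixed strategies).
#' @param lambda Cumulative-risk limit between consecutive visits
#'   (per cause for the multi rule).
#' @param kappa Interruption threshold on the Delta-horizon risk.
#' @param delta Prediction horizon (years) of the interruption rule.
#' @param u_max Upper cap on the next interval (per cause for multi).
#' @param warmup_visits Fixed early visit times with no risk predictions.
#' @param interrupt_cause Cause whose risk drives interruption.
#' @param min_interval Floor (years) on the adaptive interval; prevents
#'   degenerate zero-gap loops when the risk sits between lambda and kappa
#'   at tiny horizons.
#' @return An object of class \code{"strategy_config"}.
#' @export
strategy_config <- function(kind = c("fixed", "risk_based",
                                     "risk_based_conservative",
                                     "risk_based_multi"),
                            fixed_interval = 0.25, lambda = 0.01,
                            kappa = 0.10, delta = 1.0, u_max = 1.0,
                            warmup_visits = c(0, 0.25, 0.5),
                            interrupt_cause = 1L, min_interval = 0.05) {
  kind <- match.arg(kind)
  stopifnot(all(lambda > 0), all(lambda <= kappa), kappa < 1, delta > 0,
            all(u_max > 0), min_interval > 0,
            !is.unsorted(warmup_visits, strictly = TRUE),
            warmup_visits[1] == 0)
  if (kind == "fixed") stopifnot(fixed_interval > 0)
  structure(list(kind = kind, fixed_interval = fixed_interval,
                 lambda = lambda, kappa = kappa, delta = delta,
                 u_max = u_max, warmup_visits = warmup_visits,
                 interrupt_cause = as.integer(interrupt_cause),
                 min_interval = min_interval),
            class = "strategy_config")
}

# root of a nondecreasing curve on a grid by linear interpolation
invert_monotone_curve <- function(u_grid, risk, lambda, u_max, u_min) {
  if (risk[length(risk)] < lambda) return(u_max)
  if (risk[1] >= lambda) return(u_min)
  i <- which(risk >= lambda)[1]
  r0 <- risk[i - 1L]; r1 <- risk[i]
  u0 <- u_grid[i - 1L]; u1 <- u_grid[i]
  if (r1 <= r0) return(u1)
  u <- u0 + (lambda - r0) / (r1 - r0) * (u1 - u0)
  min(max(u, u_min), u_max)
}

#' Regular risk-based interval
#'
#' The interval \eqn{u \in (0, u_{max}]} at which the point estimate of the
#' shared-draw risk curve reaches \eqn{\lambda}; \eqn{u_{max}} when the risk
#' at the cap is still below \eqn{\lambda}, the minimum interval when the
#' risk already exceeds \eqn{\lambda} there.
#'
#' @param curve A \code{"risk_curve"} from [predict_cif_curve()], evaluated
#'   on horizons \code{t + u_grid}.
#' @param lambda Risk limit.
#' @param u_max Interval cap (years).
#' @param u_min Interval floor (years).
#' @return Interval in years.
#' @export
next_interval_risk_based <- function(curve, lambda, u_max, u_min = 0.05) {
  u_grid <- curve$s_grid - curve$t
  keep <- u_grid <= u_max + 1e-9
  invert_monotone_curve(u_grid[keep], curve$point[keep], lambda, u_max, u_min)
}

#' Conservative risk-based interval
#'
#' As [next_interval_risk_based()] but inverting the upper 97.5% posterior
#' quantile of the risk curve, so the interval is never longer than the
#' regular rule's for the same draws.
#'
#' @inheritParams next_interval_risk_based
#' @return Interval in years.
#' @export
next_interval_conservative <- function(curve, lambda, u_max, u_min = 0.05) {
  u_grid <- curve$s_grid - curve$t
  keep <- u_grid <= u_max + 1e-9
  invert_monotone_curve(u_grid[keep], curve$upper95[keep], lambda, u_max, u_min)
}

#' Multi-endpoint interval: minimum of per-cause regular rules
#'
#' @param curves List of \code{"risk_curve"} objects, one per cause.
#' @param lambdas,u_maxes Per-cause limits and caps (recycled if scalar).
#' @param u_min Interval floor.
#' @return Interval in years.
#' @export
next_interval_multi <- function(curves, lambdas, u_maxes, u_min = 0.05) {
  K <- length(curves)
  lambdas <- rep_len(lambdas, K)
  u_maxes <- rep_len(u_maxes, K)
  min(vapply(seq_len(K), function(k)
    next_interval_risk_based(curves[[k]], lambdas[k], u_maxes[k], u_min), 0))
}

#' Run one scheduling strategy on one simulated test patient
#'
#' Warm-up visits are observed first with no predictions; thereafter each
#' visit observes the biomarkers, tests the interruption rule on the
#' Delta-horizon risk, and — if monitoring continues — schedules the next
#' visit. Monitoring ends at interruption, at the patient's true event, or
#' at administrative censoring.
#'
#' @param subject A [subject_truth()] with sampled event time (the
#'   generative truth used to create observations and truncate follow-up).
#' @param params Generative [joint_model_params()] used to simulate the
#'   observed biomarker values.
#' @param posterior A \code{posterior_draws} object (the fitted model used
#'   for predictions).
#' @param strategy A [strategy_config()].
#' @param sim_config A [simulation_config()] (observation-noise scenario).
#' @param mc An [mc_control()] prediction budget.
#' @return An object of class \code{"schedule_trace"}.
#' @export
run_strategy <- function(subject, params, posterior, strategy, sim_config,
                         mc = mc_control()) {
  end_time <- subject$true_event_time
  cache <- if (inherits(posterior, "posterior_draws"))
    draw_cache(posterior, mc$n_theta) else posterior
  k_int <- strategy$interrupt_cause

  warm <- strategy$warmup_visits[strategy$warmup_visits < end_time]
  visits <- warm
  records <- if (length(warm))
    observe_biomarkers(params, subject, warm, sim_config)
  else
    data.frame(subject_id = character(), outcome = character(),
               time_years = numeric(), value = numeric())
  risk_log <- data.frame(time = numeric(), point = numeric(),
                         lower95 = numeric(), upper95 = numeric(),
                         next_interval = numeric())
  interrupted <- FALSE
  interruption_time <- NA_real_

  if (length(warm) < length(strategy$warmup_visits)) {
    termination <- if (subject$true_cause > 0) "event" else "censored"
    return(structure(list(subject_id = subject$subject_id,
                          visit_times = visits, risk = risk_log,
                          interrupted = FALSE,
                          interruption_time = NA_real_,
                          termination = termination,
                          event_code_at_termination = subject$true_cause,
                          records = records),
                     class = "schedule_trace"))
  }

  t <- warm[length(warm)]
  repeat {
    hist <- patient_history(subject$subject_id,
                            records[records$time_years <= t + 1e-9, ],
                            subject$baseline_covariates, t)
    horizon <- max(strategy$delta, max(strategy$u_max))
    s_grid <- t + sort(unique(c(seq(strategy$min_interval, horizon,
                                    by = 0.025), strategy$delta, horizon)))
    curve <- predict_cif_curve(cache, hist, k_int, s_grid, mc)
    j_delta <- match(TRUE, abs(s_grid - (t + strategy$delta)) < 1e-9)
    pi_delta <- curve$point[j_delta]

    if (pi_delta >= strategy$kappa) {
      interrupted <- TRUE
      interruption_time <- t
      risk_log <- rbind(risk_log, data.frame(
        time = t, point = pi_delta, lower95 = curve$lower95[j_delta],
        upper95 = curve$upper95[j_delta], next_interval = NA_real_))
      break
    }
    u <- switch(strategy$kind,
      fixed = strategy$fixed_interval,
      risk_based = next_interval_risk_based(curve, strategy$lambda,
                                            strategy$u_max,
                                            strategy$min_interval),
      risk_based_conservative = next_interval_conservative(
        curve, strategy$lambda, strategy$u_max, strategy$min_interval),
      risk_based_multi = {
        curves <- lapply(seq_len(cache$K), function(k)
          if (k == k_int) curve
          else predict_cif_curve(cache, hist, k, s_grid, mc))
        next_interval_multi(curves, strategy$lambda, strategy$u_max,
                            strategy$min_interval)
      })
    risk_log <- rbind(risk_log, data.frame(
      time = t, point = pi_delta, lower95 = curve$lower95[j_delta],
      upper95 = curve$upper95[j_delta], next_interval = u))
    t_next <- t + u
    if (t_next >= end_time || t_next > sim_config$censor_time - 1e-9) break
    obs <- observe_biomarkers(params, subject, t_next, sim_config)
    records <- rbind(records, obs)
    visits <- c(visits, t_next)
    t <- t_next
  }
  termination <- if (interrupted) "interrupted"
  else if (subject$true_cause > 0) "event" else "censored"
  structure(list(subject_id = subject$subject_id, visit_times = visits,
                 risk = risk_log, interrupted = interrupted,
                 interruption_time = interruption_time,
                 termination = termination,
                 event_code_at_termination =
                   if (interrupted) NA_integer_ else subject$true_cause,
                 records = records),
            class = "schedule_trace")
}
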
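# The three performance criteria and the simulation-study driver: per
# iteration, a fresh cohort is generated, the joint model is refitted on the
# training arm, all strategies are run on the same 50 test patients with the
# same posterior (paired design), and measurement burden, interruption
# accuracy and interruption-timing RMSE are scored against the generative
# truth.

#' Optimal interruption time of one subject under the generative truth
#'
#' The earliest \eqn{t} at which the subject's true conditional cumulative
#' incidence of the monitored cause over \eqn{(t, t+\Delta]} reaches
#' \eqn{\kappa}, found as the first up-crossing on a fine grid with linear
#' interpolation. \code{NA} if the threshold is never reached before the
#' subject's event/censoring time.
#'
#' @param subject A [subject_truth()] with sampled event time.
#' @param params Generative [joint_model_params()].
#' @param kappa Interruption threshold.
#' @param delta Window length in years.
#' @param cause Monitored cause.
#' @param step Grid resolution in years.
#' @return Time in years, or \code{NA_real_}.
#' @export
optimal_interruption_time <- function(subject, params, kappa = 0.10,
                                      delta = 1.0, cause = 1L, step = 0.01) {
  horizon <- subject$true_event_time
  if (is.na(horizon)) stop_jmsched("subject has no sampled event time",
                                   "jmsched_truth_missing")
  gr <- subject_risk_grid(params, subject, horizon + delta, step = step)
  risk <- grid_window_risk(gr, cause, delta)
  sel <- gr$times < horizon
  times <- gr$times[sel]; risk <- risk[sel]
  above <- risk >= kappa
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(0)
  r0 <- risk[i - 1L]; r1 <- risk[i]
  times[i - 1L] + (kappa - r0) / (r1 - r0) * (times[i] - times[i - 1L])
}

#' Score one strategy's traces against the generative truth
#'
#' In-need patients are those whose optimal interruption time falls before
#' their endpoint; accuracy is the percentage of them interrupted before the
#' endpoint. The measurement rate counts post-warm-up visits per year of
#' post-warm-up monitoring, and the RMSE compares realized and optimal
#' interruption times among patients with both.
#'
#' @param traces List of \code{"schedule_trace"} objects, one per subject.
#' @param truths Matching list of [subject_truth()] objects.
#' @param params Generative [joint_model_params()].
#' @param kappa,delta,cause Interruption-rule settings used for the truth.
#' @param warmup_end End of the warm-up period in years.
#' @param t_opt Optional precomputed vector of optimal interruption times.
#' @return A one-row data frame of class \code{"strategy_metrics"}.
#' @export
score_strategy <- function(traces, truths, params, kappa = 0.10, delta = 1.0,
                           cause = 1L, warmup_end = 0.5, t_opt = NULL) {
  stopifnot(length(traces) == length(truths))
  n <- length(traces)
  if (is.null(t_opt))
    t_opt <- vapply(truths, optimal_interruption_time, 0, params = params,
                    kappa = kappa, delta = delta, cause = cause)
  T_end <- vapply(truths, `[[`, 0, "true_event_time")
  interrupted <- vapply(traces, `[[`, TRUE, "interrupted")
  t_int <- vapply(traces, `[[`, 0, "interruption_time")
  n_visits <- vapply(traces, function(tr) length(tr$visit_times), 0L)
  n_post <- vapply(traces, function(tr)
    sum(tr$visit_times > warmup_end + 1e-9), 0L)
  mon_end <- ifelse(interrupted, t_int, T_end)
  post_years <- pmax(mon_end - warmup_end, 0)

  in_need <- !is.na(t_opt) & t_opt < T_end
  hit <- in_need & interrupted & (t_int < T_end)
  accuracy <- if (sum(in_need) == 0) NA_real_
  else 100 * sum(hit) / sum(in_need)
  both <- interrupted & !is.na(t_opt)
  rmse <- if (any(both)) sqrt(mean((t_int[both] - t_opt[both])^2))
  else NA_real_
  out <- data.frame(
    measurements_per_patient = mean(n_visits),
    measurements_per_patient_year =
      if (sum(post_years) > 0) sum(n_post) / sum(post_years) else NA_real_,
    accuracy_pct = accuracy,
    rmse_interruption = rmse,
    n_in_need = sum(in_need),
    n_interrupted = sum(interrupted),
    n_false_alarm = sum(interrupted & is.na(t_opt)))
  class(out) <- c("strategy_metrics", class(out))
  out
}

#' Default strategy set of the simulation study
#'
#' Annual, semi-annual and quarterly fixed schedules plus the regular and
#' conservative risk-based strategies, all sharing the interruption rule.
#'
#' @param lambda,kappa,delta,u_max,warmup_visits Shared thresholds.
#' @return Named list of [strategy_config()] objects.
#' @export
default_strategies <- function(lambda = 0.01, kappa = 0.10, delta = 1.0,
                               u_max = 1.0, warmup_visits = c(0, 0.25, 0.5)) {
  list(
    annual = strategy_config("fixed", fixed_interval = 1.0, lambda = lambda,
                             kappa = kappa, delta = delta, u_max = u_max,
                             warmup_visits = warmup_visits),
    semiannual = strategy_config("fixed", fixed_interval = 0.5,
                                 lambda = lambda, kappa = kappa,
                                 delta = delta, u_max = u_max,
                                 warmup_visits = warmup_visits),
    quarterly = strategy_config("fixed", fixed_interval = 0.25,
                                lambda = lambda, kappa = kappa,
                                delta = delta, u_max = u_max,
                                warmup_visits = warmup_visits),
    risk_based = strategy_config("risk_based", lambda = lambda,
                                 kappa = kappa, delta = delta, u_max = u_max,
                                 warmup_visits = warmup_visits),
    risk_based_conservative = strategy_config("risk_based_conservative",
                                              lambda = lambda, kappa = kappa,
                                              delta = delta, u_max = u_max,
                                              warmup_visits = warmup_visits))
}

#' Configuration of the full simulation study
#'
#' @param n_iterations Number of simulate-fit-schedule-score iterations.
#' @param sim A [simulation_config()].
#' @param params Generative [joint_model_params()]; defaults to the shipped
#'   calibrated parameter set for the configured scenario.
#' @param strategies Named list of [strategy_config()] objects.
#' @param fit_method \code{"laplace"} (fast) or \code{"mcmc"}.
#' @param fit_args Extra arguments passed to [fit_joint_model()].
#' @param mc An [mc_control()] prediction budget.
#' @param master_seed Integer seed from which per-iteration seeds derive.
#' @param kappa,delta,cause Interruption/truth settings.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(n_iterations = 10L, sim = simulation_config(),
                         params = NULL,
                         strategies = default_strategies(),
                         fit_method = c("laplace", "mcmc"),
                         fit_args = list(), mc = mc_control(),
                         master_seed = 1L, kappa = 0.10, delta = 1.0,
                         cause = 1L) {
  fit_method <- match.arg(fit_method)
  if (is.null(params)) params <- default_params(scenario = sim$scenario)
  stopifnot(n_iterations >= 1L)
  structure(list(n_iterations = as.integer(n_iterations), sim = sim,
                 params = params, strategies = strategies,
                 fit_method = fit_method, fit_args = fit_args, mc = mc,
                 master_seed = as.integer(master_seed), kappa = kappa,
                 delta = delta, cause = as.integer(cause)),
            class = "study_config")
}

#' Run the simulation study comparing scheduling strategies
#'
#' Each iteration generates a fresh cohort from the generative truth, fits
#' the (always well-specified-form) joint model on the training arm, runs
#' every strategy on the same test patients with the same posterior, and
#' scores the three criteria. Aggregates are medians and interquartile
#' ranges across iterations.
#'
#' @param config A [study_config()].
#' @param progress Print per-iteration progress.
#' @return A list of class \code{"study_result"} with \code{per_iteration}
#'   and \code{aggregate} data frames, iteration seeds, and the config.
#' @export
run_study <- function(config, progress = FALSE) {
  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_iterations)
  warm <- config$strategies[[1]]$warmup_visits
  warm_end <- warm[length(warm)]
  rows <- list()
  failed <- 0L
  for (it in seq_len(config$n_iterations)) {
    res <- tryCatch(
      run_study_iteration(config, seeds[it], warm, warm_end),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("iteration %d failed: %s", it, conditionMessage(res)))
      failed <- failed + 1L
      next
    }
    res$iteration <- it
    rows[[length(rows) + 1L]] <- res
    if (progress)
      message(sprintf("iteration %d/%d done", it, config$n_iterations))
  }
  if (!length(rows))
    stop_jmsched("all study iterations failed", "jmsched_study_failure")
  per_iter <- do.call(rbind, rows)
  metrics <- c("measurements_per_patient", "measurements_per_patient_year",
               "accuracy_pct", "rmse_interruption")
  agg <- do.call(rbind, lapply(split(per_iter, per_iter$strategy),
                               function(d) {
    out <- data.frame(strategy = d$strategy[1])
    for (m in metrics) {
      vals <- d[[m]][!is.na(d[[m]])]
      qs <- if (length(vals)) stats::quantile(vals, c(0.25, 0.5, 0.75),
                                              names = FALSE)
      else rep(NA_real_, 3)
      out[[paste0(m, "_median")]] <- qs[2]
      out[[paste0(m, "_q25")]] <- qs[1]
      out[[paste0(m, "_q75")]] <- qs[3]
    }
    out
  }))
  rownames(agg) <- NULL
  structure(list(per_iteration = per_iter, aggregate = agg,
                 scenario = config$sim$scenario, seeds = seeds,
                 n_failed = failed, config = config),
            class = "study_result")
}

run_study_iteration <- function(config, seed, warm, warm_end) {
  ds <- generate_dataset(config$params, config$sim, warmup_visits = warm,
                         seed = seed)
  fit <- do.call(fit_joint_model, c(list(
    longitudinal = ds$train$longitudinal, survival = ds$train$survival,
    outcomes = vapply(config$params$longitudinal, `[[`, "", "outcome"),
    covariate_names = config$params$baseline_covariate_names,
    n_causes = length(config$params$causes),
    method = config$fit_method), config$fit_args))
  truths <- ds$test$truths
  t_opt <- vapply(truths, optimal_interruption_time, 0,
                  params = config$params, kappa = config$kappa,
                  delta = config$delta, cause = config$cause)
  cache <- draw_cache(fit, config$mc$n_theta)
  out <- lapply(names(config$strategies), function(nm) {
    traces <- lapply(truths, run_strategy, params = config$params,
                     posterior = cache, strategy = config$strategies[[nm]],
                     sim_config = config$sim, mc = config$mc)
    sc <- score_strategy(traces, truths, config$params,
                         kappa = config$kappa, delta = config$delta,
                         cause = config$cause, warmup_end = warm_end,
                         t_opt = t_opt)
    sc$strategy <- nm
    sc
  })
  do.call(rbind, out)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Simulation study (%s): %d iterations (%d failed)\n",
              x$scenario, x$config$n_iterations, x$n_failed))
  print(x$aggregate, digits = 3)
  invisible(x)
}
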
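# Monte-Carlo dynamic prediction of the conditional cumulative incidence
# pi_k(t, s): for each retained posterior draw of theta, random effects are
# drawn from their conditional posterior given the biomarker history AND
# event-free survival to t (Metropolis-Hastings in a whitened space, with
# the closed-form longitudinal-only Gaussian conditional as the proposal
# frame), and the window risk is integrated by quadrature. All computations
# are vectorized across draws so the scheduler can afford a prediction at
# every visit.

#' Monte-Carlo budget for dynamic predictions
#'
#' @param n_theta Number of posterior draws of the model parameters used per
#'   prediction (thinned from the fit).
#' @param n_b Number of conditional random-effects draws per parameter draw.
#' @param mh_steps Metropolis-Hastings steps of the random-effects sampler.
#' @param surv_nodes Gauss-Legendre nodes for the survival factor S(t | b).
#' @param grid_step Spacing (years) of the integration grid for window risks.
#' @return A list of class \code{"mc_control"}.
#' @export
mc_control <- function(n_theta = 200L, n_b = 5L, mh_steps = 50L,
                       surv_nodes = 25L, grid_step = 0.02) {
  stopifnot(n_theta >= 1L, n_b >= 1L, mh_steps >= 1L)
  structure(list(n_theta = as.integer(n_theta), n_b = as.integer(n_b),
                 mh_steps = as.integer(mh_steps),
                 surv_nodes = as.integer(surv_nodes), grid_step = grid_step),
            class = "mc_control")
}

#' Longitudinal history of one patient up to a prediction time
#'
#' @param subject_id Label.
#' @param records Long-format data frame (\code{outcome}, \code{time_years},
#'   \code{value}) with all times at most \code{t}.
#' @param baseline_covariates Named or plain numeric vector (MAGGIC score).
#' @param t History time in years: the patient is known event-free at t.
#' @return An object of class \code{"patient_history"}.
#' @export
patient_history <- function(subject_id, records, baseline_covariates, t) {
  stopifnot(t >= 0)
  if (nrow(records) && any(records$time_years > t + 1e-9))
    stop_jmsched("history records must not be later than t", "jmsched_history")
  structure(list(subject_id = subject_id, records = records,
                 baseline_covariates = as.numeric(baseline_covariates),
                 t = t),
            class = "patient_history")
}

# thinned natural-scale parameter arrays for M posterior draws
draw_cache <- function(posterior, n_theta) {
  M_avail <- nrow(posterior$draws)
  idx <- if (n_theta >= M_avail) seq_len(M_avail)
  else round(seq(1, M_avail, length.out = n_theta))
  M <- length(idx)
  layout <- posterior$layout
  P <- layout$P; K <- layout$K; q <- layout$q; nw <- layout$nw
  beta <- array(0, c(M, P, 2))
  sigma <- matrix(0, M, P)
  Darr <- array(0, c(q, q, M))
  gamma <- array(0, c(M, K, nw))
  alpha <- array(0, c(M, K, P))
  shape <- matrix(0, M, K)
  log_rate <- matrix(0, M, K)
  for (m in seq_len(M)) {
    tl <- unpack_theta(posterior$draws[idx[m], ], layout)
    beta[m, , ] <- tl$beta
    sigma[m, ] <- tl$sigma
    Darr[, , m] <- tl$D
    gamma[m, , ] <- tl$gamma
    alpha[m, , ] <- tl$alpha
    shape[m, ] <- tl$shape
    log_rate[m, ] <- tl$log_rate
  }
  list(M = M, P = P, K = K, q = q, beta = beta, sigma = sigma, D = Darr,
       gamma = gamma, alpha = alpha, shape = shape, log_rate = log_rate,
       w_center = posterior$dat_meta$w_center,
       m_center = posterior$dat_meta$m_center,
       outcomes = posterior$dat_meta$outcomes)
}

# per-outcome sufficient statistics of a history
history_suff <- function(history, outcomes) {
  lapply(outcomes, function(o) {
    sel <- history$records$outcome == o
    tt <- history$records$time_years[sel]
    y <- history$records$value[sel]
    list(n = length(y), St = sum(tt), Stt = sum(tt^2),
         Sy = sum(y), Syt = sum(y * tt))
  })
}

# Gaussian longitudinal-only conditional of b per draw: list of mean matrix
# Mu (M x q) and arrays C (cov), CL (lower Cholesky of C)
long_conditional <- function(cache, suff) {
  M <- cache$M; q <- cache$q; P <- cache$P
  Mu <- matrix(0, M, q)
  CL <- array(0, c(q, q, M))
  Carr <- array(0, c(q, q, M))
  for (m in seq_len(M)) {
    Prec <- solve(cache$D[, , m])
    rhs <- numeric(q)
    for (p in seq_len(P)) {
      s <- suff[[p]]
      if (s$n == 0) next
      i0 <- 2L * p - 1L; i1 <- 2L * p
      sig2 <- cache$sigma[m, p]^2
      Mp <- matrix(c(s$n, s$St, s$St, s$Stt), 2, 2) / sig2
      Prec[c(i0, i1), c(i0, i1)] <- Prec[c(i0, i1), c(i0, i1)] + Mp
      b0 <- cache$beta[m, p, 1]; b1 <- cache$beta[m, p, 2]
      rhs[i0] <- (s$Sy - b0 * s$n - b1 * s$St) / sig2
      rhs[i1] <- (s$Syt - b0 * s$St - b1 * s$Stt) / sig2
    }
    Cm <- solve(Prec)
    Cm <- (Cm + t(Cm)) / 2
    Mu[m, ] <- drop(Cm %*% rhs)
    Carr[, , m] <- Cm
    CL[, , m] <- t(chol(Cm))
  }
  list(Mu = Mu, C = Carr, CL = CL)
}

# log S(t | b) for all draws: B is (M x q); returns M-vector
log_surv_vec <- function(cache, B, w, t, n_nodes = 25L) {
  if (t <= 0) return(numeric(nrow(B)))
  rule <- gl_rule(n_nodes)
  u <- t * rule$x
  wts <- t * rule$w
  M <- nrow(B)
  out <- numeric(M)
  wc <- w - cache$w_center
  for (k in seq_len(cache$K)) {
    a <- cache$shape[, k]
    gterm <- if (length(wc))
      drop(matrix(cache$gamma[, k, ], nrow = M) %*% wc) else 0
    ex <- cache$log_rate[, k] + log(a) + gterm
    ex <- matrix(ex, M, n_nodes) + outer(a - 1, log(u))
    for (p in seq_len(cache$P)) {
      c0 <- cache$beta[, p, 1] + B[, 2L * p - 1L] - cache$m_center[p]
      c1 <- cache$beta[, p, 2] + B[, 2L * p]
      ex <- ex + cache$alpha[, k, p] * (matrix(c0, M, n_nodes) + outer(c1, u))
    }
    out <- out - drop(exp(ex) %*% wts)
  }
  out
}

#' Draw conditional random effects given history and survival to t
#'
#' Samples from \eqn{p(b \mid \tilde Y(t), T^* > t; \theta)} for each cached
#' parameter draw by Metropolis-Hastings. The chain runs in the whitened
#' coordinates of the closed-form longitudinal-only Gaussian conditional
#' (which is the exact target when all associations are zero), so the
#' survival factor is the only non-Gaussian term.
#'
#' @param cache Internal draw cache (or a \code{posterior_draws} object).
#' @param history A [patient_history()] object.
#' @param mc An [mc_control()] budget.
#' @return List with \code{pairs} (matrix of stacked b draws,
#'   \code{n_theta * n_b} rows), \code{theta_index}, and the mean MH
#'   \code{acceptance} rate.
#' @export
sample_conditional_random_effects <- function(cache, history,
                                              mc = mc_control()) {
  if (inherits(cache, "posterior_draws")) cache <- draw_cache(cache, mc$n_theta)
  suff <- history_suff(history, cache$outcomes)
  cond <- long_conditional(cache, suff)
  M <- cache$M; q <- cache$q
  t <- history$t
  w <- history$baseline_covariates

  # b = mu + L v per draw, vectorized over draws via the q^2 scalar slices
  CLd <- lapply(seq_len(q), function(i)
    lapply(seq_len(i), function(j) cond$CL[i, j, ]))
  b_from_v <- function(V) {
    B <- cond$Mu
    for (i in seq_len(q)) for (j in seq_len(i))
      B[, i] <- B[, i] + CLd[[i]][[j]] * V[, j]
    B
  }
  V <- matrix(0, M, q)             # start at the Gaussian conditional mean
  B <- b_from_v(V)
  ls <- log_surv_vec(cache, B, w, t, mc$surv_nodes)
  lp <- -0.5 * rowSums(V^2) + ls
  prop_sd <- 2.38 / sqrt(q)
  keep_at <- unique(pmax(1L, round(seq_len(mc$n_b) * mc$mh_steps / mc$n_b)))
  pairs <- vector("list", length(keep_at))
  acc <- 0
  ki <- 0L
  for (step in seq_len(mc$mh_steps)) {
    Vp <- V + prop_sd * matrix(stats::rnorm(M * q), M, q)
    Bp <- b_from_v(Vp)
    lsp <- log_surv_vec(cache, Bp, w, t, mc$surv_nodes)
    lpp <- -0.5 * rowSums(Vp^2) + lsp
    a <- lpp - lp
    u <- log(stats::runif(M))
    take <- is.finite(a) & (u < a)
    if (any(take)) {
      V[take, ] <- Vp[take, , drop = FALSE]
      B[take, ] <- Bp[take, , drop = FALSE]
      lp[take] <- lpp[take]
    }
    acc <- acc + mean(take)
    if (ki < length(keep_at) && step == keep_at[ki + 1L]) {
      ki <- ki + 1L
      pairs[[ki]] <- B
    }
  }
  acc <- acc / mc$mh_steps
  if (acc == 0 && mc$mh_steps >= 10L)
    stop_jmsched("random-effects sampler accepted no proposals",
                 "jmsched_b_sampler")
  pairs <- do.call(rbind, pairs)
  list(pairs = pairs, theta_index = rep(seq_len(M), times = length(keep_at)),
       acceptance = acc, conditional = cond)
}

# window-risk curves for all (theta, b) pairs on a common grid, by
# cumulative trapezoidal integration of h_k exp(-(H(u) - H(t)))
pair_risk_curves <- function(cache, pairs, theta_index, w, t, s_grid, cause,
                             grid_step = 0.02) {
  s_max <- max(s_grid)
  grid <- sort(unique(round(c(t, s_grid, seq(t, s_max, by = grid_step)), 9)))
  G <- length(grid)
  nb <- nrow(pairs)
  u <- pmax(grid, 1e-12)
  wc <- w - cache$w_center
  M <- cache$M
  lam <- vector("list", cache$K)
  for (k in seq_len(cache$K)) {
    a <- cache$shape[theta_index, k]
    gterm <- if (length(wc))
      drop(matrix(cache$gamma[, k, ], nrow = M) %*% wc)[theta_index] else 0
    ex <- cache$log_rate[theta_index, k] + log(a) + gterm
    ex <- matrix(ex, nb, G) + outer(a - 1, log(u))
    for (p in seq_len(cache$P)) {
      c0 <- cache$beta[theta_index, p, 1] + pairs[, 2L * p - 1L] -
        cache$m_center[p]
      c1 <- cache$beta[theta_index, p, 2] + pairs[, 2L * p]
      ex <- ex + cache$alpha[theta_index, k, p] *
        (matrix(c0, nb, G) + outer(c1, grid))
    }
    lam[[k]] <- exp(ex)
  }
  htot <- Reduce(`+`, lam)
  dt <- diff(grid)
  # cumulative H(u) - H(t) along each row (column-sweep cumulation)
  row_cumtrapz <- function(Y) {
    inc <- sweep((Y[, -G, drop = FALSE] + Y[, -1L, drop = FALSE]) / 2, 2,
                 dt, `*`)
    out <- matrix(0, nb, G)
    for (g in 2:G) out[, g] <- out[, g - 1L] + inc[, g - 1L]
    out
  }
  Hinc <- row_cumtrapz(htot)
  cum <- row_cumtrapz(lam[[cause]] * exp(-Hinc))
  pi_pairs <- cum[, match(round(s_grid, 9), grid), drop = FALSE]
  pi_pairs[pi_pairs < 0] <- 0
  pi_pairs[pi_pairs > 1] <- 1
  pi_pairs
}

#' Predict the conditional cumulative incidence over a horizon grid
#'
#' Estimates \eqn{\pi_k(t, s)} for every \code{s} in \code{s_grid}, sharing
#' one set of \eqn{(\theta, b)} draws across the grid so that every draw's
#' curve — and hence the point estimate — is nondecreasing in \code{s} by
#' construction.
#'
#' @param posterior A \code{posterior_draws} object.
#' @param history A [patient_history()] object.
#' @param cause Cause code of interest.
#' @param s_grid Strictly increasing horizons, all greater than the history
#'   time.
#' @param mc An [mc_control()] budget.
#' @return An object of class \code{"risk_curve"}: per-\eqn{\theta} draw
#'   matrix of risks, point estimates, 95% interval curves, and the pooled
#'   pair-level draws.
#' @export
predict_cif_curve <- function(posterior, history, cause,
                              s_grid, mc = mc_control()) {
  t <- history$t
  stopifnot(all(s_grid > t), !is.unsorted(s_grid, strictly = TRUE))
  cache <- if (inherits(posterior, "posterior_draws"))
    draw_cache(posterior, mc$n_theta) else posterior
  bs <- sample_conditional_random_effects(cache, history, mc)
  pi_pairs <- pair_risk_curves(cache, bs$pairs, bs$theta_index,
                               history$baseline_covariates, t, s_grid, cause,
                               mc$grid_step)
  # within-theta average -> draws indexed by theta
  M <- cache$M
  theta_draws <- rowsum(pi_pairs, bs$theta_index) /
    as.vector(table(bs$theta_index))
  point <- colMeans(theta_draws)
  lower95 <- apply(pi_pairs, 2, stats::quantile, 0.025, names = FALSE)
  upper95 <- apply(pi_pairs, 2, stats::quantile, 0.975, names = FALSE)
  structure(list(cause = cause, t = t, s_grid = s_grid,
                 theta_draws = theta_draws, pair_draws = pi_pairs,
                 point = point, lower95 = lower95, upper95 = upper95,
                 acceptance = bs$acceptance),
            class = "risk_curve")
}

#' Predict the conditional cumulative incidence for one window
#'
#' @inheritParams predict_cif_curve
#' @param s Horizon time, \code{s > t}.
#' @return An object of class \code{"risk_prediction"} with per-\eqn{\theta}
#'   draws, the point estimate (grand mean) and 95% interval.
#' @export
predict_cif <- function(posterior, history, cause, s, mc = mc_control()) {
  curve <- predict_cif_curve(posterior, history, cause, s_grid = s, mc = mc)
  structure(list(cause = cause, window = c(history$t, s),
                 draws = drop(curve$theta_draws),
                 point_estimate = curve$point[1L],
                 lower95 = curve$lower95[1L], upper95 = curve$upper95[1L],
                 acceptance = curve$acceptance),
            class = "risk_prediction")
}

#' Degenerate posterior concentrated on one parameter set
#'
#' Wraps known generative parameters as a single-draw posterior so that the
#' Monte-Carlo predictor can be run with the truth plugged in (used for
#' self-consistency checks and by the simulation study's oracle analyses).
#'
#' @param params A [joint_model_params()] object.
#' @param n_draws Number of identical draws to expose.
#' @return A \code{posterior_draws} object.
#' @export
posterior_from_params <- function(params, n_draws = 1L) {
  P <- length(params$longitudinal)
  K <- length(params$causes)
  nw <- length(params$baseline_covariate_names)
  layout <- theta_layout(P, K, nw)
  th <- numeric(layout$npar)
  names(th) <- layout$names
  for (p in seq_len(P)) {
    spec <- params$longitudinal[[p]]
    th[paste0("beta", p, "_i")] <- spec$beta[1]
    th[paste0("beta", p, "_s")] <- spec$beta[2]
    th[paste0("log_sigma", p)] <- log(max(spec$residual_sd, 1e-8))
  }
  L <- t(chol(params$re_covariance + diag(1e-10, nrow(params$re_covariance))))
  for (j in seq_len(layout$q)) {
    th[sprintf("L%d%d", j, j)] <- log(L[j, j])
    if (j < layout$q) for (i in (j + 1L):layout$q)
      th[sprintf("L%d%d", i, j)] <- L[i, j]
  }
  outcome_names <- vapply(params$longitudinal, `[[`, "", "outcome")
  alpha_of <- function(cs) {
    out <- numeric(P)
    for (at in cs$association) {
      if (at$form != "value")
        stop_jmsched("only value-form associations can form a fitted posterior",
                     "jmsched_spec_error")
      if (is.function(at$coefficient))
        stop_jmsched("time-varying associations cannot form a fitted posterior",
                     "jmsched_spec_error")
      out[match(at$outcome, outcome_names)] <- at$coefficient
    }
    out
  }
  g1 <- params$causes[[1]]$baseline_coefficients
  if (nw > 0) th[paste0("gamma1_", seq_len(nw))] <- g1
  a1 <- alpha_of(params$causes[[1]])
  th[paste0("alpha1_", seq_len(P))] <- a1
  if (K > 1) for (k in 2:K) {
    if (nw > 0) th[paste0("gamma_off", k, "_", seq_len(nw))] <-
      params$causes[[k]]$baseline_coefficients - g1
    th[paste0("alpha_off", k, "_", seq_len(P))] <- alpha_of(params$causes[[k]]) - a1
  }
  for (k in seq_len(K)) {
    cs <- params$causes[[k]]
    th[paste0("log_shape", k)] <- log(cs$shape)
    th[paste0("log_rate", k)] <- -cs$shape * log(cs$scale)
  }
  draws <- matrix(rep(th, each = n_draws), n_draws, layout$npar)
  colnames(draws) <- layout$names
  structure(list(draws = draws, layout = layout, theta_hat = th,
                 Sigma = diag(0, layout$npar), b_mode = NULL,
                 diagnostics = data.frame(parameter = layout$names,
                                          rhat = rep(1, layout$npar),
                                          ess = rep(n_draws, layout$npar)),
                 flagged = FALSE, method = "degenerate", chains = 1L,
                 warmup = 0L, retained = n_draws,
                 acceptance = list(theta = NA_real_, b = NA_real_),
                 dat_meta = list(
                   outcomes = vapply(params$longitudinal, `[[`, "", "outcome"),
                   covariate_names = params$baseline_covariate_names,
                   K = K, w_center = rep(0, nw), m_center = rep(0, P))),
            class = "posterior_draws")
}
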
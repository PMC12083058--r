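# internal numerical helpers

.jmsched_env <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [0, 1], cached per order
gl_rule <- function(n) {
  key <- paste0("gl", n)
  rule <- .jmsched_env[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n, 0, 1)
    .jmsched_env[[key]] <- list(x = rule$x, w = rule$w)
    rule <- .jmsched_env[[key]]
  }
  rule
}

# panel boundaries covering [a, b] with panel width <= max_width
panel_breaks <- function(a, b, max_width = 0.5) {
  if (b <= a) return(c(a, b))
  n <- max(1L, ceiling((b - a) / max_width))
  seq(a, b, length.out = n + 1L)
}

# nodes and weights of a composite Gauss-Legendre rule over panels of [a, b]
panel_gl <- function(a, b, n_nodes = 15L, max_width = 0.5) {
  br <- panel_breaks(a, b, max_width)
  rule <- gl_rule(n_nodes)
  widths <- diff(br)
  nodes <- rep(br[-length(br)], each = n_nodes) + rep(widths, each = n_nodes) * rule$x
  weights <- rep(widths, each = n_nodes) * rule$w
  list(nodes = nodes, weights = weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_jmsched <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "jmsched_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# split-Rhat and bulk effective sample size for a draws matrix
# (iterations x chains); plain Gelman-Rubin split version
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(xs)
  cm <- colMeans(xs)
  cv <- apply(xs, 2, stats::var)
  if (all(cv < .Machine$double.eps)) return(1.0)
  B <- half * stats::var(cm)
  W <- mean(cv)
  vhat <- (half - 1) / half * W + B / half
  sqrt(vhat / W)
}

ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  rho_sum <- 0
  for (j in seq_len(m)) {
    v <- x[, j] - mean(x[, j])
    if (stats::var(x[, j]) < .Machine$double.eps) next
    ac <- stats::acf(v, lag.max = min(n - 2L, 100L), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1] - 1L else length(ac)
    rho_sum <- rho_sum + sum(ac[seq_len(cut)])
  }
  rho_sum <- rho_sum / m
  max(1, n * m / (1 + 2 * max(0, rho_sum)))
}
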
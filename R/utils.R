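# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's RNG stream is untouched; seed = NULL means "use current RNG".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Numerically safe log(sum(exp(w))).
logsumexp <- function(w) {
  m <- max(w)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(w - m)))
}

# Distinct integer window lengths, approximately log-spaced.
log_spaced_windows <- function(min_window, max_window, n_windows) {
  unique(round(exp(seq(log(min_window), log(max_window),
                       length.out = n_windows))))
}

# Unweighted least squares of y on x; slope, intercept and R^2.
# A flat response (zero total sum of squares) fits its constant perfectly,
# so R^2 is reported as 1 in that case.
ls_fit <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, 1 - sum(fit$residuals^2) / sst) else 1
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]),
       r2 = r2,
       residuals = fit$residuals)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L
}

# Condition used to signal a constant (zero-variance) epoch; pipeline code
# catches it and records missing feature values instead of aborting.
degenerate_epoch <- function(msg) {
  stop(structure(class = c("mfeeg_degenerate_epoch", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Best small rational approximation p/q to `ratio` by continued fractions.
rational_approx <- function(ratio, tol = 1e-9, max_den = 10000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  x <- ratio
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - ratio) < tol * ratio || x == a) break
    x <- 1 / (x - a)
  }
  c(p = p1, q = q1)
}
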
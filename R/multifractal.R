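# Multifractal singularity-spectrum estimators.
#
# Three routes to the spectrum (alpha, f(alpha)) of an epoch:
#   * chhabra_jensen(): direct estimation from q-weighted normalized box
#     measures — no Legendre transform, applicable to positive measures;
#   * mfdfa() / mfdma(): generalized fluctuation analysis with detrending
#     by local regression / backward moving average, followed by a
#     numerical Legendre transform of the mass exponents.
# All three return an `mf_spectrum` sharing summary semantics: the width
# Delta-alpha = max - min of the retained singularity strengths, and the
# height Delta-f = max - min of the retained dimensions.

#' Default moment-order grid
#'
#' -5 to 5 in steps of 0.25; contains q = 0 and q = 1 exactly. Moments with
#' q > 1 emphasize the most singular regions of the measure, q < 1 the
#' least singular ones.
#'
#' @return numeric vector.
#' @export
default_q_grid <- function() seq(-5, 5, by = 0.25)

validate_q_grid <- function(q) {
  q <- as.numeric(q)
  if (length(q) == 0) stop("'q' must be non-empty")
  if (is.unsorted(q, strictly = TRUE)) stop("'q' must be strictly increasing")
  q
}

# Normalized q-weights mu_i(q, l) = P_i^q / sum_j P_j^q, computed in log
# space so large |q| with tiny P_i cannot overflow. `lp` is log P_i
# (already normalized so sum P_i = 1); returns the Nl x nq weight matrix
# and the per-q log normalizer.
cj_weights <- function(lp, q) {
  W <- outer(lp, q)                       # log P_i^q
  lse <- apply(W, 2, logsumexp)
  list(mu = exp(sweep(W, 2, lse)), log_norm = lse)
}

#' Chhabra-Jensen direct multifractal spectrum
#'
#' Treats a positive epoch as a measure: window (box) probabilities
#' \eqn{P_i(l)} at each dyadic scale `l` are the window sums normalized by
#' the epoch total, the q-weighted measures are
#' \eqn{\mu_i(q,l) = P_i(l)^q / \sum_j P_j(l)^q}, and the two auxiliary
#' statistics
#' \deqn{M_\alpha(q,l) = \sum_i \mu_i \log P_i, \qquad
#'       M_f(q,l) = \sum_i \mu_i \log \mu_i}
#' are regressed on \eqn{\log l} across scales; their slopes are the
#' singularity strength \eqn{\alpha(q)} and dimension \eqn{f(q)} directly
#' (both equal 1 for a homogeneous measure on a 1-D support). A q value is
#' rejected when either regression has R-squared below `r2_min`; width and
#' height are taken over retained q only.
#'
#' On an exact binomial cascade both statistics are exactly linear in
#' \eqn{\log l}, and the estimator reproduces the closed-form spectrum of
#' \eqn{\tau(q) = -\log_2(p_1^q + p_2^q)} to machine precision.
#'
#' @param m positive numeric vector whose length is a power of two (use
#'   [sigmoid_transform()] to map signed signals into (0, 1) first).
#' @param q moment orders (strictly increasing; see [default_q_grid()]).
#' @param scales dyadic window sizes; default `2, 4, ..., length(m)/2`
#'   (the degenerate endpoints 1 and N are excluded).
#' @param r2_min rejection threshold for the per-q regressions (default
#'   0.9).
#' @return an [mf_spectrum] object.
#' @export
chhabra_jensen <- function(m, q = default_q_grid(), scales = NULL,
                           r2_min = 0.9) {
  m <- as.numeric(m)
  q <- validate_q_grid(q)
  N <- length(m)
  if (!is_power_of_two(N)) {
    stop("epoch length (", N, ") must be a power of two")
  }
  if (any(m <= 0) || !all(is.finite(m))) {
    stop("all values must be finite and > 0; sigmoid-transform signed signals")
  }
  if (is.null(scales)) scales <- 2^seq(1L, as.integer(log2(N)) - 1L)
  scales <- as.integer(scales)
  if (length(scales) < 3) stop("need at least 3 scales")
  if (any(N %% scales != 0)) stop("scales must divide the epoch length")

  nq <- length(q)
  Ma <- matrix(NA_real_, length(scales), nq)
  Mf <- matrix(NA_real_, length(scales), nq)
  total <- sum(m)
  for (si in seq_along(scales)) {
    P <- colSums(matrix(m, nrow = scales[si]))
    lp <- log(P) - log(total)
    wt <- cj_weights(lp, q)
    Ma[si, ] <- colSums(wt$mu * lp)
    Mf[si, ] <- colSums(wt$mu * sweep(outer(lp, q), 2, wt$log_norm))
  }
  ll <- log(scales)
  alpha <- f <- r2a <- r2f <- numeric(nq)
  for (j in seq_len(nq)) {
    fa <- ls_fit(ll, Ma[, j]); alpha[j] <- fa$slope; r2a[j] <- fa$r2
    ff <- ls_fit(ll, Mf[, j]); f[j] <- ff$slope; r2f[j] <- ff$r2
  }
  retained <- r2a >= r2_min & r2f >= r2_min
  new_mf_spectrum(method = "chhabra-jensen", q = q, alpha = alpha, f = f,
                  r2_alpha = r2a, r2_f = r2f, retained = retained,
                  scales = scales)
}

# log F_q(l) for one scale from per-segment mean square residuals F2
# (Eq.-13/14/20 style aggregation); q = 0 via the exponential of the mean
# log, everything in log space to tolerate extreme q.
log_fq <- function(lF2, q) {
  n <- length(lF2)
  vapply(q, function(qq) {
    if (qq == 0) 0.5 * mean(lF2)
    else (logsumexp(lF2 * (qq / 2)) - log(n)) / qq
  }, numeric(1))
}

# Legendre transform of generalized exponents h(q):
# tau(q) = q h(q) - D_f, alpha = dtau/dq (central differences, one-sided at
# the ends), f = q alpha - tau.
legendre_spectrum <- function(q, hq, support_dim = 1) {
  tau <- q * hq - support_dim
  n <- length(q)
  alpha <- rep(NA_real_, n)
  if (n >= 2) {
    alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
    alpha[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
    if (n >= 3) {
      i <- 2:(n - 1)
      alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
    }
  }
  list(tau = tau, alpha = alpha, f = q * alpha - tau)
}

# Common body of mfdfa()/mfdma(): fit log F_q(l) ~ log l per q, Legendre
# transform, wrap up.
legendre_mf_spectrum <- function(method, q, scales, lFq, support_dim = 1) {
  ll <- log(scales)
  nq <- length(q)
  hq <- r2 <- numeric(nq)
  for (j in seq_len(nq)) {
    fit <- ls_fit(ll, lFq[, j])
    hq[j] <- fit$slope
    r2[j] <- fit$r2
  }
  if (nq >= 3) {
    leg <- legendre_spectrum(q, hq, support_dim)
    alpha <- leg$alpha
    f <- leg$f
  } else {
    alpha <- f <- rep(NA_real_, nq)
  }
  new_mf_spectrum(method = method, q = q, alpha = alpha, f = f,
                  r2_alpha = r2, r2_f = r2, retained = rep(TRUE, nq),
                  scales = scales, hq = hq, support_dim = support_dim)
}

#' Multifractal detrended fluctuation analysis (MF-DFA)
#'
#' Generalization of [dfa()]: the same integrated, per-window linearly
#' detrended residuals are aggregated at every moment order q,
#' \deqn{F_q(l) = \left\{\frac{1}{N_l}\sum_\nu
#'   \left[F_\nu^2(l)\right]^{q/2}\right\}^{1/q}}
#' (q = 0 via the exponential of the mean logarithm). The generalized
#' exponent h(q) is the slope of \eqn{\log F_q(l)} on \eqn{\log l}; the
#' spectrum follows from the Legendre transform \eqn{\tau(q) = q h(q) -
#' D_f}, \eqn{\alpha = d\tau/dq} (central differences),
#' \eqn{f = q\alpha - \tau}. At q = 2 the exponent equals the plain DFA
#' exponent on the same epoch.
#'
#' @param x numeric vector (one epoch; signed data fine).
#' @param q moment orders; a single q yields the generalized exponent only
#'   (no Legendre transform).
#' @param scales window lengths; default 16 log-spaced values between 8
#'   and `length(x)/4`, matching [dfa()].
#' @return an [mf_spectrum] with the additional element `hq`.
#' @export
mfdfa <- function(x, q = default_q_grid(), scales = NULL) {
  x <- as.numeric(x)
  q <- validate_q_grid(q)
  N <- length(x)
  if (is.null(scales)) scales <- log_spaced_windows(8L, N %/% 4L, 16L)
  if (N < 4 * min(scales)) stop("epoch too short for the smallest scale")
  if (stats::sd(x) == 0) degenerate_epoch("constant epoch in mfdfa")
  y <- cumsum(x - mean(x))
  lFq <- matrix(NA_real_, length(scales), length(q))
  for (si in seq_along(scales)) {
    F2 <- dfa_window_f2(y, scales[si])
    F2 <- pmax(F2, .Machine$double.xmin)    # guard exact-zero residuals
    lFq[si, ] <- log_fq(log(F2), q)
  }
  legendre_mf_spectrum("mfdfa", q, scales, lFq)
}

#' Multifractal detrended moving average (MF-DMA)
#'
#' As [mfdfa()] but detrending by subtracting a backward moving average of
#' the cumulative sum,
#' \eqn{\tilde y(t) = \frac{1}{l}\sum_{z=0}^{l-1} y(t-z)}
#' (position parameter theta = 0), instead of per-window regression. The
#' residual series (defined for `t >= l`) is cut into disjoint windows of
#' length `l`, per-window root-mean-square fluctuations are aggregated over
#' q, and the spectrum follows from the same Legendre transform.
#'
#' @inheritParams mfdfa
#' @return an [mf_spectrum] with the additional element `hq`.
#' @export
mfdma <- function(x, q = default_q_grid(), scales = NULL) {
  x <- as.numeric(x)
  q <- validate_q_grid(q)
  N <- length(x)
  if (is.null(scales)) scales <- log_spaced_windows(8L, N %/% 4L, 16L)
  if (N < 4 * min(scales)) stop("epoch too short for the smallest scale")
  if (stats::sd(x) == 0) degenerate_epoch("constant epoch in mfdma")
  y <- cumsum(x)
  cy <- cumsum(y)
  lFq <- matrix(NA_real_, length(scales), length(q))
  for (si in seq_along(scales)) {
    l <- scales[si]
    t <- l:N
    ma <- (cy[t] - c(0, cy)[t - l + 1L]) / l
    eps <- y[t] - ma
    n_win <- length(eps) %/% l
    E <- matrix(eps[seq_len(n_win * l)], nrow = l)
    F2 <- pmax(colMeans(E^2), .Machine$double.xmin)
    lFq[si, ] <- log_fq(log(F2), q)
  }
  legendre_mf_spectrum("mfdma", q, scales, lFq)
}

new_mf_spectrum <- function(method, q, alpha, f, r2_alpha, r2_f, retained,
                            scales, hq = NULL, support_dim = 1) {
  ret_a <- alpha[retained]
  ret_f <- f[retained]
  width <- if (any(retained) && all(is.finite(ret_a))) {
    max(ret_a) - min(ret_a)
  } else NA_real_
  height <- if (any(retained) && all(is.finite(ret_f))) {
    max(ret_f) - min(ret_f)
  } else NA_real_
  structure(list(method = method, q = q, alpha = alpha, f = f,
                 r2_alpha = r2_alpha, r2_f = r2_f, retained = retained,
                 width = width, height = height,
                 n_rejected = sum(!retained), scales = scales, hq = hq,
                 support_dim = support_dim),
            class = "mf_spectrum")
}

#' Summarize a singularity spectrum
#'
#' Width and height over the retained moment orders, plus retention
#' counts. With zero retained q both summaries are missing and a warning
#' is raised.
#'
#' @param s an `mf_spectrum`.
#' @return named list: `width`, `height`, `n_retained`, `n_rejected`.
#' @export
spectrum_summary <- function(s) {
  stopifnot(inherits(s, "mf_spectrum"))
  if (!any(s$retained)) {
    warning("all q rejected; spectrum summaries are missing")
  }
  list(width = s$width, height = s$height,
       n_retained = sum(s$retained), n_rejected = s$n_rejected)
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat(sprintf("<mf_spectrum> %s: width %.4f, height %.4f (%d of %d q retained)\n",
              x$method,
              if (is.na(x$width)) NA else x$width,
              if (is.na(x$height)) NA else x$height,
              sum(x$retained), length(x$q)))
  invisible(x)
}

#' @export
coef.mf_spectrum <- function(object, ...) {
  c(width = object$width, height = object$height)
}

#' @export
summary.mf_spectrum <- function(object, ...) {
  cat("Multifractal singularity spectrum (", object$method, ")\n", sep = "")
  cat(sprintf("  q grid     : %g .. %g (%d values)\n",
              min(object$q), max(object$q), length(object$q)))
  cat(sprintf("  retained q : %d (rejected %d)\n",
              sum(object$retained), object$n_rejected))
  cat(sprintf("  width      : %.5f\n", object$width))
  cat(sprintf("  height     : %.5f\n", object$height))
  invisible(object)
}

#' @export
as.data.frame.mf_spectrum <- function(x, ...) {
  data.frame(q = x$q, alpha = x$alpha, f = x$f,
             r2_alpha = x$r2_alpha, r2_f = x$r2_f,
             retained = x$retained)
}

#' @export
plot.mf_spectrum <- function(x, ...) {
  keep <- x$retained & is.finite(x$alpha) & is.finite(x$f)
  graphics::plot(x$alpha[keep], x$f[keep], type = "b", pch = 16,
                 xlab = expression(alpha), ylab = expression(f(alpha)),
                 main = paste("Singularity spectrum -", x$method), ...)
  invisible(x)
}
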
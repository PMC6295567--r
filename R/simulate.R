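# Benchmark simulators with known fractal / multifractal ground truth.

#' Amplitude modulator for simulated signals
#'
#' Describes a slowly varying positive envelope \eqn{M(t)} used by
#' [modfbm_sim()] to impose a time-varying standard deviation on a
#' fractional Brownian motion. The envelope is evaluated continuously at
#' every sample (never piecewise-constant per epoch), so consecutive
#' analysis epochs see a smooth amplitude gradient.
#'
#' Shapes, with `b = breakpoints` as fractions of the series length:
#' \describe{
#'   \item{`constant`}{\eqn{M(t) = peak} everywhere.}
#'   \item{`triangular`}{linear rise `baseline -> peak` on `[0, b[1]]`, then
#'     linear fall back to `baseline`.}
#'   \item{`trapezoid`}{rise over `[0, b[1]]`, plateau at `peak` over
#'     `[b[1], b[2]]`, fall over `[b[2], 1]`. The default (`baseline =
#'     0.2 * peak`, breakpoints 0.25 and 0.75) is a modified ramp: a fifth
#'     of full amplitude at the edges, full amplitude over the middle half.}
#' }
#'
#' @param shape one of `"trapezoid"`, `"triangular"`, `"constant"`.
#' @param baseline,peak positive envelope values at the edges / the plateau.
#' @param breakpoints strictly increasing fractions in \[0, 1\].
#' @return object of class `modulator`.
#' @export
modulator <- function(shape = c("trapezoid", "triangular", "constant"),
                      peak = 1, baseline = 0.2 * peak,
                      breakpoints = NULL) {
  shape <- match.arg(shape)
  if (is.null(breakpoints)) {
    breakpoints <- switch(shape,
                          trapezoid = c(0.25, 0.75),
                          triangular = 0.5,
                          constant = numeric(0))
  }
  stopifnot(baseline > 0, peak > 0,
            all(breakpoints >= 0), all(breakpoints <= 1))
  if (length(breakpoints) > 1 && any(diff(breakpoints) <= 0)) {
    stop("'breakpoints' must be strictly increasing")
  }
  nb <- switch(shape, trapezoid = 2L, triangular = 1L, constant = 0L)
  if (length(breakpoints) != nb) {
    stop(sprintf("shape '%s' needs %d breakpoint(s)", shape, nb))
  }
  structure(list(shape = shape, baseline = baseline, peak = peak,
                 breakpoints = breakpoints),
            class = "modulator")
}

#' @param mod a [modulator()].
#' @param n number of samples; the envelope is evaluated at the midpoints
#'   `(i - 0.5) / n`.
#' @return numeric vector of length `n`, strictly positive.
#' @rdname modulator
#' @export
modulator_eval <- function(mod, n) {
  stopifnot(inherits(mod, "modulator"), n >= 1)
  tt <- (seq_len(n) - 0.5) / n
  b <- mod$breakpoints
  lo <- mod$baseline
  hi <- mod$peak
  ramp <- function(t, t0, t1, v0, v1) v0 + (v1 - v0) * (t - t0) / (t1 - t0)
  m <- switch(mod$shape,
    constant = rep(hi, n),
    triangular = ifelse(tt < b[1],
                        ramp(tt, 0, b[1], lo, hi),
                        ramp(tt, b[1], 1, hi, lo)),
    trapezoid = ifelse(tt < b[1], ramp(tt, 0, b[1], lo, hi),
                ifelse(tt < b[2], hi, ramp(tt, b[2], 1, hi, lo))))
  m
}

#' @export
print.modulator <- function(x, ...) {
  cat(sprintf("<modulator> %s: baseline %g, peak %g",
              x$shape, x$baseline, x$peak))
  if (length(x$breakpoints)) {
    cat(", breakpoints", paste(x$breakpoints, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary Gaussian increments of fractional Brownian
#' motion with Hurst exponent `hurst`, using the Wood-Chan / circulant
#' embedding construction: the target autocovariance
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} +
#'   |k-1|^{2H}\right)}
#' is embedded in a circulant matrix of order `2n`, whose eigenvalues are
#' obtained by FFT of the symmetrized first row; a complex Gaussian vector
#' weighted by the square-root eigenvalues is transformed back and its real
#' part read off. The method is exact (no truncation of the covariance).
#'
#' If the embedding produces an eigenvalue below `-1e-10 * max(eigenvalue)`
#' the generation fails with an error; negative eigenvalues within that
#' tolerance (floating-point dust) are clamped to zero with a warning.
#'
#' @param n number of samples (>= 1).
#' @param hurst Hurst exponent in (0, 1).
#' @param sigma standard deviation of the increments.
#' @param seed optional integer; fixes the draw without disturbing the
#'   caller's RNG stream.
#' @return numeric vector of length `n`.
#' @seealso [fbm_sim()], [modfbm_sim()]
#' @export
fgn_sim <- function(n, hurst, sigma = 1, seed = NULL) {
  stopifnot(n >= 1, hurst > 0, hurst < 1, sigma > 0)
  n <- as.integer(n)
  if (n == 1L) return(with_seed(seed, stats::rnorm(1, sd = sigma)))
  k <- 0:n
  g <- (sigma^2 / 2) *
    (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) + abs(k - 1)^(2 * hurst))
  row <- c(g[1:n], g[n + 1], rev(g[2:n]))      # symmetrized, length 2n
  lam <- Re(stats::fft(row))
  tol <- 1e-10 * max(lam)
  if (min(lam) < -tol) {
    stop("circulant embedding is not positive semi-definite for H = ", hurst,
         ", n = ", n, " (min eigenvalue ", signif(min(lam), 3), ")")
  }
  if (any(lam < 0)) {
    warning("clamping ", sum(lam < 0),
            " slightly negative embedding eigenvalue(s) to zero")
    lam[lam < 0] <- 0
  }
  m <- 2L * n
  with_seed(seed, {
    # Re(fft(w * z)) with z complex standard normal has covariance
    # sum_k w_k^2 cos(2 pi k d / m) = gamma(d) when w = sqrt(lambda / m).
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    Re(stats::fft(sqrt(lam / m) * z))[1:n]
  })
}

#' Fractional Brownian motion
#'
#' Cumulative sum of [fgn_sim()] increments; the first value equals the
#' first increment (the motion starts at zero one step before the series).
#'
#' @inheritParams fgn_sim
#' @return numeric vector of length `n`.
#' @export
fbm_sim <- function(n, hurst, sigma = 1, seed = NULL) {
  cumsum(fgn_sim(n, hurst, sigma = sigma, seed = seed))
}

#' Variance-modulated fractional Brownian motion
#'
#' Pointwise product \eqn{M(t) \cdot B_H(t)} of a continuous positive
#' envelope (see [modulator()]) with an fBm profile. Because the envelope
#' multiplies the profile, the standard deviation of the output within an
#' analysis epoch tracks the envelope level over that epoch.
#'
#' @inheritParams fgn_sim
#' @param mod a [modulator()]; the default trapezoid rises from
#'   `0.2 * peak` to `peak` over the first quarter of the series, holds the
#'   plateau until three quarters, and descends afterwards.
#' @return numeric vector of length `n`.
#' @export
modfbm_sim <- function(n, hurst, mod = modulator(), sigma = 1, seed = NULL) {
  modulator_eval(mod, n) * fbm_sim(n, hurst, sigma = sigma, seed = seed)
}

#' Binomial multiplicative cascade (p-model)
#'
#' Recursive halving of an interval of height `eps0`: at each split the two
#' children receive heights `2 * p1 * parent` and `2 * (1 - p1) * parent`,
#' with the side taking `p1` chosen by an independent fair coin flip. After
#' `levels` halvings the series has `2^levels` strictly positive values and
#' its total sum is conserved at every level (`p1 + p2 = 1`). The resulting
#' measure is exactly multifractal with mass exponents
#' \eqn{\tau(q) = -\log_2(p_1^q + p_2^q)}.
#'
#' @param levels number of halvings (series length `2^levels`).
#' @param p1 weight fraction in (0, 1); `p2 = 1 - p1`.
#' @param eps0 initial height (positive).
#' @param seed optional integer seed.
#' @return numeric vector of length `2^levels`, strictly positive.
#' @export
pmodel_sim <- function(levels, p1, eps0 = 1, seed = NULL) {
  stopifnot(levels >= 1, p1 > 0, p1 < 1, eps0 > 0)
  levels <- as.integer(levels)
  with_seed(seed, {
    v <- eps0
    for (k in seq_len(levels)) {
      left_gets_p1 <- stats::runif(length(v)) < 0.5
      a <- ifelse(left_gets_p1, 2 * p1, 2 * (1 - p1)) * v
      b <- ifelse(left_gets_p1, 2 * (1 - p1), 2 * p1) * v
      v <- as.vector(rbind(a, b))
    }
    v
  })
}

#' Surrogate series
#'
#' `"shuffle"` returns a random permutation of the input (identical
#' multiset of values, all temporal structure destroyed); `"gaussian"`
#' returns i.i.d. normal draws matching the input's sample mean and
#' standard deviation.
#'
#' @param x numeric vector or `mf_ts`.
#' @param kind `"shuffle"` or `"gaussian"`.
#' @param seed optional integer seed.
#' @return numeric vector of the same length as `x`.
#' @export
surrogate_series <- function(x, kind = c("shuffle", "gaussian"),
                             seed = NULL) {
  kind <- match.arg(kind)
  v <- ts_values(x)
  if (length(v) == 0) stop("'x' must be non-empty")
  with_seed(seed, {
    switch(kind,
      shuffle = if (length(v) == 1) v else sample(v),
      gaussian = stats::rnorm(length(v), mean = mean(v),
                              sd = if (length(v) > 1) stats::sd(v) else 0))
  })
}
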
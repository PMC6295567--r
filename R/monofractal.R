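# Per-epoch monofractal estimators: Higuchi fractal dimension and the DFA
# scaling exponent. Both are exactly invariant under affine amplitude maps
# of the input (they operate on differences / detrended residuals), which
# is why epoch-wise standardization cannot change their values.

#' Higuchi fractal dimension
#'
#' For every down-sampling factor `d = 1..d_max` and offset `m = 1..d` the
#' normalized curve length
#' \deqn{L_m(d) = \frac{1}{d}\left[\sum_{i}
#'   |X(m+id) - X(m+(i-1)d)|\right]\frac{N-1}{\lfloor (N-m)/d\rfloor d}}
#' is computed and averaged over `m`. If \eqn{\langle L(d)\rangle \propto
#' d^{-FD}}, the fractal dimension `FD` is the negative slope of
#' \eqn{\log\langle L(d)\rangle} on \eqn{\log d}, fitted by unweighted
#' least squares over all `d`. For a smooth curve FD = 1; for uncorrelated
#' noise FD approaches 2; for an exactly self-similar graph FD = 2 - H.
#'
#' @param x numeric vector (one epoch).
#' @param d_max largest down-sampling factor (>= 2). The default 64 keeps
#'   at least 16 points in each reconstructed sub-series of a 1,024-sample
#'   epoch.
#' @return A `fractal_fit` object (subclass `higuchi_fd`) with elements
#'   `value` (the FD estimate), `r_squared` of the log-log fit,
#'   `scales_used`, and `log_points` (table of log scale vs log statistic).
#' @examples
#' higuchi_fd(seq(0, 1, length.out = 512))          # straight line: FD ~ 1
#' @export
higuchi_fd <- function(x, d_max = 64L) {
  x <- as.numeric(x)
  N <- length(x)
  d_max <- as.integer(d_max)
  if (d_max < 2) stop("'d_max' must be at least 2")
  if (d_max < 3) stop("fewer than 3 usable scales; increase 'd_max'")
  if (N < 4 * d_max) {
    stop("epoch too short (", N, ") for d_max = ", d_max,
         "; need at least 4 * d_max samples")
  }
  Lmean <- numeric(d_max)
  for (d in seq_len(d_max)) {
    dx <- abs(x[(1 + d):N] - x[1:(N - d)])
    grp <- ((seq_along(dx) - 1L) %% d) + 1L      # offset m of each term
    s <- rowsum(dx, grp)[, 1]
    m <- seq_len(d)
    n_m <- (N - m) %/% d
    Lmean[d] <- mean(s * (N - 1) / (n_m * d) / d)
  }
  pts <- data.frame(log_scale = log(seq_len(d_max)),
                    log_stat = log(Lmean))
  fit <- ls_fit(pts$log_scale, pts$log_stat)
  new_fractal_fit("higuchi_fd", value = -fit$slope, r_squared = fit$r2,
                  scales_used = seq_len(d_max), log_points = pts,
                  label = "Higuchi fractal dimension")
}

# Residuals of an epoch's integrated profile after per-window linear
# detrending; shared by dfa() and mfdfa() so that MF-DFA at q = 2 reduces
# to DFA exactly. Returns per-window mean squared residuals.
dfa_window_f2 <- function(profile, l) {
  N <- length(profile)
  n_win <- N %/% l                          # trailing partial window dropped
  Y <- matrix(profile[seq_len(n_win * l)], nrow = l)
  X <- cbind(1, seq_len(l))
  R <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  colMeans(R^2)
}

#' Detrended fluctuation analysis
#'
#' The input is integrated about its mean, \eqn{y(k) = \sum_{i\le k} (X(i) -
#' \langle X\rangle)}, divided into non-overlapping windows of length `l`
#' (trailing partial windows discarded), the linear trend removed in each,
#' and the root-mean-square residual \eqn{F(l)} collected over a set of
#' window lengths. The scaling exponent is the least-squares slope of
#' \eqn{\log F(l)} on \eqn{\log l}.
#'
#' The series is integrated as part of the method, so the exponent
#' estimates the Hurst exponent of the *increments* the input represents:
#' white noise gives ~0.5, fractional Gaussian noise with Hurst exponent H
#' gives ~H, and feeding an fBm profile (already integrated once) shifts
#' the exponent by about +1.
#'
#' @param x numeric vector (one epoch).
#' @param min_window,max_window window-length range in samples; defaults 8
#'   and `length(x) / 4`.
#' @param n_windows number of log-spaced window lengths (default 16;
#'   duplicates after rounding are removed).
#' @return A `fractal_fit` object (subclass `dfa`) with the exponent in
#'   `value` plus fit diagnostics as in [higuchi_fd()].
#' @export
dfa <- function(x, min_window = 8L, max_window = NULL, n_windows = 16L) {
  x <- as.numeric(x)
  N <- length(x)
  if (is.null(max_window)) max_window <- N %/% 4L
  if (min_window < 4 || min_window >= max_window || max_window > N / 4) {
    stop("need 4 <= min_window < max_window <= length(x)/4")
  }
  scales <- log_spaced_windows(min_window, max_window, n_windows)
  if (length(scales) < 3) stop("fewer than 3 window sizes")
  y <- cumsum(x - mean(x))
  Fl <- vapply(scales, function(l) sqrt(mean(dfa_window_f2(y, l))),
               numeric(1))
  pts <- data.frame(log_scale = log(scales), log_stat = log(Fl))
  fit <- ls_fit(pts$log_scale, pts$log_stat)
  new_fractal_fit("dfa", value = fit$slope, r_squared = fit$r2,
                  scales_used = scales, log_points = pts,
                  label = "DFA scaling exponent")
}

new_fractal_fit <- function(subclass, value, r_squared, scales_used,
                            log_points, label) {
  structure(list(value = unname(value), r_squared = r_squared,
                 scales_used = scales_used, log_points = log_points,
                 label = label),
            class = c(subclass, "fractal_fit"))
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("%s: %.4f  (R^2 = %.4f, %d scales)\n",
              x$label, x$value, x$r_squared, length(x$scales_used)))
  invisible(x)
}

#' @export
coef.fractal_fit <- function(object, ...) {
  stats::setNames(object$value, "value")
}

#' @export
summary.fractal_fit <- function(object, ...) {
  cat(object$label, "\n")
  cat(sprintf("  estimate : %.6f\n", object$value))
  cat(sprintf("  R^2      : %.6f\n", object$r_squared))
  cat(sprintf("  scales   : %d (%d .. %d samples)\n",
              length(object$scales_used), min(object$scales_used),
              max(object$scales_used)))
  invisible(object)
}

#' @export
residuals.fractal_fit <- function(object, ...) {
  fit <- ls_fit(object$log_points$log_scale, object$log_points$log_stat)
  fit$residuals
}

#' @export
plot.fractal_fit <- function(x, ...) {
  graphics::plot(x$log_points$log_scale, x$log_points$log_stat,
                 xlab = "log scale", ylab = "log statistic",
                 main = x$label, ...)
  fit <- ls_fit(x$log_points$log_scale, x$log_points$log_stat)
  graphics::abline(fit$intercept, fit$slope, lty = 2)
  invisible(x)
}
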
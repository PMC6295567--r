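# Conventional per-epoch EEG measures and feature-redundancy analysis.

#' Classical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-15, beta 15-30, gamma 30-60 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 15, 30),
             hi = c(4, 8, 15, 30, 60))
}

validate_bands <- function(bands, fs) {
  stopifnot(all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo < 0) || any(bands$lo >= bands$hi)) {
    stop("bands need 0 <= lo < hi")
  }
  if (any(bands$hi > fs / 2)) {
    stop("band edge above the Nyquist frequency (", fs / 2, " Hz)")
  }
  bands
}

#' Conventional epoch features
#'
#' Mean, sample standard deviation, line length (the sum of absolute
#' successive differences — a classic seizure-detection feature), and mean
#' band power per frequency band from a single-segment periodogram (no
#' taper, no detrending). Band power is the mean of the power spectral
#' density over Fourier bins with `lo <= f < hi`; a band containing no bin
#' at this epoch length and sampling rate yields NA.
#'
#' @param x numeric vector (one epoch).
#' @param fs sampling rate in Hz.
#' @param bands band definitions as in [eeg_bands()].
#' @return named numeric vector: `mean`, `std`, `line_length`, and one
#'   `bp_<name>` entry per band.
#' @export
conventional_features <- function(x, fs, bands = eeg_bands()) {
  x <- as.numeric(x)
  bands <- validate_bands(bands, fs)
  out <- c(mean = mean(x), std = stats::sd(x),
           line_length = sum(abs(diff(x))))
  sp <- stats::spec.pgram(x, taper = 0, fast = FALSE, detrend = FALSE,
                          demean = FALSE, plot = FALSE)
  f_hz <- sp$freq * fs
  bp <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- f_hz >= bands$lo[i] & f_hz < bands$hi[i]
    if (!any(sel)) NA_real_ else mean(sp$spec[sel])
  }, numeric(1))
  names(bp) <- paste0("bp_", bands$name)
  c(out, bp)
}

#' Per-epoch feature table
#'
#' One row per epoch: conventional features of the raw epoch plus fractal
#' features. Fractal features come in two variants — computed on the raw
#' epoch and (suffix `_std`) on the epoch standardized to zero mean and
#' unit standard deviation. The Chhabra-Jensen spectrum operates on the
#' sigmoid-mapped values (raw or standardized respectively); its per-epoch
#' count of rejected moment orders is emitted as `cj_n_rejected_q` /
#' `cj_n_rejected_q_std`. Degenerate (constant) epochs yield missing
#' feature values; their count is attached as attribute `n_degenerate`.
#'
#' @param x numeric vector or [mf_ts()].
#' @param fs sampling rate (required for plain vectors).
#' @param epoch_length samples per epoch (power of two for the
#'   Chhabra-Jensen features; default 1024).
#' @param bands band definitions, see [eeg_bands()].
#' @param v sigmoid scale for the Chhabra-Jensen mapping.
#' @param d_max Higuchi down-sampling range.
#' @param q moment orders for the multifractal estimators.
#' @param estimators multifractal estimators to include: subset of
#'   `c("cj", "mfdfa", "mfdma")` (default `"cj"` only).
#' @return data.frame, one row per epoch, with attribute `n_degenerate`.
#' @export
epoch_features <- function(x, fs = NULL, epoch_length = 1024L,
                           bands = eeg_bands(), v = 1, d_max = 64L,
                           q = default_q_grid(), estimators = "cj") {
  fs <- ts_fs(x, fs)
  estimators <- match.arg(estimators, c("cj", "mfdfa", "mfdma"),
                          several.ok = TRUE)
  grid <- split_epochs(x, epoch_length, fs = fs)
  n_degenerate <- 0L

  one_epoch <- function(e) {
    conv <- conventional_features(e, fs, bands)
    res <- tryCatch({
      es <- standardize_epoch(e)
      row <- c(higuchi_fd = higuchi_fd(e, d_max)$value,
               higuchi_fd_std = higuchi_fd(es, d_max)$value,
               dfa_h = dfa(e)$value,
               dfa_h_std = dfa(es)$value)
      if ("cj" %in% estimators) {
        cj <- chhabra_jensen(sigmoid_transform(e, v), q = q)
        cjs <- chhabra_jensen(sigmoid_transform(es, v), q = q)
        row <- c(row,
                 cj_width = cj$width, cj_height = cj$height,
                 cj_n_rejected_q = cj$n_rejected,
                 cj_width_std = cjs$width, cj_height_std = cjs$height,
                 cj_n_rejected_q_std = cjs$n_rejected)
      }
      if ("mfdfa" %in% estimators) {
        mf <- mfdfa(es, q = q)
        row <- c(row, mfdfa_width_std = mf$width,
                 mfdfa_height_std = mf$height)
      }
      if ("mfdma" %in% estimators) {
        md <- mfdma(es, q = q)
        row <- c(row, mfdma_width_std = md$width,
                 mfdma_height_std = md$height)
      }
      row
    }, mfeeg_degenerate_epoch = function(cond) {
      n_degenerate <<- n_degenerate + 1L
      NULL
    })
    list(conv = conv, fractal = res)
  }

  rows <- apply(grid$epochs, 2, one_epoch)
  template <- NULL
  for (r in rows) if (!is.null(r$fractal)) { template <- r$fractal; break }
  tab <- do.call(rbind, lapply(rows, function(r) {
    fr <- if (is.null(r$fractal)) {
      stats::setNames(rep(NA_real_, length(template)), names(template))
    } else r$fractal
    c(r$conv, fr)
  }))
  out <- data.frame(epoch = seq_len(grid$n_epochs), tab)
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Pairwise Pearson correlation of a feature table
#'
#' Pairwise-complete Pearson correlations of all numeric columns. Columns
#' with zero variance produce missing entries with a warning. The matrix
#' is symmetric with unit diagonal.
#'
#' @param tab data.frame of features (non-numeric columns and an `epoch`
#'   index column are ignored).
#' @return correlation matrix.
#' @export
pearson_matrix <- function(tab) {
  m <- feature_matrix(tab)
  if (nrow(m) < 3) stop("need at least 3 rows")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    warning("zero-variance column(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "))
  }
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

feature_matrix <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  m <- as.matrix(tab[, num, drop = FALSE])
  m[, setdiff(colnames(m), "epoch"), drop = FALSE]
}

# Rank-based transform of each margin to standard normal quantiles
# (average ranks for ties).
copnorm <- function(x) {
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

#' Gaussian-copula mutual information
#'
#' Rank-transforms both margins to normal quantiles and evaluates the
#' Gaussian MI \eqn{-\frac{1}{2}\ln(1 - r^2)} of the transformed pair,
#' which estimates a lower bound on the true MI that is invariant to
#' strictly monotone marginal transforms. A bias-corrected value
#' (subtracting the analytic small-sample bias of the Gaussian entropy
#' estimate, \eqn{[\psi((n-1)/2) - \psi((n-2)/2)]/2}) is returned
#' alongside the raw estimate. Units: nats.
#'
#' @param a,b numeric vectors (paired observations; incomplete pairs are
#'   dropped).
#' @return named numeric vector `c(mi, mi_bc)`, or NAs when a margin is
#'   constant (all-tied).
#' @export
gc_mutual_information <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 10) stop("need at least 10 paired complete observations")
  if (length(unique(a)) == 1 || length(unique(b)) == 1) {
    warning("constant margin; mutual information undefined")
    return(c(mi = NA_real_, mi_bc = NA_real_))
  }
  r <- stats::cor(copnorm(a), copnorm(b))
  mi <- -0.5 * log1p(-r^2)
  bias <- (digamma((n - 1) / 2) - digamma((n - 2) / 2)) / 2
  c(mi = mi, mi_bc = mi - bias)
}

#' Feature redundancy report
#'
#' Full pairwise Pearson and Gaussian-copula MI matrices, plus a per-
#' feature summary of redundancy against the conventional-feature block
#' (mean, std, line length and band powers): the maximum absolute
#' correlation and maximum MI each feature attains against any
#' conventional feature. Low values flag features carrying information not
#' already present in the conventional set.
#'
#' @param tab feature table as from [epoch_features()].
#' @param conventional column names forming the reference block; defaults
#'   to mean/std/line_length plus all `bp_*` columns present.
#' @return list with `pearson` (matrix), `mi` (matrix, raw GCMI in nats)
#'   and `summary` (data.frame: feature, max_abs_r, max_mi).
#' @export
redundancy_report <- function(tab, conventional = NULL) {
  m <- feature_matrix(tab)
  if (is.null(conventional)) {
    conventional <- intersect(
      c("mean", "std", "line_length",
        grep("^bp_", colnames(m), value = TRUE)),
      colnames(m))
  }
  if (length(conventional) == 0) stop("no conventional columns found")
  pr <- pearson_matrix(tab)
  p <- ncol(m)
  mi <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) {
    for (j in i:p) {
      val <- tryCatch(
        suppressWarnings(gc_mutual_information(m[, i], m[, j])[["mi"]]),
        error = function(e) NA_real_)
      mi[i, j] <- mi[j, i] <- val
    }
  }
  others <- setdiff(colnames(m), "epoch")
  summ <- do.call(rbind, lapply(others, function(feat) {
    ref <- setdiff(conventional, feat)
    data.frame(feature = feat,
               max_abs_r = suppressWarnings(
                 max(abs(pr[feat, ref]), na.rm = TRUE)),
               max_mi = suppressWarnings(max(mi[feat, ref], na.rm = TRUE)))
  }))
  summ$max_abs_r[!is.finite(summ$max_abs_r)] <- NA_real_
  summ$max_mi[!is.finite(summ$max_mi)] <- NA_real_
  list(pearson = pr, mi = mi, summary = summ[order(summ$max_abs_r), ])
}
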
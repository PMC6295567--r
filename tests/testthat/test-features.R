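test_that("band power concentrates where the signal lives", {
  fs <- 250
  x <- sin(2 * pi * 10 * (0:1023) / fs)    # 10 Hz: alpha band
  f <- conventional_features(x, fs)
  sp <- stats::spec.pgram(x, taper = 0, fast = FALSE, detrend = FALSE,
                          demean = FALSE, plot = FALSE)
  f_hz <- sp$freq * fs
  total <- sum(sp$spec[f_hz >= 0.5 & f_hz < 60])
  in_alpha <- sum(sp$spec[f_hz >= 8 & f_hz < 15])
  expect_gt(in_alpha / total, 0.95)
  expect_gt(f[["bp_alpha"]], max(f[["bp_delta"]], f[["bp_beta"]],
                                 f[["bp_gamma"]]))
})

test_that("conventional features scale with their homogeneity degrees", {
  x <- rnorm(1024)
  f1 <- conventional_features(x, 250)
  f2 <- conventional_features(2 * x, 250)
  expect_equal(f2[["line_length"]], 2 * f1[["line_length"]])
  expect_equal(f2[["std"]], 2 * f1[["std"]])
  bp <- grep("^bp_", names(f1), value = TRUE)
  expect_equal(unname(f2[bp]), unname(4 * f1[bp]), tolerance = 1e-12)
  expect_equal(conventional_features(rep(1, 256), 250)[["line_length"]], 0)
  expect_error(conventional_features(x, 100), "Nyquist")
})

test_that("pearson matrix is symmetric with unit diagonal", {
  set.seed(1)
  tab <- data.frame(a = rnorm(1800), b = rnorm(1800))
  tab$c <- -tab$a
  m <- pearson_matrix(tab)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["a", "c"], -1)
  expect_lt(abs(m["a", "b"]), 0.08)      # independent columns
  tab$z <- 0
  expect_warning(mz <- pearson_matrix(tab), "zero-variance")
  expect_true(is.na(mz["z", "a"]))
})

test_that("GCMI matches the Gaussian closed form and is rank-invariant", {
  set.seed(2)
  n <- 1e5
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  mi <- gc_mutual_information(a, b)
  expect_equal(unname(mi[["mi"]]), -0.5 * log(0.75), tolerance = 0.01)
  expect_lt(mi[["mi_bc"]], mi[["mi"]])

  # invariance under strictly monotone marginal transforms
  set.seed(3)
  u <- rnorm(500); w <- 0.6 * u + rnorm(500)
  base <- gc_mutual_information(u, w)
  for (f in list(exp, function(t) t^3, function(t) 5 * t - 2)) {
    expect_equal(gc_mutual_information(f(u), w), base, tolerance = 1e-12)
  }

  ind <- gc_mutual_information(rnorm(1800), rnorm(1800))
  expect_lt(ind[["mi"]], 0.01)
  expect_warning(res <- gc_mutual_information(rep(1, 50), rnorm(50)),
                 "constant")
  expect_true(all(is.na(res)))
  expect_error(gc_mutual_information(1:5, 1:5), "at least 10")
})

test_that("redundancy report flags copies and spares independent features", {
  set.seed(4)
  n <- 400
  std <- abs(rnorm(n)) + 1
  tab <- data.frame(std = std,
                    # conventional block is internally correlated, as in
                    # real recordings
                    mean = 0.7 * std + 0.2 * rnorm(n),
                    line_length = 2 * std + 0.1 * rnorm(n))
  tab$cj_width_std <- tab$std              # exact copy: fully redundant
  tab$indep <- rnorm(n)                    # carries fresh information
  rep <- redundancy_report(tab)
  summ <- rep$summary
  expect_equal(summ$max_abs_r[summ$feature == "cj_width_std"], 1)
  expect_equal(summ$feature[which.min(summ$max_abs_r)], "indep")
  expect_lt(summ$max_abs_r[summ$feature == "indep"], 0.2)
  expect_equal(rep$mi, t(rep$mi))
})

test_that("epoch feature tables carry fractal columns and missing rows", {
  set.seed(5)
  x <- c(rnorm(1024), rep(1, 1024), rnorm(1024))
  tab <- epoch_features(x, fs = 250, epoch_length = 1024,
                        q = seq(-3, 3, 0.5))
  expect_equal(nrow(tab), 3)
  expect_true(all(c("mean", "std", "line_length", "bp_alpha",
                    "higuchi_fd", "higuchi_fd_std", "dfa_h", "dfa_h_std",
                    "cj_width", "cj_height", "cj_n_rejected_q",
                    "cj_width_std") %in% names(tab)))
  expect_equal(attr(tab, "n_degenerate"), 1L)
  expect_true(is.na(tab$higuchi_fd[2]))      # the constant epoch
  expect_false(anyNA(tab$higuchi_fd[c(1, 3)]))
  # conventional features still defined on the constant epoch
  expect_equal(tab$line_length[2], 0)
})

test_that("standardization decouples spectrum width from epoch variance", {
  # variance-modulated persistent noise spanning the sigmoid's transition
  # range: the raw-epoch spectrum width follows the epoch std closely,
  # the standardized variant does not
  n <- 120 * 1024
  mod <- modulator("triangular", peak = 2, baseline = 0.25)
  x <- modulator_eval(mod, n) * fgn_sim(n, 0.7, seed = 31)
  tab <- epoch_features(x, fs = 512, epoch_length = 1024,
                        q = seq(-3, 3, 0.5))
  pr <- pearson_matrix(tab)
  expect_gt(pr["cj_width", "std"], 0.8)
  expect_lt(abs(pr["cj_width_std", "std"]), 0.3)
  rep <- redundancy_report(tab)
  summ <- rep$summary
  expect_gt(summ$max_abs_r[summ$feature == "cj_width"], 0.8)
  expect_lt(summ$max_abs_r[summ$feature == "cj_width_std"],
            summ$max_abs_r[summ$feature == "cj_width"])
})
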
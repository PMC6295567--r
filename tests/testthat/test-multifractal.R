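test_that("a homogeneous measure has a point spectrum at alpha = f = 1", {
  s <- chhabra_jensen(rep(2.5, 1024))
  expect_true(all(abs(s$alpha - 1) < 1e-6))
  expect_true(all(abs(s$f - 1) < 1e-6))
  expect_lt(s$width, 1e-6)
  expect_lt(s$height, 1e-6)
  expect_true(all(s$retained))
})

test_that("Chhabra-Jensen reproduces the binomial-cascade closed form", {
  for (p1 in c(0.3, 0.4)) {
    m <- pmodel_sim(10, p1, seed = round(100 * p1))
    s <- chhabra_jensen(m)
    sel <- s$q >= -2 & s$q <= 2
    expect_lt(max(abs(s$alpha[sel] - cascade_alpha(s$q[sel], p1))), 0.05)
    expect_lt(max(abs(s$f[sel] - cascade_f(s$q[sel], p1))), 0.05)
    # exact multiplicative structure: the fit is linear to machine precision
    expect_true(all(s$r2_alpha > 1 - 1e-10))
  }
  s4 <- chhabra_jensen(pmodel_sim(10, 0.4, seed = 40))
  expect_equal(s4$alpha[s4$q == 1],
               -(0.4 * log2(0.4) + 0.6 * log2(0.6)),  # binary entropy
               tolerance = 1e-9)
})

test_that("CJ alpha(q) is non-increasing and f respects the support bound", {
  m <- pmodel_sim(12, 0.35, seed = 12)
  s <- chhabra_jensen(m)
  expect_true(all(diff(s$alpha) <= 1e-9))
  expect_true(all(s$f[s$retained] <= 1 + 0.05))
})

test_that("q-weights are normalized and rejection honors the R^2 rule", {
  set.seed(3)
  for (i in 1:5) {
    lp <- log(runif(64)); lp <- lp - logsumexp_ref(lp)
    wt <- mfeeg:::cj_weights(lp, seq(-5, 5, 0.5))
    expect_true(all(abs(colSums(wt$mu) - 1) < 1e-12))
  }
  # an epoch of noise: raising the threshold must reject at least as many q
  x <- sigmoid_transform(standardize_epoch(rnorm(1024)))
  s_loose <- chhabra_jensen(x, r2_min = 0)
  s_tight <- chhabra_jensen(x, r2_min = 0.995)
  expect_true(all(s_loose$retained))
  expect_identical(s_tight$retained,
                   s_tight$r2_alpha >= 0.995 & s_tight$r2_f >= 0.995)
  expect_gte(s_tight$n_rejected, s_loose$n_rejected)
})

test_that("CJ input contract is enforced", {
  expect_error(chhabra_jensen(runif(1000)), "power of two")
  expect_error(chhabra_jensen(c(runif(1023), -1)), "> 0")
  s <- chhabra_jensen(pmodel_sim(10, 0.4, seed = 1), q = 0)
  expect_equal(s$width, 0)               # single-q grid: degenerate width
})

test_that("MF-DFA separates monofractal noise from a cascade", {
  set.seed(8)
  fgn_ep <- matrix(fgn_sim(50 * 1024, 0.7, seed = 5), nrow = 1024)
  w_fgn <- apply(fgn_ep, 2, function(e) mfdfa(e)$width)
  expect_lt(mean(w_fgn), 0.3)

  pm_ep <- matrix(pmodel_sim(16, 0.4, seed = 6), nrow = 1024)
  w_pm <- apply(pm_ep, 2,
                function(e) mfdfa(standardize_epoch(e))$width)
  expect_gt(mean(w_pm), 2 * mean(w_fgn))
})

test_that("MF-DFA at q = 2 reduces to plain DFA", {
  x <- fgn_sim(1024, 0.6, seed = 17)
  s <- mfdfa(x, q = 2)
  expect_equal(s$hq, dfa(x)$value, tolerance = 1e-10)
})

test_that("MF-DMA scaling on fGn is consistent with its Hurst exponent", {
  hs <- vapply(1:8, function(s) {
    mfdma(fgn_sim(4096, 0.7, seed = 200 + s), q = 2)$hq
  }, numeric(1))
  expect_lt(abs(mean(hs) - 0.7), 0.1)
  expect_error(mfdma(rep(1, 1024)), class = "mfeeg_degenerate_epoch")
  w <- mfdma(standardize_epoch(pmodel_sim(10, 0.4, seed = 2)))$width
  expect_gt(w, 0)
})

test_that("spectrum summaries report width, height and rejection counts", {
  sp <- mfeeg:::new_mf_spectrum("chhabra-jensen", q = c(-1, 0, 1),
                                alpha = c(1.3, 1.0, 0.7),
                                f = c(0, 1, 0),
                                r2_alpha = rep(1, 3), r2_f = rep(1, 3),
                                retained = rep(TRUE, 3), scales = c(2, 4, 8))
  out <- spectrum_summary(sp)
  expect_equal(out$width, 0.6)
  expect_equal(out$height, 1)
  expect_equal(out$n_rejected, 0)

  none <- mfeeg:::new_mf_spectrum("chhabra-jensen", q = 0, alpha = 1, f = 1,
                                  r2_alpha = 0.1, r2_f = 0.1,
                                  retained = FALSE, scales = c(2, 4, 8))
  expect_warning(res <- spectrum_summary(none), "rejected")
  expect_true(is.na(res$width) && is.na(res$height))
})
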
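test_that("generators are reproducible under a fixed seed", {
  expect_identical(fgn_sim(512, 0.7, seed = 5), fgn_sim(512, 0.7, seed = 5))
  expect_identical(fbm_sim(512, 0.3, seed = 5), fbm_sim(512, 0.3, seed = 5))
  expect_identical(pmodel_sim(8, 0.4, seed = 5), pmodel_sim(8, 0.4, seed = 5))
  expect_identical(surrogate_series(1:20, "shuffle", seed = 5),
                   surrogate_series(1:20, "shuffle", seed = 5))
  # seeding must not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(fgn_sim(64, 0.6, seed = 1)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("fGn with H = 0.5 is white noise", {
  x <- fgn_sim(2^14, 0.5, seed = 2)
  ac <- stats::acf(x, lag.max = 10, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 4 / sqrt(length(x))))
})

test_that("fGn autocovariance matches the closed form (H = 0.7)", {
  n <- 2^13
  n_seeds <- 50
  lags <- 0:20
  est <- sapply(seq_len(n_seeds), function(s) {
    x <- fgn_sim(n, 0.7, seed = 100 + s)
    vapply(lags, function(k) sample_acov(x, k), numeric(1))
  })
  mc_mean <- rowMeans(est)
  mc_se <- apply(est, 1, stats::sd) / sqrt(n_seeds)
  expect_true(all(abs(mc_mean - fgn_gamma(lags, 0.7)) < 3 * mc_se + 1e-12))
})

test_that("fBm is the cumulative sum of fGn and starts at its first increment", {
  g <- fgn_sim(256, 0.6, seed = 7)
  b <- fbm_sim(256, 0.6, seed = 7)
  expect_identical(b, cumsum(g))
  expect_identical(b[1], g[1])
  expect_length(fbm_sim(1, 0.6, seed = 7), 1)
  expect_identical(fbm_sim(1, 0.6, seed = 7), fgn_sim(1, 0.6, seed = 7))
})

test_that("H = 0.5 fBm behaves like a standard random walk", {
  n <- 400
  ends <- vapply(1:300, function(s) fbm_sim(n, 0.5, seed = s)[n], numeric(1))
  expect_lt(abs(var(ends) / n - 1), 0.35)
})

test_that("constant modulator scales fBm exactly and degenerates gracefully", {
  mc <- modulator("constant", peak = 3)
  expect_identical(modfbm_sim(512, 0.7, mod = mc, seed = 1),
                   3 * fbm_sim(512, 0.7, seed = 1))
  # trapezoid with peak == baseline collapses to the constant case
  mflat <- modulator("trapezoid", peak = 2, baseline = 2)
  expect_equal(modfbm_sim(512, 0.7, mod = mflat, seed = 1),
               2 * fbm_sim(512, 0.7, seed = 1))
})

test_that("per-epoch std of modulated fBm tracks the envelope", {
  n_ep <- 1800L; L <- 1024L
  mod <- modulator("triangular", peak = 1, baseline = 0.05)
  x <- modfbm_sim(n_ep * L, 0.7, mod = mod, seed = 11)
  m <- modulator_eval(mod, n_ep * L)
  sds <- apply(matrix(x, nrow = L), 2, sd)
  m_ep <- colMeans(matrix(m, nrow = L))
  # epoch-level correlation is diluted by the fBm's own epoch-to-epoch
  # wander; the slow component of the std time course follows the envelope
  # almost perfectly
  expect_gt(cor(sds, m_ep), 0.6)
  sm <- as.vector(stats::filter(sds, rep(1 / 101, 101)))
  ok <- !is.na(sm)
  expect_gt(cor(sm[ok], m_ep[ok]), 0.9)
})

test_that("modulator validation rejects bad shapes", {
  expect_error(modulator("trapezoid", baseline = 0), "baseline")
  expect_error(modulator("trapezoid", breakpoints = c(0.75, 0.25)),
               "increasing")
  expect_error(modulator("triangular", breakpoints = c(0.2, 0.8)),
               "breakpoint")
})

test_that("p-model produces the exact cascade multiset and conserves mass", {
  # one split: heights 2*p1*eps and 2*p2*eps in seeded order
  v1 <- pmodel_sim(1, 0.4, eps0 = 1, seed = 3)
  expect_setequal(round(v1, 12), c(0.8, 1.2))
  # mass conservation at every level
  for (lev in c(1, 5, 10)) {
    v <- pmodel_sim(lev, 0.37, eps0 = 2, seed = lev)
    expect_equal(sum(v), 2^lev * 2, tolerance = 1e-12)
  }
  # full multiset at depth 10: 2^10 p1^j p2^(10-j) with binomial counts
  v <- pmodel_sim(10, 0.4, seed = 9)
  j <- 0:10
  theo <- rep(2^10 * 0.4^j * 0.6^(10 - j), choose(10, j))
  expect_equal(sort(v), sort(theo), tolerance = 1e-12)
  expect_true(all(v > 0))
})

test_that("surrogates preserve what they promise", {
  x <- fbm_sim(5000, 0.7, seed = 4)
  sh <- surrogate_series(x, "shuffle", seed = 1)
  expect_identical(sort(sh), sort(x))
  g <- surrogate_series(x, "gaussian", seed = 1)
  n <- length(x)
  expect_lt(abs(mean(g) - mean(x)), 3 * sd(x) / sqrt(n))
  expect_lt(abs(sd(g) - sd(x)), 3 * sd(x) / sqrt(2 * n))
  expect_identical(surrogate_series(4.2, "shuffle", seed = 1), 4.2)
})
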
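test_that("4-bin toy trace matches the hand-computed correlation", {
  tr <- photon_trace(1:4, c(2L, 0L, 2L, 0L))
  cur <- autocorrelate(tr, max_lag_bins = 2, method = "direct")
  # lag 1: pairs (2,0),(0,2),(2,0): mean product 0; means 4/3 and 2/3
  # G = 0 / (4/3 * 2/3) - 1 = -1
  expect_equal(cur$G[1], -1)
  # lag 2: pairs (2,2),(0,0): mean product 2; means 1 and 1 -> G = 1
  expect_equal(cur$G[2], 1)
})

test_that("constant traces have zero correlation and zero traces are rejected", {
  tr <- photon_trace(1:100 * 1e-4, rep(3L, 100))
  cur <- autocorrelate(tr, max_lag_bins = 10, method = "direct")
  expect_true(all(abs(cur$G) < 1e-12))
  tr0 <- photon_trace(1:100 * 1e-4, integer(100))
  expect_error(autocorrelate(tr0, max_lag_bins = 10), "all-zero")
})

test_that("independent Poisson bins are uncorrelated at every lag", {
  set.seed(60)
  K <- 40000
  tr <- photon_trace(1:K * 1e-4, rpois(K, 2))
  cur <- autocorrelate(tr, max_lag_bins = 64)
  expect_true(all(abs(cur$G) < 3 / sqrt(K)))
})

test_that("multi-tau agrees with the direct estimator", {
  set.seed(61)
  cfg <- sim_config(D = 10, mu_mol = 1e5, mu_back = 1e3, K = 2e4,
                    n_molecules = 0, init_region = c(1.5, 1.5, 4.5), seed = 62)
  tr <- simulate_stationary_trace(cfg, mean_occupancy = 3)
  mt <- autocorrelate(tr, max_lag_bins = 256, method = "multitau")
  di <- autocorrelate(tr, max_lag_bins = 256, method = "direct")
  # stage-0 lags coincide exactly with the direct estimator
  small <- mt$lag <= 16 * 1e-4
  expect_equal(mt$G[small], di$G[round(mt$lag[small] / 1e-4)],
               tolerance = 1e-12)
  # coarse lags agree up to the octave-averaging error
  g0 <- mt$G[1]
  for (i in which(!small)) {
    j <- round(mt$lag[i] / 1e-4)
    expect_lt(abs(mt$G[i] - di$G[j]), 0.1 * g0 + 0.02)
  }
})

test_that("correlation estimate is invariant under count rescaling", {
  set.seed(63)
  K <- 5000
  w <- rpois(K, 3)
  t1 <- photon_trace(1:K * 1e-4, w)
  t5 <- photon_trace(1:K * 1e-4, 5L * w)
  c1 <- autocorrelate(t1, max_lag_bins = 64)
  c5 <- autocorrelate(t5, max_lag_bins = 64)
  expect_equal(c1$G, c5$G)
})

test_that("fitting a noiseless theoretical curve recovers its parameters", {
  psf <- std_psf()
  s2 <- (1.5 / 0.3)^2
  tauD <- 0.00225  # = omega_xy^2 / (4 * 10)
  lag <- exp(seq(log(1e-4), log(0.5), length.out = 60))
  G <- 0.5 / ((1 + lag / tauD) * sqrt(1 + lag / (s2 * tauD)))
  cur <- structure(data.frame(lag = lag, G = G),
                   class = c("fcs_curve", "data.frame"), dt = 1e-4)
  fit <- fit_fcs_model(cur, psf)
  expect_true(fit$converged)
  expect_equal(fit$tau_D, tauD, tolerance = 1e-6)
  expect_equal(fit$D_hat, 10, tolerance = 1e-6)
  expect_equal(fit$G0, 0.5, tolerance = 1e-6)
  # D_hat is invariant under uniform rescaling of G
  cur2 <- cur; cur2$G <- 3 * cur2$G
  fit2 <- fit_fcs_model(cur2, psf)
  expect_equal(fit2$D_hat, fit$D_hat, tolerance = 1e-6)
})

test_that("FCS on a long simulated trace recovers D and the occupancy scale", {
  set.seed(64)
  psf <- std_psf()
  cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4, K = 5e5,
                    n_molecules = 0, init_region = c(2, 2, 7), psf = psf,
                    seed = 65)
  tr <- simulate_stationary_trace(cfg, mean_occupancy = 2)
  fit <- fit_fcs_model(autocorrelate(tr, max_lag_bins = 4000), psf)
  expect_true(fit$converged)
  expect_lt(abs(fit$D_hat / 10 - 1), 0.3)
  # amplitude ~ 1/<N> up to the background dilution factor
  expect_gt(fit$N_hat, 1); expect_lt(fit$N_hat, 4)
})

test_that("the data-efficiency comparison walks lengths lazily and reports both methods", {
  psf <- std_psf()
  cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4, K = 900,
                    n_molecules = 0, psf = psf, init_region = c(1.5, 1.5, 4.5))
  res <- compare_data_efficiency(10, cfg, trace_lengths = c(300, 900),
                                 n_replicates = 2, seed = 5,
                                 mean_occupancy = 2, n_iter = 250,
                                 N_model = 5)
  expect_true(all(c("length", "method", "median_abs_log2_error", "n_fail")
                  %in% names(res)))
  expect_true(all(res$median_abs_log2_error >= 0))
  expect_true(all(res$n_fail >= 0 & res$n_fail <= 2))
  for (m in c("min_length_bayes", "min_length_fcs", "length_ratio"))
    expect_false(is.null(attr(res, m)))
  # once a method reaches factor-2 it is not re-run at longer lengths
  for (m in c("bayes", "fcs")) {
    ml <- attr(res, paste0("min_length_", m))
    if (is.finite(ml))
      expect_false(any(res$method == m & res$length > ml))
  }
})

test_that("two halves of a stationary trace give consistent estimates", {
  set.seed(66)
  psf <- std_psf()
  cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4, K = 2e5,
                    n_molecules = 0, init_region = c(2, 2, 7), psf = psf,
                    seed = 67)
  tr <- simulate_stationary_trace(cfg, mean_occupancy = 2)
  h <- length(tr$counts) / 2
  t1 <- photon_trace(tr$times[1:h], tr$counts[1:h])
  t2 <- photon_trace(tr$times[1:h], tr$counts[(h + 1):(2 * h)])
  f1 <- fit_fcs_model(autocorrelate(t1, max_lag_bins = 2000), psf)
  f2 <- fit_fcs_model(autocorrelate(t2, max_lag_bins = 2000), psf)
  expect_true(f1$converged && f2$converged)
  expect_lt(abs(log2(f1$D_hat / f2$D_hat)), 1)
})
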
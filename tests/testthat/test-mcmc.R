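test_that("posterior summaries behave on degenerate and symmetric draws", {
  base <- list(draws = data.frame(iteration = 1:200,
                                  D = rep(2.5, 200),
                                  mu_mol = rnorm(200, 100, 1),
                                  mu_back = rexp(200),
                                  n_active = rep(1L, 200)),
               n_components = 1L)
  class(base) <- "fcs_posterior"
  s <- summarize_posterior(base, "D")
  expect_equal(unname(s), c(2.5, 2.5, 2.5))
  # symmetric draws: median ~ mean
  set.seed(70)
  base$draws$mu_mol <- rnorm(200, 50, 4)
  s2 <- summarize_posterior(base, "mu_mol")
  expect_lt(abs(s2["median"] - mean(base$draws$mu_mol)), 4 * 4 / sqrt(200))
  expect_error(summarize_posterior(base, "bogus"), "unknown parameter")
  short <- base; short$draws <- base$draws[1:50, ]
  expect_error(summarize_posterior(short, "D"), "at least 100")
})

test_that("chains are reproducible for a fixed seed", {
  psf <- std_psf()
  cfg <- sim_config(K = 150, n_molecules = 1, init_region = tight_box(),
                    seed = 71)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  priors <- prior_config(N_model = 3)
  p1 <- run_mcmc(tr, psf, priors, n_iter = 120, n_burn = 20, seed = 5)
  p2 <- run_mcmc(tr, psf, priors, n_iter = 120, n_burn = 20, seed = 5)
  expect_identical(p1$draws, p2$draws)
})

test_that("a near-empty trace returns the priors", {
  # K = 1 and zero counts: only the first bin's likelihood is present and
  # every increment-driven conditional collapses to its prior
  psf <- std_psf()
  priors <- calib_priors(N_model = 2)
  tr <- photon_trace(1e-4, 0L)
  set.seed(72)
  post <- run_mcmc(tr, psf, priors, n_iter = 4000, n_burn = 500, seed = 72)
  d <- post$draws$D
  # quantile agreement with the inverse-gamma prior
  qs <- quantile(d, c(0.25, 0.5, 0.75))
  iq <- 1 / qgamma(c(0.75, 0.5, 0.25), shape = 5, rate = 20)
  expect_lt(max(abs(log(qs / iq))), 0.2)
  ksm <- suppressWarnings(stats::ks.test(post$draws$mu_mol, stats::pgamma,
                                         shape = 4, rate = 1e-4))
  expect_lt(unname(ksm$statistic), 0.05)
})

test_that("active-population estimates respect the truncation and find bursts", {
  psf <- std_psf()
  set.seed(73)
  # a single-molecule burst trace, with the brightness scale pinned so the
  # molecule count is identified (unknown brightness and count trade off)
  cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, K = 1000,
                    n_molecules = 1, init_region = tight_box(), seed = 74)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  priors <- prior_config(N_model = 6, mu_mol_shape = 100, mu_mol_rate = 2e-3)
  post <- run_mcmc(tr, psf, priors, n_iter = 1500, seed = 75)
  pop <- estimate_active_population(post)
  expect_equal(sum(pop), 1)
  expect_true(all(as.integer(names(pop)) <= 6))
  expect_identical(names(pop)[which.max(pop)], "1")
  # pure background: mode at zero
  cfg0 <- sim_config(mu_back = 1e3, K = 400, n_molecules = 0, seed = 76)
  tr0 <- simulate_trace(cfg0, keep_trajectories = FALSE)
  post0 <- run_mcmc(tr0, psf, priors, n_iter = 800, seed = 77)
  pop0 <- estimate_active_population(post0)
  expect_identical(names(pop0)[which.max(pop0)], "0")
})

test_that("all reported rates and D stay strictly positive", {
  psf <- std_psf()
  cfg <- sim_config(K = 200, n_molecules = 1, init_region = tight_box(),
                    seed = 78)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  post <- run_mcmc(tr, psf, prior_config(N_model = 4), n_iter = 300,
                   n_burn = 100, seed = 79)
  expect_true(all(post$draws$D > 0))
  expect_true(all(post$draws$mu_mol > 0))
  expect_true(all(post$draws$mu_back > 0))
  expect_true(all(post$draws$n_active >= 0 & post$draws$n_active <= 4))
})

test_that("the multi-component sampler reduces to the single-D law", {
  psf <- std_psf()
  cfg <- sim_config(K = 120, n_molecules = 1, init_region = tight_box(),
                    seed = 80)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  priors <- prior_config(N_model = 3)
  p1 <- run_mcmc(tr, psf, priors, n_iter = 150, n_burn = 50, seed = 9)
  p2 <- run_mcmc_multi_d(tr, psf, priors, n_components = 1,
                         n_iter = 150, n_burn = 50, seed = 9)
  expect_equal(p1$draws$D, p2$draws$D)
  expect_equal(p1$draws$mu_back, p2$draws$mu_back)
})

test_that("posterior draws can be persisted as delimited text", {
  psf <- std_psf()
  cfg <- sim_config(K = 100, n_molecules = 0, seed = 81)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  post <- run_mcmc(tr, psf, prior_config(N_model = 2), n_iter = 150,
                   n_burn = 50, seed = 10)
  f <- withr::local_tempfile(fileext = ".txt")
  write_posterior(post, f)
  back <- read.table(f, header = TRUE, comment.char = "#")
  expect_equal(nrow(back), nrow(post$draws))
  expect_equal(back$D, post$draws$D)
})

test_that("run_mcmc validates its arguments", {
  psf <- std_psf()
  tr <- photon_trace(numeric(0), integer(0))
  expect_error(run_mcmc(tr, psf, prior_config(), n_iter = 10), "non-empty")
  tr2 <- photon_trace(1e-4 * (1:5), rep(0L, 5))
  expect_error(run_mcmc(tr2, psf, prior_config(), n_iter = 10, n_burn = 10),
               "n_iter > n_burn")
})
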
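# Oracle checks for the individual conditional updates of the sampler.

test_that("loads under a flat likelihood reproduce the Beta-Bernoulli mean", {
  # empty trace: the likelihood ratio is 1, so after many load/weight sweeps
  # E[sum b] = N * A_q / (A_q + B_q)
  psf <- std_psf()
  priors <- prior_config(N_model = 8, A_q = 1, B_q = 3)  # E = 2
  tr <- photon_trace(numeric(0), integer(0))
  set.seed(42)
  st <- init_state(tr, psf, priors)
  tot <- 0; M <- 3000
  for (i in 1:M) {
    st <- sample_loads(st, tr, psf, priors)
    tot <- tot + sum(st$loads)
  }
  # chain of iid Bernoulli sweeps; se ~ sqrt(N p(1-p) / M)
  expect_lt(abs(tot / M - 2), 5 * sqrt(8 * 0.25 * 0.75 / M))
})

test_that("loads concentrate at zero on a pure-background trace", {
  psf <- std_psf()
  priors <- prior_config(N_model = 5, A_q = 1, B_q = 9,
                         mu_back_shape = 1, mu_back_rate = 1e-3)
  set.seed(43)
  cfg <- sim_config(mu_back = 1e3, K = 1000, n_molecules = 0, seed = 17)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  st <- init_state(tr, psf, priors)
  st$mu_back <- 1e3  # held at truth for this check
  tot <- 0; M <- 400
  for (i in 1:M) {
    st <- sample_trajectories(st, tr, psf, priors)
    st <- sample_loads(st, tr, psf, priors)
    tot <- tot + sum(st$loads)
  }
  expect_lt(tot / M, 0.6)  # prior alone would give 0.5 active
})

test_that("two molecules with identical trajectories get equal activation rates", {
  psf <- std_psf()
  priors <- prior_config(N_model = 2, A_q = 1, B_q = 1)
  set.seed(44)
  K <- 100
  cfg <- sim_config(K = K, n_molecules = 1, init_region = tight_box(),
                    seed = 3)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  st0 <- init_state(tr, psf, priors)
  st0$traj[[2]] <- st0$traj[[1]]  # identical copies
  st0$loads[] <- 0L
  st0 <- bnpfcs:::refresh_psf_cache(st0, psf)
  # one load sweep from the same all-off state, many times: the two
  # molecules must be activated equally often
  counts <- c(0, 0); M <- 2000
  for (i in 1:M) {
    st <- sample_loads(st0, tr, psf, priors)
    counts <- counts + st$loads
  }
  p <- counts / M
  expect_lt(abs(p[1] - p[2]), 5 * sqrt(0.5 / M))
})

test_that("diffusion conditional matches the closed form and a grid oracle", {
  psf <- std_psf()
  priors <- prior_config(N_model = 1, D_shape = 3, D_scale = 12)
  dt <- 1e-4; K <- 11   # 10 increments per axis
  set.seed(45)
  traj <- matrix(cumsum(rnorm(3 * K, sd = sqrt(2 * 7 * dt))), K, 3)
  # make the three axes independent random walks
  traj <- apply(matrix(rnorm(3 * K, sd = sqrt(2 * 7 * dt)), K, 3), 2, cumsum)
  st <- fcs_state(D = 5, mu_mol = 5e4, mu_back = 1e3, loads = 1L, q = 0.5,
                  traj = list(traj), dtvec = rep(dt, K))
  ssq <- sum(diff(traj)^2) / (4 * dt)
  M <- 3 * (K - 1)
  # empirical mean of the update vs the inverse-gamma mean
  set.seed(46)
  draws <- replicate(20000, sample_diffusion(st, priors)$D)
  ig_mean <- (priors$D_scale + ssq) / (priors$D_shape + M / 2 - 1)
  expect_lt(abs(mean(draws) / ig_mean - 1), 0.03)

  # grid oracle: unnormalised posterior density on a grid
  grid <- seq(0.5, 60, length.out = 4000)
  logpost <- -(priors$D_shape + M / 2 + 1) * log(grid) -
    (priors$D_scale + ssq) / grid
  post <- exp(logpost - max(logpost)); post <- post / sum(post)
  grid_mean <- sum(grid * post)
  expect_lt(abs(mean(draws) / grid_mean - 1), 0.03)

  # all-zero increments push the scale to the prior scale
  st0 <- st; st0$traj[[1]] <- matrix(0.2, K, 3)
  set.seed(47)
  d0 <- replicate(20000, sample_diffusion(st0, priors)$D)
  expect_lt(abs(mean(d0) / (priors$D_scale / (priors$D_shape + M / 2 - 1)) - 1),
            0.05)
})

test_that("diffusion conditional concentrates near truth with many increments", {
  priors <- prior_config(D_shape = 2, D_scale = 10)
  dt <- 1e-4; K <- round(1e5 / 3) + 1
  set.seed(48)
  traj <- apply(matrix(rnorm(3 * K, sd = sqrt(2 * 10 * dt)), K, 3), 2, cumsum)
  st <- fcs_state(D = 3, mu_mol = 5e4, mu_back = 1e3, loads = 1L, q = 0.5,
                  traj = list(traj), dtvec = rep(dt, K))
  d <- replicate(50, sample_diffusion(st, priors)$D)
  expect_lt(abs(mean(d) / 10 - 1), 0.02)
})

test_that("rate updates reduce to Poisson-gamma conjugacy with no active molecule", {
  psf <- std_psf()
  priors <- prior_config(N_model = 2, mu_back_shape = 2, mu_back_rate = 2e-3,
                         mu_mol_shape = 3, mu_mol_rate = 1e-4)
  set.seed(49)
  K <- 500; dt <- 1e-4
  w <- rpois(K, 0.2)
  tr <- photon_trace(dt * (1:K), w)
  st <- init_state(tr, psf, priors)   # loads start at zero
  Svals <- replicate(20000, {
    s2 <- sample_rates(st, tr, psf, priors)
    c(s2$mu_back, s2$mu_mol)
  })
  S <- sum(w); T <- K * dt
  # background: gamma(shape + S, rate + T)
  expect_lt(abs(mean(Svals[1, ]) / ((2 + S) / (2e-3 + T)) - 1), 0.02)
  ks <- suppressWarnings(
    stats::ks.test(Svals[1, ], stats::pgamma, shape = 2 + S, rate = 2e-3 + T))
  expect_lt(unname(ks$statistic), 0.02)
  # brightness: equals its prior distributionally
  ks2 <- suppressWarnings(
    stats::ks.test(Svals[2, ], stats::pgamma, shape = 3, rate = 1e-4))
  expect_lt(unname(ks2$statistic), 0.02)
})

test_that("inactive trajectories are refreshed from the prior and leave the likelihood unchanged", {
  psf <- std_psf()
  priors <- prior_config(N_model = 2)
  set.seed(50)
  cfg <- sim_config(K = 80, n_molecules = 1, seed = 51)
  tr <- simulate_trace(cfg, keep_trajectories = FALSE)
  st <- init_state(tr, psf, priors)  # both inactive
  ll0 <- log_likelihood(st, tr, psf)
  st2 <- sample_trajectories(st, tr, psf, priors)
  expect_false(identical(st$traj[[1]], st2$traj[[1]]))  # redrawn
  expect_equal(log_likelihood(st2, tr, psf), ll0)       # no effect
})

test_that("a bright static molecule's inferred PSF value matches rate inversion", {
  # single active molecule pinned near the centre with high counts: the
  # posterior of PSF(position) concentrates near the value implied by the
  # observed mean rate (grid-inversion oracle).
  psf <- std_psf()
  set.seed(52)
  K <- 400; dt <- 1e-4
  true_pos <- c(0.12, -0.08, 0.3)
  p_true <- evaluate_psf(psf, true_pos[1], true_pos[2], true_pos[3])
  mu_mol <- 2e5; mu_back <- 1e3
  w <- rpois(K, dt * (mu_back + mu_mol * p_true))
  tr <- photon_trace(dt * (1:K), w)
  # D prior pushed to tiny values -> effectively static molecule
  priors <- prior_config(N_model = 1, A_q = 9, B_q = 1,
                         D_shape = 20, D_scale = 0.02,
                         mu_mol_shape = 400, mu_mol_rate = 2e-3,   # tight at 2e5
                         mu_back_shape = 400, mu_back_rate = 0.4)  # tight at 1e3
  st <- init_state(tr, psf, priors)
  st$loads[1] <- 1L
  ctl <- mcmc_control(adapt = FALSE)
  ps <- numeric(600)
  for (i in 1:600) {
    st <- sample_trajectories(st, tr, psf, priors, ctl)
    st <- sample_diffusion(st, priors)
    P <- bnpfcs:::get_psf_matrix(st, psf)
    ps[i] <- mean(P[, 1])
  }
  est <- median(ps[301:600])
  # oracle: invert the observed mean count rate
  p_hat <- (mean(w) / dt - mu_back) / mu_mol
  expect_lt(abs(est - p_hat) / p_hat, 0.25)
})
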
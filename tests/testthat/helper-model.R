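# Shared fixtures: the standard confocal geometry used across the tests and
# a couple of small builders.

std_psf <- function() confocal_psf("gaussian3d", omega_xy = 0.3, omega_z = 1.5)

# tight initial box realising "n molecules inside the effective volume"
tight_box <- function(psf = std_psf()) c(psf$omega_xy, psf$omega_xy, psf$omega_z)

# small prior set with finite low-order moments, used by calibration checks
calib_priors <- function(N_model = 2) {
  prior_config(N_model = N_model, A_q = 1, B_q = 1,
               D_shape = 5, D_scale = 20,
               mu_mol_shape = 4, mu_mol_rate = 1e-4,
               mu_back_shape = 3, mu_back_rate = 3e-3)
}

# effective sample size (initial positive-autocorrelation estimator)
ess_of <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  r <- stats::acf(x, lag.max = min(n - 1L, 300L), plot = FALSE)$acf[-1]
  s <- 0; k <- 1
  while (k <= length(r) && r[k] > 0.05) { s <- s + r[k]; k <- k + 1 }
  n / (1 + 2 * s)
}
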
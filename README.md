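# bnpfcs

Bayesian non-parametric analysis of photon-count traces from single-focus
confocal microscopy, with a classical FCS baseline for comparison.

## The problem

Fluorescence correlation spectroscopy (FCS) estimates diffusion
coefficients by autocorrelating the fluorescence intensity recorded while
molecules diffuse through a confocal volume, then fitting a closed-form
decay. That route needs seconds to minutes of data. The same physical
information — how long bursts last, how bright they are, how often they
recur — is already present in a few hundred milliseconds of binned photon
counts, if the counts are modelled directly.

`bnpfcs` implements that direct route. The observed counts are Poisson,

    w_k ~ Poisson( dt * ( mu_back + sum_n b_n * mu_mol * PSF(x_k^n, y_k^n, z_k^n) ) ),

with free Brownian motion for the latent molecule positions
(per-axis increment variance `2 D dt`) and a Beta–Bernoulli prior on the
binary loads `b_n`, so the number of contributing molecules is inferred
rather than fixed. A Markov chain Monte Carlo engine returns joint
posterior samples over the diffusion coefficient `D`, the molecular
brightness `mu_mol`, the background rate `mu_back`, the active molecule
count and the latent trajectories — from a single short trace.

The package contains:

* `simulate_trace()` / `simulate_stationary_trace()` — forward simulators
  (the exact generative model; a reservoir variant for long stationary
  recordings);
* `run_mcmc()` / `run_mcmc_multi_d()` — posterior sampling, single or
  multiple diffusion components;
* `autocorrelate()` / `fit_fcs_model()` — multi-tau correlator and the
  standard FCS diffusion-model fit;
* `compare_data_efficiency()` — head-to-head trace-length comparison of
  the two routes;
* `bin_timestamps()`, `read_trace()`/`write_trace()`, `read_run_config()`
  and a thin command-line tool (`exec/bnpfcs`) with subcommands
  `simulate`, `infer`, `fcs`, `compare`, `fixtures`.

## Worked example

Simulate the standard validation condition — five molecules inside the
effective volume of a 3D Gaussian confocal PSF (omega_xy = 0.3 um,
omega_z = 1.5 um), brightness 5e4 photons/s against a background of
1e3 photons/s, 100 us bins for 100 ms — then recover the parameters:

```r
library(bnpfcs)

psf <- confocal_psf("gaussian3d", omega_xy = 0.3, omega_z = 1.5)
cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4,
                  K = 1000, n_molecules = 5, psf = psf,
                  init_region = c(0.3, 0.3, 1.5), seed = 1)
trace <- simulate_trace(cfg)
post  <- run_mcmc(trace, psf, prior_config(), n_iter = 3000, seed = 2)
post
```

```
Posterior samples: 1500 retained draws ( 3000 iterations, 1500 burn-in )
  D        median 9.45  95% CI [3.49, 21.47]
  mu_mol   median 1.159e+05  95% CI [7.841e+04, 2.483e+05]
  mu_back  median 1211  95% CI [982.4, 1436]
  active molecules: mode 2
```

The 95% credible interval for `D` covers the ground truth (10 um^2/s)
from a 0.1-second trace and the median sits within 6% of it; the
background interval is close to its 1e3 photons/s truth. The brightness
and active-count marginals illustrate an honest limitation of such short
traces: molecules that overlap inside the volume can be explained by
fewer, brighter emitters, so `mu_mol` runs high while the active count
runs low — the joint posterior spreads over these trade-offs rather than
hiding them (the methods vignette discusses this degeneracy). The
classical baseline on the same kind of data:

```r
curve <- autocorrelate(trace)
fit_fcs_model(curve, psf)     # needs far longer traces to stabilise
```

On a 5-second stationary recording (the acceptance script's FCS check,
seed 1) the baseline recovers `D_hat = 12.2 um^2/s` and an occupancy
`N_hat = 1.96` for a simulated mean occupancy of 2. On 0.05-second
segments both routes become unreliable — their trace-length requirements
are measured head-to-head by `compare_data_efficiency()`, and the methods
vignette discusses why the posterior route's short-trace advantage is
modest under weakly-informative priors.

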
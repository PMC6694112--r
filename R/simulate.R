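#' Simulation configuration
#'
#' Bundles everything the forward model needs: the diffusion coefficient,
#' molecular brightness and background rate, the binning, the number of
#' molecules, the PSF and the initial-position region.  Defaults follow the
#' standard single-molecule confocal regime: 100 us bins over 100 ms, a
#' brightness of 5e4 photons/s against a background of 1e3 photons/s, and a
#' 3D Gaussian confocal volume with omega_xy = 0.3 um, omega_z = 1.5 um.
#'
#' @param D diffusion coefficient, um^2/s (> 0, or 0 for static molecules).
#' @param mu_mol molecular brightness: detected photon rate of one molecule
#'   at the centre of the confocal volume, photons/s.
#' @param mu_back background photon emission rate, photons/s (>= 0).
#' @param dt bin width, seconds.
#' @param K number of bins.
#' @param n_molecules number of simulated molecules (>= 0).
#' @param psf a \code{\link{confocal_psf}}.
#' @param init_region half-widths (x, y, z) of the uniform initial-position
#'   box, micrometres.  The default, four lateral / four axial PSF radii,
#'   is wide enough that the box edge has negligible effect on the photon
#'   statistics of 100 ms traces at typical diffusion coefficients.  Use
#'   half-widths comparable to (omega_xy, omega_xy, omega_z) to start the
#'   molecules "inside the effective volume".
#' @param substeps sub-steps per bin for the optional within-bin motion
#'   refinement (1 = positions evaluated once per bin, at the bin end; the
#'   discrete-time reference model).
#' @param seed integer seed; trajectory and count streams are derived from it
#'   so each is reproducible on its own.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(D = 10, mu_mol = 5e4, mu_back = 1e3,
                       dt = 1e-4, K = 1000, n_molecules = 1,
                       psf = confocal_psf("gaussian3d", 0.3, 1.5),
                       init_region = NULL, substeps = 1L, seed = NULL) {
  stopifnot(inherits(psf, "confocal_psf"))
  if (!is.numeric(D) || D < 0) stop("'D' must be non-negative")
  if (mu_mol <= 0) stop("'mu_mol' must be positive")
  if (mu_back < 0) stop("'mu_back' must be non-negative")
  if (dt <= 0) stop("'dt' must be positive")
  if (K < 1 || K != round(K)) stop("'K' must be a positive integer")
  if (n_molecules < 0 || n_molecules != round(n_molecules))
    stop("'n_molecules' must be a non-negative integer")
  if (is.null(init_region))
    init_region <- c(4 * psf$omega_xy, 4 * psf$omega_xy, 4 * psf_wz(psf))
  stopifnot(length(init_region) == 3, all(init_region > 0))
  structure(list(D = D, mu_mol = mu_mol, mu_back = mu_back, dt = dt,
                 K = as.integer(K), n_molecules = as.integer(n_molecules),
                 psf = psf, init_region = as.numeric(init_region),
                 substeps = as.integer(substeps), seed = seed),
            class = "sim_config")
}

# draw one free Brownian path: K x 3 matrix of positions at the bin ends
draw_trajectory <- function(K, D, dtvec, init_region) {
  if (K == 0) return(matrix(numeric(0), 0, 3))
  x0 <- runif(3, -init_region, init_region)
  if (K == 1) return(matrix(x0, nrow = 1))
  sd <- sqrt(2 * D * dtvec[-1])
  incr <- matrix(rnorm(3 * (K - 1), sd = rep(sd, 3)), ncol = 3)
  pos <- rbind(x0, sweep(apply(incr, 2, cumsum), 2, x0, `+`))
  dimnames(pos) <- NULL
  unname(pos)
}

#' Simulate free Brownian molecule trajectories
#'
#' Initial positions are uniform over the configured box; each subsequent
#' per-axis increment is an independent zero-mean Gaussian with variance
#' \code{2 * D * dt}.  Motion is free: there are no spatial boundaries.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list of \code{n_molecules} matrices of size \code{K x 3}
#'   (columns x, y, z, micrometres; row k is the position at time t_k).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dtvec <- rep(config$dt, config$K)
  lapply(seq_len(config$n_molecules), function(n)
    draw_trajectory(config$K, config$D, dtvec, config$init_region))
}

#' Instantaneous emission rate of one molecule
#'
#' \code{load * mu_mol * PSF(x, y, z)}: an inactive molecule
#' (\code{load = 0}) emits nothing regardless of position.
#'
#' @param psf a \code{\link{confocal_psf}}.
#' @param mu_mol molecular brightness, photons/s.
#' @param load 0 or 1.
#' @param x,y,z position, micrometres.
#' @return detected photon emission rate, photons/s.
#' @export
emission_rate <- function(psf, mu_mol, load, x, y, z) {
  stopifnot(mu_mol > 0, all(load %in% c(0, 1)))
  load * mu_mol * evaluate_psf(psf, x, y, z)
}

#' Simulate binned photon counts given trajectories
#'
#' Bin k's count is Poisson with mean
#' \code{dt * (mu_back + sum_n load_n * mu_mol * PSF(pos_n[k, ]))}, i.e. shot
#' noise around the PSF-modulated rates; draws are independent across bins
#' given the rates.
#'
#' @param trajectories list of \code{K x 3} position matrices.
#' @param loads binary vector, one per trajectory (default: all 1).
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{photon_trace}}.
#' @export
simulate_counts <- function(trajectories, loads = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(loads)) loads <- rep(1L, length(trajectories))
  stopifnot(length(loads) == length(trajectories), all(loads %in% c(0, 1)))
  K <- config$K
  for (traj in trajectories)
    if (nrow(traj) != K) stop("all trajectories must have K positions")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  S <- numeric(K)
  for (i in seq_along(trajectories))
    if (loads[i] == 1) S <- S + psf_values(config$psf, trajectories[[i]])
  rate <- config$dt * (config$mu_back + config$mu_mol * S)
  photon_trace(times = config$dt * seq_len(K), counts = rpois(K, rate))
}

#' Simulate a complete photon trace
#'
#' Convenience wrapper: draws trajectories and counts under one
#' configuration.  With \code{substeps > 1} the motion is sub-resolved within
#' each bin and the bin rate uses the average PSF value over the sub-steps,
#' for fidelity studies of the discrete-time approximation; the returned
#' trajectories are still reported at the bin ends.
#'
#' @param config a \code{\link{sim_config}}.
#' @param keep_trajectories return the latent trajectories alongside the
#'   trace.
#' @return a \code{\link{photon_trace}}; if \code{keep_trajectories}, the
#'   trajectories and ground-truth parameters are attached as attributes
#'   \code{"trajectories"} and \code{"truth"}.
#' @examples
#' cfg <- sim_config(D = 10, K = 200, n_molecules = 1, seed = 7)
#' tr <- simulate_trace(cfg)
#' @export
simulate_trace <- function(config, keep_trajectories = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$substeps > 1L) return(simulate_trace_substepped(config,
                                                             keep_trajectories))
  trajs <- simulate_trajectories(config)
  trace <- simulate_counts(trajs, config = config)
  if (keep_trajectories) {
    attr(trace, "trajectories") <- trajs
    attr(trace, "truth") <- config[c("D", "mu_mol", "mu_back", "n_molecules")]
  }
  trace
}

simulate_trace_substepped <- function(config, keep_trajectories) {
  m <- config$substeps
  fine <- sim_config(D = config$D, mu_mol = config$mu_mol,
                     mu_back = config$mu_back, dt = config$dt / m,
                     K = config$K * m, n_molecules = config$n_molecules,
                     psf = config$psf, init_region = config$init_region,
                     seed = config$seed)
  trajs <- simulate_trajectories(fine)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  S <- numeric(fine$K)
  for (traj in trajs) S <- S + psf_values(config$psf, traj)
  # average the PSF-modulated rate over the m sub-steps of each bin
  S_bin <- colMeans(matrix(S, nrow = m))
  rate <- config$dt * (config$mu_back + config$mu_mol * S_bin)
  trace <- photon_trace(times = config$dt * seq_len(config$K),
                        counts = rpois(config$K, rate))
  if (keep_trajectories) {
    ends <- seq(m, fine$K, by = m)
    attr(trace, "trajectories") <- lapply(trajs, function(p) p[ends, , drop = FALSE])
    attr(trace, "truth") <- config[c("D", "mu_mol", "mu_back", "n_molecules")]
  }
  trace
}

#' Simulate a long stationary trace from a dilute molecular reservoir
#'
#' For traces lasting many volume-crossing times, a fixed set of free paths
#' started near the confocal volume drifts away and the signal dies out.
#' This generator emulates a dilute solution at equilibrium instead:
#' \code{n_molecules} independent Brownian paths live in a box much larger
#' than the confocal volume and wrap periodically at its faces, so the
#' occupancy of the confocal region is statistically stationary for
#' arbitrarily long traces.  Only the summed PSF signal is kept, so memory
#' stays O(K) regardless of the molecule count.
#'
#' @param config a \code{\link{sim_config}}; \code{init_region} is reused as
#'   the reservoir box half-widths and should be much larger than the PSF.
#' @param mean_occupancy if not \code{NULL}, overrides \code{n_molecules} so
#'   the expected number of molecules in the effective volume equals this
#'   value (3D Gaussian PSF only).
#' @return a \code{\link{photon_trace}} with attribute \code{"truth"}.
#' @export
simulate_stationary_trace <- function(config, mean_occupancy = NULL) {
  stopifnot(inherits(config, "sim_config"))
  box <- config$init_region
  n <- config$n_molecules
  if (!is.null(mean_occupancy)) {
    conc <- mean_occupancy / effective_volume(config$psf)
    n <- max(1L, round(conc * prod(2 * box)))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- cpp_sum_psf_paths(n, config$K, config$D, config$dt, box,
                         psf_variant_code(config$psf),
                         config$psf$omega_xy, psf_wz(config$psf))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  rate <- config$dt * (config$mu_back + config$mu_mol * S)
  trace <- photon_trace(times = config$dt * seq_len(config$K),
                        counts = rpois(config$K, rate))
  attr(trace, "truth") <- list(D = config$D, mu_mol = config$mu_mol,
                               mu_back = config$mu_back, n_molecules = n)
  trace
}
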
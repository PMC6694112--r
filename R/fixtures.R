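#' Generate the reference grid of synthetic traces
#'
#' Writes the full grid of simulation conditions used throughout the
#' package's validation studies, with a manifest recording every
#' ground-truth parameter:
#' \itemize{
#'   \item molecule-number pair: 1 and 5 molecules inside the effective
#'     volume, otherwise identical (D = 10 um^2/s, brightness 5e4,
#'     background 1e3 photons/s, 100 us bins, 100 ms);
#'   \item diffusion grid: D = 0.01, 0.1, 1, 10, 100 um^2/s, cut from
#'     continuous dilute recordings;
#'   \item trace-length grid: nested segments of 5e2, 1e3, 5e3, 1e4, 5e4
#'     bins cut from one long stationary trace (capped by
#'     \code{max_length_bins});
#'   \item brightness grid: 1e4, 5e4, 1e5 photons/s over the same molecular
#'     trajectories (only the count draw differs).
#' }
#' All conditions use a 3D Gaussian PSF with omega_xy = 0.3 um and
#' omega_z = 1.5 um.  "n molecules inside the effective volume" is realised
#' exactly under the model: n free Brownian molecules whose initial
#' positions are uniform over the tight box of half-widths
#' (omega_xy, omega_xy, omega_z).  The long continuous recordings use the
#' stationary reservoir generator at mean occupancy 1.
#'
#' @param output_dir writable directory (created if missing).
#' @param seed integer root seed; each condition derives its own stream.
#' @param max_length_bins cap on the trace-length grid (default 5e4; lower
#'   it for quick runs).
#' @return invisibly, the manifest data frame (also written as
#'   \code{manifest.csv}).
#' @export
make_fixture_traces <- function(output_dir, seed = 1L,
                                max_length_bins = 50000L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  psf <- confocal_psf("gaussian3d", 0.3, 1.5)
  tight <- c(psf$omega_xy, psf$omega_xy, psf$omega_z)
  box <- c(2, 2, 7)
  rows <- list()
  add <- function(file, condition, n_molecules, D, mu_mol, mu_back, dt, K,
                  sd) {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, condition = condition, n_molecules = n_molecules,
      D = D, mu_mol = mu_mol, mu_back = mu_back, dt = dt, K = K, seed = sd)
  }

  # molecule-number pair: exact-model traces, 1 vs 5 molecules in the volume
  for (n in c(1L, 5L)) {
    sd <- seed + 100L + n
    cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4,
                      K = 1000L, n_molecules = n, psf = psf,
                      init_region = tight, seed = sd)
    f <- sprintf("molecules_n%d.txt", n)
    write_trace(simulate_trace(cfg, keep_trajectories = FALSE),
                file.path(output_dir, f),
                header = list(D = 10, mu_mol = 5e4, mu_back = 1e3,
                              n_molecules = n, seed = sd))
    add(f, "molecule_number", n, 10, 5e4, 1e3, 1e-4, 1000L, sd)
  }

  # diffusion-coefficient grid: dilute continuous recordings
  for (D in c(0.01, 0.1, 1, 10, 100)) {
    sd <- seed + 200L + round(100 * log10(D))
    cfg <- sim_config(D = D, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4,
                      K = 1000L, n_molecules = 0L, psf = psf,
                      init_region = box, seed = sd)
    tr <- simulate_stationary_trace(cfg, mean_occupancy = 1)
    f <- sprintf("diffusion_D%g.txt", D)
    write_trace(tr, file.path(output_dir, f),
                header = list(D = D, mu_mol = 5e4, mu_back = 1e3, seed = sd))
    add(f, "diffusion", attr(tr, "truth")$n_molecules, D, 5e4, 1e3, 1e-4,
        1000L, sd)
  }

  # trace-length grid: nested segments of one long stationary trace
  lengths <- c(500L, 1000L, 5000L, 10000L, 50000L)
  lengths <- lengths[lengths <= max_length_bins]
  sd <- seed + 300L
  cfg <- sim_config(D = 10, mu_mol = 5e4, mu_back = 1e3, dt = 1e-4,
                    K = max(lengths), n_molecules = 0L, psf = psf,
                    init_region = box, seed = sd)
  long <- simulate_stationary_trace(cfg, mean_occupancy = 1)
  n_res <- attr(long, "truth")$n_molecules
  for (Ki in lengths) {
    f <- sprintf("length_K%d.txt", Ki)
    seg <- photon_trace(long$times[seq_len(Ki)], long$counts[seq_len(Ki)])
    write_trace(seg, file.path(output_dir, f),
                header = list(D = 10, mu_mol = 5e4, mu_back = 1e3,
                              seed = sd))
    add(f, "trace_length", n_res, 10, 5e4, 1e3, 1e-4, Ki, sd)
  }

  # brightness grid over the same molecular trajectories: the path stream
  # is fixed by the shared seed, only mu_mol differs between the traces
  sd <- seed + 400L
  for (mu in c(1e4, 5e4, 1e5)) {
    cfg <- sim_config(D = 10, mu_mol = mu, mu_back = 1e3, dt = 1e-4,
                      K = 1000L, n_molecules = 1L, psf = psf,
                      init_region = tight, seed = sd)
    f <- sprintf("brightness_mu%g.txt", mu)
    write_trace(simulate_trace(cfg, keep_trajectories = FALSE),
                file.path(output_dir, f),
                header = list(D = 10, mu_mol = mu, mu_back = 1e3, seed = sd))
    add(f, "brightness", 1L, 10, mu, 1e3, 1e-4, 1000L, sd)
  }

  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
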
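#' Normalised intensity autocorrelation of a photon trace
#'
#' Computes \eqn{G(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle /
#' \langle F\rangle^2} with \eqn{\delta F = F - \langle F\rangle}, excluding
#' the zero-lag shot-noise point.  The default estimator is the multi-tau
#' scheme used by hardware correlators: a fixed number of linear lags per
#' octave, with the series coarsened by a factor of two between octaves, and
#' symmetric normalisation (the means of the two overlapping segments).  A
#' direct linear-lag estimator is kept for small exact checks.
#'
#' @param trace a \code{\link{photon_trace}} with at least
#'   \code{2 * max_lag_bins} bins.
#' @param max_lag_bins largest lag, in bins (default \code{K / 4}).
#' @param method \code{"multitau"} or \code{"direct"}.
#' @param points_per_octave linear lags per octave of the multi-tau scheme.
#' @return a data frame of class \code{fcs_curve} with columns \code{lag}
#'   (seconds) and \code{G} (dimensionless).
#' @examples
#' tr <- photon_trace((1:4), c(2, 0, 2, 0))
#' autocorrelate(tr, max_lag_bins = 2, method = "direct")  # G(1) = -1
#' @export
autocorrelate <- function(trace, max_lag_bins = NULL,
                          method = c("multitau", "direct"),
                          points_per_octave = 8L) {
  stopifnot(inherits(trace, "photon_trace"))
  method <- match.arg(method)
  F <- as.numeric(trace$counts)
  K <- length(F)
  if (is.null(max_lag_bins)) max_lag_bins <- max(1L, K %/% 4L)
  if (K < 2L * max_lag_bins)
    stop("trace too short: need K >= 2 * max_lag_bins")
  if (all(F == 0))
    stop("all-zero trace: autocorrelation normalisation undefined")
  dt <- median(diff(trace$times))

  if (method == "direct") {
    lags <- seq_len(max_lag_bins)
    G <- vapply(lags, function(l) corr_at_lag(F, l), numeric(1))
  } else {
    m <- as.integer(points_per_octave)
    lags <- integer(0); G <- numeric(0)
    series <- F
    level <- 0L
    repeat {
      cand <- if (level == 0L) seq_len(2L * m) else (m + 1L):(2L * m)
      for (l in cand) {
        lag_bins <- l * 2L^level
        if (lag_bins > max_lag_bins || l >= length(series)) next
        lags <- c(lags, lag_bins)
        G <- c(G, corr_at_lag(series, l))
      }
      if (2L * m * 2L^(level + 1L) > max_lag_bins) break
      n2 <- length(series) %/% 2L
      if (n2 < 2L * m + 2L) break
      series <- series[seq_len(2L * n2)]
      series <- series[c(TRUE, FALSE)] + series[c(FALSE, TRUE)]
      level <- level + 1L
    }
    o <- order(lags)
    lags <- lags[o]; G <- G[o]
  }
  structure(data.frame(lag = lags * dt, G = G),
            class = c("fcs_curve", "data.frame"),
            dt = dt, K = K, method = method)
}

# symmetric-normalisation correlation at one integer lag
corr_at_lag <- function(F, l) {
  n <- length(F)
  a <- F[1:(n - l)]
  b <- F[(1 + l):n]
  ma <- mean(a); mb <- mean(b)
  if (ma == 0 || mb == 0) return(NA_real_)
  mean(a * b) / (ma * mb) - 1
}

#' Fit the standard diffusion model to a correlation curve
#'
#' Least-squares fit of
#' \deqn{G(\tau) = G_0\,(1+\tau/\tau_D)^{-1}\,(1+\tau/(s^2\tau_D))^{-1/2}}
#' with aspect ratio \eqn{s = \omega_z/\omega_{xy}}; the axial factor is
#' dropped for the cylindrical PSF variant.  The diffusion coefficient is
#' recovered from the lateral diffusion time as
#' \eqn{\hat D = \omega_{xy}^2 / (4\tau_D)}.
#'
#' @param curve an \code{fcs_curve} from \code{\link{autocorrelate}} with at
#'   least 10 lags.
#' @param psf a \code{\link{confocal_psf}}.
#' @return a list of class \code{fcs_fit}: \code{D_hat} (um^2/s),
#'   \code{tau_D} (s), \code{G0}, \code{N_hat = 1/G0} (mean occupancy),
#'   \code{residual_norm} and \code{converged}.  Non-convergence is flagged,
#'   not raised.
#' @export
fit_fcs_model <- function(curve, psf) {
  stopifnot(inherits(curve, "fcs_curve"), inherits(psf, "confocal_psf"))
  ok <- is.finite(curve$G)
  tau <- curve$lag[ok]; G <- curve$G[ok]
  if (length(tau) < 10) stop("need at least 10 finite lags to fit")
  s2 <- if (psf$variant == "gaussian_cylindrical") Inf
        else (psf_wz(psf) / psf$omega_xy)^2

  G0_start <- max(mean(G[seq_len(min(3, length(G)))]), 1e-3)
  half <- which(G < G0_start / 2)
  tauD_start <- if (length(half) > 0) max(tau[half[1]], tau[1]) else median(tau)

  model <- if (is.finite(s2))
    G ~ G0 / ((1 + tau / tauD) * sqrt(1 + tau / (s2 * tauD)))
  else
    G ~ G0 / (1 + tau / tauD)
  fit <- tryCatch(
    minpack.lm::nlsLM(model,
                      data = list(G = G, tau = tau, s2 = s2),
                      start = list(G0 = G0_start, tauD = tauD_start),
                      lower = c(1e-12, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(D_hat = NA_real_, tau_D = NA_real_, G0 = NA_real_,
                N_hat = NA_real_, residual_norm = NA_real_,
                converged = FALSE, message = conditionMessage(fit))
    return(structure(out, class = "fcs_fit"))
  }
  cf <- coef(fit)
  tauD <- unname(cf["tauD"]); G0 <- unname(cf["G0"])
  structure(list(
    D_hat = psf$omega_xy^2 / (4 * tauD),
    tau_D = tauD, G0 = G0, N_hat = 1 / G0,
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    converged = TRUE, message = "converged"
  ), class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (!x$converged) {
    cat("FCS fit: NOT converged (", x$message, ")\n")
  } else {
    cat(sprintf(
      "FCS fit: D_hat = %.4g um^2/s (tau_D = %.4g s), G0 = %.4g, N_hat = %.3g\n",
      x$D_hat, x$tau_D, x$G0, x$N_hat))
  }
  invisible(x)
}

#' Data efficiency of posterior inference versus classical FCS
#'
#' Simulates replicate stationary traces at a known diffusion coefficient
#' and, walking the trace lengths in increasing order, estimates D by both
#' routes (posterior median from \code{\link{run_mcmc}};
#' \code{\link{autocorrelate}} + \code{\link{fit_fcs_model}}) on nested
#' initial segments of each replicate, mirroring how trace-length studies
#' cut a single recording.  A method "reaches factor-2 accuracy" at the
#' shortest length where its median \code{|log2(D_hat / true_D)|} over
#' replicates is at most 1; once a method has reached it, longer lengths
#' are not re-run for that method (they cannot change its minimal length).
#' The ratio of the two minimal lengths is the headline efficiency figure.
#' Failed FCS fits are scored as misses (infinite error), not dropped.
#'
#' @param true_D ground-truth diffusion coefficient, um^2/s.
#' @param sim_config a \code{\link{sim_config}} giving rates, binning and
#'   PSF; its \code{init_region} is used as the reservoir box.
#' @param trace_lengths increasing vector of lengths (bins).
#' @param n_replicates replicates per length.
#' @param seed integer seed.
#' @param mean_occupancy expected molecules in the effective volume for the
#'   stationary generator (default 1: the dilute single-molecule regime).
#' @param priors,n_iter,N_model sampler settings for the Bayesian route.
#' @return a data frame (length, method, median_abs_log2_error, n_fail)
#'   with attributes \code{min_length_bayes}, \code{min_length_fcs} (Inf if
#'   never reached) and \code{length_ratio}.
#' @export
compare_data_efficiency <- function(true_D, sim_config, trace_lengths,
                                    n_replicates = 5L, seed = 1L,
                                    mean_occupancy = 1,
                                    priors = NULL, n_iter = 600L,
                                    N_model = 10L) {
  stopifnot(inherits(sim_config, "sim_config"), length(trace_lengths) >= 2)
  trace_lengths <- sort(as.integer(trace_lengths))
  K_max <- max(trace_lengths)
  if (is.null(priors))
    priors <- prior_config(N_model = N_model)

  longs <- lapply(seq_len(n_replicates), function(r) {
    cfg <- sim_config
    cfg$D <- true_D
    cfg$K <- K_max
    cfg$seed <- seed + 7919L * r
    simulate_stationary_trace(cfg, mean_occupancy = mean_occupancy)
  })

  rows <- list()
  min_len <- c(bayes = Inf, fcs = Inf)
  for (i in seq_along(trace_lengths)) {
    Ki <- trace_lengths[i]
    segs <- lapply(longs, function(long)
      photon_trace(long$times[seq_len(Ki)], long$counts[seq_len(Ki)]))
    for (m in c("bayes", "fcs")) {
      if (is.finite(min_len[m])) next
      errs <- vapply(seq_len(n_replicates), function(r) {
        if (m == "bayes") {
          post <- run_mcmc(segs[[r]], sim_config$psf, priors,
                           n_iter = n_iter,
                           seed = seed + 104729L * r + i)
          abs(log2(summarize_posterior(post, "D")["median"] / true_D))
        } else {
          fcs_D <- tryCatch({
            fit <- fit_fcs_model(autocorrelate(segs[[r]]), sim_config$psf)
            if (fit$converged && is.finite(fit$D_hat) && fit$D_hat > 0)
              fit$D_hat else NA_real_
          }, error = function(e) NA_real_)
          if (is.na(fcs_D)) Inf else abs(log2(fcs_D / true_D))
        }
      }, numeric(1))
      med <- median(errs)
      rows[[length(rows) + 1L]] <- data.frame(
        length = Ki, method = m, median_abs_log2_error = med,
        n_fail = sum(!is.finite(errs)))
      if (med <= 1) min_len[m] <- Ki
    }
  }

  out <- do.call(rbind, rows)
  attr(out, "min_length_bayes") <- unname(min_len["bayes"])
  attr(out, "min_length_fcs") <- unname(min_len["fcs"])
  attr(out, "length_ratio") <- unname(min_len["fcs"] / min_len["bayes"])
  out
}

#' Write a correlation curve as two-column delimited text
#'
#' @param curve an \code{fcs_curve}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bnpfcs correlation curve", "# lag_s G"), con)
  writeLines(sprintf("%.17g %.17g", curve$lag, curve$G), con)
  invisible(path)
}
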
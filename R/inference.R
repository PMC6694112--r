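#' Construct a latent state of the model
#'
#' A latent state holds one full configuration of the unknowns: the
#' diffusion coefficient(s) \code{D}, the molecular brightness
#' \code{mu_mol}, the background rate \code{mu_back}, the binary loads
#' \code{b_n} with their Beta-Bernoulli weights \code{q_n}, the component
#' assignments (for the multiple-diffusion-coefficient variant) and one
#' trajectory per model molecule.
#'
#' @param D vector of diffusion coefficients, one per component, um^2/s.
#' @param mu_mol molecular brightness, photons/s.
#' @param mu_back background rate, photons/s.
#' @param loads integer 0/1 vector, one per model molecule.
#' @param q load weights in (0, 1), one per model molecule.
#' @param traj list of \code{K x 3} position matrices, one per molecule.
#' @param dtvec bin widths \code{t_k - t_{k-1}}, seconds (length K).
#' @param comp component assignment per molecule (default: all 1).
#' @return an object of class \code{fcs_state}.
#' @export
fcs_state <- function(D, mu_mol, mu_back, loads, q, traj, dtvec,
                      comp = rep(1L, length(loads))) {
  N <- length(loads)
  stopifnot(length(q) == N, length(traj) == N, length(comp) == N,
            all(D > 0), mu_mol > 0, mu_back >= 0,
            all(loads %in% c(0L, 1L)), all(q > 0 & q < 1),
            all(comp >= 1 & comp <= length(D)))
  K <- length(dtvec)
  for (p in traj) stopifnot(nrow(p) == K)
  structure(list(D = as.numeric(D), comp = as.integer(comp),
                 mu_mol = mu_mol, mu_back = mu_back,
                 loads = as.integer(loads), q = as.numeric(q),
                 traj = traj, dtvec = as.numeric(dtvec), K = as.integer(K)),
            class = "fcs_state")
}

#' Draw an initial latent state
#'
#' By default this is the sampler's over-dispersed initialisation: scalars
#' from their priors, all loads off, trajectories from the prior.  With
#' \code{prior_draw = TRUE} the loads are drawn from their Bernoulli priors
#' as well, giving an exact draw from the full prior (used by calibration
#' checks).
#'
#' @param trace a \code{\link{photon_trace}} (only its binning is used).
#' @param psf a \code{\link{confocal_psf}}.
#' @param priors a \code{\link{prior_config}}.
#' @param n_components number of diffusion components.
#' @param prior_draw draw the loads from the prior instead of starting all
#'   inactive.
#' @return an \code{\link{fcs_state}}.
#' @export
init_state <- function(trace, psf, priors, n_components = 1L,
                       prior_draw = FALSE) {
  K <- length(trace$counts)
  dtvec <- trace_dt(trace)
  N <- priors$N_model
  box <- resolve_init_box(priors, psf)
  D <- vapply(seq_len(n_components), function(i)
    rinvgamma1(priors$D_shape, priors$D_scale), numeric(1))
  mu_mol <- rgamma(1L, priors$mu_mol_shape, priors$mu_mol_rate)
  mu_back <- rgamma(1L, priors$mu_back_shape, priors$mu_back_rate)
  comp <- if (N > 0) sample.int(n_components, N, replace = TRUE) else integer(0)
  q <- rbeta(N, priors$A_q, priors$B_q)
  loads <- if (prior_draw) as.integer(runif(N) < q) else integer(N)
  traj <- lapply(seq_len(N), function(n)
    draw_trajectory(K, D[comp[n]], dtvec, box))
  st <- fcs_state(D, mu_mol, mu_back, loads, q, traj, dtvec, comp)
  refresh_psf_cache(st, psf)
}

# ---- PSF cache ------------------------------------------------------------
# attr "P": K x N matrix of PSF values of every model molecule's trajectory.
refresh_psf_cache <- function(state, psf) {
  N <- length(state$loads)
  P <- matrix(0, nrow = state$K, ncol = max(N, 0L))
  for (n in seq_len(N)) P[, n] <- psf_values(psf, state$traj[[n]])
  attr(state, "P") <- P
  state
}

get_psf_matrix <- function(state, psf) {
  P <- attr(state, "P")
  if (is.null(P) || ncol(P) != length(state$loads) || nrow(P) != state$K)
    P <- attr(refresh_psf_cache(state, psf), "P")
  P
}

# summed active PSF signal per bin
active_signal <- function(state, P) {
  act <- which(state$loads == 1L)
  if (length(act) == 0) return(numeric(state$K))
  if (length(act) == 1) return(P[, act])
  rowSums(P[, act, drop = FALSE])
}

# ---- Likelihood -----------------------------------------------------------

#' Poisson log-likelihood of a latent state
#'
#' Sum over bins of the Poisson log-probability of the observed count at
#' rate \code{(t_k - t_{k-1}) * (mu_back + sum_n b_n mu_mol PSF(pos_n_k))}.
#' Returns \code{-Inf} (not an error) for states that make a positive count
#' impossible, e.g. zero background with all loads off.
#'
#' @param state an \code{\link{fcs_state}}.
#' @param trace a \code{\link{photon_trace}}.
#' @param psf a \code{\link{confocal_psf}}.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, trace, psf) {
  stopifnot(inherits(state, "fcs_state"), inherits(trace, "photon_trace"))
  if (length(trace$counts) != state$K)
    stop("state and trace have different numbers of bins")
  P <- get_psf_matrix(state, psf)
  S <- active_signal(state, P)
  rate <- state$dtvec * (state$mu_back + state$mu_mol * S)
  sum(dpois(trace$counts, rate, log = TRUE))
}

# log-likelihood from a precomputed signal vector (internal fast path)
loglik_from_signal <- function(w, dtvec, mu_back, mu_mol, S) {
  rate <- dtvec * (mu_back + mu_mol * S)
  idx <- w > 0L
  sum(w[idx] * log(rate[idx])) - sum(rate)
}

# ---- Conditional updates --------------------------------------------------

#' Resample the molecule loads and their Beta-Bernoulli weights
#'
#' Each load \code{b_n} is drawn from its full conditional: a Bernoulli
#' whose odds multiply the prior odds \code{q_n / (1 - q_n)} by the
#' likelihood ratio of switching molecule n's current trajectory on.  Each
#' weight is then refreshed from its Beta full conditional
#' \code{Beta(A_q + b_n, B_q + 1 - b_n)}.
#'
#' @param state an \code{\link{fcs_state}}.
#' @param trace a \code{\link{photon_trace}}.
#' @param psf a \code{\link{confocal_psf}}.
#' @param priors a \code{\link{prior_config}}.
#' @return the updated \code{\link{fcs_state}}.
#' @export
sample_loads <- function(state, trace, psf, priors) {
  N <- length(state$loads)
  if (N == 0) return(state)
  P <- get_psf_matrix(state, psf)
  w <- trace$counts
  dtvec <- state$dtvec
  S <- active_signal(state, P)
  idx <- which(w > 0L)
  for (n in sample.int(N)) {   # random scan: molecule labels are exchangeable
    pn <- P[, n]
    S_wo <- if (state$loads[n] == 1L) pmax(S - pn, 0) else S
    if (state$K > 0) {
      r0 <- dtvec * (state$mu_back + state$mu_mol * S_wo)
      r1 <- r0 + dtvec * state$mu_mol * pn
      llr <- sum(w[idx] * (log(r1[idx]) - log(r0[idx]))) - sum(r1 - r0)
    } else llr <- 0
    logit1 <- qlogis(state$q[n]) + llr
    b_new <- if (is.nan(logit1)) state$loads[n] else
      as.integer(runif(1L) < plogis(logit1))
    state$loads[n] <- b_new
    S <- if (b_new == 1L) S_wo + pn else S_wo
    state$q[n] <- rbeta(1L, priors$A_q + b_new, priors$B_q + 1L - b_new)
  }
  state
}

#' Resample the latent molecule trajectories
#'
#' Active molecules are updated by single-site random-walk Metropolis
#' sweeps (each site's move touches one Poisson bin and the two adjacent
#' Gaussian increments) followed by a whole-trajectory translation move that
#' helps molecules enter or leave the bright region as a block.  Inactive
#' molecules do not touch the likelihood, so their trajectories are simply
#' redrawn from the free-diffusion prior at the current D.
#'
#' @inheritParams sample_loads
#' @param control a \code{\link{mcmc_control}} (proposal scales).
#' @return the updated \code{\link{fcs_state}}.
#' @export
sample_trajectories <- function(state, trace, psf, priors,
                                control = mcmc_control()) {
  N <- length(state$loads)
  if (N == 0 || state$K == 0) return(state)
  P <- get_psf_matrix(state, psf)
  w <- trace$counts
  dtvec <- state$dtvec
  box <- resolve_init_box(priors, psf)
  code <- psf_variant_code(psf)
  dt_med <- median(dtvec)
  prop_sd <- control$prop_sd
  if (is.null(prop_sd))
    prop_sd <- pmax(sqrt(2 * state$D[state$comp] * dt_med), 0.02 * psf$omega_xy)
  prop_sd <- rep_len(prop_sd, N)
  shift_sd <- if (is.null(control$shift_sd)) psf$omega_xy / 2 else control$shift_sd
  scale <- dtvec * state$mu_mol
  S <- active_signal(state, P)
  idx <- which(w > 0L)
  acc <- matrix(0, N, 2)   # accepted, proposed (site moves)
  acc_shift <- c(0, 0)

  for (n in seq_len(N)) {
    Dn <- state$D[state$comp[n]]
    if (state$loads[n] == 0L) {
      state$traj[[n]] <- draw_trajectory(state$K, Dn, dtvec, box)
      P[, n] <- psf_values(psf, state$traj[[n]])
      next
    }
    other <- dtvec * (state$mu_back + state$mu_mol * pmax(S - P[, n], 0))
    pos <- state$traj[[n]]
    pn <- P[, n]
    for (s in seq_len(control$bridge_passes)) {
      res <- cpp_bridge_refresh(pos, pn, w, other, scale, Dn, dtvec,
                                code, psf$omega_xy, psf_wz(psf),
                                as.integer(control$bridge_L))
      pos <- res$pos; pn <- res$psf
    }
    for (s in seq_len(control$anchor_passes)) {
      # proposals at a randomly scaled diffusivity let the local path
      # roughness jump between scales (the acceptance ratio stays exact)
      fac <- sample(control$anchor_D_factors, 1L)
      res <- cpp_anchor_refresh(pos, pn, w, other, scale, Dn, dtvec,
                                code, psf$omega_xy, psf_wz(psf),
                                psf$omega_xy / 2, psf_wz(psf) / 2,
                                as.integer(control$anchor_L), Dn * fac)
      pos <- res$pos; pn <- res$psf
    }
    for (s in seq_len(control$traj_sweeps)) {
      res <- cpp_traj_sweep(pos, pn, w, other, scale, Dn, dtvec,
                            code, psf$omega_xy, psf_wz(psf), box, prop_sd[n])
      pos <- res$pos; pn <- res$psf
      acc[n, ] <- acc[n, ] + c(res$n_accept, state$K)
    }
    # whole-trajectory translation (prior-invariant except the initial box)
    delta <- rnorm(3L, 0, shift_sd)
    first <- pos[1, ] + delta
    if (all(abs(first) <= box)) {
      pos2 <- sweep(pos, 2L, delta, `+`)
      pn2 <- psf_values(psf, pos2)
      r1 <- other + scale * pn
      r2 <- other + scale * pn2
      dll <- sum(w[idx] * (log(r2[idx]) - log(r1[idx]))) - sum(r2 - r1)
      acc_shift[2] <- acc_shift[2] + 1
      if (is.finite(dll) && log(runif(1L)) < dll) {
        pos <- pos2; pn <- pn2
        acc_shift[1] <- acc_shift[1] + 1
      }
    }
    state$traj[[n]] <- pos
    S <- pmax(S - P[, n], 0) + pn
    P[, n] <- pn
  }
  attr(state, "P") <- P
  attr(state, "acc_traj") <- acc
  attr(state, "acc_shift") <- acc_shift
  state
}

# per-molecule sum over axes and steps of increment^2 / (4 dt)
increment_ssq <- function(traj, dtvec) {
  K <- nrow(traj)
  if (K < 2) return(0)
  d <- diff(traj)
  sum(rowSums(d * d) / (4 * dtvec[-1]))
}

#' Resample the diffusion coefficient(s)
#'
#' The Gaussian increment model is conjugate to an inverse-gamma prior:
#' with M increments (over all molecules, axes and steps) of widths
#' \code{dt_i} and values \code{delta_i}, the full conditional of D is
#' inverse-gamma with shape \code{D_shape + M/2} and scale
#' \code{D_scale + sum(delta_i^2 / (4 dt_i))}.  With several components,
#' each molecule's assignment is first refreshed from its categorical full
#' conditional (symmetric prior over components) and each component's D is
#' then updated from its members' increments.
#'
#' @param state an \code{\link{fcs_state}}.
#' @param priors a \code{\link{prior_config}}.
#' @return the updated \code{\link{fcs_state}}.
#' @export
sample_diffusion <- function(state, priors) {
  N <- length(state$loads)
  M_mol <- 3 * max(state$K - 1L, 0L)
  ssq <- vapply(state$traj, increment_ssq, numeric(1), dtvec = state$dtvec)
  ncomp <- length(state$D)
  if (ncomp > 1L && N > 0 && M_mol > 0) {
    # categorical full conditional of each assignment given the increments
    logp <- outer(ssq, state$D, function(s, d) -s / d) -
      (M_mol / 2) * matrix(log(state$D), N, ncomp, byrow = TRUE)
    for (n in seq_len(N)) {
      p <- exp(logp[n, ] - max(logp[n, ]))
      state$comp[n] <- sample.int(ncomp, 1L, prob = p)
    }
  }
  for (m in seq_len(ncomp)) {
    members <- which(state$comp == m)
    M <- length(members) * M_mol
    state$D[m] <- rinvgamma1(priors$D_shape + M / 2,
                             priors$D_scale + sum(ssq[members]))
  }
  state
}

# Blocked variant used inside the sweep: draws each component's D from its
# conditional given the ACTIVE members' increments only (the inactive
# members' trajectories, which never touch the likelihood, are integrated
# out analytically) and then redraws those inactive trajectories from the
# prior at the new D.  Jointly this is an exact Gibbs update of
# (D, inactive trajectories); it avoids the heavy autocorrelation the plain
# conditional inherits from the prior-drawn inactive increments.
sample_diffusion_blocked <- function(state, psf, priors) {
  N <- length(state$loads)
  M_mol <- 3 * max(state$K - 1L, 0L)
  ssq <- vapply(state$traj, increment_ssq, numeric(1), dtvec = state$dtvec)
  ncomp <- length(state$D)
  if (ncomp > 1L && N > 0 && M_mol > 0) {
    logp <- outer(ssq, state$D, function(s, d) -s / d) -
      (M_mol / 2) * matrix(log(state$D), N, ncomp, byrow = TRUE)
    for (n in seq_len(N)) {
      p <- exp(logp[n, ] - max(logp[n, ]))
      state$comp[n] <- sample.int(ncomp, 1L, prob = p)
    }
  }
  for (m in seq_len(ncomp)) {
    act <- which(state$comp == m & state$loads == 1L)
    state$D[m] <- rinvgamma1(priors$D_shape + length(act) * M_mol / 2,
                             priors$D_scale + sum(ssq[act]))
  }
  # pair the marginalised draw with a prior refresh of the inactive paths
  box <- resolve_init_box(priors, psf)
  P <- get_psf_matrix(state, psf)
  for (n in which(state$loads == 0L)) {
    state$traj[[n]] <- draw_trajectory(state$K, state$D[state$comp[n]],
                                       state$dtvec, box)
    P[, n] <- psf_values(psf, state$traj[[n]])
  }
  attr(state, "P") <- P
  state
}

# Joint (D, trajectories) rescaling move per component: propose D' on the
# log scale and map every member trajectory through
# pos' = pivot + sqrt(D'/D) (pos - pivot), where the pivot is the molecule's
# position at a bin drawn from a count-weighted, state-independent
# distribution (so bursts stay put while the path's roughness rescales).
# The Gaussian increment prior and the Jacobian of the map cancel exactly,
# leaving prior(D), likelihood (of active members), the initial-position box
# indicator and the log-scale Hastings term.  Breaks the inertia the
# conjugate update inherits from the trajectories' realised roughness.
rescale_move <- function(state, trace, psf, priors, control) {
  if (state$K < 2) return(state)
  P <- get_psf_matrix(state, psf)
  w <- trace$counts
  box <- resolve_init_box(priors, psf)
  acc <- c(0, 0)
  wprob <- w + 0.25  # count-weighted pivot bin, every bin reachable
  for (rep in seq_len(control$rescale_reps)) for (m in seq_along(state$D)) {
    kp <- sample.int(state$K, 1L, prob = wprob)
    members <- which(state$comp == m)
    D_old <- state$D[m]
    D_new <- D_old * exp(control$rescale_sd * rnorm(1L))
    g <- sqrt(D_new / D_old)
    remap <- function(pos) {
      piv <- pos[kp, ]
      sweep(sweep(pos, 2L, piv, `-`) * g, 2L, piv, `+`)
    }
    # the initial position keeps its uniform-box prior: reject if any
    # transformed member leaves the box
    ok <- all(vapply(members, function(n) {
      x1 <- state$traj[[n]][kp, ] + g * (state$traj[[n]][1, ] -
                                           state$traj[[n]][kp, ])
      all(abs(x1) <= box)
    }, logical(1)))
    acc[2] <- acc[2] + 1
    if (!ok) next
    act <- members[state$loads[members] == 1L]
    S_old <- active_signal(state, P)
    new_traj <- list(); new_psf <- list()
    S_new <- S_old
    for (n in act) {
      pos2 <- remap(state$traj[[n]])
      pn2 <- psf_values(psf, pos2)
      new_traj[[as.character(n)]] <- pos2
      new_psf[[as.character(n)]] <- pn2
      S_new <- pmax(S_new - P[, n], 0) + pn2
    }
    dll <- if (length(act) > 0)
      loglik_from_signal(w, state$dtvec, state$mu_back, state$mu_mol, S_new) -
      loglik_from_signal(w, state$dtvec, state$mu_back, state$mu_mol, S_old)
    else 0
    logr <- dll +
      dinvgamma_log(D_new, priors$D_shape, priors$D_scale) -
      dinvgamma_log(D_old, priors$D_shape, priors$D_scale) +
      log(D_new / D_old)
    if (is.finite(logr) && log(runif(1L)) < logr) {
      acc[1] <- acc[1] + 1
      state$D[m] <- D_new
      for (n in members) {
        if (state$loads[n] == 1L) {
          state$traj[[n]] <- new_traj[[as.character(n)]]
          P[, n] <- new_psf[[as.character(n)]]
        } else {
          state$traj[[n]] <- remap(state$traj[[n]])
          P[, n] <- psf_values(psf, state$traj[[n]])
        }
      }
    }
  }
  attr(state, "P") <- P
  attr(state, "acc_rescale") <- acc
  state
}

#' Resample the brightness and background rates
#'
#' When no molecule is active the background's full conditional is an exact
#' gamma (Poisson-gamma conjugacy: shape + total counts, rate + total
#' duration) and the brightness conditional equals its prior; both are drawn
#' directly.  Otherwise the two rates are updated by log-scale random-walk
#' Metropolis steps targeting their full conditionals.
#'
#' @inheritParams sample_trajectories
#' @return the updated \code{\link{fcs_state}}.
#' @export
sample_rates <- function(state, trace, psf, priors,
                         control = mcmc_control()) {
  w <- trace$counts
  dtvec <- state$dtvec
  P <- get_psf_matrix(state, psf)
  S <- active_signal(state, P)
  any_active <- any(state$loads == 1L) && any(S > 0)
  if (!any_active) {
    state$mu_back <- rgamma(1L, priors$mu_back_shape + sum(w),
                            rate = priors$mu_back_rate + sum(dtvec))
    state$mu_mol <- rgamma(1L, priors$mu_mol_shape, priors$mu_mol_rate)
    attr(state, "acc_back") <- c(1, 1)
    attr(state, "acc_mol") <- c(1, 1)
    return(state)
  }
  sdb <- control$rate_prop_sd[1]
  sdm <- control$rate_prop_sd[length(control$rate_prop_sd)]
  ll <- loglik_from_signal(w, dtvec, state$mu_back, state$mu_mol, S)
  # background
  mb_new <- state$mu_back * exp(sdb * rnorm(1L))
  ll_new <- loglik_from_signal(w, dtvec, mb_new, state$mu_mol, S)
  logr <- ll_new - ll +
    priors$mu_back_shape * log(mb_new / state$mu_back) -
    priors$mu_back_rate * (mb_new - state$mu_back)
  accb <- is.finite(logr) && log(runif(1L)) < logr
  if (accb) { state$mu_back <- mb_new; ll <- ll_new }
  # brightness
  mm_new <- state$mu_mol * exp(sdm * rnorm(1L))
  ll_new <- loglik_from_signal(w, dtvec, state$mu_back, mm_new, S)
  logr <- ll_new - ll +
    priors$mu_mol_shape * log(mm_new / state$mu_mol) -
    priors$mu_mol_rate * (mm_new - state$mu_mol)
  accm <- is.finite(logr) && log(runif(1L)) < logr
  if (accm) state$mu_mol <- mm_new
  attr(state, "acc_back") <- c(as.numeric(accb), 1)
  attr(state, "acc_mol") <- c(as.numeric(accm), 1)
  state
}

#' One full MCMC cycle over all conditional updates
#'
#' Applies, in order: loads and weights, trajectories, the blocked
#' conjugate diffusion update (inactive trajectories marginalised
#' analytically and refreshed from the prior at the new D), the joint
#' diffusion/trajectory rescaling move, and the two rate updates.  Every
#' kernel targets the same joint posterior, so the cycle leaves it
#' invariant.
#'
#' @inheritParams sample_trajectories
#' @return the updated \code{\link{fcs_state}}.
#' @export
mcmc_sweep <- function(state, trace, psf, priors, control = mcmc_control()) {
  state <- sample_loads(state, trace, psf, priors)
  state <- sample_trajectories(state, trace, psf, priors, control)
  acc_t <- attr(state, "acc_traj"); acc_s <- attr(state, "acc_shift")
  state <- sample_diffusion_blocked(state, psf, priors)
  state <- rescale_move(state, trace, psf, priors, control)
  acc_r <- attr(state, "acc_rescale")
  state <- sample_rates(state, trace, psf, priors, control)
  attr(state, "acc_traj") <- acc_t
  attr(state, "acc_shift") <- acc_s
  attr(state, "acc_rescale") <- acc_r
  state
}

#' Simulate photon counts from a latent state
#'
#' Forward-draw of the observation model given a full latent configuration;
#' used by prior-predictive and calibration checks.
#'
#' @param state an \code{\link{fcs_state}}.
#' @param psf a \code{\link{confocal_psf}}.
#' @param times bin end times; defaults to cumulative bin widths.
#' @return a \code{\link{photon_trace}}.
#' @export
simulate_from_state <- function(state, psf, times = cumsum(state$dtvec)) {
  P <- get_psf_matrix(state, psf)
  S <- active_signal(state, P)
  rate <- state$dtvec * (state$mu_back + state$mu_mol * S)
  photon_trace(times, rpois(state$K, rate))
}

#' Tuning parameters of the MCMC engine
#'
#' @param traj_sweeps single-site Metropolis sweeps per molecule per cycle.
#' @param prop_sd site proposal standard deviation, micrometres
#'   (\code{NULL}: derived from the current D and bin width, then adapted
#'   during burn-in towards 25-45\% acceptance).
#' @param shift_sd whole-trajectory translation proposal sd, micrometres
#'   (\code{NULL}: half the lateral PSF radius).
#' @param rescale_sd log-scale sd of the joint diffusion/trajectory
#'   rescaling proposal.
#' @param rescale_reps rescaling attempts per cycle.
#' @param rate_prop_sd log-scale sd for the background and brightness
#'   Metropolis updates (length 1 or 2).
#' @param bridge_L window length (bins) of the Brownian-bridge
#'   independence proposals that refresh active trajectories from the
#'   conditional prior.
#' @param bridge_passes bridge-refresh passes per molecule per cycle.
#' @param anchor_L window length (bins) of the data-anchored proposals
#'   that drive a molecule through the bright region at a window's
#'   maximum-count bin (with exact Metropolis-Hastings correction).
#' @param anchor_passes anchored-refresh passes per molecule per cycle.
#' @param anchor_D_factors candidate scalings of the current D at which
#'   anchored proposals are generated (one is drawn per pass).
#' @param adapt adapt proposal scales during burn-in.
#' @param adapt_batch sweeps per adaptation batch.
#' @return a list of class \code{mcmc_control}.
#' @export
mcmc_control <- function(traj_sweeps = 2L, prop_sd = NULL, shift_sd = NULL,
                         rescale_sd = 0.5, rescale_reps = 3L,
                         rate_prop_sd = c(0.15, 0.15),
                         bridge_L = 16L, bridge_passes = 2L,
                         anchor_L = 32L, anchor_passes = 2L,
                         anchor_D_factors = c(1 / 3, 1, 3),
                         adapt = TRUE, adapt_batch = 50L) {
  structure(list(traj_sweeps = as.integer(traj_sweeps), prop_sd = prop_sd,
                 shift_sd = shift_sd, rescale_sd = rescale_sd,
                 rescale_reps = as.integer(rescale_reps),
                 rate_prop_sd = rate_prop_sd, bridge_L = as.integer(bridge_L),
                 bridge_passes = as.integer(bridge_passes),
                 anchor_L = as.integer(anchor_L),
                 anchor_passes = as.integer(anchor_passes),
                 anchor_D_factors = anchor_D_factors, adapt = adapt,
                 adapt_batch = as.integer(adapt_batch)),
            class = "mcmc_control")
}

# effective sample size from the initial positive autocorrelation sum
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  r <- acf(x, lag.max = min(n - 1L, 250L), plot = FALSE)$acf[-1]
  s <- 0; k <- 1
  while (k <= length(r) && r[k] > 0.05) { s <- s + r[k]; k <- k + 1 }
  n / (1 + 2 * s)
}

#' Posterior sampling for a photon-count trace
#'
#' Runs the Markov chain Monte Carlo sampler over the joint posterior of the
#' diffusion coefficient(s), molecular brightness, background rate, loads,
#' weights and trajectories, starting from an over-dispersed initialisation
#' (scalars from their priors, loads off).  Site-update proposal scales are
#' adapted during burn-in only, so the retained chain is a fixed-kernel
#' Markov chain.
#'
#' @param trace a \code{\link{photon_trace}} (non-empty).
#' @param psf a \code{\link{confocal_psf}}.
#' @param priors a \code{\link{prior_config}}.
#' @param n_iter total MCMC cycles.
#' @param n_burn cycles discarded as burn-in (< n_iter).
#' @param thin keep every \code{thin}-th post-burn-in state.
#' @param seed integer seed for reproducibility.
#' @param n_components number of diffusion coefficients (1 = standard model).
#' @param control a \code{\link{mcmc_control}}.
#' @param keep_states also retain the full latent states (memory-heavy).
#' @param verbose print progress every few hundred sweeps.
#' @return an object of class \code{fcs_posterior}: a list with
#'   \code{draws} (data frame of retained scalar draws: D or D1..Dm,
#'   mu_mol, mu_back, n_active), sampler metadata and acceptance rates.
#' @examples
#' \donttest{
#' cfg <- sim_config(D = 10, K = 300, n_molecules = 2,
#'                   init_region = c(0.3, 0.3, 1.5), seed = 1)
#' tr <- simulate_trace(cfg)
#' fit <- run_mcmc(tr, cfg$psf, prior_config(N_model = 5),
#'                 n_iter = 400, seed = 1)
#' summarize_posterior(fit, "D")
#' }
#' @export
run_mcmc <- function(trace, psf, priors = prior_config(), n_iter = 3000L,
                     n_burn = floor(n_iter / 2), thin = 1L, seed = NULL,
                     n_components = 1L, control = mcmc_control(),
                     keep_states = FALSE, verbose = FALSE) {
  stopifnot(inherits(trace, "photon_trace"), inherits(psf, "confocal_psf"),
            inherits(priors, "prior_config"))
  K <- length(trace$counts)
  if (K < 1) stop("'trace' must be non-empty")
  if (!(n_iter > n_burn && n_burn >= 0)) stop("need n_iter > n_burn >= 0")
  if (n_components < 1) stop("'n_components' must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  state <- init_state(trace, psf, priors, n_components)
  N <- priors$N_model
  dt_med <- median(state$dtvec)
  ctl <- control
  if (is.null(ctl$prop_sd))
    ctl$prop_sd <- rep(pmax(sqrt(2 * mean(state$D) * dt_med),
                            0.05 * psf$omega_xy), max(N, 1L))
  else ctl$prop_sd <- rep_len(ctl$prop_sd, max(N, 1L))
  if (is.null(ctl$shift_sd)) ctl$shift_sd <- psf$omega_xy / 2

  keep <- seq(n_burn + 1L, n_iter, by = thin)
  n_keep <- length(keep)
  Dm <- matrix(NA_real_, n_keep, n_components)
  mu_mol_s <- mu_back_s <- numeric(n_keep)
  n_active_s <- integer(n_keep)
  states <- if (keep_states) vector("list", n_keep) else NULL
  acc_tot <- list(traj = c(0, 0), shift = c(0, 0), rescale = c(0, 0),
                  back = c(0, 0), mol = c(0, 0))
  batch_acc <- matrix(0, max(N, 1L), 2)
  bad_ll <- 0L
  j <- 0L

  for (i in seq_len(n_iter)) {
    state <- mcmc_sweep(state, trace, psf, priors, ctl)
    at <- attr(state, "acc_traj")
    if (!is.null(at)) {
      batch_acc[seq_len(nrow(at)), ] <- batch_acc[seq_len(nrow(at)), ] + at
      acc_tot$traj <- acc_tot$traj + colSums(at)
    }
    for (nm in c("shift", "rescale", "back", "mol")) {
      a <- attr(state, paste0("acc_", nm))
      if (!is.null(a)) acc_tot[[nm]] <- acc_tot[[nm]] + a
    }
    # adapt site proposal scales during burn-in only
    if (ctl$adapt && i <= n_burn && i %% ctl$adapt_batch == 0L) {
      prop <- batch_acc[, 2] > 0
      frac <- ifelse(prop, batch_acc[, 1] / pmax(batch_acc[, 2], 1), NA)
      up <- prop & frac > 0.45
      dn <- prop & frac < 0.25
      ctl$prop_sd[up] <- ctl$prop_sd[up] * exp(0.25)
      ctl$prop_sd[dn] <- ctl$prop_sd[dn] * exp(-0.25)
      batch_acc[] <- 0
    }
    # divergence guard: a persistently impossible state aborts with context
    if (i %% 100L == 0L) {
      P <- get_psf_matrix(state, psf)
      ll <- loglik_from_signal(trace$counts, state$dtvec, state$mu_back,
                               state$mu_mol, active_signal(state, P))
      bad_ll <- if (!is.finite(ll)) bad_ll + 1L else 0L
      if (bad_ll >= 3L)
        stop("MCMC diverged: non-finite log-likelihood persisting at ",
             "iteration ", i)
    }
    if (i > n_burn && (i - n_burn - 1L) %% thin == 0L) {
      j <- j + 1L
      Dm[j, ] <- state$D
      mu_mol_s[j] <- state$mu_mol
      mu_back_s[j] <- state$mu_back
      n_active_s[j] <- sum(state$loads)
      if (keep_states) states[[j]] <- state
    }
    if (verbose && i %% 500L == 0L)
      message("iteration ", i, "/", n_iter, "  D = ",
              paste(signif(state$D, 3), collapse = ", "),
              "  active = ", sum(state$loads))
  }

  draws <- data.frame(iteration = keep)
  if (n_components == 1L) draws$D <- Dm[, 1]
  else for (m in seq_len(n_components)) draws[[paste0("D", m)]] <- Dm[, m]
  draws$mu_mol <- mu_mol_s
  draws$mu_back <- mu_back_s
  draws$n_active <- n_active_s

  rate_of <- function(a) if (a[2] > 0) a[1] / a[2] else NA_real_
  structure(list(
    draws = draws,
    n_iter = n_iter, n_burn = n_burn, thin = thin, seed = seed,
    n_components = n_components, priors = priors, psf = psf,
    acceptance = lapply(acc_tot, rate_of),
    ess = c(D = ess(Dm[, 1]), mu_back = ess(mu_back_s),
            mu_mol = ess(mu_mol_s)),
    states = states
  ), class = "fcs_posterior")
}

#' Posterior sampling with several diffusion coefficients
#'
#' Variant of \code{\link{run_mcmc}} in which every model molecule carries a
#' component assignment to one of \code{n_components} diffusion
#' coefficients (symmetric prior over assignments; each component's D is
#' updated by the conjugate step restricted to its members).  With
#' \code{n_components = 1} the inference law is identical to
#' \code{\link{run_mcmc}}.
#'
#' @inheritParams run_mcmc
#' @param n_components number of diffusion components.
#' @return an \code{fcs_posterior}; component draws are in columns
#'   \code{D1..Dm} (labels are exchangeable; summaries sort them).
#' @export
run_mcmc_multi_d <- function(trace, psf, priors = prior_config(),
                             n_components = 2L, n_iter = 3000L,
                             n_burn = floor(n_iter / 2), thin = 1L,
                             seed = NULL, control = mcmc_control(),
                             verbose = FALSE) {
  run_mcmc(trace, psf, priors, n_iter = n_iter, n_burn = n_burn, thin = thin,
           seed = seed, n_components = n_components, control = control,
           verbose = verbose)
}

#' Posterior distribution of the number of active molecules
#'
#' @param samples an \code{fcs_posterior}.
#' @return a named numeric vector: posterior probability mass of the active
#'   count \code{sum_n b_n} at each observed value.
#' @export
estimate_active_population <- function(samples) {
  stopifnot(inherits(samples, "fcs_posterior"))
  n <- samples$draws$n_active
  if (length(n) == 0) stop("no post-burn-in samples")
  tab <- table(factor(n, levels = 0:max(n)))
  p <- as.numeric(tab) / length(n)
  names(p) <- names(tab)
  p
}

#' Central credible interval of a scalar posterior marginal
#'
#' @param samples an \code{fcs_posterior} with at least 100 retained draws.
#' @param parameter name of a scalar draw: \code{"D"} (or \code{"D1"},
#'   \code{"D2"}, ... for the multi-component variant, reported on
#'   per-draw ascending-sorted components), \code{"mu_mol"},
#'   \code{"mu_back"} or \code{"n_active"}.
#' @param level interval probability (default 0.95).
#' @return named vector \code{(median, lower, upper)}.
#' @export
summarize_posterior <- function(samples, parameter = "D", level = 0.95) {
  stopifnot(inherits(samples, "fcs_posterior"))
  draws <- samples$draws
  if (nrow(draws) < 100)
    stop("need at least 100 post-burn-in samples (have ", nrow(draws), ")")
  ncomp <- samples$n_components
  if (ncomp > 1L && grepl("^D[0-9]+$", parameter)) {
    j <- as.integer(sub("^D", "", parameter))
    if (j < 1 || j > ncomp) stop("unknown parameter '", parameter, "'")
    Dmat <- as.matrix(draws[paste0("D", seq_len(ncomp))])
    x <- apply(Dmat, 1L, function(r) sort(r)[j])
  } else {
    if (!parameter %in% names(draws))
      stop("unknown parameter '", parameter, "'")
    x <- draws[[parameter]]
  }
  a <- (1 - level) / 2
  qs <- quantile(x, c(0.5, a, 1 - a), names = FALSE, type = 7)
  c(median = qs[1], lower = qs[2], upper = qs[3])
}

#' @export
print.fcs_posterior <- function(x, ...) {
  cat("Posterior samples:", nrow(x$draws), "retained draws (",
      x$n_iter, "iterations,", x$n_burn, "burn-in )\n")
  pars <- if (x$n_components == 1L) "D" else paste0("D", seq_len(x$n_components))
  for (p in c(pars, "mu_mol", "mu_back")) {
    s <- summarize_posterior(x, p)
    cat(sprintf("  %-8s median %.4g  95%% CI [%.4g, %.4g]\n",
                p, s["median"], s["lower"], s["upper"]))
  }
  pop <- estimate_active_population(x)
  cat("  active molecules: mode", names(pop)[which.max(pop)], "\n")
  invisible(x)
}

#' Persist posterior draws as delimited text
#'
#' One row per retained iteration; '#' header lines record the seed and
#' sampler settings.
#'
#' @param samples an \code{fcs_posterior}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_posterior <- function(samples, path) {
  stopifnot(inherits(samples, "fcs_posterior"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bnpfcs posterior draws",
               sprintf("# seed = %s", format(samples$seed)),
               sprintf("# n_iter = %d, n_burn = %d, thin = %d",
                       samples$n_iter, samples$n_burn, samples$thin)), con)
  write.table(samples$draws, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
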
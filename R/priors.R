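#' Prior configuration for posterior inference
#'
#' The truncated non-parametric model carries \code{N_model} model molecules
#' (active plus inactive).  Each load \code{b_n} has a Bernoulli(\code{q_n})
#' prior with \code{q_n ~ Beta(A_q, B_q)}, so the prior expected number of
#' active molecules is \code{N_model * A_q / (A_q + B_q)} (2 under the
#' defaults).  The diffusion coefficient has an inverse-gamma prior
#' (conjugate to the Gaussian increment model) and the two rates have gamma
#' priors (conjugate in the background-only limit).  All defaults are weakly
#' informative: prior coefficient of variation at least 1.
#'
#' @param N_model truncation level: number of model molecules (0 allowed;
#'   it yields a pure-background model).
#' @param A_q,B_q Beta hyperparameters of the load weights.
#' @param D_shape,D_scale inverse-gamma shape/scale for D (um^2/s scale).
#'   The defaults (shape 1, scale 5) are an order-of-magnitude statement:
#'   median ~7 um^2/s with ~95% prior mass spread over 1.4-200, covering
#'   the range of common intracellular and in-vitro tracers.
#' @param mu_mol_shape,mu_mol_rate gamma shape/rate for the molecular
#'   brightness (photons/s); the default is exponential with mean 5e4.
#' @param mu_back_shape,mu_back_rate gamma shape/rate for the background
#'   rate (photons/s); the default is exponential with mean 1e3.
#' @param init_box half-widths (x, y, z) of the uniform prior on initial
#'   molecule positions, micrometres; \code{NULL} derives
#'   \code{(4 omega_xy, 4 omega_xy, 4 omega_z)} from the PSF at run time.
#' @return a list of class \code{prior_config}.
#' @export
prior_config <- function(N_model = 20L, A_q = 1, B_q = 9,
                         D_shape = 1, D_scale = 5,
                         mu_mol_shape = 1, mu_mol_rate = 1 / 5e4,
                         mu_back_shape = 1, mu_back_rate = 1 / 1e3,
                         init_box = NULL) {
  if (N_model < 0 || N_model != round(N_model))
    stop("'N_model' must be a non-negative integer")
  hyp <- c(A_q = A_q, B_q = B_q, D_shape = D_shape, D_scale = D_scale,
           mu_mol_shape = mu_mol_shape, mu_mol_rate = mu_mol_rate,
           mu_back_shape = mu_back_shape, mu_back_rate = mu_back_rate)
  if (any(!is.finite(hyp)) || any(hyp <= 0))
    stop("all prior hyperparameters must be positive")
  if (!is.null(init_box)) stopifnot(length(init_box) == 3, all(init_box > 0))
  structure(list(N_model = as.integer(N_model), A_q = A_q, B_q = B_q,
                 D_shape = D_shape, D_scale = D_scale,
                 mu_mol_shape = mu_mol_shape, mu_mol_rate = mu_mol_rate,
                 mu_back_shape = mu_back_shape, mu_back_rate = mu_back_rate,
                 init_box = init_box),
            class = "prior_config")
}

# fill the initial-position box from the PSF when the user left it NULL
resolve_init_box <- function(priors, psf) {
  if (!is.null(priors$init_box)) return(priors$init_box)
  c(4 * psf$omega_xy, 4 * psf$omega_xy, 4 * psf_wz(psf))
}

rinvgamma1 <- function(shape, scale) 1 / rgamma(1L, shape = shape, rate = scale)

dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}
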
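#' Read a structured run configuration
#'
#' Configurations are YAML files with the fixed key groups \code{psf},
#' \code{sim}, \code{priors}, \code{mcmc}, \code{io} and \code{seed}.
#' Unknown keys are errors, not warnings, so typos cannot silently fall
#' back to defaults.  Units are fixed package-wide (micrometres, seconds,
#' photons per second); nothing is inferred from file contents.
#'
#' Recognised keys:
#' \itemize{
#'   \item \code{psf}: \code{variant}, \code{omega_xy_um}, \code{omega_z_um}
#'   \item \code{sim}: \code{D}, \code{mu_mol}, \code{mu_back}, \code{dt},
#'     \code{K}, \code{n_molecules}, \code{init_region}, \code{substeps}
#'   \item \code{priors}: \code{N_model}, \code{A_q}, \code{B_q},
#'     \code{D_shape}, \code{D_scale}, \code{mu_mol_shape},
#'     \code{mu_mol_rate}, \code{mu_back_shape}, \code{mu_back_rate},
#'     \code{init_box}
#'   \item \code{mcmc}: \code{n_iter}, \code{n_burn}, \code{thin},
#'     \code{n_components}
#'   \item \code{io}: \code{trace}, \code{output_dir}
#'   \item \code{seed}: integer
#' }
#'
#' @param path YAML file path.
#' @return a list of class \code{run_config} with elements \code{psf}
#'   (a \code{\link{confocal_psf}}), \code{sim}, \code{priors}
#'   (a \code{\link{prior_config}}), \code{mcmc}, \code{io}, \code{seed}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known_top <- c("psf", "sim", "priors", "mcmc", "io", "seed")
  check_keys(raw, known_top, "top level")

  psf <- NULL
  if (!is.null(raw$psf)) {
    check_keys(raw$psf, c("variant", "omega_xy_um", "omega_z_um"), "psf")
    psf <- confocal_psf(raw$psf$variant %||% "gaussian3d",
                        omega_xy = raw$psf$omega_xy_um %||% 0.3,
                        omega_z = raw$psf$omega_z_um %||% 1.5)
  } else {
    psf <- confocal_psf("gaussian3d", 0.3, 1.5)
  }

  sim <- NULL
  if (!is.null(raw$sim)) {
    check_keys(raw$sim, c("D", "mu_mol", "mu_back", "dt", "K",
                          "n_molecules", "init_region", "substeps"), "sim")
    args <- raw$sim
    args$psf <- psf
    args$seed <- raw$seed
    sim <- do.call(sim_config, args)
  }

  priors <- prior_config()
  if (!is.null(raw$priors)) {
    check_keys(raw$priors, c("N_model", "A_q", "B_q", "D_shape", "D_scale",
                             "mu_mol_shape", "mu_mol_rate", "mu_back_shape",
                             "mu_back_rate", "init_box"), "priors")
    priors <- do.call(prior_config, raw$priors)
  }

  mcmc <- list(n_iter = 3000L, n_burn = NULL, thin = 1L, n_components = 1L)
  if (!is.null(raw$mcmc)) {
    check_keys(raw$mcmc, names(mcmc), "mcmc")
    mcmc <- modifyList(mcmc, raw$mcmc)
  }

  io <- list(trace = NULL, output_dir = ".")
  if (!is.null(raw$io)) {
    check_keys(raw$io, names(io), "io")
    io <- modifyList(io, raw$io)
  }

  structure(list(psf = psf, sim = sim, priors = priors, mcmc = mcmc,
                 io = io, seed = raw$seed %||% 1L),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

# ---- command-line entry point --------------------------------------------
# Thin dispatcher behind exec/bnpfcs; returns an exit status rather than
# quitting so it can be unit-tested in-process.
# Exit codes: 0 success, 1 user error (bad arguments/config), 2 runtime
# failure.
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bnpfcs <simulate|infer|fcs|compare|fixtures> --config FILE",
    "              [--out DIR] [--seed INT]", sep = "\n")
  if (length(args) < 1L) { message(usage); return(1L) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  if (is.null(opts)) { message(usage); return(1L) }

  run <- function() {
    out_dir <- opts$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (cmd == "fixtures") {
      make_fixture_traces(out_dir, seed = as.integer(opts$seed %||% 1L),
                          max_length_bins = 5000L)
      return(0L)
    }
    if (is.null(opts$config)) { message(usage); return(1L) }
    cfg <- read_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    log_line <- sprintf("seed = %s; config = %s", format(cfg$seed),
                        normalizePath(opts$config))
    if (cmd == "simulate") {
      if (is.null(cfg$sim)) stop("config has no 'sim' section")
      cfg$sim$seed <- cfg$seed
      trace <- simulate_trace(cfg$sim, keep_trajectories = FALSE)
      write_trace(trace, file.path(out_dir, "trace.txt"),
                  header = list(seed = cfg$seed))
    } else if (cmd == "infer") {
      trace <- read_trace(cfg$io$trace %||% stop("io.trace not set"))
      n_burn <- cfg$mcmc$n_burn %||% floor(cfg$mcmc$n_iter / 2)
      post <- run_mcmc(trace, cfg$psf, cfg$priors,
                       n_iter = cfg$mcmc$n_iter, n_burn = n_burn,
                       thin = cfg$mcmc$thin, seed = cfg$seed,
                       n_components = cfg$mcmc$n_components)
      write_posterior(post, file.path(out_dir, "posterior.txt"))
    } else if (cmd == "fcs") {
      trace <- read_trace(cfg$io$trace %||% stop("io.trace not set"))
      curve <- autocorrelate(trace)
      write_curve(curve, file.path(out_dir, "correlation.txt"))
      fit <- fit_fcs_model(curve, cfg$psf)
      writeLines(c("# bnpfcs FCS fit",
                   sprintf("D_hat %.17g", fit$D_hat),
                   sprintf("tau_D %.17g", fit$tau_D),
                   sprintf("G0 %.17g", fit$G0),
                   sprintf("converged %s", fit$converged)),
                 file.path(out_dir, "fcs_fit.txt"))
    } else if (cmd == "compare") {
      if (is.null(cfg$sim)) stop("config has no 'sim' section")
      res <- compare_data_efficiency(
        true_D = cfg$sim$D, sim_config = cfg$sim,
        trace_lengths = c(500L, 2000L), n_replicates = 2L,
        seed = cfg$seed)
      utils::write.csv(res, file.path(out_dir, "efficiency.csv"),
                       row.names = FALSE)
    } else {
      message("unknown command '", cmd, "'\n", usage)
      return(1L)
    }
    writeLines(c(log_line, R.version.string),
               file.path(out_dir, "run_log.txt"))
    0L
  }
  status <- tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    if (inherits(e, "simpleError") &&
        grepl("config|usage|not set|not found|unknown", conditionMessage(e)))
      1L else 2L
  })
  status
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) return(NULL)
    opts[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
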
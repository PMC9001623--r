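# R-side interface to the compiled 1D Metropolis engine: configuration,
# runs, step-size auto-tuning, and RDF estimation from sampled conformations.

#' Monte Carlo configuration
#'
#' One MCS (Monte Carlo sweep) proposes one move per particle; a move
#' displaces a particle by `u ~ Uniform(-lambda, +lambda)`, is rejected if it
#' violates the hard core (or leaves the domain, in `walls` mode), and is
#' otherwise accepted with the Metropolis probability `min(1, exp(-dE))`
#' (kT = 1 throughout).
#'
#' @param n_particles number of particles (nucleosomes).
#' @param domain_length domain size in bp.
#' @param core_diameter hard-core exclusion in bp (the section's mean
#'   nucleosome length; 0 disables the core).
#' @param lambda_max maximum displacement per move, bp.
#' @param n_steps number of sweeps.
#' @param boundary `"periodic"` (minimum-image distances; default) or
#'   `"walls"`.
#' @param seed integer RNG seed for the compiled engine.
#' @param sample_every record a conformation every this many sweeps.
#' @param burn_in sweeps discarded before sampling (default 10% of
#'   `n_steps`).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_particles, domain_length, core_diameter = 0,
                      lambda_max = 64, n_steps = 10000,
                      boundary = c("periodic", "walls"), seed = 1,
                      sample_every = 100, burn_in = NULL) {
  boundary <- match.arg(boundary)
  burn_in <- burn_in %||% floor(0.1 * n_steps)
  stopifnot(lambda_max > 0, n_particles >= 1, n_steps >= 1,
            core_diameter >= 0, burn_in >= 0, sample_every >= 1)
  if (n_particles * core_diameter >= domain_length)
    stop("infeasible packing: n_particles * core_diameter >= domain_length")
  structure(list(n_particles = as.integer(n_particles),
                 domain_length = domain_length,
                 core_diameter = core_diameter, lambda_max = lambda_max,
                 n_steps = as.integer(n_steps), boundary = boundary,
                 seed = as.integer(seed),
                 sample_every = as.integer(sample_every),
                 burn_in = as.integer(burn_in), kT = 1),
            class = "mc_config")
}

#' Run a 1D Metropolis Monte Carlo simulation
#'
#' Particles start equally spaced (always feasible when the packing is
#' feasible, and deterministic). Identical `(seed, config, potential)` give
#' identical trajectories.
#'
#' @param potential a [glj_params()] or `NULL` for hard-core-only / free
#'   particles.
#' @param config an [mc_config()].
#' @return A list of class `mc_run`: `samples` (matrix, one sorted
#'   conformation per row), `sample_sweeps`, `acceptance` (fraction),
#'   `energy_incremental`, `energy_recomputed`, `final_positions`, `config`,
#'   `potential`.
#' @export
run_mc <- function(potential, config) {
  stopifnot(inherits(config, "mc_config"))
  has_pot <- !is.null(potential)
  if (has_pot) stopifnot(inherits(potential, "glj_params"))
  L <- config$domain_length
  n <- config$n_particles
  init <- (seq_len(n) - 0.5) * L / n
  r_cut <- if (has_pot) potential$r_cut else 0
  if (has_pot && config$boundary == "periodic" && r_cut > L / 2)
    warning("r_cut > domain_length/2 under periodic boundary: clamped to L/2")
  res <- .mc_run_cpp(init, L, config$core_diameter, has_pot,
                     if (has_pot) potential$epsilon else 0,
                     if (has_pot) potential$sigma else 1,
                     if (has_pot) potential$delta_exp else 2,
                     if (has_pot) potential$nu_exp else 1,
                     if (has_pot) min(r_cut, if (config$boundary == "periodic") L / 2 else Inf) else 0,
                     config$lambda_max, config$n_steps, config$burn_in,
                     config$sample_every, config$boundary == "periodic",
                     as.numeric(config$seed))
  res$config <- config
  res$potential <- potential
  class(res) <- "mc_run"
  res
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf(
    "<mc_run> N=%d, L=%g bp, %d sweeps, %d samples, acceptance %.1f%%\n",
    x$config$n_particles, x$config$domain_length, x$config$n_steps,
    nrow(x$samples), 100 * x$acceptance))
  invisible(x)
}

#' Auto-tune the maximum displacement lambda
#'
#' Runs short pilot simulations over a geometric ladder of lambda values and
#' returns the smallest value whose measured acceptance is at or below the
#' target rate (50% by default, matching the rule that lambda is the
#' smallest displacement bound keeping acceptance <= 50% on average). If
#' every ladder value accepts more than the target, the largest is returned
#' with a warning (e.g. free particles, where nothing is ever rejected).
#'
#' @param potential a [glj_params()] or `NULL`.
#' @param config an [mc_config()]; its `lambda_max` is ignored.
#' @param grid geometric lambda ladder in bp.
#' @param pilot_sweeps sweeps per pilot run.
#' @param target maximum acceptable acceptance rate.
#' @return Selected lambda (bp), with attribute `"acceptance"` giving the
#'   measured pilot acceptance at each grid value.
#' @export
tune_lambda <- function(potential, config, grid = 2^(0:10),
                        pilot_sweeps = 500, target = 0.5) {
  stopifnot(inherits(config, "mc_config"))
  acc <- numeric(length(grid))
  for (k in seq_along(grid)) {
    cfg <- config
    cfg$lambda_max <- grid[k]
    cfg$n_steps <- as.integer(pilot_sweeps)
    cfg$burn_in <- 0L
    cfg$sample_every <- as.integer(pilot_sweeps + 1) # no samples needed
    cfg$seed <- derive_seed(config$seed, 7000 + k)
    acc[k] <- run_mc(potential, cfg)$acceptance
    if (acc[k] <= target) {
      return(structure(grid[k], acceptance = stats::setNames(acc[1:k], grid[1:k])))
    }
  }
  warning("no ladder value reached the target acceptance; returning largest")
  structure(grid[length(grid)],
            acceptance = stats::setNames(acc, grid))
}

#' Export sampled conformations as TSV
#'
#' One row per sample: the sweep index followed by the sorted particle
#' positions.
#'
#' @param run an `mc_run`.
#' @param path output path.
#' @export
write_conformations <- function(run, path) {
  stopifnot(inherits(run, "mc_run"))
  df <- data.frame(sweep_index = run$sample_sweeps, run$samples)
  names(df) <- c("sweep_index", paste0("x", seq_len(ncol(run$samples))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average RDF over sampled conformations
#'
#' @param run an `mc_run` (or a plain matrix of conformations with attributes
#'   supplied via the other arguments).
#' @param bin_width,r_max binning as in [compute_rdf()].
#' @return An `rdf_curve`; the mean of the per-conformation RDFs.
#' @export
rdf_from_conformations <- function(run, bin_width = 10, r_max = 1000) {
  stopifnot(inherits(run, "mc_run"))
  if (nrow(run$samples) == 0) stop("no sampled conformations")
  L <- run$config$domain_length
  periodic <- run$config$boundary == "periodic"
  if (periodic) r_max <- min(r_max, L / 2)
  counts <- .pair_counts_cpp(run$samples, L, bin_width, r_max, periodic)
  rdf_from_counts(counts, n_conf = nrow(run$samples),
                  n_particles = run$config$n_particles, domain_length = L,
                  bin_width = bin_width, r_max = r_max,
                  edge = if (periodic) "periodic" else "open")
}
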
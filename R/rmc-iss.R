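# Reverse Monte Carlo with the intuitive selection strategy (ISS): fit the
# generalized Lennard-Jones parameters to a target RDF by a tournament over
# candidate potentials evaluated at geometrically increasing inner-MC
# precision. Each round evaluates the surviving pool at the next rung of the
# sweep ladder, scores candidates by the mean squared residual against the
# target, and keeps a fraction theta. All candidates in a round share the
# same inner-MC seed (common random numbers), which reduces selection noise.

#' ISS optimizer configuration
#'
#' @param theta selection ratio in (0, 1); each round keeps
#'   `ceiling(theta * pool)` candidates (default 0.25).
#' @param pool_size initial number of candidate potentials (default 64; with
#'   theta = 0.25 the pool shrinks 64 -> 16 -> 4 -> 1 over the ladder).
#' @param step_ladder strictly increasing inner-MC sweep counts, one per
#'   round.
#' @param domains named list of `c(lo, hi)` bounds for `epsilon`, `sigma`,
#'   `nu_exp`, and `delta_exp`. `delta_exp` is sampled uniformly between the
#'   candidate's `nu_exp` (exclusive) and its upper bound, which enforces
#'   `delta_exp > nu_exp` at sampling.
#' @param r_cut potential cutoff in bp carried into every candidate.
#' @param p residual degrees-of-freedom correction passed to [msr()]
#'   (default 5: the four potential parameters plus an intercept).
#' @param seed master seed; per-round inner-MC seeds and the candidate pool
#'   are derived from it.
#' @return An object of class `iss_config`.
#' @export
iss_config <- function(theta = 0.25, pool_size = 64,
                       step_ladder = c(1e3, 1e4, 1e5, 1e6),
                       domains = list(epsilon = c(0.1, 5),
                                      sigma = c(140, 170),
                                      nu_exp = c(1, 12),
                                      delta_exp = c(NA, 24)),
                       r_cut = 500, p = 5, seed = 1) {
  stopifnot(theta > 0, theta < 1, pool_size >= 2,
            all(diff(step_ladder) > 0))
  structure(list(theta = theta, pool_size = as.integer(pool_size),
                 step_ladder = as.integer(step_ladder), domains = domains,
                 r_cut = r_cut, p = as.integer(p), seed = as.integer(seed)),
            class = "iss_config")
}

#' Mean squared residual between two RDF curves
#'
#' `MSR = sum((x - xhat)^2) / (n - p)` over the bins whose midpoints fall in
#' `[r_min_fit, r_max_fit]`, where `n` is the number of compared bins and `p`
#' the number of fitted parameters including the intercept.
#'
#' @param target,simulated `rdf_curve` objects on identical binning.
#' @param p degrees-of-freedom correction (default 5).
#' @param r_min_fit,r_max_fit fitting window in bp (defaults: the full
#'   common range).
#' @return The MSR (non-negative scalar).
#' @export
msr <- function(target, simulated, p = 5, r_min_fit = -Inf,
                r_max_fit = Inf) {
  stopifnot(inherits(target, "rdf_curve"), inherits(simulated, "rdf_curve"))
  nb <- min(length(target$g), length(simulated$g))
  if (target$bin_width != simulated$bin_width ||
      !isTRUE(all.equal(target$r[seq_len(nb)], simulated$r[seq_len(nb)])))
    stop("mismatched binning between target and simulated RDF")
  keep <- which(target$r[seq_len(nb)] >= r_min_fit &
                target$r[seq_len(nb)] <= r_max_fit)
  n <- length(keep)
  if (n <= p) stop("not enough bins in the fitting window (n <= p)")
  sum((target$g[keep] - simulated$g[keep])^2) / (n - p)
}

# Low-discrepancy candidate pool over the domain box. delta_exp is drawn
# uniformly in (nu_exp, delta_hi], guaranteeing a valid repulsion/attraction
# ordering for every candidate.
sample_candidates <- function(cfg) {
  d <- cfg$domains
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 1))
  u <- lhs::randomLHS(cfg$pool_size, 4)
  eps <- d$epsilon[1] + u[, 1] * diff(d$epsilon)
  sig <- d$sigma[1] + u[, 2] * diff(d$sigma)
  nu <- d$nu_exp[1] + u[, 3] * diff(d$nu_exp)
  delta_hi <- d$delta_exp[2]
  del <- nu + u[, 4] * (delta_hi - nu)
  del <- pmax(del, nu + 0.25) # keep exponents distinguishable
  lapply(seq_len(cfg$pool_size), function(i)
    glj_params(eps[i], sig[i], del[i], nu[i], r_cut = cfg$r_cut))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

#' Fit a potential to a target RDF with the intuitive selection strategy
#'
#' Round `t` runs each surviving candidate's inner Monte Carlo for
#' `step_ladder[t]` sweeps (all candidates sharing one per-round seed),
#' scores candidates by [msr()] against the target over the fitting window,
#' and keeps the best `ceiling(theta * pool)`. When a single candidate
#' remains it is evaluated once more at the next rung (its reported MSR);
#' if the ladder is exhausted with several survivors the one with the lowest
#' last-round MSR wins. Ties break toward the lower candidate index.
#'
#' @param target `rdf_curve` to match.
#' @param n_particles,domain_length,core_diameter section metadata for the
#'   inner MC (particle count, data-span length in bp, hard-core diameter in
#'   bp).
#' @param cfg an [iss_config()].
#' @param lambda_max displacement bound for the inner MC (tune once per
#'   section with [tune_lambda()]).
#' @param r_min_fit,r_max_fit fitting window; defaults to
#'   `[core_diameter, r_cut]`.
#' @return An object of class `fit_result`: `params`, `msr`, `n_rounds`,
#'   `history` (data.frame with round, pool size, best MSR), `candidates`.
#' @export
iss_fit <- function(target, n_particles, domain_length, core_diameter,
                    cfg = iss_config(), lambda_max = 64,
                    r_min_fit = NULL, r_max_fit = NULL) {
  stopifnot(inherits(target, "rdf_curve"))
  if (sum(target$g > 0) < 2) stop("degenerate target RDF")
  r_min_fit <- r_min_fit %||% core_diameter
  r_max_fit <- r_max_fit %||% cfg$r_cut
  cands <- sample_candidates(cfg)
  idx <- seq_along(cands)
  history <- data.frame(round = integer(0), pool = integer(0),
                        best_msr = numeric(0))
  best_msr <- NA_real_
  winner <- NA_integer_
  scores <- NULL
  for (t in seq_along(cfg$step_ladder)) {
    sweeps <- cfg$step_ladder[t]
    round_seed <- derive_seed(cfg$seed, 100 + t) # common random numbers
    scores <- vapply(idx, function(i) {
      run <- run_mc(cands[[i]],
                    mc_config(n_particles, domain_length, core_diameter,
                              lambda_max = lambda_max, n_steps = sweeps,
                              seed = round_seed,
                              sample_every = max(1L, sweeps %/% 50L)))
      sim <- rdf_from_conformations(run, bin_width = target$bin_width,
                                    r_max = target$r_max)
      msr(target, sim, p = cfg$p, r_min_fit = r_min_fit,
          r_max_fit = r_max_fit)
    }, numeric(1))
    ord <- order(scores, idx) # tie-break: lower candidate index
    best_msr <- scores[ord[1]]
    history <- rbind(history, data.frame(round = t, pool = length(idx),
                                         best_msr = best_msr))
    if (length(idx) == 1L) { # final high-precision evaluation of the champion
      winner <- idx[1]
      break
    }
    keep <- max(1L, ceiling(cfg$theta * length(idx)))
    idx <- idx[ord[seq_len(keep)]]
    winner <- idx[1]
  }
  structure(list(params = cands[[winner]], msr = best_msr,
                 n_rounds = nrow(history), history = history,
                 candidates = cands, winner_index = winner),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> msr=%.4g after %d rounds\n", x$msr, x$n_rounds))
  print(x$params)
  invisible(x)
}

#' Fit one genome section
#'
#' Computes the section's RDF from nucleosome centers (open-interval edge
#' correction), tunes the displacement bound on the section's hard-rod
#' skeleton, and runs [iss_fit()]. Sections with fewer than `min_nucleosomes`
#' are flagged unfit (the RDF would be too noisy) instead of raising, so
#' genome-wide runs complete.
#'
#' @param nucs [nucleosome_set()] in section-local coordinates (see
#'   [nucleosomes_in_section()]).
#' @param section one row of [partition_sections()].
#' @param cfg an [iss_config()].
#' @param bin_width,r_max RDF binning.
#' @param min_nucleosomes unfit threshold (default 20).
#' @return A list of class `section_fit`: `fit` (a `fit_result` or `NULL`),
#'   `rdf`, `fit_ok`, `n_nucleosomes`, `mean_length`, `lambda`,
#'   `acceptance`, `section`.
#' @export
fit_section <- function(nucs, section, cfg = iss_config(), bin_width = 10,
                        r_max = 1000, min_nucleosomes = 20) {
  n <- n_nucleosomes(nucs)
  L <- section$data_end - section$data_start
  if (n < min_nucleosomes) {
    return(structure(list(fit = NULL, rdf = NULL, fit_ok = FALSE,
                          n_nucleosomes = n, mean_length = nucs$mean_length,
                          lambda = NA_real_, acceptance = NA_real_,
                          section = section),
                     class = "section_fit"))
  }
  target <- compute_rdf(nucs$centers, L, bin_width = bin_width,
                        r_max = r_max, edge = "open")
  core <- nucs$mean_length
  base_cfg <- mc_config(n, L, core, seed = derive_seed(cfg$seed, 9))
  lambda <- tune_lambda(NULL, base_cfg)
  fit <- iss_fit(target, n, L, core, cfg = cfg,
                 lambda_max = as.numeric(lambda))
  structure(list(fit = fit, rdf = target, fit_ok = TRUE,
                 n_nucleosomes = n, mean_length = core,
                 lambda = as.numeric(lambda), acceptance = NA_real_,
                 section = section),
            class = "section_fit")
}
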
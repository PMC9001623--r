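# Reduced isothermal compressibility by the block density distribution
# method: count particles in M_b equal blocks per conformation, pool the
# counts, take variance over mean, and extrapolate the finite-block bias
# (linear in M_b, i.e. in 1/L at fixed section size) to M_b = 0.

#' Block-count census over conformations
#'
#' Splits the section `[0, L0)` into `M_b` equal blocks, counts particle
#' centers per block in every conformation, and pools all blocks of all
#' conformations into one count histogram.
#'
#' @param confs matrix of conformations (one per row) or an `mc_run`.
#' @param L0 section length in bp.
#' @param M_b number of blocks.
#' @return An object of class `block_census`: `M_b`, `L` (block size),
#'   `counts` (named integer histogram over N), `n_conformations`.
#' @export
block_census <- function(confs, L0, M_b) {
  if (inherits(confs, "mc_run")) confs <- confs$samples
  if (is.null(dim(confs))) confs <- matrix(confs, nrow = 1)
  if (nrow(confs) == 0) stop("no conformations")
  stopifnot(M_b >= 1)
  Lb <- L0 / M_b
  counts <- integer(0)
  for (r in seq_len(nrow(confs))) {
    b <- pmin(floor(confs[r, ] / Lb), M_b - 1)
    counts <- c(counts, tabulate(b + 1, nbins = M_b))
  }
  h <- table(counts)
  structure(list(M_b = as.integer(M_b), L = Lb,
                 counts = stats::setNames(as.integer(h), names(h)),
                 n_conformations = nrow(confs)),
            class = "block_census")
}

#' Reduced isothermal compressibility of a block census
#'
#' The variance-to-mean ratio of the pooled block counts,
#' `(<N^2> - <N>^2) / <N>`. This is the raw finite-size estimate; see
#' [section_chi()] for the fixed-N ensemble correction and extrapolation.
#'
#' @param census a [block_census()], or a named histogram (names = counts N,
#'   values = frequencies).
#' @return Non-negative scalar.
#' @export
chi_block <- function(census) {
  h <- if (inherits(census, "block_census")) census$counts else census
  N <- as.numeric(names(h))
  w <- as.numeric(h)
  m1 <- sum(N * w) / sum(w)
  if (m1 == 0) stop("empty blocks: <N> = 0")
  m2 <- sum(N^2 * w) / sum(w)
  (m2 - m1^2) / m1
}

#' Extrapolate block compressibilities to the thermodynamic limit
#'
#' Unweighted ordinary least squares of `chi` against `M_b`; since the block
#' size is `L = L0 / M_b`, a term linear in `M_b` is the `c / L` finite-size
#' bias, and the intercept at `M_b = 0` is the thermodynamic-limit estimate
#' `chi_inf`.
#'
#' @param chi_blocks data.frame (or 2-column matrix) with columns `M_b` and
#'   `chi`; at least 3 distinct `M_b` values.
#' @return An object of class `chi_estimate`: `chi_blocks`, `chi_inf`,
#'   `slope`, `r_squared`, `clipped` (TRUE when a negative intercept was
#'   clipped to 0).
#' @export
extrapolate_chi <- function(chi_blocks) {
  chi_blocks <- as.data.frame(chi_blocks)
  names(chi_blocks)[1:2] <- c("M_b", "chi")
  if (length(unique(chi_blocks$M_b)) < 3)
    stop("need at least 3 distinct M_b values")
  fit <- lm(chi ~ M_b, data = chi_blocks)
  chi_inf <- unname(coef(fit)[1])
  clipped <- FALSE
  if (chi_inf < 0) {
    warning("negative extrapolated compressibility clipped to 0")
    chi_inf <- 0
    clipped <- TRUE
  }
  ss_tot <- sum((chi_blocks$chi - mean(chi_blocks$chi))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(chi_blocks = chi_blocks, chi_inf = chi_inf,
                 slope = unname(coef(fit)[2]),
                 r_squared = r2, clipped = clipped),
            class = "chi_estimate")
}

#' @export
print.chi_estimate <- function(x, ...) {
  cat(sprintf("<chi_estimate> chi_inf=%.4f (slope %.3g/block, R^2=%.3f)\n",
              x$chi_inf, x$slope, x$r_squared))
  invisible(x)
}

#' Section compressibility from a fitted potential
#'
#' Generates conformations with [run_mc()] under the section's fitted
#' potential, computes the block census for each `M_b`, and extrapolates to
#' `M_b = 0`. Because the simulation holds the particle number fixed, the
#' raw variance-to-mean ratio is suppressed by the factor `1 - 1/M_b`
#' (exactly binomial for an ideal gas); each block estimate is divided by
#' this factor before extrapolation so that `chi_inf` refers to the
#' unconstrained (grand-canonical) fluctuations the thermodynamic limit is
#' defined for.
#'
#' @param potential a [glj_params()] or `NULL` (hard rods / free particles).
#' @param mc_cfg an [mc_config()] describing the section (particle count,
#'   data-span length, hard core, sweeps).
#' @param M_b_list block numbers (default `c(4, 8, 16, 32, 64)`).
#' @param ensemble_correction divide each raw chi by `1 - 1/M_b` (default
#'   TRUE).
#' @return A `chi_estimate` with an extra field `acceptance`.
#' @export
section_chi <- function(potential, mc_cfg, M_b_list = c(4, 8, 16, 32, 64),
                        ensemble_correction = TRUE) {
  stopifnot(all(M_b_list >= 2), length(M_b_list) >= 3)
  run <- run_mc(potential, mc_cfg)
  if (nrow(run$samples) == 0) stop("no sampled conformations; increase n_steps")
  chi <- vapply(M_b_list, function(mb) {
    raw <- chi_block(block_census(run$samples, mc_cfg$domain_length, mb))
    if (ensemble_correction) raw / (1 - 1 / mb) else raw
  }, numeric(1))
  est <- extrapolate_chi(data.frame(M_b = M_b_list, chi = chi))
  est$acceptance <- run$acceptance
  est
}
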
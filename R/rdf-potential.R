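# 1D radial distribution functions, the mean-field (potential-of-mean-force)
# inversion, and the generalized Lennard-Jones pair potential.

#' Construct generalized Lennard-Jones potential parameters
#'
#' The ansatz is `V(r) = 4*epsilon*((sigma/r)^delta_exp - (sigma/r)^nu_exp)`,
#' cut and shifted at `r_cut` so the potential is continuous and zero at and
#' beyond the cutoff. `epsilon` (in units of kT) sets the amplitude, `sigma`
#' (bp) the length scale (the zero crossing), `delta_exp` the short-range
#' repulsion steepness and `nu_exp` the long-range attraction.
#'
#' @param epsilon well amplitude, kT units, `> 0`.
#' @param sigma length scale in bp, `> 0`.
#' @param delta_exp repulsive exponent, `> nu_exp`.
#' @param nu_exp attractive exponent, `> 0`.
#' @param r_cut cutoff distance in bp (`Inf` for no cutoff), `> sigma`.
#' @return An object of class `glj_params`.
#' @export
glj_params <- function(epsilon, sigma, delta_exp, nu_exp, r_cut = 500) {
  stopifnot(epsilon > 0, sigma > 0, nu_exp > 0, delta_exp > nu_exp,
            r_cut > sigma)
  structure(list(epsilon = epsilon, sigma = sigma, delta_exp = delta_exp,
                 nu_exp = nu_exp, r_cut = r_cut),
            class = "glj_params")
}

#' @export
print.glj_params <- function(x, ...) {
  cat(sprintf(
    "<glj_params> eps=%.3g kT, sigma=%.1f bp, delta=%.2f, nu=%.2f, r_cut=%.0f; r*=%.1f bp\n",
    x$epsilon, x$sigma, x$delta_exp, x$nu_exp, x$r_cut, glj_rmin(x)))
  invisible(x)
}

#' Evaluate the generalized Lennard-Jones potential
#'
#' Cut-and-shifted: `V(r) - V(r_cut)` for `r <= r_cut`, exactly 0 beyond.
#'
#' @param params a [glj_params()].
#' @param r distances in bp (vectorized), all `> 0`.
#' @return Energies in kT units.
#' @export
glj_energy <- function(params, r) {
  stopifnot(inherits(params, "glj_params"))
  if (any(r <= 0)) stop("r must be > 0")
  v <- function(rr) {
    s <- params$sigma / rr
    4 * params$epsilon * (s^params$delta_exp - s^params$nu_exp)
  }
  shift <- if (is.finite(params$r_cut)) v(params$r_cut) else 0
  ifelse(r > params$r_cut, 0, v(r) - shift)
}

#' Location of the potential minimum
#'
#' For the generalized Lennard-Jones form the minimum lies at
#' `r* = sigma * (delta_exp/nu_exp)^(1/(delta_exp - nu_exp))`.
#'
#' @param params a [glj_params()].
#' @return r* in bp.
#' @export
glj_rmin <- function(params) {
  params$sigma *
    (params$delta_exp / params$nu_exp)^(1 / (params$delta_exp - params$nu_exp))
}

#' Compute a 1D radial distribution function
#'
#' Bins all ordered pair separations `|x_i - x_j| <= r_max` into uniform bins
#' of width `bin_width` and normalizes by `N * rho * 2*bin_width` (the 1D
#' shell measure counts both directions), with `rho = N / domain_length`, so
#' a homogeneous unconstrained system gives `g = 1` in every bin.
#'
#' @param positions numeric vector of particle positions in bp.
#' @param domain_length domain size in bp.
#' @param bin_width bin width in bp (default 10).
#' @param r_max largest separation retained (default 1000).
#' @param edge one of `"open"` (finite open interval: each bin additionally
#'   normalized by the fraction `(L - r)/L` of pair placements geometrically
#'   able to realize that separation) or `"periodic"` (minimum-image
#'   distances on a ring, no edge factor; requires `r_max <= L/2`).
#' @return An object of class `rdf_curve`: `bin_edges`, `r` (midpoints), `g`,
#'   raw ordered-pair `counts`, `n_particles`, `density`, and the settings.
#' @export
compute_rdf <- function(positions, domain_length, bin_width = 10,
                        r_max = 1000, edge = c("open", "periodic")) {
  edge <- match.arg(edge)
  n <- length(positions)
  if (n < 2) stop("insufficient particles (N < 2)")
  stopifnot(bin_width >= 1, r_max <= domain_length)
  if (edge == "periodic" && r_max > domain_length / 2)
    stop("periodic RDF requires r_max <= domain_length/2")
  counts <- .pair_counts_cpp(matrix(positions, nrow = 1), domain_length,
                             bin_width, r_max, edge == "periodic")
  rdf_from_counts(counts, n_conf = 1L, n_particles = n,
                  domain_length = domain_length, bin_width = bin_width,
                  r_max = r_max, edge = edge)
}

# Shared normalization: counts are ordered-pair tallies summed over n_conf
# conformations.
rdf_from_counts <- function(counts, n_conf, n_particles, domain_length,
                            bin_width, r_max, edge) {
  nbin <- length(counts)
  edges <- seq(0, by = bin_width, length.out = nbin + 1)
  mid <- (edges[-1] + edges[-(nbin + 1)]) / 2
  rho <- n_particles / domain_length
  norm <- n_particles * rho * 2 * bin_width
  geom <- if (edge == "open") pmax(domain_length - mid, 0) / domain_length else 1
  g <- counts / n_conf / (norm * geom)
  g[!is.finite(g)] <- 0
  structure(list(bin_edges = edges, r = mid, g = as.numeric(g),
                 counts = as.numeric(counts), n_conformations = n_conf,
                 n_particles = n_particles, density = rho,
                 domain_length = domain_length, bin_width = bin_width,
                 r_max = r_max, edge = edge),
            class = "rdf_curve")
}

#' @export
print.rdf_curve <- function(x, ...) {
  cat(sprintf(
    "<rdf_curve> %d bins of %g bp up to %g bp; N=%d, rho=%.4g /bp, peak g=%.2f at %g bp\n",
    length(x$g), x$bin_width, x$r_max, x$n_particles, x$density,
    max(x$g), x$r[which.max(x$g)]))
  invisible(x)
}

#' Write / read an RDF curve as two-column TSV (bin midpoint, g)
#' @param rdf an `rdf_curve`.
#' @param path output path.
#' @export
write_rdf <- function(rdf, path) {
  write.table(data.frame(r = rdf$r, g = rdf$g), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-field potential (potential of mean force)
#'
#' `-log(max(g, floor_g))` per bin, in kT units. The floor bounds the
#' potential where `g = 0` (hard-core region, unpopulated bins). The default
#' floor is one pseudo-count relative to the number of pair slots,
#' `1 / (N * r_max / bin_width)`.
#'
#' @param rdf an `rdf_curve`.
#' @param floor_g positive lower bound applied to g before taking the log.
#' @return Numeric vector of potential values per bin.
#' @export
mean_field_potential <- function(rdf, floor_g = NULL) {
  stopifnot(inherits(rdf, "rdf_curve"))
  if (is.null(floor_g))
    floor_g <- 1 / (rdf$n_particles * rdf$r_max / rdf$bin_width)
  stopifnot(floor_g > 0)
  -log(pmax(rdf$g, floor_g))
}
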
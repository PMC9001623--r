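# Synthetic positioning tracks with known statistical structure: Poisson
# (ideal gas), Tonks gas (hard rods), and equilibrium samples of a known
# generalized Lennard-Jones potential, plus missing-data corruption that
# mimics noisy MNase-derived tracks. Every generator is deterministic under
# a fixed seed and returns the ground truth needed for recovery tests.

#' Specification for a synthetic positioning track
#'
#' @param kind `"poisson"` (centers uniform i.i.d., no exclusion),
#'   `"tonks"` (hard rods of `nucleosome_length`, exact equilibrium
#'   sampling), or `"glj"` (equilibrium Monte Carlo sample under
#'   `potential`).
#' @param chrom_length track length in bp.
#' @param n_nucleosomes number of nucleosomes before dropout.
#' @param nucleosome_length painted length in bp (default 147, the canonical
#'   core particle).
#' @param potential a [glj_params()] (required for `kind = "glj"`).
#' @param dropout_rate fraction of nucleosomes deleted independently.
#' @param jitter_sd Gaussian center jitter in bp.
#' @param seed RNG seed.
#' @param mc_sweeps equilibration sweeps for `kind = "glj"`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("poisson", "tonks", "glj"),
                           chrom_length, n_nucleosomes,
                           nucleosome_length = 147, potential = NULL,
                           dropout_rate = 0, jitter_sd = 0, seed = 1,
                           mc_sweeps = 5000) {
  kind <- match.arg(kind)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, jitter_sd >= 0)
  if (kind %in% c("tonks", "glj") &&
      n_nucleosomes * nucleosome_length >= chrom_length)
    stop("infeasible packing")
  if (kind == "glj" && is.null(potential))
    stop("kind = 'glj' requires a potential")
  structure(list(kind = kind, chrom_length = chrom_length,
                 n_nucleosomes = as.integer(n_nucleosomes),
                 nucleosome_length = nucleosome_length,
                 potential = potential, dropout_rate = dropout_rate,
                 jitter_sd = jitter_sd, seed = as.integer(seed),
                 mc_sweeps = as.integer(mc_sweeps)),
            class = "synthetic_spec")
}

# Exact equilibrium sample of N hard rods of length `len` on [0, L):
# uniform points in the free volume, sorted, plus cumulative rod offsets.
sample_tonks_centers <- function(n, L, len) {
  free <- L - n * len
  gaps <- sort(runif(n, 0, free))
  gaps + (seq_len(n) - 1) * len + len / 2
}

# Paint centers as runs of 1s of length `len` (overlaps merge naturally).
paint_centers <- function(centers, L, len, chrom_name = "chr") {
  values <- integer(L)
  s <- pmax(0, floor(centers) - floor(len / 2))
  e <- pmin(L, s + len)
  for (i in seq_along(s)) if (e[i] > s[i]) values[(s[i] + 1):e[i]] <- 1L
  occupancy_track(chrom_name, values)
}

#' Generate a synthetic occupancy track with known truth
#'
#' @param spec a [synthetic_spec()].
#' @param chrom_name chromosome name for the track.
#' @return A list: `track` (an [occupancy_track()]), `truth` (list with the
#'   pre-dropout `centers`, the surviving `kept_centers`, and `potential`
#'   where applicable), `spec`.
#' @export
generate_track <- function(spec, chrom_name = "chr") {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  L <- spec$chrom_length
  n <- spec$n_nucleosomes
  len <- spec$nucleosome_length
  centers <- switch(spec$kind,
    poisson = sort(runif(n, len / 2, L - len / 2)),
    tonks = sample_tonks_centers(n, L, len),
    glj = {
      run <- run_mc(spec$potential,
                    mc_config(n, L, len, lambda_max = 64,
                              n_steps = spec$mc_sweeps,
                              seed = derive_seed(spec$seed, 3),
                              sample_every = spec$mc_sweeps)) # final conf only
      sort(run$final_positions)
    })
  kept <- centers
  if (spec$dropout_rate > 0)
    kept <- kept[runif(length(kept)) >= spec$dropout_rate]
  if (spec$jitter_sd > 0) {
    kept <- kept + rnorm(length(kept), 0, spec$jitter_sd)
    kept <- pmin(pmax(kept, len / 2), L - len / 2)
    kept <- sort(kept)
  }
  list(track = paint_centers(kept, L, len, chrom_name),
       truth = list(centers = centers, kept_centers = kept,
                    potential = spec$potential),
       spec = spec)
}

#' Corrupt a track with dropout and center jitter
#'
#' Parses the track into nucleosomes, deletes each independently with
#' probability `dropout_rate`, jitters the surviving centers by a rounded
#' Gaussian (clipped to the domain), and repaints with each nucleosome's own
#' length.
#'
#' @param track an [occupancy_track()].
#' @param dropout_rate deletion probability per nucleosome.
#' @param jitter_sd jitter standard deviation in bp.
#' @param seed RNG seed.
#' @return A corrupted [occupancy_track()] of the same length.
#' @export
corrupt_track <- function(track, dropout_rate = 0, jitter_sd = 0, seed = 1) {
  stopifnot(inherits(track, "occupancy_track"),
            dropout_rate >= 0, dropout_rate < 1, jitter_sd >= 0)
  if (dropout_rate == 0 && jitter_sd == 0) return(track)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nucs <- suppressWarnings(track_to_nucleosomes(track))
  k <- n_nucleosomes(nucs)
  if (k == 0) return(track)
  keep <- runif(k) >= dropout_rate
  centers <- nucs$centers[keep]
  lens <- (nucs$intervals[, "end"] - nucs$intervals[, "start"])[keep]
  if (jitter_sd > 0) {
    centers <- round(centers + rnorm(length(centers), 0, jitter_sd))
    centers <- pmin(pmax(centers, ceiling(lens / 2)),
                    track$length - ceiling(lens / 2))
  }
  values <- integer(track$length)
  s <- pmax(0, centers - floor(lens / 2))
  e <- pmin(track$length, s + lens)
  for (i in seq_along(s)) if (e[i] > s[i]) values[(s[i] + 1):e[i]] <- 1L
  occupancy_track(track$chrom_name, values)
}

#' Default potential families for the genome fixture
#'
#' Three families spanning behaviors the classifier should separate, chosen
#' so that each leaves a distinct signature in the measurable features: a
#' dense family with a deep well at the canonical ~168 bp spacing
#' (heterochromatin-like regular array), a dense family preferring a wider
#' ~226 bp spacing with a softer, broader well (so the fitted exponents must
#' differ), and a sparse hard-rod family without attraction whose
#' compressibility is a strong outlier (euchromatin-like irregular array).
#'
#' @return Named list of family definitions (`potential`,
#'   `n_per_core`, `kind`).
#' @export
default_families <- function() {
  list(
    dense_ordered = list(kind = "glj",
                         potential = glj_params(2.5, 150, 12, 6),
                         n_per_core = 267),
    dense_wide = list(kind = "glj",
                      potential = glj_params(2.5, 160, 4, 2),
                      n_per_core = 240),
    sparse_outlier = list(kind = "tonks", potential = NULL,
                          n_per_core = 80)
  )
}

#' Write a synthetic multi-chromosome genome fixture to disk
#'
#' Each chromosome starts with a pad of `overlap` bp followed by consecutive
#' `core_len` blocks, each block generated independently under its assigned
#' family, so that the pipeline's section cores coincide exactly with the
#' generated blocks. Families are assigned in contiguous runs so most
#' sections see single-family data across their overlaps too. Writes one
#' bedGraph per chromosome plus a truth TSV with the generating family of
#' every section.
#'
#' @param out_dir output directory (created if needed).
#' @param n_chroms number of chromosomes.
#' @param sections_per_chrom core blocks per chromosome.
#' @param families family definitions as in [default_families()].
#' @param block_run length of same-family runs along a chromosome
#'   (default 3).
#' @param seed master seed.
#' @param core_len core block length in bp.
#' @return Invisibly, a list with `tracks` (bedGraph paths), `truth_path`,
#'   and the `truth` data.frame (`chrom`, `section`, `family`).
#' @export
make_genome_fixture <- function(out_dir, n_chroms = 2,
                                sections_per_chrom = 9,
                                families = default_families(),
                                block_run = 3, seed = 1, core_len = 50000,
                                overlap = 12500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam_names <- names(families)
  truth <- data.frame(chrom = character(0), section = integer(0),
                      family = character(0))
  paths <- character(0)
  counter <- 0
  gen_block <- function(fam, len, seed) {
    n <- max(2L, as.integer(round(fam$n_per_core * len / core_len)))
    sp <- synthetic_spec(fam$kind, len, n, potential = fam$potential,
                         seed = seed)
    generate_track(sp)$track$values
  }
  for (ci in seq_len(n_chroms)) {
    chrom <- sprintf("chrS%d", ci)
    fam_of <- function(si) { # si 1-based block index within chromosome
      ((ci - 1) * sections_per_chrom + si - 1) %/% block_run %%
        length(families) + 1
    }
    counter <- counter + 1
    values <- gen_block(families[[fam_of(1)]], overlap,
                        derive_seed(seed, 100000 + counter))
    for (si in seq_len(sections_per_chrom)) {
      counter <- counter + 1
      fam_i <- fam_of(si)
      fam <- families[[fam_i]]
      values <- c(values, gen_block(fam, core_len,
                                    derive_seed(seed, counter)))
      truth <- rbind(truth, data.frame(chrom = chrom, section = si - 1L,
                                       family = fam_names[fam_i]))
    }
    track <- occupancy_track(chrom, values)
    p <- file.path(out_dir, paste0(chrom, ".bedGraph"))
    write_track_bedgraph(track, p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(tracks = paths, truth_path = truth_path, truth = truth))
}

#' Write an occupancy track as bedGraph (runs of constant value)
#' @param track an [occupancy_track()].
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- sprintf("%s\t%d\t%d\t%d", track$chrom_name, starts, ends,
                   r$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
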
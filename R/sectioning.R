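# Chromosome sectioning with symmetric overlaps, and the rolling-mean
# density view of an occupancy track.

#' Partition a chromosome into overlapping sections
#'
#' Section `i` has a core span `[overlap + core_len*i, overlap + core_len*(i+1))`
#' and a data span `[core_len*i, core_len*i + core_len + 2*overlap)`, both
#' clipped to the chromosome; with the defaults the data span is 75,000 bp,
#' so neighboring sections share 25,000 bp of data and section boundaries are
#' deliberately fuzzy. The number of sections is `floor(L / core_len)`; a
#' trailing remainder shorter than `core_len` is merged into the last
#' section's data span rather than forming a short section of its own.
#'
#' @param chrom_length chromosome length in bp.
#' @param core_len section core length in bp (default 50,000).
#' @param overlap overlap on each side in bp (default 12,500).
#' @param chrom_name chromosome name carried through to the result.
#' @return A data.frame with one row per section: `index` (0-based), `chrom`,
#'   `data_start`, `data_end`, `core_start`, `core_end`.
#' @export
partition_sections <- function(chrom_length, core_len = 50000,
                               overlap = 12500, chrom_name = "chr") {
  stopifnot(chrom_length >= 1, core_len >= 1, overlap >= 0)
  if (core_len <= 2 * overlap)
    warning("core_len <= 2*overlap: cores are dominated by overlap")
  n <- floor(chrom_length / core_len)
  if (n < 1) {
    warning("chromosome shorter than core_len: single whole-chromosome section")
    return(data.frame(index = 0L, chrom = chrom_name,
                      data_start = 0, data_end = chrom_length,
                      core_start = 0, core_end = chrom_length))
  }
  i <- seq_len(n) - 1L
  core_start <- pmin(overlap + core_len * i, chrom_length)
  core_end <- pmin(overlap + core_len * (i + 1), chrom_length)
  data_start <- pmax(core_len * i, 0)
  data_end <- pmin(core_len * i + core_len + 2 * overlap, chrom_length)
  data_end[n] <- chrom_length # merge trailing remainder into last section
  data.frame(index = i, chrom = chrom_name,
             data_start = data_start, data_end = data_end,
             core_start = core_start, core_end = core_end)
}

#' Rolling-mean nucleosome density
#'
#' Centered moving average of the 0/1 occupancy values; at the edges the
#' window is truncated to the available positions (mean over what exists).
#' This is the smoothed density view used to visualize coverage at the
#' multi-kilobase scale.
#'
#' @param track an [occupancy_track()].
#' @param window window size in bp (default 5,000).
#' @return Numeric vector in `[0, 1]`, same length as the track.
#' @export
rolling_mean_density <- function(track, window = 5000) {
  stopifnot(inherits(track, "occupancy_track"), window >= 1)
  n <- track$length
  if (window > n) {
    warning("window larger than track: whole-track mean everywhere")
    return(rep(mean(track$values), n))
  }
  half_l <- floor((window - 1) / 2)
  half_r <- window - 1 - half_l
  cs <- c(0, cumsum(track$values))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Restrict a nucleosome set to one section's data span
#'
#' A nucleosome belongs to the section iff its center lies in
#' `[data_start, data_end)`; coordinates are re-expressed relative to
#' `data_start` and the mean length is recomputed over the kept nucleosomes.
#'
#' @param nucs a [nucleosome_set()].
#' @param section one row of [partition_sections()] output.
#' @return A [nucleosome_set()] in section-local coordinates (possibly empty).
#' @export
nucleosomes_in_section <- function(nucs, section) {
  stopifnot(inherits(nucs, "nucleosome_set"))
  keep <- nucs$centers >= section$data_start & nucs$centers < section$data_end
  if (!any(keep)) {
    return(structure(list(chrom_name = nucs$chrom_name,
                          intervals = cbind(start = numeric(0), end = numeric(0)),
                          centers = numeric(0), mean_length = NA_real_),
                     class = "nucleosome_set"))
  }
  structure(list(chrom_name = nucs$chrom_name,
                 intervals = cbind(start = nucs$intervals[keep, "start"] - section$data_start,
                                   end = nucs$intervals[keep, "end"] - section$data_start),
                 centers = nucs$centers[keep] - section$data_start,
                 mean_length = mean(nucs$intervals[keep, "end"] -
                                    nucs$intervals[keep, "start"])),
            class = "nucleosome_set")
}
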
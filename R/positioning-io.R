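# Reading/writing nucleosome positioning data and converting between the
# binary per-basepair occupancy representation and nucleosome interval sets.
# All coordinates are 0-based, half-open internally; 1-based formats (wiggle,
# rtracklayer's GRanges) are converted on read.

#' Construct a binary occupancy track
#'
#' A track stores, for one chromosome, a 0/1 value per basepair: 1 where the
#' basepair is covered by a nucleosome, 0 in voids (including missing data,
#' which is not imputed).
#'
#' @param chrom_name chromosome name.
#' @param values integer/numeric vector of 0s and 1s, index = 0-based position + 1.
#' @return An object of class `occupancy_track`.
#' @export
occupancy_track <- function(chrom_name, values) {
  values <- as.integer(values)
  if (length(values) < 1L) stop("track length must be >= 1")
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("occupancy values must be 0 or 1")
  structure(list(chrom_name = as.character(chrom_name),
                 length = length(values),
                 values = values),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %s: %d bp, %.1f%% covered\n",
              x$chrom_name, x$length, 100 * mean(x$values)))
  invisible(x)
}

#' Construct a nucleosome set
#'
#' Sorted, non-overlapping 0-based half-open intervals with their center
#' positions (midpoint, rounded down) and the arithmetic mean interval length.
#'
#' @param chrom_name chromosome name.
#' @param starts,ends integer vectors of interval bounds (0-based half-open).
#' @return An object of class `nucleosome_set` with fields `chrom_name`,
#'   `intervals` (two-column matrix), `centers`, `mean_length`.
#' @export
nucleosome_set <- function(chrom_name, starts, ends) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (any(ends <= starts))
    stop(sprintf("interval with end <= start at entry %d",
                 which(ends <= starts)[1]))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)]))
    stop("overlapping nucleosome intervals")
  structure(list(chrom_name = as.character(chrom_name),
                 intervals = cbind(start = starts, end = ends),
                 centers = floor((starts + ends) / 2),
                 mean_length = if (length(starts)) mean(ends - starts) else NA_real_),
            class = "nucleosome_set")
}

#' @export
print.nucleosome_set <- function(x, ...) {
  cat(sprintf("<nucleosome_set> %s: %d nucleosomes, mean length %.1f bp\n",
              x$chrom_name, nrow(x$intervals), x$mean_length))
  invisible(x)
}

#' Number of nucleosomes in a set
#' @param x a `nucleosome_set`.
#' @export
n_nucleosomes <- function(x) nrow(x$intervals)

#' Read a binary occupancy track
#'
#' Reads per-basepair occupancy from bedGraph, wiggle (fixed or variable
#' step), or a plain two-column `position value` text file (1-based
#' positions). Records must belong to a single chromosome. Any strictly
#' positive value is coerced to 1 (with a warning when non-0/1 values are
#' seen); uncovered positions are 0.
#'
#' @param path input file.
#' @param format_hint one of `"bedgraph"`, `"wig"`, `"two_column"`.
#' @param declared_length optional chromosome length in bp overriding the
#'   maximum end coordinate (e.g. from a chrom.sizes file).
#' @return An [occupancy_track()].
#' @export
read_occupancy <- function(path,
                           format_hint = c("bedgraph", "wig", "two_column"),
                           declared_length = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format_hint == "two_column") {
    df <- read.table(path, header = FALSE,
                     col.names = c("pos", "value"),
                     colClasses = c("numeric", "numeric"))
    if (nrow(df) == 0 && is.null(declared_length))
      stop("empty file and no declared_length")
    if (any(df$pos < 1)) stop("negative or zero 1-based position")
    chrom <- "chr"
    starts0 <- df$pos - 1; ends0 <- df$pos; vals <- df$value
  } else {
    fmt <- if (format_hint == "bedgraph") "bedGraph" else "WIG"
    gr <- tryCatch(rtracklayer::import(path, format = fmt),
                   error = function(e) NULL)
    if (is.null(gr) || length(gr) == 0) {
      if (is.null(declared_length))
        stop("empty file and no declared_length")
      return(occupancy_track("chr", integer(declared_length)))
    }
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (length(unique(chrom)) > 1)
      stop("track contains more than one chromosome: ",
           paste(unique(chrom), collapse = ", "))
    chrom <- chrom[1]
    starts0 <- GenomicRanges::start(gr) - 1 # GRanges is 1-based closed
    ends0 <- GenomicRanges::end(gr)
    vals <- S4Vectors::mcols(gr)$score
  }
  if (any(starts0 < 0)) stop("negative coordinates in input")
  if (any(!vals %in% c(0, 1))) {
    warning("values other than 0/1 found; coercing positive values to 1")
    vals <- as.numeric(vals > 0)
  }
  L <- max(ends0, declared_length %||% 0)
  if (!is.null(declared_length) && max(ends0) > declared_length)
    stop("records extend past declared chromosome length")
  values <- integer(L)
  # conflict check: a basepair covered by both a 1-record and a 0-record
  cov1 <- integer(L); cov0 <- integer(L)
  for (i in seq_along(starts0)) {
    if (ends0[i] <= starts0[i]) next
    idx <- (starts0[i] + 1):ends0[i]
    if (vals[i] > 0) cov1[idx] <- 1L else cov0[idx] <- 1L
  }
  if (any(cov1 & cov0))
    stop("overlapping records with conflicting values")
  values[cov1 == 1L] <- 1L
  occupancy_track(chrom, values)
}

#' Read a chrom.sizes file
#'
#' @param path two-column text file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("chrom", "size"))
  stats::setNames(as.numeric(df$size), as.character(df$chrom))
}

#' Extract nucleosome intervals from a binary track
#'
#' Each maximal run of consecutive 1s becomes one nucleosome interval; the
#' center is the midpoint rounded down. An all-zero track yields an empty set
#' with `mean_length = NA` (flagged by a warning).
#'
#' @param track an [occupancy_track()].
#' @return A [nucleosome_set()].
#' @export
track_to_nucleosomes <- function(track) {
  stopifnot(inherits(track, "occupancy_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  if (!any(keep)) {
    warning("all-zero track: empty nucleosome set, mean_length undefined")
    return(structure(list(chrom_name = track$chrom_name,
                          intervals = cbind(start = numeric(0), end = numeric(0)),
                          centers = numeric(0), mean_length = NA_real_),
                     class = "nucleosome_set"))
  }
  nucleosome_set(track$chrom_name, starts[keep], ends[keep])
}

#' Paint a nucleosome set back onto a binary track
#'
#' Inverse of [track_to_nucleosomes()] for sorted non-overlapping sets.
#'
#' @param nucs a [nucleosome_set()].
#' @param length track length in bp (default: max interval end).
#' @return An [occupancy_track()].
#' @export
nucleosomes_to_track <- function(nucs, length = NULL) {
  stopifnot(inherits(nucs, "nucleosome_set"))
  L <- length %||% if (nrow(nucs$intervals)) max(nucs$intervals[, "end"]) else 1
  values <- integer(L)
  for (i in seq_len(nrow(nucs$intervals))) {
    s <- max(0, nucs$intervals[i, "start"]); e <- min(L, nucs$intervals[i, "end"])
    if (e > s) values[(s + 1):e] <- 1L
  }
  occupancy_track(nucs$chrom_name, values)
}

#' Read nucleosome positions from a BED-like file
#'
#' BED3+ with 0-based half-open coordinates, as produced by nucleosome
#' position callers. Extra columns are ignored; output is sorted by start.
#'
#' @param path BED file.
#' @return A [nucleosome_set()].
#' @export
read_nucleosome_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED input needs at least 3 columns")
  chrom <- unique(as.character(df[[1]]))
  if (length(chrom) > 1)
    stop("BED contains more than one chromosome")
  starts <- as.numeric(df[[2]]); ends <- as.numeric(df[[3]])
  bad <- which(ends <= starts)
  if (length(bad))
    stop(sprintf("end <= start at line %d", bad[1]))
  if (any(starts < 0)) stop("negative coordinates in BED input")
  nucleosome_set(chrom, starts, ends)
}

#' Write per-section results to TSV
#'
#' @param results a data.frame of section results with columns `chrom`,
#'   `core_start`, `core_end`, `epsilon`, `sigma`, `delta_exp`, `nu_exp`,
#'   `msr`, `chi_inf`, `class_label`.
#' @param path output TSV path.
#' @param bedgraph_path optional path for a bedGraph of class labels over the
#'   core spans (see [export_class_track()]).
#' @export
write_results <- function(results, path, bedgraph_path = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a nonempty data.frame")
  cols <- c("chrom", "core_start", "core_end", "epsilon", "sigma",
            "delta_exp", "nu_exp", "msr", "chi_inf", "class_label")
  miss <- setdiff(cols, names(results))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- results[, cols]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedgraph_path)) export_class_track(results, bedgraph_path)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
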
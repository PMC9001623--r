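# Pipeline orchestration: a single validated config drives sectioning, RDF,
# ISS fitting, compressibility, and classification over a set of tracks.
# Each stage is a plain function so it can be scripted; a thin command-line
# wrapper lives in inst/scripts/nucpot.R.

default_config <- function() {
  list(
    seed = 1,
    section = list(core_len = 50000, overlap = 12500),
    density = list(window = 5000),
    rdf = list(bin_width = 10, r_max = 1000),
    mc = list(n_steps = 1e6, sample_every = 100, boundary = "periodic"),
    iss = list(theta = 0.25, pool_size = 64,
               step_ladder = c(1e3, 1e4, 1e5, 1e6), r_cut = 500, p = 5,
               min_nucleosomes = 20),
    chi = list(M_b_list = c(4, 8, 16, 32, 64), n_steps = 1e6,
               sample_every = 100),
    classify = list(k = 3, n_restarts = 50, k_list = c(2, 3, 4, 5))
  )
}

#' Load and validate a pipeline configuration
#'
#' Starts from the documented defaults and overlays a YAML file and/or an
#' override list. Unknown keys raise an error (typo protection).
#'
#' @param path optional YAML config path.
#' @param overrides optional nested list of overrides applied last.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  merge_into <- function(base, new, prefix = "") {
    for (k in names(new)) {
      key <- paste0(prefix, k)
      if (!k %in% names(base))
        stop("unknown config key: ", key)
      if (is.list(base[[k]]) && is.list(new[[k]]))
        base[[k]] <- merge_into(base[[k]], new[[k]], paste0(key, "."))
      else base[[k]] <- new[[k]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_into(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Reduced, desk-scale configuration for tests and examples
#'
#' Same structure as [pipeline_config()] but with a shortened inner-MC step
#' ladder and fewer sweeps so a full run finishes in minutes.
#'
#' @param seed master seed.
#' @return `pipeline_config`.
#' @export
test_scale_config <- function(seed = 1) {
  pipeline_config(overrides = list(
    seed = seed,
    iss = list(pool_size = 48, step_ladder = c(300, 1000, 3000, 8000)),
    mc = list(n_steps = 2e4),
    chi = list(n_steps = 2e4, sample_every = 50)
  ))
}

#' Generate the synthetic genome fixture (pipeline stage)
#'
#' @param out_dir output directory.
#' @param config a `pipeline_config`.
#' @param ... passed to [make_genome_fixture()].
#' @return See [make_genome_fixture()].
#' @export
pipeline_simulate <- function(out_dir, config = pipeline_config(), ...) {
  make_genome_fixture(out_dir, seed = config$seed,
                      core_len = config$section$core_len,
                      overlap = config$section$overlap, ...)
}

#' Fit potentials for every section of a set of tracks (pipeline stage)
#'
#' @param track_paths bedGraph paths, one chromosome each.
#' @param config a `pipeline_config`.
#' @param out_path optional TSV path; when it exists, already-fitted
#'   sections are skipped unless `force = TRUE` (resumable runs).
#' @param force recompute sections already present in `out_path`.
#' @param verbose print one progress line per section.
#' @return data.frame with one row per section: coordinates, fitted
#'   parameters, `msr`, `lambda`, `n_nucleosomes`, `mean_length`, `fit_ok`,
#'   plus placeholder `chi_inf`/`class_label` columns.
#' @export
pipeline_fit <- function(track_paths, config = pipeline_config(),
                         out_path = NULL, force = FALSE, verbose = TRUE) {
  prev <- NULL
  if (!is.null(out_path) && file.exists(out_path) && !force)
    prev <- read_results(out_path)
  rows <- list()
  sec_counter <- 0
  for (path in track_paths) {
    track <- read_occupancy(path, "bedgraph")
    nucs <- track_to_nucleosomes(track)
    sections <- partition_sections(track$length,
                                   config$section$core_len,
                                   config$section$overlap,
                                   chrom_name = track$chrom_name)
    for (i in seq_len(nrow(sections))) {
      sec <- sections[i, ]
      sec_counter <- sec_counter + 1
      if (!is.null(prev)) {
        hit <- prev[prev$chrom == sec$chrom &
                    prev$core_start == sec$core_start, ]
        if (nrow(hit) == 1) {
          rows[[length(rows) + 1]] <- hit
          next
        }
      }
      local_nucs <- nucleosomes_in_section(nucs, sec)
      # one shared candidate pool and shared inner-MC streams for all
      # sections: differences between fitted sections then reflect their
      # data, not Monte Carlo luck (common random numbers across sections)
      cfg <- iss_config(theta = config$iss$theta,
                        pool_size = config$iss$pool_size,
                        step_ladder = config$iss$step_ladder,
                        r_cut = config$iss$r_cut, p = config$iss$p,
                        seed = derive_seed(config$seed, 777))
      sf <- fit_section(local_nucs, sec, cfg,
                        bin_width = config$rdf$bin_width,
                        r_max = config$rdf$r_max,
                        min_nucleosomes = config$iss$min_nucleosomes)
      row <- data.frame(
        chrom = sec$chrom, section = sec$index,
        core_start = sec$core_start, core_end = sec$core_end,
        data_start = sec$data_start, data_end = sec$data_end,
        n_nucleosomes = sf$n_nucleosomes,
        mean_length = sf$mean_length,
        epsilon = if (sf$fit_ok) sf$fit$params$epsilon else NA_real_,
        sigma = if (sf$fit_ok) sf$fit$params$sigma else NA_real_,
        delta_exp = if (sf$fit_ok) sf$fit$params$delta_exp else NA_real_,
        nu_exp = if (sf$fit_ok) sf$fit$params$nu_exp else NA_real_,
        r_cut = config$iss$r_cut,
        msr = if (sf$fit_ok) sf$fit$msr else NA_real_,
        lambda = sf$lambda, fit_ok = sf$fit_ok,
        chi_inf = NA_real_, class_label = NA_integer_)
      rows[[length(rows) + 1]] <- row
      if (verbose)
        message(sprintf("[fit] %s section %d: n=%d %s msr=%.4g",
                        sec$chrom, sec$index, sf$n_nucleosomes,
                        if (sf$fit_ok) "ok" else "UNFIT",
                        if (sf$fit_ok) sf$fit$msr else NA))
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_path)) write_results_full(res, out_path)
  res
}

# Full-width TSV round trip used by the resumable pipeline (the compact
# spec'd export lives in write_results()).
write_results_full <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Add extrapolated compressibilities to fitted sections (pipeline stage)
#'
#' Runs the section Monte Carlo under each fitted potential and fills the
#' `chi_inf` column (plus `chi_slope`, `chi_r2`).
#'
#' @param results data.frame from [pipeline_fit()].
#' @param config a `pipeline_config`.
#' @param verbose progress lines.
#' @return `results` with compressibility columns filled.
#' @export
pipeline_chi <- function(results, config = pipeline_config(),
                         verbose = TRUE) {
  if (!all(c("epsilon", "fit_ok") %in% names(results)))
    stop("run pipeline_fit() first")
  results$chi_slope <- NA_real_
  results$chi_r2 <- NA_real_
  for (i in seq_len(nrow(results))) {
    if (!isTRUE(results$fit_ok[i])) next
    pot <- glj_params(results$epsilon[i], results$sigma[i],
                      results$delta_exp[i], results$nu_exp[i],
                      results$r_cut[i])
    L <- results$data_end[i] - results$data_start[i]
    cfg <- mc_config(results$n_nucleosomes[i], L,
                     results$mean_length[i],
                     lambda_max = results$lambda[i],
                     n_steps = config$chi$n_steps,
                     sample_every = config$chi$sample_every,
                     seed = derive_seed(config$seed, 50000 + i))
    est <- section_chi(pot, cfg, M_b_list = config$chi$M_b_list)
    results$chi_inf[i] <- est$chi_inf
    results$chi_slope[i] <- est$slope
    results$chi_r2[i] <- est$r_squared
    if (verbose)
      message(sprintf("[chi] %s section %d: chi_inf=%.4f (R2=%.2f)",
                      results$chrom[i], results$section[i], est$chi_inf,
                      est$r_squared))
  }
  results
}

#' Classify sections into chromatin-like states (pipeline stage)
#'
#' @param results data.frame from [pipeline_chi()].
#' @param config a `pipeline_config`.
#' @param bedgraph_path optional class-track bedGraph output.
#' @param pca_path optional TSV with the PCA projection and per-k labels.
#' @return `results` with `class_label` filled (NA for unfit sections).
#' @export
pipeline_classify <- function(results, config = pipeline_config(),
                              bedgraph_path = NULL, pca_path = NULL) {
  feats <- feature_matrix(results, k = config$classify$k)
  labels <- kmeans_classify(feats, k = config$classify$k,
                            n_restarts = config$classify$n_restarts,
                            seed = config$seed)
  results$class_label <- NA_integer_
  results$class_label[attr(feats, "kept")] <- as.integer(labels)
  if (!is.null(bedgraph_path)) export_class_track(results, bedgraph_path)
  if (!is.null(pca_path)) {
    diag <- pca_diagnostic(feats, k_list = config$classify$k_list,
                           seed = config$seed)
    df <- data.frame(PC1 = diag$projection[, 1], PC2 = diag$projection[, 2])
    for (k in names(diag$labels))
      df[[paste0("labels_k", k)]] <- as.integer(diag$labels[[k]])
    write.table(df, pca_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results
}

#' Run the full pipeline on a set of tracks
#'
#' @param track_paths bedGraph paths.
#' @param config a `pipeline_config`.
#' @param out_dir output directory for TSV/bedGraph artifacts (optional).
#' @param verbose progress lines.
#' @return Final results data.frame.
#' @export
pipeline_run <- function(track_paths, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- pipeline_fit(track_paths, config, verbose = verbose)
  res <- pipeline_chi(res, config, verbose = verbose)
  res <- pipeline_classify(
    res, config,
    bedgraph_path = if (!is.null(out_dir))
      file.path(out_dir, "class_labels.bedGraph"),
    pca_path = if (!is.null(out_dir)) file.path(out_dir, "pca.tsv"))
  if (!is.null(out_dir)) {
    write_results_full(res, file.path(out_dir, "sections_full.tsv"))
    write_results(res, file.path(out_dir, "sections.tsv"))
  }
  res
}
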
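test_that("free particles sample a uniform density with flat RDF", {
  cfg <- mc_config(200, 75000, 0, lambda_max = 1024, n_steps = 10000,
                   seed = 11, sample_every = 50)
  run <- run_mc(NULL, cfg)
  expect_equal(run$acceptance, 1) # nothing to reject
  g <- rdf_from_conformations(run, 10, 1000)
  expect_lt(abs(mean(g$g[g$r > 100]) - 1), 0.05)
  # one-body density uniform (detailed balance); samples a few sweeps apart
  # are correlated, so the bound is on the relative deviation per bin
  pooled <- as.vector(run$samples)
  counts <- tabulate(findInterval(pooled, seq(0, 75000, length.out = 6)),
                     nbins = 5)
  expected <- length(pooled) / 5
  expect_true(all(abs(counts - expected) / expected < 0.06))
})

test_that("hard-core exclusion holds in every sampled conformation", {
  cfg <- mc_config(150, 40000, 147, lambda_max = 256, n_steps = 3000,
                   seed = 4, sample_every = 100)
  run <- run_mc(NULL, cfg)
  expect_gt(nrow(run$samples), 10)
  for (r in seq_len(nrow(run$samples))) {
    x <- sort(run$samples[r, ])
    gaps <- c(diff(x), 40000 - (x[length(x)] - x[1]))
    expect_true(all(gaps >= 147))
  }
})

test_that("incremental energy matches a full recomputation", {
  pot <- glj_params(1.5, 150, 12, 6, 500)
  cfg <- mc_config(200, 75000, 147, lambda_max = 64, n_steps = 2000,
                   seed = 5)
  run <- run_mc(pot, cfg)
  expect_equal(run$energy_incremental, run$energy_recomputed,
               tolerance = 1e-8)
  expect_true(run$acceptance > 0 && run$acceptance < 1)
})

test_that("identical seeds give identical trajectories, different seeds differ", {
  pot <- glj_params(1, 150, 12, 6, 500)
  cfg <- mc_config(100, 40000, 147, lambda_max = 64, n_steps = 1000, seed = 9)
  r1 <- run_mc(pot, cfg)
  r2 <- run_mc(pot, cfg)
  expect_identical(r1$samples, r2$samples)
  cfg$seed <- 10L
  r3 <- run_mc(pot, cfg)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("two strongly bound particles separate near the potential minimum", {
  pot <- glj_params(3, 150, 12, 6, r_cut = 500)
  cfg <- mc_config(2, 1000, 0, lambda_max = 32, n_steps = 60000, seed = 13,
                   sample_every = 10)
  run <- run_mc(pot, cfg)
  sep <- apply(run$samples, 1, function(x) {
    d <- abs(x[2] - x[1]); min(d, 1000 - d)
  })
  h <- hist(sep, breaks = seq(0, 500, by = 10), plot = FALSE)
  mode_bin <- h$mids[which.max(h$counts)]
  # Boltzmann oracle on the ring: p(s) ~ exp(-V(s)); mode at r*
  s <- seq(1, 500, by = 0.25)
  dens <- exp(-glj_energy(pot, s))
  oracle_mode <- s[which.max(dens)]
  expect_equal(oracle_mode, glj_rmin(pot), tolerance = 0.01)
  expect_lt(abs(mode_bin - oracle_mode), 10.01) # within one bin
  # and the sampled mean separation matches the Boltzmann integral
  oracle_mean <- sum(s * dens) / sum(dens)
  expect_lt(abs(mean(sep) - oracle_mean) / oracle_mean, 0.05)
})

test_that("tune_lambda returns the smallest ladder value meeting the target", {
  cfg <- mc_config(200, 75000, 147, n_steps = 1000, seed = 42)
  lam <- tune_lambda(NULL, cfg)
  acc <- attr(lam, "acceptance")
  expect_true(all(acc[-length(acc)] > 0.5))
  expect_lte(acc[length(acc)], 0.5)
  # self-consistency: a fresh run at the tuned lambda stays at or below 50%
  cfg$lambda_max <- as.numeric(lam)
  cfg$n_steps <- 3000L
  expect_lte(run_mc(NULL, cfg)$acceptance, 0.5)
  # doubling lambda cannot increase acceptance
  cfg2 <- cfg
  cfg2$lambda_max <- 2 * cfg$lambda_max
  expect_lte(run_mc(NULL, cfg2)$acceptance,
             run_mc(NULL, cfg)$acceptance + 0.02)
})

test_that("free particles never reach the 50% target and warn", {
  cfg <- mc_config(50, 75000, 0, n_steps = 500, seed = 3)
  expect_warning(lam <- tune_lambda(NULL, cfg), "largest")
  expect_equal(as.numeric(lam), 1024)
})

test_that("rdf_from_conformations averages per-conformation RDFs", {
  cfg <- mc_config(100, 40000, 147, lambda_max = 256, n_steps = 2000,
                   seed = 21, sample_every = 100)
  run <- run_mc(NULL, cfg)
  g_all <- rdf_from_conformations(run, 10, 1000)
  # single conformation equals compute_rdf (periodic) of that conformation
  one <- run
  one$samples <- run$samples[1, , drop = FALSE]
  g_one <- rdf_from_conformations(one, 10, 1000)
  direct <- compute_rdf(run$samples[1, ], 40000, 10, 1000, edge = "periodic")
  expect_equal(g_one$g, direct$g)
  # duplicating the conformation list leaves the average unchanged
  dup <- run
  dup$samples <- rbind(run$samples, run$samples)
  expect_equal(rdf_from_conformations(dup, 10, 1000)$g, g_all$g)
  # averaging reduces noise relative to a single sample
  expect_lt(sd(g_all$g[g_all$r > 300]), sd(g_one$g[g_one$r > 300]))
})

test_that("conformation export round-trips through TSV", {
  cfg <- mc_config(20, 10000, 147, lambda_max = 64, n_steps = 500, seed = 2,
                   sample_every = 100)
  run <- run_mc(NULL, cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_conformations(run, p)
  back <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(back$sweep_index, run$sample_sweeps)
  expect_equal(unname(as.matrix(back[, -1])), unname(run$samples),
               tolerance = 1e-12)
})

test_that("infeasible packing is rejected before any sweep", {
  expect_error(mc_config(100, 10000, 147), "infeasible")
})
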
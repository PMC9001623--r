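test_that("block census pools counts across blocks and conformations", {
  conf <- matrix(seq(500, 9500, length.out = 10), nrow = 1)
  cen <- block_census(conf, 10000, 1)
  expect_equal(cen$counts, c("10" = 1L))
  expect_equal(chi_block(cen), 0)

  # equally spaced particles, blocks dividing N evenly: zero variance
  conf2 <- matrix((0:19 + 0.5) * 500, nrow = 1)
  cen2 <- block_census(conf2, 10000, 4)
  expect_equal(chi_block(cen2), 0)

  # histogram invariance under conformation relabeling
  confs <- rbind(conf2, conf2[, 20:1])
  expect_equal(block_census(confs, 10000, 4)$counts,
               stats::setNames(cen2$counts * 2L, names(cen2$counts)))
})

test_that("chi of simple histograms follows the variance-over-mean formula", {
  expect_equal(chi_block(c("10" = 1)), 0)
  expect_equal(chi_block(c("0" = 1, "2" = 1)), 1)
  expect_error(chi_block(c("0" = 5)), "empty")
})

test_that("Poisson-placed particles have unit variance-to-mean ratio", {
  set.seed(5)
  confs <- t(replicate(200, sort(runif(400, 0, 75000))))
  chis <- sapply(c(4, 8, 16, 32), function(mb)
    chi_block(block_census(confs, 75000, mb)) / (1 - 1 / mb))
  expect_true(all(abs(chis - 1) < 0.1))
})

test_that("extrapolation is exact OLS with intercept at M_b = 0", {
  est <- extrapolate_chi(data.frame(M_b = c(1, 2, 4),
                                    chi = c(0.30, 0.35, 0.45)))
  expect_equal(est$chi_inf, 0.25)
  expect_equal(est$slope, 0.05)
  expect_equal(est$r_squared, 1)

  est2 <- extrapolate_chi(data.frame(M_b = c(4, 8, 16, 32), chi = 0.7))
  expect_equal(est2$chi_inf, 0.7)
  expect_equal(est2$slope, 0)

  expect_error(extrapolate_chi(data.frame(M_b = c(1, 2), chi = c(1, 2))),
               "at least 3")
  expect_warning(
    clip <- extrapolate_chi(data.frame(M_b = c(4, 8, 16),
                                       chi = c(0.01, 0.30, 0.60))),
    "clipped")
  expect_equal(clip$chi_inf, 0)
  expect_true(clip$clipped)
})

test_that("ideal-gas sections extrapolate to unit compressibility", {
  cfg <- mc_config(400, 75000, 0, lambda_max = 1024, n_steps = 50000,
                   seed = 7, sample_every = 200)
  est <- section_chi(NULL, cfg, M_b_list = c(4, 8, 16, 32))
  expect_lt(abs(est$chi_inf - 1), 0.1)
})

test_that("Tonks gas at half packing extrapolates to (1 - eta)^2", {
  cfg <- mc_config(250, 73500, 147, lambda_max = 512, n_steps = 60000,
                   seed = 8, sample_every = 200)
  est <- section_chi(NULL, cfg, M_b_list = c(4, 8, 16, 32))
  expect_lt(abs(est$chi_inf - 0.25), 0.03)
  # the 1/L (per-block-linear) extrapolation fits the data well
  expect_gt(est$r_squared, 0.8)
})

test_that("deeper wells rigidify a commensurate array (exact NN oracle)", {
  # Independent oracle: exact NPT transfer integral for a 1D fluid with
  # nearest-neighbor interactions. The spacing distribution is
  # p(r) ~ exp(-P r - V(r)); solving <r> = a for P gives
  # chi = Var(r) / <r>^2 (which reduces to (1 - eta)^2 for hard rods).
  chi_exact_nn <- function(pot, a_target, core = 147) {
    V <- function(r) glj_energy(pot, r)
    f <- function(P) {
      r <- seq(core, 4000, by = 0.5)
      w <- exp(-P * r - V(r))
      m <- sum(w * r) / sum(w)
      c(m, sum(w * r^2) / sum(w) - m^2)
    }
    P <- stats::uniroot(function(P) f(P)[1] - a_target, c(1e-6, 1),
                        tol = 1e-10)$root
    mv <- f(P)
    mv[2] / mv[1]^2
  }
  # commensurate packing: spacing = well minimum, nucleosomes sit in wells
  mk <- function(eps, seed) {
    pot <- glj_params(eps, 150, 12, 6, 500)
    cfg <- mc_config(445, 75000, 147, lambda_max = 32, n_steps = 40000,
                     seed = seed, sample_every = 100)
    section_chi(pot, cfg, M_b_list = c(4, 8, 16, 32))$chi_inf
  }
  deep <- mk(3, 31)
  shallow <- mk(0.5, 32)
  expect_lt(deep, shallow)
  a <- 75000 / 445
  expect_lt(abs(deep - chi_exact_nn(glj_params(3, 150, 12, 6, 500), a)),
            0.005)
  expect_lt(abs(shallow - chi_exact_nn(glj_params(0.5, 150, 12, 6, 500), a)),
            0.005)
})
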
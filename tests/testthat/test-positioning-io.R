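test_that("bedGraph occupancy reading transcribes runs and handles edge cases", {
  p <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr2\t0\t10\t1", "chr2\t10\t20\t0"), p)
  tr <- read_occupancy(p, "bedgraph")
  expect_equal(tr$length, 20)
  expect_equal(tr$values, rep(c(1L, 0L), each = 10))
  expect_equal(tr$chrom_name, "chr2")

  # empty file with declared length -> all-zero track
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(character(0), p2)
  tr2 <- read_occupancy(p2, "bedgraph", declared_length = 100)
  expect_equal(tr2$length, 100)
  expect_true(all(tr2$values == 0))

  # positive non-0/1 value coerced to 1 with a warning
  p3 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr2\t0\t5\t3.7", p3)
  expect_warning(tr3 <- read_occupancy(p3, "bedgraph"), "coercing")
  expect_equal(tr3$values, rep(1L, 5))

  # conflicting overlap -> error
  p4 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr2\t0\t10\t1", "chr2\t5\t15\t0"), p4)
  expect_error(read_occupancy(p4, "bedgraph"), "conflicting")
})

test_that("two-column and wiggle formats read to the same track as bedGraph", {
  vals <- c(0, 1, 1, 1, 0, 0, 1, 0)
  p2c <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d %d", seq_along(vals), vals), p2c)
  tr <- read_occupancy(p2c, "two_column")
  expect_equal(tr$values, as.integer(vals))

  pw <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", as.character(vals)), pw)
  trw <- read_occupancy(pw, "wig")
  expect_equal(trw$values, as.integer(vals))
})

test_that("track_to_nucleosomes extracts maximal runs with floor-midpoint centers", {
  tr <- occupancy_track("c", c(0, 0, 0, 1, 1, 1, 1, 0, 0, 0))
  ns <- track_to_nucleosomes(tr)
  expect_equal(unname(ns$intervals[1, ]), c(3, 7))
  expect_equal(ns$centers, 5)
  expect_equal(ns$mean_length, 4)

  ns2 <- track_to_nucleosomes(occupancy_track("c", c(1, 1, 0, 1, 1)))
  expect_equal(unname(ns2$intervals[, "start"]), c(0, 3))
  expect_equal(unname(ns2$intervals[, "end"]), c(2, 5))
  expect_equal(ns2$centers, c(1, 4))
  expect_equal(ns2$mean_length, 2)

  expect_warning(ns3 <- track_to_nucleosomes(occupancy_track("c", rep(0, 5))),
                 "all-zero")
  expect_equal(n_nucleosomes(ns3), 0)
  expect_true(is.na(ns3$mean_length))
})

test_that("track <-> nucleosome conversion is a bijection and conserves coverage", {
  set.seed(7)
  for (i in 1:10) {
    vals <- rbinom(200, 1, 0.4)
    if (sum(vals) == 0) vals[5] <- 1L
    tr <- occupancy_track("c", vals)
    ns <- track_to_nucleosomes(tr)
    back <- nucleosomes_to_track(ns, length = tr$length)
    expect_identical(back$values, tr$values)
    expect_equal(sum(ns$intervals[, "end"] - ns$intervals[, "start"]),
                 sum(vals))
  }
})

test_that("BED reading sorts, validates and keeps only coordinates", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t647\tx\t9", "chr2\t100\t247\ty\t3"), p)
  ns <- read_nucleosome_bed(p)
  expect_equal(unname(ns$intervals[, "start"]), c(100, 500))
  expect_equal(ns$mean_length, 147)

  p2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t200\t150", p2)
  expect_error(read_nucleosome_bed(p2), "line 1")
})

test_that("results TSV round-trips values and exports integer class labels", {
  res <- data.frame(chrom = "chrS1", core_start = c(12500, 62500),
                    core_end = c(62500, 112500),
                    epsilon = c(1.234567, 2.5), sigma = c(150.1, 160.9),
                    delta_exp = c(12.3, 9.1), nu_exp = c(6.2, 3.3),
                    msr = c(0.0123456, 0.5), chi_inf = c(0.25, 0.5),
                    class_label = c(0L, 2L))
  p <- withr::local_tempfile(fileext = ".tsv")
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_results(res, p, bedgraph_path = bg)
  back <- read_results(p)
  expect_equal(nrow(back), 2)
  expect_equal(back$epsilon, res$epsilon, tolerance = 1e-6)
  expect_true(all(back$class_label == c(0L, 2L)))
  expect_equal(length(readLines(bg)), 2)
  expect_error(write_results(res[0, ], p), "nonempty")
})
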
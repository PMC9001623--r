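# Build a section-results data.frame around given feature rows.
fake_results <- function(feats, fit_ok = TRUE) {
  data.frame(chrom = "c", core_start = seq_len(nrow(feats)) * 100,
             core_end = seq_len(nrow(feats)) * 100 + 50,
             delta_exp = feats[, 1], nu_exp = feats[, 2],
             chi_inf = feats[, 3], fit_ok = fit_ok)
}

blobs3 <- function(n_per = 20, sd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(12, 6, 0.05), c(20, 3, 0.3), c(12, 6, 0.8))
  feats <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per, centers[k, 1], sd * 10),
          rnorm(n_per, centers[k, 2], sd * 5),
          rnorm(n_per, centers[k, 3], sd))))
  list(feats = feats, truth = rep(0:2, each = n_per))
}

test_that("feature matrix standardizes and excludes unfit sections", {
  b <- blobs3()
  res <- fake_results(b$feats)
  res$fit_ok[5] <- FALSE
  m <- feature_matrix(res)
  expect_equal(nrow(m), nrow(res) - 1)
  expect_true(all(abs(colMeans(m)) < 1e-12))
  expect_equal(unname(apply(m, 2, sd)), rep(1, 3))
  expect_false(5 %in% attr(m, "kept"))
  # constant column left at zero with warning
  res2 <- fake_results(cbind(7, b$feats[, 2:3]))
  expect_warning(m2 <- feature_matrix(res2), "constant")
  expect_true(all(m2[, 1] == 0))
})

test_that("k-means recovers constructed blobs with canonical chi ordering", {
  b <- blobs3(sd = 0.03)
  m <- feature_matrix(fake_results(b$feats))
  lab <- kmeans_classify(m, k = 3, seed = 5)
  expect_equal(as.integer(lab), b$truth) # canonical: ascending chi
  expect_equal(rand_index(lab, b$truth), 1)
  # reruns with the same seed are identical; restart order cannot matter
  lab2 <- kmeans_classify(m, k = 3, seed = 99)
  expect_equal(as.integer(lab), as.integer(lab2))
  # duplicated rows get identical labels
  mdup <- rbind(m, m)
  labdup <- kmeans_classify(mdup, k = 3, seed = 5)
  expect_equal(labdup[seq_len(nrow(m))], labdup[nrow(m) + seq_len(nrow(m))])
})

test_that("k equal to the number of distinct points gives zero inertia", {
  m <- matrix(c(0, 0, 0, 5, 5, 5, 9, 1, 4), 3, 3, byrow = TRUE)
  lab <- kmeans_classify(m, k = 3, seed = 2)
  expect_equal(attr(lab, "inertia"), 0)
  expect_equal(sort(as.integer(lab)), 0:2)
  expect_error(kmeans_classify(m, k = 1), "k must be")
})

test_that("PCA diagnostic favors three clusters on three-blob data", {
  b <- blobs3(sd = 0.04, seed = 7)
  m <- feature_matrix(fake_results(b$feats))
  d <- pca_diagnostic(m, k_list = 2:4, seed = 3)
  expect_equal(dim(d$projection), c(nrow(m), 2))
  sil <- d$silhouette
  expect_gt(sil$mean_width[sil$k == 3], sil$mean_width[sil$k == 2])
  expect_gt(sil$mean_width[sil$k == 3], sil$mean_width[sil$k == 4])
  # explained variance of the first two PCs beats any axis-aligned pair
  v <- apply(m, 2, var)
  expect_gte(sum(d$explained) * sum(v) + 1e-9,
             sum(v) - min(v))
})

test_that("PCA explained variance is rotation invariant", {
  b <- blobs3(seed = 11)
  m <- feature_matrix(fake_results(b$feats))
  q <- qr.Q(qr(matrix(c(1, 2, 3, -1, 0.5, 2, 0.3, -2, 1), 3, 3)))
  d1 <- pca_diagnostic(m, k_list = 2, seed = 1)
  d2 <- pca_diagnostic(m %*% q, k_list = 2, seed = 1)
  expect_equal(d1$explained, d2$explained, tolerance = 1e-10)
})

test_that("class track export writes one record per section with -1 sentinel", {
  res <- fake_results(blobs3(n_per = 2)$feats)
  res$class_label <- c(0L, 0L, 1L, 1L, NA, 2L)
  res$fit_ok[5] <- FALSE
  p <- withr::local_tempfile(fileext = ".bedGraph")
  export_class_track(res, p)
  lines <- readLines(p)
  expect_equal(length(lines), 6)
  expect_match(lines[5], "-1$")
  expect_equal(sum(grepl("-1$", lines)), 1)
  # adjacent same-label sections stay separate records
  expect_equal(length(grep("\t0$", lines)), 2)
})

test_that("clustering is invariant to section input order", {
  b <- blobs3(sd = 0.03, seed = 13)
  m <- feature_matrix(fake_results(b$feats))
  perm <- sample(seq_len(nrow(m)))
  lab_perm <- kmeans_classify(m[perm, ], k = 3, seed = 5)
  lab <- kmeans_classify(m, k = 3, seed = 5)
  expect_equal(as.integer(lab_perm), as.integer(lab)[perm])
})
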
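test_that("z-scoring standardises columns and drops constants", {
  set.seed(1)
  vals <- cbind(a = rnorm(30, 100, 20), b = runif(30), c = rep(4, 30))
  expect_warning(z <- zscore_markers(toy_cohort(vals)), "zero-variance")
  expect_equal(colnames(z), c("a", "b"))
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  pre <- scale(vals[, 1:2])
  expect_equal(unname(z), unname(pre[, 1:2]), ignore_attr = TRUE)
})

test_that("patient distance is the Euclidean metric", {
  z <- rbind(c(0, 0), c(3, 4), c(0, 0))
  d <- as.matrix(patient_distance(z))
  expect_equal(d[1, 2], 5)
  expect_equal(d[1, 3], 0)
  expect_equal(d, t(d))
  set.seed(2)
  zz <- matrix(rnorm(60), 20, 3)
  dd <- as.matrix(patient_distance(zz))
  for (i in 1:50) {
    tri <- sample(20, 3)
    expect_lte(dd[tri[1], tri[3]],
               dd[tri[1], tri[2]] + dd[tri[2], tri[3]] + 1e-12)
  }
})

test_that("marker distance is 1 - |r| with sign-blindness", {
  set.seed(3)
  x <- rnorm(50)
  z <- cbind(a = x, b = -x + rnorm(50, sd = 1e-8), c = rnorm(50))
  d <- as.matrix(marker_distance(z))
  expect_equal(d[1, 1], 0)
  expect_lt(d[1, 2], 1e-6)        # exact negation: |r| = 1
  set.seed(4)
  big <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_gt(as.matrix(marker_distance(big))[1, 2], 0.95)
})

test_that("Ward linkage merges nearest points first with monotone heights", {
  d <- dist(c(0, 1, 10))
  tree <- ward_linkage(d)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))   # merge {0, 1} first
  expect_true(!is.unsorted(tree$height))
  # brute-force Lance-Williams oracle on random configurations, n <= 7
  for (s in 1:5) {
    set.seed(s)
    pts <- matrix(rnorm(14), 7, 2)
    dd <- dist(pts)
    expect_equal(ward_linkage(dd)$height, ward_oracle_heights(dd),
                 tolerance = 1e-9)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_linkage(bad), "symmetric")
})

test_that("cutting a two-blob configuration recovers the blobs", {
  set.seed(5)
  z <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 5, 0.3), 10, 2))
  tree <- ward_linkage(dist(z))
  labels <- assign_profiles(tree, 2)
  expect_equal(length(unique(labels[1:10])), 1L)
  expect_equal(length(unique(labels[11:20])), 1L)
  expect_equal(length(unique(labels)), 2L)
})

test_that("Hopkins distinguishes uniform noise from clustered data", {
  hs <- vapply(1:100, function(s) {
    set.seed(s)
    hopkins_stat(matrix(runif(200 * 10), 200, 10), seed = s)
  }, numeric(1))
  expect_gte(mean(hs > 0.4 & hs < 0.6), 0.9)

  set.seed(6)
  blobs <- rbind(matrix(rnorm(300, 0, 0.05), 100, 3),
                 matrix(rnorm(300, 3, 0.05), 100, 3))
  expect_gt(hopkins_stat(blobs, seed = 1), 0.8)
  expect_identical(hopkins_stat(blobs, seed = 2), hopkins_stat(blobs, seed = 2))
  expect_error(hopkins_stat(matrix(rnorm(20), 10, 2)), "20 rows")
})

test_that("silhouette and gap agree on well-separated planted blobs", {
  set.seed(7)
  z <- rbind(matrix(rnorm(100, 0, 0.4), 50, 2),
             matrix(rnorm(100, 6, 0.4), 50, 2),
             sweep(matrix(rnorm(100, 0, 0.4), 50, 2), 2, c(6, 0), "+"))
  ck <- choose_k(z, k_range = 2:6, B = 20, seed = 7)
  expect_equal(ck$k_sil, 3L)
  expect_equal(ck$k_gap, 3L)
  expect_equal(ck$k, 3L)
  ck2 <- choose_k(z, k_range = 2:2, B = 5, seed = 7)
  expect_equal(ck2$k, 2L)
})

test_that("profile labels are renumbered by decreasing size, deterministically", {
  set.seed(8)
  z <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
             matrix(rnorm(20, 6, 0.3), 10, 2))
  tree <- ward_linkage(dist(z))
  labels <- assign_profiles(tree, 2)
  expect_equal(unname(labels[1]), 1L)            # biggest cluster is profile 1
  expect_equal(sum(labels == 1), 30L)
  expect_identical(labels, assign_profiles(tree, 2))
  expect_equal(length(unique(assign_profiles(tree, 40))), 40L)
  expect_error(assign_profiles(tree, 41), "exceeds")
})

test_that("nested cuts only merge clusters, never split them", {
  set.seed(9)
  z <- matrix(rnorm(80), 40, 2)
  tree <- ward_linkage(dist(z))
  for (k in 3:6) {
    fine <- stats::cutree(tree, k)
    coarse <- stats::cutree(tree, k - 1)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
})

test_that("heat-map export writes the dendrogram-ordered matrix", {
  set.seed(10)
  z <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("m%d", 1:6)))
  pt <- ward_linkage(dist(z))
  mt <- ward_linkage(marker_distance(z))
  labels <- assign_profiles(pt, 2)
  out_png <- withr::local_tempfile(fileext = ".png")
  res <- heatmap_export(z, pt, mt, labels, out_png)
  expect_true(file.exists(res$image))
  mat <- as.matrix(read.delim(res$matrix, row.names = 1))
  expect_equal(rownames(mat), rownames(z)[pt$order])
  expect_equal(colnames(mat), colnames(z)[mt$order])
  # determinism: a second export yields an identical ordered matrix
  res2 <- heatmap_export(z, pt, mt, labels,
                         withr::local_tempfile(fileext = ".png"))
  expect_identical(readLines(res$matrix), readLines(res2$matrix))
})

test_that("profile recovery on default cohorts reaches the planted partition", {
  aris <- vapply(1:10, function(s) {
    g <- generate_profile_cohort(generator_config(seed = s))
    pp <- preprocess_cohort(g$table, g$ann)
    pr <- cluster_profiles(pp$table, seed = s, k = 6)
    mclust::adjustedRandIndex(pr$labels,
                              g$truth$true_profile[names(pr$labels)])
  }, numeric(1))
  expect_gte(mean(aris >= 0.7), 0.8)
})
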
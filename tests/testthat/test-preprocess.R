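test_that("the missingness filter applies a strict threshold", {
  set.seed(1)
  vals <- matrix(rnorm(100 * 3, 10), 100, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  vals[1:11, 1] <- NA   # 11% missing -> dropped
  vals[1:10, 2] <- NA   # exactly 10% -> retained
  tab <- toy_cohort(vals)
  out <- drop_high_missing(tab, threshold = 0.10)
  expect_equal(colnames(out$table$values), c("b", "c"))
  expect_equal(out$report$marker, "a")

  clean <- toy_cohort(matrix(rnorm(20), 10, 2))
  same <- drop_high_missing(clean)
  expect_equal(same$table$values, clean$values)
  expect_equal(nrow(same$report), 0L)

  allbad <- toy_cohort(matrix(c(NA, NA, 1, NA, NA, 2), 3, 2))
  expect_error(drop_high_missing(allbad), "all markers")
})

test_that("two-nearest-neighbour imputation reproduces the hand-worked example", {
  # P3 misses marker2; its z-scored marker1 value is distant from both
  # others but P1 and P2 are the only candidates -> imputed mean(10, 14)
  vals <- matrix(c(1, 1.1, 9,
                   10, 14, NA), 3, 2,
                 dimnames = list(c("P1", "P2", "P3"), c("m1", "m2")))
  out <- impute_knn2(toy_cohort(vals))
  expect_equal(out$table$values["P3", "m2"], 12.0)
  expect_false(any(out$table$mask))
  expect_setequal(strsplit(out$report$neighbors, ";")[[1]], c("P1", "P2"))
})

test_that("imputation picks the two genuinely closest neighbours", {
  # brute-force check over all neighbour pairs on a 6-patient toy
  set.seed(42)
  vals <- matrix(rnorm(6 * 4, 50, 10), 6, 4,
                 dimnames = list(paste0("P", 1:6), paste0("m", 1:4)))
  vals[1, 2] <- NA
  out <- impute_knn2(toy_cohort(vals))
  # oracle: z-score by observed moments, overlap-normalised distance
  mu <- colMeans(vals, na.rm = TRUE); sdv <- apply(vals, 2, sd, na.rm = TRUE)
  z <- sweep(sweep(vals, 2, mu), 2, sdv, "/")
  d <- sapply(2:6, function(k) {
    sh <- !is.na(z[1, ]) & !is.na(z[k, ])
    sqrt(sum((z[1, sh] - z[k, sh])^2) / sum(sh))
  })
  nb <- (2:6)[order(d)][1:2]
  expect_equal(out$table$values[1, 2], mean(vals[nb, 2]))
})

test_that("imputation is the identity on complete tables and bounded by observed values", {
  clean <- toy_cohort(matrix(rnorm(40, 100, 5), 10, 4))
  out <- impute_knn2(clean)
  expect_equal(out$table$values, clean$values)
  expect_equal(nrow(out$report), 0L)

  set.seed(7)
  vals <- matrix(rnorm(30 * 5, 20, 4), 30, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  vals[sample(length(vals), 20)] <- NA
  filled <- impute_knn2(toy_cohort(vals))
  for (j in 1:5) {
    obs <- vals[!is.na(vals[, j]), j]
    imp <- filled$table$values[is.na(vals[, j]), j]
    expect_true(all(imp >= min(obs) & imp <= max(obs)))
  }
  # equal-valued neighbours impute exactly that value
  eq <- matrix(c(5, 5, NA, 1, 1.05, 1), 3, 2,
               dimnames = list(NULL, c("m1", "m2")))
  expect_equal(impute_knn2(toy_cohort(eq))$table$values[3, "m1"], 5)
})

test_that("imputation fails loudly for an unmatchable patient", {
  # A observes only m2, shared only with D; its neighbours for m1 (B, C)
  # share no observed marker with it
  vals <- matrix(c(NA, 2, 3, NA,
                   5, NA, NA, 6), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("m1", "m2")))
  expect_error(impute_knn2(toy_cohort(vals)), "A")
})

test_that("dedup keeps the marker that best separates the NCI groups", {
  set.seed(11)
  n <- 60
  flags <- rep(c(TRUE, FALSE), each = n / 2)
  base <- rnorm(n) + ifelse(flags, 1.2, 0)
  twin <- base + rnorm(n, sd = 0.05)      # |r| ~ 0.999
  indep <- rnorm(n)
  vals <- cbind(strong = base, weak = twin, other = indep)
  rownames(vals) <- sprintf("P%02d", 1:n)
  tab <- toy_cohort(vals)
  ann <- clinical_annotations(rownames(vals),
                              ifelse(flags, "ANI", "none"))
  out <- dedup_correlated(tab, ann)
  # oracle: exhaustive pooled-t computation decides the survivor
  tstat <- function(x) {
    x1 <- x[flags]; x0 <- x[!flags]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
                 (n - 2))
    (mean(x1) - mean(x0)) / (sp * sqrt(2 / (n / 2)))
  }
  winner <- c("strong", "weak")[which.max(abs(c(tstat(base), tstat(twin))))]
  expect_equal(sort(colnames(out$table$values)), sort(c(winner, "other")))
  expect_equal(nrow(out$report), 1L)
  expect_gt(out$report$abs_r, 0.95)
})

test_that("dedup collapses whole correlation components and is otherwise inert", {
  set.seed(12)
  n <- 80
  flags <- rep(c(TRUE, FALSE), each = n / 2)
  a <- rnorm(n) + flags * 1
  vals <- cbind(a = a, b = a + rnorm(n, sd = 0.03),
                c = a + rnorm(n, sd = 0.03), d = rnorm(n))
  rownames(vals) <- sprintf("P%02d", 1:n)
  ann <- clinical_annotations(rownames(vals), ifelse(flags, "MND", "none"))
  out <- dedup_correlated(toy_cohort(vals), ann)
  expect_equal(ncol(out$table$values), 2L)   # one survivor of {a,b,c}, plus d
  expect_equal(nrow(out$report), 2L)

  indep <- toy_cohort(matrix(rnorm(n * 3), n, 3,
                             dimnames = list(rownames(vals), NULL)))
  same <- dedup_correlated(indep, ann)
  expect_equal(same$table$values, indep$values)

  holey <- toy_cohort(rbind(c(1, NA), matrix(rnorm(2 * n - 2), ncol = 2)))
  ann2 <- clinical_annotations(rownames(holey$values),
                               rep(c("ANI", "none"), length.out = n))
  expect_error(dedup_correlated(holey, ann2), "impute")
})

test_that("the staged pipeline is idempotent on its own output", {
  g <- generate_profile_cohort(generator_config(seed = 20))
  pp <- preprocess_cohort(g$table, g$ann)
  again <- preprocess_cohort(pp$table, g$ann)
  expect_equal(again$table$values, pp$table$values)
  expect_equal(nrow(again$dropped), 0L)
  expect_equal(nrow(again$dedup), 0L)
  # the concentrated-missingness markers were dropped, duplicates removed
  expect_true(all(!g$truth$high_missing_markers %in%
                    colnames(pp$table$values)))
  expect_false(all(c("t8_cd38_pct", "t8_cd38hi_pct") %in%
                     colnames(pp$table$values)))
})
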
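test_that("Kruskal-Wallis H matches the closed-form and its exact p the permutation law", {
  kw <- kruskal_wallis(1:6, rep(c("A", "B"), each = 3))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$p, 0.100, tolerance = 1e-9)  # 2 extreme splits of 20

  kw3 <- kruskal_wallis(c(1.5, 2.7, 9.1), c("a", "b", "c"))
  expect_equal(kw3$H, 2.0)

  expect_equal(kruskal_wallis(rep(5, 6), rep(c("A", "B"), 3)),
               list(H = 0, p = 1))
  two <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(two$H, 0)
  expect_equal(two$p, 1)
  expect_error(kruskal_wallis(1:4, rep("A", 4)), "2 groups")
})

test_that("large-sample Kruskal-Wallis uses the chi-square reference", {
  set.seed(1)
  x <- rnorm(90)
  g <- rep(c("a", "b", "c"), 30)
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$p, pchisq(kw$H, df = 2, lower.tail = FALSE))
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.2)), c(0.015, 0.15, 0.2))
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(0.2), 0.2)                     # m = 1 identity
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(bh_adjust(p), bh_hand(p))
  sorted <- sort(runif(20))
  expect_true(!is.unsorted(bh_adjust(sorted)))          # monotone on sorted
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the two-group comparison picks t or Mann-Whitney as appropriate", {
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30) + 2
  res <- two_group_compare(c(a, b), rep(c(FALSE, TRUE), each = 30))
  expect_equal(res$test, "t")
  expect_lt(res$p, 0.01)
  # agreement with the reference implementation
  ref <- t.test(b, a, var.equal = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))

  set.seed(4)
  h <- exp(rnorm(30, sd = 1.5)); h2 <- exp(rnorm(30, sd = 1.5)) * 3
  skewed <- two_group_compare(c(h, h2), rep(c(FALSE, TRUE), each = 30))
  expect_equal(skewed$test, "mann-whitney")
  ref2 <- suppressWarnings(wilcox.test(h2, h, exact = FALSE, correct = TRUE))
  expect_equal(skewed$p, ref2$p.value)

  same <- two_group_compare(rep(c(1, 2, 3, 4), 4),
                            rep(c(TRUE, FALSE), each = 8))
  expect_gt(same$p, 0.95)
  expect_error(two_group_compare(1:5, c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               "at least 3")
})

test_that("screening ranks the planted discriminating markers ahead of noise", {
  # At the planted effect sizes the adjusted p-values sit near the 0.05
  # boundary (as the published ones do), so exact selection of all six is
  # not a stable event; their p-value ranking and an excess of selections
  # over the null rate are.
  res <- vapply(1:10, function(s) {
    g <- generate_nci_substudy(seed = s)
    sc <- screen_markers(g$table, g$ann, alpha = 0.05, grouping = "two")
    i <- match(g$truth$informative_markers, sc$marker)
    c(median_rank = median(rank(sc$p)[i]), n_selected = sum(sc$selected[i]))
  }, numeric(2))
  expect_gte(mean(res["median_rank", ] <= 10), 0.9)
  expect_gte(sum(res["n_selected", ]), 5)  # null expectation is ~0.5 total
})

test_that("screening controls the FDR on null cohorts", {
  # direct KW + BH selection rule on effect-free cohorts
  any_hit <- vapply(1:200, function(s) {
    set.seed(s)
    vals <- matrix(rnorm(65 * 59), 65, 59)
    grp <- c(rep("none", 40), rep("ANI", 16), rep("MND", 9))
    p <- apply(vals, 2, function(x) kruskal_wallis(x, grp)$p)
    any(bh_adjust(p) <= 0.05)
  }, logical(1))
  expect_lte(mean(any_hit), 0.10)
})

test_that("alpha = 0 selects nothing and q >= p always", {
  g <- generate_nci_substudy(seed = 5)
  sc <- screen_markers(g$table, g$ann, alpha = 0)
  expect_equal(sum(sc$selected), 0L)
  expect_true(all(sc$q >= sc$p - 1e-12))
  expect_true(all(sc$q <= 1))
})

test_that("WMH comparison dichotomises Fazekas scores and reports rank correlation", {
  g <- generate_nci_substudy(seed = 6)
  ann <- generate_wmh_annotations(g$table, g$ann, seed = 6)
  res <- wmh_compare(g$table, ann, "t4_hladr_pct")
  expect_gt(res$spearman_r, 0.5)
  # the planted negative coupling depresses the marker in the 2-3 group
  expect_lt(res$periventricular$group_stats$mean[1],
            res$periventricular$group_stats$mean[2])
  # identical score vectors have rank correlation 1
  ann2 <- clinical_annotations(g$ann$patient_id, g$ann$nci_class,
                               fazekas_pv = rep(0:3, length.out = 65),
                               fazekas_deep = rep(0:3, length.out = 65))
  expect_equal(wmh_compare(g$table, ann2)$spearman_r, 1)
  # empty dichotomised group -> not computable, no error
  ann3 <- clinical_annotations(g$ann$patient_id, g$ann$nci_class,
                               fazekas_pv = rep(1L, 65),
                               fazekas_deep = rep(1L, 65))
  expect_null(wmh_compare(g$table, ann3)$periventricular)
})

test_that("prevalence summary reproduces published cohort arithmetic", {
  ann <- clinical_annotations(
    sprintf("P%02d", 1:65),
    c(rep("none", 40), rep("ANI", 16), rep("MND", 9)))
  pv <- prevalence_summary(ann)
  expect_equal(pv$pct_nci, 38)
  expect_equal(pv$pct_mnd, 14)
  expect_equal(unname(pv$counts), c(40L, 16L, 9L))
  none <- clinical_annotations(c("a", "b"), c("none", "none"))
  expect_equal(prevalence_summary(none)$pct_nci, 0)
  expect_error(prevalence_summary(clinical_annotations("a")), "known NCI")
})
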
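test_that("the default profile cohort has the planted shape and is reproducible", {
  g <- generate_profile_cohort(generator_config(seed = 1))
  expect_equal(nrow(g$table$values), 240L)
  expect_gte(ncol(g$table$values), 59L)
  expect_equal(sort(unique(g$truth$true_profile)), 1:6)
  expect_equal(unname(table(g$truth$true_profile)), rep(40L, 6),
               ignore_attr = TRUE)
  g2 <- generate_profile_cohort(generator_config(seed = 1))
  expect_identical(g$table$values, g2$table$values)
  expect_identical(g$table$mask, g2$table$mask)
  expect_identical(g$ann$nci_class, g2$ann$nci_class)
  g3 <- generate_profile_cohort(generator_config(seed = 2))
  expect_false(identical(g$table$values, g3$table$values))
})

test_that("values respect physiologic ranges and planted moments", {
  g <- generate_profile_cohort(generator_config(seed = 3))
  vals <- g$table$values
  pct <- g$table$markers$measure == "percent"
  expect_true(all(vals[, pct] >= 0 & vals[, pct] <= 100, na.rm = TRUE))
  expect_true(all(vals >= 0, na.rm = TRUE))
  # profile 1 members show the planted low senescent-T4 percentage
  p1 <- names(g$truth$true_profile)[g$truth$true_profile == 1]
  x <- vals[p1, "t4_cd57_pct"]
  se <- 1.9 / sqrt(sum(!is.na(x)))
  # censoring at 0 lifts the mean slightly above the latent 2.2
  expect_lt(abs(mean(x, na.rm = TRUE) - 2.2), 3 * se + 0.25)
})

test_that("missingness matches its configured binomial expectation", {
  cfg <- generator_config(seed = 4)
  g <- generate_profile_cohort(cfg)
  plain <- setdiff(colnames(g$table$values), g$truth$high_missing_markers)
  m <- g$table$mask[, plain]
  rate <- cfg$sporadic_missing_rate
  n <- length(m)
  expect_lt(abs(mean(m) - rate), 2 * sqrt(rate * (1 - rate) / n))
  expect_length(g$truth$high_missing_markers, 2L)
  hi <- colMeans(g$table$mask[, g$truth$high_missing_markers, drop = FALSE])
  expect_true(all(hi > 0.10))   # concentrated markers exceed the QC threshold
})

test_that("planted duplicate pairs reach the target correlation", {
  g <- generate_profile_cohort(generator_config(seed = 5))
  v <- g$table$values
  r1 <- cor(v[, "t8_cd38_pct"], v[, "t8_cd38hi_pct"],
            use = "pairwise.complete.obs")
  r2 <- cor(v[, "t4_cd38_pct"], v[, "t4_cd38hi_pct"],
            use = "pairwise.complete.obs")
  expect_gte(abs(r1), 0.95)
  expect_gte(abs(r2), 0.95)
})

test_that("NCI probabilities drive the planted flags", {
  cfg0 <- generator_config(nci_prob = rep(0, 6), seed = 6)
  g0 <- generate_profile_cohort(cfg0)
  expect_equal(sum(g0$ann$nci_flag), 0L)
  cfg1 <- generator_config(nci_prob = rep(1, 6), seed = 6)
  g1 <- generate_profile_cohort(cfg1)
  expect_true(all(g1$ann$nci_flag))
})

test_that("bad effect tables and configs are rejected", {
  eff <- rbind(default_profile_effects(),
               data.frame(profile = 1L, id = "not_a_marker", mean = 1, sd = 1))
  expect_error(generate_profile_cohort(generator_config(
    profile_effect_table = eff)), "unknown marker")
  expect_error(generator_config(nci_prob = rep(2, 6)))
  expect_error(generator_config(fazekas_marginals = list(
    pv = c(0.5, 0.5, 0.5, 0.5), deep = c(0.25, 0.25, 0.25, 0.25))),
    "sum to 1")
})

test_that("the NCI substudy draws group-conditional moments for the six markers", {
  g <- generate_nci_substudy(seed = 7)
  expect_equal(nrow(g$table$values), 65L)
  expect_equal(sum(g$ann$nci_flag), 25L)
  expect_equal(sum(g$ann$nci_class == "ANI"), 16L)
  expect_equal(sum(g$ann$nci_class == "MND"), 9L)
  expect_false(any(g$table$mask))
  # group-conditional means of %HLA-DR+ T4 within 3 SE of the planted values
  x <- g$table$values[, "t4_hladr_pct"]
  pos <- g$ann$nci_flag
  expect_lt(abs(mean(x[pos]) - 19.0), 3 * 8.4 / sqrt(25))
  expect_lt(abs(mean(x[!pos]) - 27.5), 3 * 13.5 / sqrt(40))
})

test_that("a single-group substudy is rejected downstream", {
  g <- generate_nci_substudy(seed = 8, n_nci_pos = 0)
  expect_equal(sum(g$ann$nci_flag), 0L)
  expect_error(dedup_correlated(g$table, g$ann), "NCI group")
  x <- g$table$values[, 1:2]
  expect_error(fit_lda(x, g$ann$nci_flag), "both classes")
})

test_that("Fazekas scores match their marginals and latent correlation", {
  cfg <- generator_config(n_per_profile = rep(400L, 6), seed = 9)
  g <- generate_profile_cohort(cfg)
  ann <- generate_wmh_annotations(g$table, g$ann, seed = 9)
  n <- nrow(g$table$values)
  freq <- tabulate(ann$fazekas_pv + 1L, 4) / n
  target <- c(0.12, 0.54, 0.25, 0.09)
  for (i in 1:4) {
    expect_lt(abs(freq[i] - target[i]),
              3 * sqrt(target[i] * (1 - target[i]) / n))
  }
  expect_gt(cor(ann$fazekas_pv, ann$fazekas_deep, method = "spearman"), 0.7)
  # the coupling depresses the marker in the high-WMH group
  hi <- ann$fazekas_pv >= 2
  x <- g$table$values[, "t4_hladr_pct"]
  expect_lt(mean(x[hi], na.rm = TRUE), mean(x[!hi], na.rm = TRUE))
})

test_that("zero WMH coupling leaves the marker unrelated to the scores", {
  g <- generate_profile_cohort(generator_config(seed = 10))
  ann <- generate_wmh_annotations(g$table, g$ann, coupling = 0, seed = 10)
  x <- g$table$values[, "t4_hladr_pct"]
  ok <- !is.na(x)
  p <- cor.test(x[ok], ann$fazekas_pv[ok], method = "kendall")$p.value
  expect_gt(p, 0.01)
})

test_that("MRI missingness marks the requested number of patients", {
  g <- generate_nci_substudy(seed = 11)
  ann <- generate_wmh_annotations(g$table, g$ann, n_missing_mri = 9, seed = 11)
  expect_equal(sum(is.na(ann$fazekas_pv)), 9L)
  expect_equal(sum(is.na(ann$fazekas_deep)), 9L)
})

test_that("generator configs load from YAML with defaults preserved", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99",
               "within_block_rho: 0.2",
               "nci_prob: [0.5, 0.1, 0.5, 0.1, 0.1, 0.1]"), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$within_block_rho, 0.2)
  expect_equal(cfg$nci_prob, c(0.5, 0.1, 0.5, 0.1, 0.1, 0.1))
  expect_equal(cfg$n_per_profile, rep(40L, 6))    # untouched default
  g <- generate_profile_cohort(cfg)
  expect_equal(nrow(g$table$values), 240L)
})

test_that("truth records round-trip to CSV", {
  g <- generate_profile_cohort(generator_config(seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(g$truth, path)
  back <- read.csv(path)
  expect_equal(back$true_profile, unname(g$truth$true_profile))
})
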
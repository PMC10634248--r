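# Univariate marker screening against neurocognitive status.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]).  The
#' p-value comes from the chi-square reference distribution on k-1 degrees
#' of freedom, except for very small samples (N <= 8 under
#' `p_method = "auto"`), where the chi-square approximation is poor and the
#' exact permutation distribution of H (all distinct reassignments of the
#' observations to groups of the observed sizes) is enumerated instead.
#' The degenerate case where every value is identical is defined as
#' H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels of the same length; at least two groups, each
#'   with at least one observation.
#' @param p_method `"auto"` (exact permutation when N <= 8, chi-square
#'   otherwise), `"chisq"`, or `"permutation"`.
#' @return A list with elements `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups,
                           p_method = c("auto", "chisq", "permutation")) {
  p_method <- match.arg(p_method)
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop2("need at least 2 groups")
  if (any(tabulate(groups) == 0)) groups <- droplevels(groups)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  exact <- p_method == "permutation" ||
    (p_method == "auto" && length(values) <= 8)
  if (!exact) return(list(H = H, p = kt$p.value))
  if (length(values) > 10) {
    stop2("exact permutation p is only available for N <= 10")
  }
  sizes <- tabulate(groups)
  labs <- levels(groups)
  perms <- list()
  build <- function(assign, gi) {
    if (gi > length(labs)) { perms[[length(perms) + 1L]] <<- assign; return() }
    free <- which(is.na(assign))
    for (pick in utils::combn(free, sizes[gi], simplify = FALSE)) {
      a2 <- assign
      a2[pick] <- gi
      build(a2, gi + 1L)
    }
  }
  build(rep(NA_integer_, length(values)), 1L)
  hs <- vapply(perms, function(a) {
    unname(stats::kruskal.test(values, factor(a))$statistic)
  }, numeric(1))
  list(H = H, p = mean(hs >= H - 1e-12))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (via [stats::p.adjust()]), returned in
#' input order.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group comparison with automatic test choice
#'
#' Runs a Shapiro-Wilk normality check in each group; when neither group
#' rejects normality at `normality_alpha` a two-sided pooled-variance
#' Student t test is used, otherwise a two-sided Mann-Whitney test with
#' normal approximation and continuity/tie correction.
#'
#' @param values numeric vector.
#' @param flags logical group indicator (same length); both groups need at
#'   least 3 observations.
#' @param normality_alpha Shapiro-Wilk level (default 0.05).
#' @return A list with `test` (`"t"` or `"mann-whitney"`), `statistic`,
#'   `p`, and `group_stats` (per-group n, mean, sd).
#' @export
two_group_compare <- function(values, flags, normality_alpha = 0.05) {
  stopifnot(length(values) == length(flags), is.logical(flags))
  ok <- !is.na(values) & !is.na(flags)
  values <- values[ok]; flags <- flags[ok]
  x1 <- values[flags]; x0 <- values[!flags]
  if (length(x1) < 3 || length(x0) < 3) {
    stop2("both groups need at least 3 observations")
  }
  shapiro_ok <- function(x) {
    if (length(unique(x)) == 1L) return(FALSE)   # constant: not normal
    stats::shapiro.test(x)$p.value >= normality_alpha
  }
  normal <- shapiro_ok(x1) && shapiro_ok(x0)
  if (normal) {
    ht <- stats::t.test(x1, x0, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x1, x0, exact = FALSE, correct = TRUE))
    test <- "mann-whitney"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       group_stats = data.frame(
         group = c("flagged", "unflagged"),
         n = c(length(x1), length(x0)),
         mean = c(mean(x1), mean(x0)),
         sd = c(stats::sd(x1), stats::sd(x0))))
}

#' Screen all markers against neurocognitive status
#'
#' For every marker, runs a Kruskal-Wallis test across the outcome groups
#' (three levels none/ANI/MND by default, or the two-level NCI dichotomy),
#' adjusts the raw p-values with Benjamini-Hochberg across all tested
#' markers, and flags markers with adjusted p <= `alpha`.  A two-group
#' comparison ([two_group_compare()]) of NCI+ versus NCI- is reported per
#' marker alongside.
#'
#' @param table a completed [cohort_table()] (no missing values).
#' @param ann matching [clinical_annotations()]; patients with unknown NCI
#'   class are excluded.
#' @param alpha selection level on the adjusted p-value (default 0.05).
#' @param grouping `"three"` (none/ANI/MND) or `"two"` (NCI- / NCI+).
#' @return A data.frame of class `screen_result`, one row per marker:
#'   `marker`, `H`, `p`, `q`, `selected`, the two-group `test`/`stat2`/`p2`,
#'   and group means/SDs.
#' @export
screen_markers <- function(table, ann, alpha = 0.05,
                           grouping = c("three", "two")) {
  grouping <- match.arg(grouping)
  if (any(table$mask)) stop2("screening requires a completed table; impute first")
  stopifnot(identical(ann$patient_id, patient_ids(table)), alpha >= 0)
  use <- ann$nci_class != "unknown"
  if (sum(use) < 4) stop2("too few patients with known NCI class")
  vals <- table$values[use, , drop = FALSE]
  cls <- ann$nci_class[use]
  flag <- ann$nci_flag[use]
  grp <- if (grouping == "three") cls else ifelse(flag, "NCI+", "NCI-")
  if (length(unique(grp)) < 2) stop2("need at least 2 outcome groups")
  rows <- lapply(seq_len(ncol(vals)), function(j) {
    kw <- kruskal_wallis(vals[, j], grp)
    tg <- two_group_compare(vals[, j], flag)
    gs <- stats::aggregate(vals[, j], list(class = cls),
                           function(x) c(mean = mean(x), sd = stats::sd(x)))
    means <- stats::setNames(gs$x[, "mean"], paste0("mean_", gs$class))
    sds <- stats::setNames(gs$x[, "sd"], paste0("sd_", gs$class))
    c(list(marker = colnames(vals)[j], H = kw$H, p = kw$p,
           test = tg$test, stat2 = tg$statistic, p2 = tg$p,
           mean_nci_pos = tg$group_stats$mean[1],
           sd_nci_pos = tg$group_stats$sd[1],
           mean_nci_neg = tg$group_stats$mean[2],
           sd_nci_neg = tg$group_stats$sd[2]),
      as.list(means), as.list(sds))
  })
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  res$q <- bh_adjust(res$p)
  res$selected <- res$q <= alpha
  res <- res[, c("marker", "H", "p", "q", "selected",
                 setdiff(names(res), c("marker", "H", "p", "q", "selected")))]
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Compare a marker across dichotomised Fazekas groups
#'
#' Dichotomises each Fazekas score (periventricular and deep) into 0-1
#' versus 2-3, compares the marker between the two groups with
#' [two_group_compare()], and reports the Spearman rank correlation between
#' the two scores.  Patients without MRI are excluded pairwise.
#'
#' @param table a [cohort_table()].
#' @param ann matching [clinical_annotations()] with Fazekas scores for at
#'   least 10 patients.
#' @param marker_id marker to compare (default `"t4_hladr_pct"`).
#' @return A list with elements `periventricular`, `deep` (each either a
#'   [two_group_compare()] result or `NULL` when a dichotomised group is
#'   empty or too small) and `spearman_r`.
#' @export
wmh_compare <- function(table, ann, marker_id = "t4_hladr_pct") {
  j <- match(marker_id, marker_ids(table))
  if (is.na(j)) stop2("unknown marker id: ", marker_id)
  stopifnot(identical(ann$patient_id, patient_ids(table)))
  has_mri <- !is.na(ann$fazekas_pv) | !is.na(ann$fazekas_deep)
  if (sum(has_mri) < 10) stop2("Fazekas scores available for fewer than 10 patients")
  x <- table$values[, j]
  cmp <- function(score) {
    ok <- !is.na(score) & !is.na(x)
    hi <- score[ok] >= 2
    if (sum(hi) < 3 || sum(!hi) < 3) return(NULL)   # not computable
    two_group_compare(x[ok], hi)
  }
  both <- !is.na(ann$fazekas_pv) & !is.na(ann$fazekas_deep)
  rho <- if (sum(both) >= 3 &&
             stats::sd(ann$fazekas_pv[both]) > 0 &&
             stats::sd(ann$fazekas_deep[both]) > 0) {
    stats::cor(ann$fazekas_pv[both], ann$fazekas_deep[both],
               method = "spearman")
  } else NA_real_
  list(periventricular = cmp(ann$fazekas_pv), deep = cmp(ann$fazekas_deep),
       spearman_r = rho)
}

#' Prevalence summary of neurocognitive impairment
#'
#' Percentages of NCI (ANI or MND), ANI and MND among classified patients
#' (unknowns excluded), rounded to the nearest integer, together with the
#' exact fractions and counts.
#'
#' @param ann [clinical_annotations()].
#' @return A list with `counts` (named: none, ANI, MND), `pct_nci`,
#'   `pct_ani`, `pct_mnd` (rounded) and `frac_nci`, `frac_ani`, `frac_mnd`.
#' @export
prevalence_summary <- function(ann) {
  cls <- ann$nci_class[ann$nci_class != "unknown"]
  n <- length(cls)
  if (n == 0) stop2("no patients with a known NCI class")
  counts <- c(none = sum(cls == "none"), ANI = sum(cls == "ANI"),
              MND = sum(cls == "MND"))
  frac <- counts / n
  list(counts = counts,
       pct_nci = round(100 * (frac[["ANI"]] + frac[["MND"]])),
       pct_ani = round(100 * frac[["ANI"]]),
       pct_mnd = round(100 * frac[["MND"]]),
       frac_nci = frac[["ANI"]] + frac[["MND"]],
       frac_ani = frac[["ANI"]], frac_mnd = frac[["MND"]])
}
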
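# Profile characterisation and profile-outcome enrichment statistics.

# Normalise input to a validated 2x2 integer matrix
# rows = in target profile yes/no, columns = NCI yes/no.
.as_table2x2 <- function(t) {
  m <- as.matrix(t)
  if (!all(dim(m) == c(2, 2))) stop2("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop2("cell counts must be non-negative integers")
  if (sum(m) == 0) stop2("empty table")
  storage.mode(m) <- "double"
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities (with
#' margins fixed) of all tables at most as probable as the observed one
#' (with a small relative tolerance), as computed by [stats::fisher.test()].
#'
#' @param t 2x2 matrix of counts (rows = profile yes/no, columns = NCI
#'   yes/no).
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(t) {
  m <- .as_table2x2(t)
  stats::fisher.test(m)$p.value
}

#' Odds ratio with Woolf confidence interval
#'
#' Sample odds ratio `(a d)/(b c)`; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied first.  The
#' confidence interval is Woolf's logit interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the (possibly
#' corrected) cells.
#'
#' @param t 2x2 matrix of counts.
#' @param level confidence level (default 0.95).
#' @return A list: `or`, `lo`, `hi`, `corrected` (whether +0.5 was
#'   applied), `unstable` (two zero cells on a diagonal).
#' @export
odds_ratio_ci <- function(t, level = 0.95) {
  m <- .as_table2x2(t)
  corrected <- any(m == 0)
  unstable <- (m[1, 1] == 0 && m[2, 2] == 0) || (m[1, 2] == 0 && m[2, 1] == 0)
  if (corrected) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / m))
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       corrected = corrected, unstable = unstable)
}

#' NCI enrichment of a set of profiles
#'
#' Builds the 2x2 table (membership in the target profile set versus the
#' rest, by NCI status) and reports the odds ratio with confidence
#' interval and Fisher's exact p-value.
#'
#' @param labels integer profile labels.
#' @param nci logical NCI flags (same length; `NA` excluded).
#' @param target profile id(s) forming the target set.
#' @param level confidence level (default 0.95).
#' @return A list: `table` (2x2 matrix), `or`, `lo`, `hi`, `p`,
#'   `corrected`, `unstable`.
#' @export
nci_enrichment <- function(labels, nci, target, level = 0.95) {
  stopifnot(length(labels) == length(nci), length(target) >= 1)
  ok <- !is.na(nci) & !is.na(labels)
  labels <- labels[ok]; nci <- nci[ok]
  in_target <- labels %in% target
  if (all(in_target) || !any(in_target)) {
    stop2("target profile set must be a proper non-empty subset of patients")
  }
  m <- matrix(c(sum(in_target & nci), sum(in_target & !nci),
                sum(!in_target & nci), sum(!in_target & !nci)),
              2, 2, byrow = TRUE,
              dimnames = list(profile = c("target", "rest"),
                              nci = c("NCI+", "NCI-")))
  orci <- odds_ratio_ci(m, level)
  c(list(table = m, p = fisher_exact(m)), orci)
}

#' Profile-versus-rest marker comparisons
#'
#' Compares every marker between the members of one profile and all other
#' patients with [two_group_compare()], and ranks markers by p-value: the
#' top-ranked marker is the profile's most characteristic one.
#'
#' @param table a completed [cohort_table()].
#' @param labels profile labels aligned with the table's patients.
#' @param profile the profile id to characterise.
#' @return A data.frame sorted by `p`: `marker`, `test`, `statistic`, `p`,
#'   `mean_profile`, `sd_profile`, `mean_rest`, `sd_rest`, `direction`.
#' @export
profile_vs_rest_markers <- function(table, labels, profile) {
  stopifnot(length(labels) == nrow(table$values))
  if (any(table$mask)) stop2("profile characterisation requires a completed table")
  flags <- labels == profile
  if (!any(flags) || all(flags)) stop2("profile and rest must both be non-empty")
  rows <- lapply(seq_len(ncol(table$values)), function(j) {
    tg <- two_group_compare(table$values[, j], flags)
    data.frame(marker = marker_ids(table)[j], test = tg$test,
               statistic = tg$statistic, p = tg$p,
               mean_profile = tg$group_stats$mean[1],
               sd_profile = tg$group_stats$sd[1],
               mean_rest = tg$group_stats$mean[2],
               sd_rest = tg$group_stats$sd[2],
               direction = sign(tg$group_stats$mean[1] - tg$group_stats$mean[2]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$p, res$marker), , drop = FALSE]
}

#' Compare a profile against external reference values
#'
#' Welch two-sample t tests computed from summary statistics: the profile
#' members' sample moments against the published mean/SD/n of an external
#' (e.g. age-matched general-population) reference, marker by marker.
#'
#' @param table a completed [cohort_table()].
#' @param labels profile labels.
#' @param profile the profile id.
#' @param reference data.frame with columns `marker`, `mean`, `sd`, `n`.
#' @return A data.frame: `marker`, `t`, `df`, `p`, `mean_profile`,
#'   `mean_reference`, `direction`.  Reference markers absent from the
#'   table are skipped with a warning.
#' @export
compare_to_reference <- function(table, labels, profile, reference) {
  stopifnot(all(c("marker", "mean", "sd", "n") %in% names(reference)))
  flags <- labels == profile
  if (sum(flags) < 2) stop2("profile needs at least 2 members")
  missing <- setdiff(reference$marker, marker_ids(table))
  if (length(missing)) {
    warning("reference marker(s) not in cohort, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    reference <- reference[!reference$marker %in% missing, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    id <- reference$marker[i]
    x <- table$values[flags, match(id, marker_ids(table))]
    x <- x[!is.na(x)]
    m1 <- mean(x); s1 <- stats::sd(x); n1 <- length(x)
    m2 <- reference$mean[i]; s2 <- reference$sd[i]; n2 <- reference$n[i]
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    tval <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    data.frame(marker = id, t = tval, df = df,
               p = 2 * stats::pt(-abs(tval), df),
               mean_profile = m1, mean_reference = m2,
               direction = sign(m1 - m2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
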
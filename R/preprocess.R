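# Marker-level quality control, applied in the fixed order
# drop_high_missing -> impute_knn2 -> dedup_correlated.

#' Discard markers with excessive missingness
#'
#' Removes every marker whose fraction of missing values is strictly above
#' `threshold` (default 10\%).
#'
#' @param table a [cohort_table()].
#' @param threshold missingness fraction in (0, 1).
#' @return A list with the filtered `table` and a `report` data.frame
#'   (`marker`, `missing_fraction`) of the dropped markers.
#' @export
drop_high_missing <- function(table, threshold = 0.10) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- colMeans(table$mask)
  drop <- frac > threshold
  if (all(drop)) stop2("all markers exceed the missingness threshold")
  report <- data.frame(marker = marker_ids(table)[drop],
                       missing_fraction = unname(frac[drop]),
                       stringsAsFactors = FALSE)
  list(table = subset_markers(table, marker_ids(table)[!drop]),
       report = report)
}

# Pairwise patient distance used by the imputation: Euclidean over the
# markers observed in both patients, each marker standardised by its
# observed mean/SD, normalised by sqrt(#shared markers) so distances are
# comparable across different overlaps.  Returns Inf when no marker is
# shared.
.impute_distance <- function(zi, zj) {
  shared <- !is.na(zi) & !is.na(zj)
  m <- sum(shared)
  if (m == 0) return(Inf)
  sqrt(sum((zi[shared] - zj[shared])^2) / m)
}

#' Two-nearest-neighbour mean imputation
#'
#' Replaces each missing cell with the mean of that marker's values in the
#' two nearest neighbouring patients.  Distance between patients is the
#' overlap-normalised Euclidean distance over markers observed in both,
#' with each marker standardised by its observed mean and SD; candidate
#' neighbours must have the target marker observed.
#'
#' @param table a [cohort_table()]; every marker needs at least two
#'   observed values.
#' @return A list with the completed `table` (empty mask) and a `report`
#'   data.frame of imputed cells (`patient`, `marker`, `value`,
#'   `neighbors`).
#' @export
impute_knn2 <- function(table) {
  vals <- table$values
  mask <- table$mask
  if (!any(mask)) {
    return(list(table = table,
                report = data.frame(patient = character(0), marker = character(0),
                                    value = numeric(0), neighbors = character(0))))
  }
  nobs <- colSums(!mask)
  if (any(nobs < 2)) {
    stop2("marker(s) with fewer than 2 observed values: ",
          paste(colnames(vals)[nobs < 2], collapse = ", "))
  }
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- sweep(sweep(vals, 2, mu), 2, sdv, "/")
  n <- nrow(vals)
  rep_rows <- list()
  out <- vals
  for (i in seq_len(n)) {
    miss_j <- which(mask[i, ])
    if (!length(miss_j)) next
    d <- vapply(seq_len(n), function(k) {
      if (k == i) Inf else .impute_distance(z[i, ], z[k, ])
    }, numeric(1))
    if (all(!is.finite(d))) {
      stop2("patient '", rownames(vals)[i],
            "' shares no observed marker with any other patient")
    }
    for (j in miss_j) {
      cand <- which(!mask[, j] & is.finite(d))
      if (length(cand) < 2) {
        stop2("fewer than 2 candidate neighbours for patient '",
              rownames(vals)[i], "', marker '", colnames(vals)[j], "'")
      }
      nb <- cand[order(d[cand], cand)][1:2]
      val <- mean(vals[nb, j])
      out[i, j] <- val
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(patient = rownames(vals)[i], marker = colnames(vals)[j],
                   value = val,
                   neighbors = paste(rownames(vals)[nb], collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  new_mask <- matrix(FALSE, n, ncol(vals), dimnames = dimnames(vals))
  list(table = cohort_table(out, new_mask, table$markers),
       report = do.call(rbind, rep_rows))
}

# Pooled-variance two-sample Student t statistic for marker retention.
.pooled_t <- function(x, g) {
  x1 <- x[g]; x0 <- x[!g]
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2)
  if (sp2 == 0) return(0)
  (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

#' Deduplicate highly correlated markers
#'
#' Computes pairwise Pearson correlations and, within each connected
#' component of the graph on marker pairs with `|r|` strictly above
#' `r_threshold`, retains the single marker that best separates NCI+ from
#' NCI- patients by absolute pooled-variance Student t statistic; the rest
#' are removed.  Applying the rule per connected component (rather than
#' pairwise) makes the outcome independent of marker order.
#'
#' @param table a completed [cohort_table()] (no missing values).
#' @param ann matching [clinical_annotations()]; both NCI groups need at
#'   least 2 classified patients.
#' @param r_threshold correlation threshold (default 0.95).
#' @return A list with the deduplicated `table` and a `report` data.frame
#'   of decisions (`kept`, `removed`, `abs_r`, `t_kept`, `t_removed`).
#' @export
dedup_correlated <- function(table, ann, r_threshold = 0.95) {
  if (any(table$mask)) stop2("dedup requires a completed table; impute first")
  stopifnot(identical(ann$patient_id, patient_ids(table)))
  g <- ann$nci_flag
  keep_pat <- !is.na(g)
  if (sum(g[keep_pat]) < 2 || sum(!g[keep_pat]) < 2) {
    stop2("need at least 2 patients in each NCI group for marker retention")
  }
  vals <- table$values
  p <- ncol(vals)
  cm <- suppressWarnings(stats::cor(vals))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) > r_threshold
  diag(adj) <- FALSE
  # connected components via repeated BFS
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  tstat <- vapply(seq_len(p), function(j)
    .pooled_t(vals[keep_pat, j], g[keep_pat]), numeric(1))
  keep <- logical(p)
  rep_rows <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) == 1L) {
      keep[members] <- TRUE
      next
    }
    best <- members[order(-abs(tstat[members]), members)][1]
    keep[best] <- TRUE
    for (m in setdiff(members, best)) {
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(kept = colnames(vals)[best], removed = colnames(vals)[m],
                   abs_r = abs(cm[best, m]),
                   t_kept = tstat[best], t_removed = tstat[m],
                   stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(kept = character(0), removed = character(0), abs_r = numeric(0),
               t_kept = numeric(0), t_removed = numeric(0))
  list(table = subset_markers(table, colnames(vals)[keep]), report = report)
}

#' Run the full marker-level quality-control pipeline
#'
#' Applies, in order, [drop_high_missing()], [impute_knn2()] and
#' [dedup_correlated()].
#'
#' @inheritParams dedup_correlated
#' @param missing_threshold passed to [drop_high_missing()].
#' @return A list with the final `table` and the three stage reports.
#' @export
preprocess_cohort <- function(table, ann, missing_threshold = 0.10,
                              r_threshold = 0.95) {
  s1 <- drop_high_missing(table, missing_threshold)
  s2 <- impute_knn2(s1$table)
  s3 <- dedup_correlated(s2$table, ann, r_threshold)
  list(table = s3$table,
       dropped = s1$report, imputed = s2$report, dedup = s3$report)
}
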
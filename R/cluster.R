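# Double hierarchical clustering of patients (Euclidean distance on
# z-scored markers) and markers (1 - |Pearson correlation|), both under
# Ward's minimum-variance linkage, with clusterability (Hopkins) and
# cluster-number (silhouette, gap statistic) diagnostics.

#' Z-score the marker columns of a cohort
#'
#' Centres and scales every marker column to mean 0, SD 1.  Markers have
#' wildly different units (percentages, cells/uL, pg/mL), so
#' standardisation is required before a Euclidean patient distance is
#' meaningful.  Zero-variance columns are dropped with a warning.
#'
#' @param table a completed [cohort_table()] (no missing values), or a
#'   numeric matrix.
#' @param markers optional character vector restricting to a subset of
#'   marker columns.
#' @return Numeric matrix of z-scores.
#' @export
zscore_markers <- function(table, markers = NULL) {
  vals <- if (inherits(table, "cohort_table")) {
    if (any(table$mask)) stop2("z-scoring requires a completed table")
    table$values
  } else as.matrix(table)
  if (anyNA(vals)) stop2("z-scoring requires a completed table")
  if (!is.null(markers)) {
    idx <- match(markers, colnames(vals))
    if (anyNA(idx)) stop2("unknown marker id: ",
                          paste(markers[is.na(idx)], collapse = ", "))
    vals <- vals[, idx, drop = FALSE]
  }
  sds <- apply(vals, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning("dropping zero-variance marker(s): ",
            paste(colnames(vals)[zero], collapse = ", "), call. = FALSE)
    vals <- vals[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  sweep(sweep(vals, 2, colMeans(vals)), 2, sds, "/")
}

#' Euclidean distance between patients
#'
#' @param z z-scored patients x markers matrix.
#' @return A `dist` object (symmetric, zero diagonal).
#' @export
patient_distance <- function(z) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop2("non-finite values in the z-scored matrix")
  stats::dist(z, method = "euclidean")
}

#' Correlation-based distance between markers
#'
#' `d(a, b) = 1 - |Pearson r(a, b)|` across patients, so that markers which
#' rise or fall together (in either direction) are close.
#'
#' @param z z-scored patients x markers matrix with >= 3 patients.
#' @return A `dist` object over markers.
#' @export
marker_distance <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 3) stop2("need at least 3 patients")
  sds <- apply(z, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    stop2("zero-variance marker(s): drop them before computing distances")
  }
  stats::as.dist(1 - abs(stats::cor(z)))
}

#' Ward linkage
#'
#' Agglomerative clustering under Ward's minimum-variance criterion
#' (Lance-Williams recurrence on squared dissimilarities;
#' [stats::hclust()] method `"ward.D2"`).
#'
#' @param d a `dist` object or symmetric distance matrix with zero
#'   diagonal, n >= 2.
#' @return An `hclust` tree.
#' @export
ward_linkage <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
      stop2("distance matrix must be symmetric")
    }
    if (any(abs(diag(d)) > 1e-8)) stop2("distance matrix must have zero diagonal")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) stop2("`d` must be a dist object or matrix")
  if (attr(d, "Size") < 2) stop2("need at least 2 items")
  stats::hclust(d, method = "ward.D2")
}

#' Hopkins clusterability statistic
#'
#' `H = sum(u) / (sum(u) + sum(w))` where, for `m = max(1,
#' floor(sample_fraction * n))` draws, `u_i` is the nearest-neighbour
#' distance from a uniform random point in the per-dimension bounding box
#' of `z` to the data, and `w_i` the nearest-neighbour distance from a
#' sampled data point to the remaining data.  Values near 0.5 indicate
#' spatial randomness; values near 1 indicate strong cluster structure
#' (real points sit in dense pockets, so their neighbour distances `w` are
#' small relative to those of uniform probes).
#'
#' @param z numeric matrix with at least 20 rows.
#' @param sample_fraction fraction of rows sampled (default 0.1).
#' @param seed integer seed.
#' @return Hopkins statistic in `[0, 1]`.
#' @export
hopkins_stat <- function(z, sample_fraction = 0.1, seed = 1L) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 20) stop2("Hopkins statistic needs at least 20 rows")
  m <- max(1L, floor(sample_fraction * n))
  lo <- apply(z, 2, min); hi <- apply(z, 2, max)
  with_seed(seed, {
    # nearest-neighbour distance from each row of `q` to rows of `ref`,
    # excluding index `skip[i]` when given
    nn_dist <- function(q, ref, skip = NULL) {
      vapply(seq_len(nrow(q)), function(i) {
        d2 <- colSums((t(ref) - q[i, ])^2)
        if (!is.null(skip)) d2[skip[i]] <- Inf
        sqrt(min(d2))
      }, numeric(1))
    }
    u_pts <- matrix(stats::runif(m * ncol(z), rep(lo, each = m),
                                 rep(hi, each = m)), nrow = m)
    idx <- sample.int(n, m)
    u <- nn_dist(u_pts, z)
    w <- nn_dist(z[idx, , drop = FALSE], z, skip = idx)
    sum(u) / (sum(u) + sum(w))
  })
}

# Mean silhouette width of a partition; singleton clusters contribute 0.
.mean_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(labels, d)
  if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
}

#' Choose the number of patient clusters
#'
#' Evaluates cuts of the Ward tree at each `k` in `k_range` with two
#' criteria: the mean silhouette width, and the Tibshirani gap statistic
#' (`B` uniform reference data sets drawn from the per-dimension bounding
#' box, within-cluster dispersion measured with squared Euclidean
#' distances).  The gap choice is the smallest `k` with
#' `Gap(k) >= Gap(k+1) - s_{k+1}`; when silhouette and gap disagree the
#' gap choice is returned as `k` (both are reported).
#'
#' @param z z-scored patients x markers matrix.
#' @param d_patients optional pre-computed patient `dist`.
#' @param k_range candidate cluster numbers (default `2:10`).
#' @param B number of gap reference data sets (default 50).
#' @param seed integer seed (reference draws).
#' @return A list: `k`, `k_sil`, `k_gap`, `silhouette` (data.frame `k`,
#'   `width`), `gap` (data.frame `k`, `gap`, `se`), `tree` (the patient
#'   Ward tree).
#' @export
choose_k <- function(z, d_patients = NULL, k_range = 2:10, B = 50L,
                     seed = 1L) {
  z <- as.matrix(z)
  n <- nrow(z)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stop2("k_range must lie within 2..n-1")
  }
  if (is.null(d_patients)) d_patients <- patient_distance(z)
  tree <- ward_linkage(d_patients)
  sil <- vapply(k_range, function(k)
    .mean_silhouette(stats::cutree(tree, k), d_patients), numeric(1))
  ward_cut <- function(x, k) {
    list(cluster = stats::cutree(
      stats::hclust(stats::dist(x), method = "ward.D2"), k))
  }
  gp <- with_seed(seed,
    cluster::clusGap(z, FUNcluster = ward_cut, K.max = max(k_range),
                     B = B, d.power = 2, spaceH0 = "original",
                     verbose = FALSE))
  tab <- gp$Tab[k_range, , drop = FALSE]
  gap <- tab[, "gap"]; se <- tab[, "SE.sim"]
  k_gap <- NA_integer_
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) { k_gap <- k_range[i]; break }
  }
  if (is.na(k_gap)) k_gap <- k_range[which.max(gap)]
  k_sil <- k_range[which.max(sil)]
  list(k = k_gap, k_sil = k_sil, k_gap = k_gap,
       silhouette = data.frame(k = k_range, width = sil),
       gap = data.frame(k = k_range, gap = gap, se = se),
       tree = tree)
}

#' Cut a patient tree into profiles
#'
#' Cuts the Ward tree at `k` clusters and renumbers the labels 1..k by
#' decreasing cluster size (ties broken by the first patient index), so
#' profile 1 is always the largest cluster.
#'
#' @param tree an `hclust` tree over patients.
#' @param k number of profiles (<= number of patients).
#' @return Integer vector of profile labels named by patient.
#' @export
assign_profiles <- function(tree, k) {
  n <- length(tree$order)
  if (k > n) stop2("k exceeds the number of patients")
  raw <- stats::cutree(tree, k)
  size <- table(raw)
  first <- vapply(names(size), function(l) min(which(raw == l)), numeric(1))
  ord <- order(-as.integer(size), first)
  remap <- integer(length(size))
  remap[as.integer(names(size))[ord]] <- seq_along(ord)
  stats::setNames(remap[raw], names(raw))
}

#' Export the double-clustering heat map
#'
#' Writes a heat map of the z-scored matrix with rows (patients) and
#' columns (markers) ordered by their Ward dendrograms and a profile
#' annotation band, plus the dendrogram-ordered matrix as TSV for exact
#' comparison.
#'
#' @param z z-scored patients x markers matrix.
#' @param patient_tree,marker_tree `hclust` trees over rows and columns.
#' @param labels profile labels from [assign_profiles()].
#' @param path output image path (`.png` or `.pdf`); the ordered matrix is
#'   written next to it with suffix `_matrix.tsv`.
#' @return Invisibly, a list with the image and TSV paths.
#' @export
heatmap_export <- function(z, patient_tree, marker_tree, labels, path) {
  z <- as.matrix(z)
  stopifnot(length(patient_tree$order) == nrow(z),
            length(marker_tree$order) == ncol(z),
            length(labels) == nrow(z))
  tsv <- sub("\\.(png|pdf|svg)$", "_matrix.tsv", path)
  if (tsv == path) tsv <- paste0(path, "_matrix.tsv")
  ordered <- z[patient_tree$order, marker_tree$order, drop = FALSE]
  utils::write.table(round(ordered, 6), tsv, sep = "\t", quote = FALSE,
                     col.names = NA)
  ann <- data.frame(profile = factor(labels),
                    row.names = rownames(z))
  ok <- tryCatch({
    pheatmap::pheatmap(z, cluster_rows = stats::as.hclust(patient_tree),
                       cluster_cols = stats::as.hclust(marker_tree),
                       annotation_row = ann, show_rownames = nrow(z) <= 60,
                       filename = path, silent = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop2("cannot write heat map '", path, "': ",
                         conditionMessage(ok))
  invisible(list(image = path, matrix = tsv))
}

#' Identify immune activation profiles by double hierarchical clustering
#'
#' Convenience wrapper chaining [zscore_markers()], [hopkins_stat()],
#' [patient_distance()], [marker_distance()], [ward_linkage()],
#' [choose_k()] and [assign_profiles()].  By default only percentage and
#' soluble-concentration markers enter the clustering (percentages are more
#' stable over time than absolute counts).
#'
#' @param table a completed [cohort_table()].
#' @param markers optional marker subset; default selects markers measured
#'   as percent or concentration.
#' @param k_range,B,seed passed to [choose_k()] / [hopkins_stat()].
#' @param k optional fixed number of profiles, bypassing [choose_k()].
#' @return A list of class `profile_result`: `labels`, `k`, `hopkins`,
#'   `patient_tree`, `marker_tree`, `diagnostics` (the [choose_k()]
#'   output, `NULL` when `k` was fixed), `z`.
#' @export
cluster_profiles <- function(table, markers = NULL, k_range = 2:10, B = 50L,
                             seed = 1L, k = NULL) {
  if (is.null(markers) && inherits(table, "cohort_table")) {
    markers <- table$markers$id[table$markers$measure %in%
                                  c("percent", "concentration")]
  }
  z <- suppressWarnings(zscore_markers(table, markers))
  dp <- patient_distance(z)
  hop <- hopkins_stat(z, seed = seed)
  marker_tree <- ward_linkage(marker_distance(z))
  if (is.null(k)) {
    diag <- choose_k(z, dp, k_range = k_range, B = B, seed = seed)
    tree <- diag$tree
    k <- diag$k
  } else {
    diag <- NULL
    tree <- ward_linkage(dp)
  }
  labels <- assign_profiles(tree, k)
  structure(list(labels = labels, k = k, hopkins = hop,
                 patient_tree = tree, marker_tree = marker_tree,
                 diagnostics = diag, z = z),
            class = "profile_result")
}

#' @export
print.profile_result <- function(x, ...) {
  cat(sprintf("<profile_result> %d patients, k = %d profiles, Hopkins %.3f\n",
              length(x$labels), x$k, x$hopkins))
  print(table(profile = x$labels))
  invisible(x)
}
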
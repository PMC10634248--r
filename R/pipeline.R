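# End-to-end orchestration of the two analysis arms, with seeded,
# reproducible report files.  Every output file starts with comment lines
# recording the configuration hash and stage seeds.

.write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the supervised biomarker arm
#'
#' Executes, in order: marker-level quality control
#' ([preprocess_cohort()]), Kruskal-Wallis screening with
#' Benjamini-Hochberg FDR ([screen_markers()]), repeated-CV LDA on the
#' selected markers ([cv_evaluate()]), and genetic-algorithm subset
#' selection ([select_solutions()]).  Writes `preprocess_report.tsv`,
#' `screen.tsv`, `cv_report.tsv`, `ga_solutions.tsv` and `run_log.txt` to
#' `outdir`.  When no marker survives selection the LDA and GA stages are
#' skipped with a message.
#'
#' @param table a [cohort_table()] with NCI-labelled annotations `ann`.
#' @param ann matching [clinical_annotations()].
#' @param outdir output directory (created if needed).
#' @param alpha screening selection level.
#' @param missing_threshold,dedup_r quality-control thresholds.
#' @param cv_repeats,cv_folds CV protocol for the selected-marker LDA.
#' @param kw_grouping outcome grouping for the screening Kruskal-Wallis
#'   test, `"three"` (none/ANI/MND) or `"two"` (NCI- / NCI+).
#' @param ga ga configuration ([ga_config()]) or `NULL` to skip the GA.
#' @param seed integer seed governing all stage seeds.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_supervised <- function(table, ann, outdir, alpha = 0.05,
                           missing_threshold = 0.10, dedup_r = 0.95,
                           cv_repeats = 30L, cv_folds = 2L,
                           kw_grouping = c("three", "two"),
                           ga = ga_config(), seed = 1L) {
  kw_grouping <- match.arg(kw_grouping)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 2)
  cfg <- list(alpha = alpha, missing_threshold = missing_threshold,
              dedup_r = dedup_r, cv_repeats = cv_repeats,
              cv_folds = cv_folds, seed = seed)
  hash <- config_hash(cfg)
  hdr <- function(stage, st_seed) {
    sprintf("config=%s stage=%s seed=%d", hash, stage, st_seed)
  }
  log <- c(sprintf("config=%s seed=%d", hash, seed),
           sprintf("input: %d patients x %d markers",
                   nrow(table$values), ncol(table$values)))

  pp <- preprocess_cohort(table, ann, missing_threshold, dedup_r)
  log <- c(log, sprintf(
    "preprocess: dropped=%d imputed=%d dedup_removed=%d -> %d markers",
    nrow(pp$dropped), if (is.null(pp$imputed)) 0L else nrow(pp$imputed),
    nrow(pp$dedup), ncol(pp$table$values)))
  pp_report <- rbind(
    if (nrow(pp$dropped)) data.frame(step = "drop", detail = pp$dropped$marker,
                                     value = pp$dropped$missing_fraction),
    if (!is.null(pp$imputed) && nrow(pp$imputed))
      data.frame(step = "impute",
                 detail = paste(pp$imputed$patient, pp$imputed$marker, sep = ":"),
                 value = pp$imputed$value),
    if (nrow(pp$dedup)) data.frame(step = "dedup",
                                   detail = paste(pp$dedup$removed, "->",
                                                  pp$dedup$kept),
                                   value = pp$dedup$abs_r))
  if (is.null(pp_report)) {
    pp_report <- data.frame(step = character(0), detail = character(0),
                            value = numeric(0))
  }
  .write_report(pp_report, file.path(outdir, "preprocess_report.tsv"),
                hdr("preprocess", seed))

  sc <- screen_markers(pp$table, ann, alpha = alpha, grouping = kw_grouping)
  .write_report(as.data.frame(sc), file.path(outdir, "screen.tsv"),
                hdr("screen", seed))
  sel <- sc$marker[sc$selected]
  log <- c(log, sprintf("screen: %d/%d markers selected at alpha=%g",
                        length(sel), nrow(sc), alpha))

  cv <- NULL; sols <- NULL
  if (length(sel) == 0) {
    message("no marker selected at alpha = ", alpha,
            "; LDA and GA stages skipped")
    log <- c(log, "lda/ga: skipped (empty selection)")
  } else {
    known <- ann$nci_class != "unknown"
    x <- pp$table$values[known, sel, drop = FALSE]
    y <- ann$nci_flag[known]
    cv <- cv_evaluate(x, y, n_repeats = cv_repeats, n_folds = cv_folds,
                      seed = seeds[1])
    .write_report(
      data.frame(n_markers = length(sel),
                 markers = paste(sel, collapse = ";"),
                 accuracy = cv$accuracy, accuracy_sd = cv$accuracy_sd,
                 sensitivity = cv$sensitivity, specificity = cv$specificity,
                 n_repeats = cv_repeats, n_folds = cv_folds),
      file.path(outdir, "cv_report.tsv"), hdr("lda_cv", seeds[1]))
    log <- c(log, sprintf("lda_cv: accuracy=%.3f sens=%.3f spec=%.3f",
                          cv$accuracy, cv$sensitivity, cv$specificity))
    if (!is.null(ga) && length(sel) < 2) {
      message("fewer than 2 selected markers; GA stage skipped")
      log <- c(log, "ga: skipped (fewer than 2 selected markers)")
    } else if (!is.null(ga)) {
      ga$seed <- seeds[2]
      sols <- select_solutions(x, y, ga)
      .write_report(as.data.frame(sols),
                    file.path(outdir, "ga_solutions.tsv"),
                    hdr("ga", seeds[2]))
      log <- c(log, sprintf("ga: %d solutions, best accuracy=%.3f (%s)",
                            nrow(sols), sols$accuracy[1], sols$markers[1]))
    }
  }
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(list(preprocess = pp, screen = sc, cv = cv, ga_solutions = sols,
                 outdir = outdir))
}

#' Run the unsupervised profiling arm
#'
#' Z-scores the percentage and soluble markers, assesses clusterability
#' (Hopkins), performs the double Ward clustering with silhouette and gap
#' diagnostics, assigns immune activation profiles, exports the heat map
#' and dendrogram-ordered matrix, characterises each profile by its
#' profile-versus-rest markers, and (when NCI labels are available) tests
#' each profile's NCI enrichment.  Writes `diagnostics.tsv`,
#' `profiles.tsv`, `profile_markers.tsv`, `enrichment.tsv`, `heatmap.png`
#' and `run_log.txt` to `outdir`.
#'
#' @param table a completed [cohort_table()] (preprocessed; no missing
#'   values among the clustered markers).
#' @param ann optional [clinical_annotations()]; enrichment is skipped
#'   with a warning when absent or unlabelled.
#' @param outdir output directory.
#' @param k_range,gap_b candidate k and gap reference count.
#' @param markers optional marker subset for the clustering.
#' @param seed integer seed.
#' @return Invisibly, a list with the `profile_result`, per-profile top
#'   markers, enrichment table and output paths.
#' @export
run_profiles <- function(table, ann = NULL, outdir, k_range = 2:10,
                         gap_b = 50L, markers = NULL, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(k_range = k_range, gap_b = gap_b, seed = seed)
  hash <- config_hash(cfg)
  hdr <- sprintf("config=%s stage=profiles seed=%d", hash, seed)
  log <- c(sprintf("config=%s seed=%d", hash, seed),
           sprintf("input: %d patients x %d markers",
                   nrow(table$values), ncol(table$values)))

  pr <- cluster_profiles(table, markers = markers, k_range = k_range,
                         B = gap_b, seed = seed)
  log <- c(log, sprintf("clustering: hopkins=%.3f k=%d (sil=%d gap=%d)",
                        pr$hopkins, pr$k, pr$diagnostics$k_sil,
                        pr$diagnostics$k_gap))
  diag_df <- merge(pr$diagnostics$silhouette, pr$diagnostics$gap, by = "k")
  diag_df$hopkins <- pr$hopkins
  .write_report(diag_df, file.path(outdir, "diagnostics.tsv"), hdr)
  .write_report(data.frame(patient_id = names(pr$labels),
                           profile = unname(pr$labels)),
                file.path(outdir, "profiles.tsv"), hdr)
  heatmap_export(pr$z, pr$patient_tree, pr$marker_tree, pr$labels,
                 file.path(outdir, "heatmap.png"))

  top <- do.call(rbind, lapply(seq_len(pr$k), function(p) {
    pv <- profile_vs_rest_markers(table, pr$labels, p)
    cbind(profile = p, utils::head(pv, 5))
  }))
  .write_report(top, file.path(outdir, "profile_markers.tsv"), hdr)

  enr <- NULL
  if (is.null(ann) || all(is.na(ann$nci_flag))) {
    warning("no NCI labels available; enrichment skipped", call. = FALSE)
    log <- c(log, "enrichment: skipped (no labels)")
  } else {
    enr <- do.call(rbind, lapply(seq_len(pr$k), function(p) {
      e <- nci_enrichment(pr$labels, ann$nci_flag, p)
      data.frame(profile = p, a = e$table[1, 1], b = e$table[1, 2],
                 c = e$table[2, 1], d = e$table[2, 2],
                 or = e$or, lo = e$lo, hi = e$hi, p_value = e$p)
    }))
    .write_report(enr, file.path(outdir, "enrichment.tsv"), hdr)
    log <- c(log, sprintf("enrichment: max OR=%.2f (profile %d)",
                          max(enr$or), enr$profile[which.max(enr$or)]))
  }
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(list(profiles = pr, top_markers = top, enrichment = enr,
                 outdir = outdir))
}
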
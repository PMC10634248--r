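# Synthetic cohort generation.
#
# The generator plants the statistical structure the analysis pipeline
# assumes: six latent immune-activation profiles with characteristic marker
# shifts, NCI prevalence elevated in two profiles, the six NCI-discriminating
# markers drawn from their published group-conditional moments, sporadic and
# concentrated missingness, and near-duplicate marker pairs.  Where a group
# mean and SD are published they are used verbatim; everywhere else the
# baseline table fixes a plausible scale.

#' Baseline marker moments
#'
#' Per-marker baseline mean and SD used by the synthetic generator for every
#' marker without a profile- or group-specific override.  Markers whose
#' cohort-level moments are published use those values; the remainder are
#' fixed at physiologically plausible scales for a treated HIV cohort aged
#' 55-70 (percentages of parent populations, cells/uL, pg/mL or ng/mL).
#'
#' @return `data.frame` with columns `id`, `mean`, `sd`.
#' @export
default_baseline <- function() {
  tab <- c(
    # CD4 T-cell percentages
    "t4_hladr_pct", 22, 11,    "t4_cd38_pct", 30, 12,
    "t4_cd38hi_pct", 5, 3,     "t4_hladr_cd38_pct", 8, 5,
    "t4_hladr_cd38neg_pct", 14, 8, "t4_pd1_pct", 25, 10,
    "t4_cd57_pct", 8.8, 8.1,   "t4_cd57_cd28neg_pct", 6, 5,
    "t4_cd57_cd28neg_cd27neg_pct", 4, 3.5,
    "t4_naive_pct", 30, 12,    "t4_cm_pct", 35, 10,  "t4_em_pct", 25, 10,
    # CD4 T-cell counts
    "t4_hladr_abs", 150, 100,  "t4_cd38_abs", 210, 120,
    "t4_cd38hi_abs", 35, 25,   "t4_hladr_cd38_abs", 56, 45,
    "t4_hladr_cd38neg_abs", 98, 70, "t4_pd1_abs", 175, 110,
    "t4_cd57_abs", 62, 55,     "t4_cd57_cd28neg_abs", 170, 130,
    "t4_cd57_cd28neg_cd27neg_abs", 30, 25,
    "t4_naive_abs", 210, 130,  "t4_cm_abs", 245, 120, "t4_em_abs", 175, 100,
    # CD8 T-cell percentages
    "t8_hladr_pct", 58, 17,    "t8_cd38_pct", 37.1, 12.8,
    "t8_cd38hi_pct", 10, 5,    "t8_hladr_cd38_pct", 20, 10,
    "t8_hladr_cd38neg_pct", 35, 12, "t8_pd1_pct", 30, 10,
    "t8_cd57_pct", 37.3, 11.4, "t8_cd57_cd28neg_pct", 30, 11,
    "t8_cd57_cd28neg_cd27neg_pct", 25, 10,
    "t8_naive_pct", 20, 10,    "t8_cm_pct", 20, 8,   "t8_em_pct", 40, 12,
    # CD8 T-cell counts
    "t8_hladr_abs", 400, 250,  "t8_cd38_abs", 280, 160,
    "t8_cd38hi_abs", 75, 50,   "t8_hladr_cd38_abs", 150, 120,
    "t8_hladr_cd38neg_abs", 260, 150, "t8_pd1_abs", 225, 120,
    "t8_cd57_abs", 280, 140,   "t8_cd57_cd28neg_abs", 225, 120,
    "t8_cd57_cd28neg_cd27neg_abs", 140, 110,
    "t8_naive_abs", 150, 100,  "t8_cm_abs", 150, 80,  "t8_em_abs", 300, 150,
    # NK cells
    "nk_hladr_pct", 10, 5,     "nk_hladr_abs", 20, 12,
    "nk_cd56neg_pct", 8, 6,    "nk_cd56neg_abs", 15, 10,
    "nk_cd57_pct", 40, 15,     "nk_cd57_abs", 80, 45,
    # soluble markers
    "scd163", 858, 535,        "stnfri", 1250, 420,
    "tpa", 11.3, 7.0,          "sepcr", 100, 35,
    # global / auxiliary
    "lymphocytes_abs", 1800, 600,
    "cd8_pct", 50, 11,         "cd4_abs", 712, 382
  )
  m <- matrix(tab, ncol = 3, byrow = TRUE)
  data.frame(id = m[, 1], mean = as.numeric(m[, 2]), sd = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Planted profile effects
#'
#' Per-(profile, marker) mean/SD overrides defining the six planted immune
#' activation profiles.  The characteristic markers use the published
#' per-profile moments; each profile additionally shifts a coherent set of
#' related markers of the same biological axis so that the profiles are
#' separable multivariate clusters and not single-marker artefacts:
#' profile 1 = globally low T-cell activation and senescence; profile 2 =
#' high CD38 activation; profile 3 = poor CD4 reconstitution with naive
#' depletion and exhaustion; profile 4 = monocyte/inflammation activation;
#' profile 5 = endothelial activation; profile 6 = high HLA-DR activation.
#'
#' @return `data.frame` with columns `profile`, `id`, `mean`, `sd`.
#' @export
default_profile_effects <- function() {
  tab <- list(
    # profile 1: globally low activated/senescent T cells
    c(1, "t4_cd57_pct", 2.2, 1.9),   c(1, "t8_cd57_pct", 19.6, 8.7),
    c(1, "t4_hladr_pct", 14.5, 4.6), c(1, "t8_hladr_pct", 44.7, 16.3),
    c(1, "t4_cd57_cd28neg_pct", 1.5, 1.2),
    c(1, "t4_cd57_cd28neg_cd27neg_pct", 1.0, 1.0),
    c(1, "t8_cd57_cd28neg_pct", 12, 5),
    c(1, "t8_cd57_cd28neg_cd27neg_pct", 9, 4.5),
    c(1, "t4_hladr_cd38_pct", 3.2, 2),
    c(1, "t4_hladr_cd38neg_pct", 6.5, 3.5),
    c(1, "t8_hladr_cd38_pct", 9, 5),
    c(1, "t8_hladr_cd38neg_pct", 20, 7),
    c(1, "nk_cd57_pct", 23, 9),
    # profile 2: high CD38+ activation
    c(2, "t8_cd38_pct", 57.3, 13.3), c(2, "t4_cd38_pct", 52, 9),
    c(2, "t8_hladr_cd38_pct", 38, 8), c(2, "t4_hladr_cd38_pct", 16, 4.5),
    c(2, "t8_hladr_pct", 69, 12),
    # profile 3: low CD4 count, naive depletion, exhaustion
    c(3, "cd4_abs", 576, 250),       c(3, "t4_hladr_pct", 20.5, 9.1),
    c(3, "t8_hladr_pct", 51.2, 16.6),c(3, "t4_cd57_pct", 3.8, 3.1),
    c(3, "t8_cd57_pct", 20.0, 9.0),  c(3, "t4_naive_pct", 11, 5),
    c(3, "t8_naive_pct", 7, 4),      c(3, "t4_pd1_pct", 40, 8),
    c(3, "t8_pd1_pct", 44, 9),       c(3, "t4_em_pct", 39, 9),
    c(3, "t8_em_pct", 53, 10),       c(3, "t4_cm_pct", 27, 8),
    # profile 4: monocyte activation / inflammation
    c(4, "scd163", 974, 466),        c(4, "stnfri", 2400, 380),
    c(4, "nk_cd56neg_pct", 21, 5.5), c(4, "nk_hladr_pct", 17, 5),
    # profile 5: endothelial activation with mild immunosenescence
    c(5, "tpa", 16.4, 9.8),          c(5, "sepcr", 225, 35),
    c(5, "t8_cd57_pct", 42, 10),     c(5, "nk_cd57_pct", 47, 12),
    c(5, "t8_cd57_cd28neg_pct", 35, 9),
    # profile 6: high HLA-DR+ activation
    c(6, "t4_hladr_pct", 44.9, 13.7),c(6, "t8_hladr_pct", 78, 11),
    c(6, "t4_hladr_cd38_pct", 17, 5),c(6, "t8_hladr_cd38_pct", 32, 8),
    c(6, "t4_hladr_cd38neg_pct", 29, 8), c(6, "nk_hladr_pct", 20, 5.5),
    c(6, "t8_hladr_cd38neg_pct", 46, 10)
  )
  m <- do.call(rbind, tab)
  data.frame(profile = as.integer(m[, 1]), id = m[, 2],
             mean = as.numeric(m[, 3]), sd = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
}

# Published group-conditional moments of the six markers that discriminate
# NCI+ (ANI or MND) from NCI- participants in the 65-patient substudy.
nci_substudy_effects <- function() {
  tab <- list(
    #    id                              NCI+ mean/sd   NCI- mean/sd
    c("t4_hladr_pct",                    19.0, 8.4,     27.5, 13.5),
    c("cd8_pct",                         46.0, 11.1,    51.8, 11.1),
    c("t8_hladr_abs",                    290, 219,      473, 263),
    c("t8_hladr_cd38_abs",               106, 102,      169, 136),
    c("t4_cd57_cd28neg_abs",             108, 93,       223, 170),
    c("t8_cd57_cd28neg_cd27neg_abs",     82, 83,        170, 148)
  )
  m <- do.call(rbind, tab)
  data.frame(id = m[, 1],
             mean_pos = as.numeric(m[, 2]), sd_pos = as.numeric(m[, 3]),
             mean_neg = as.numeric(m[, 4]), sd_neg = as.numeric(m[, 5]),
             stringsAsFactors = FALSE)
}

#' Synthetic-cohort generator configuration
#'
#' Assembles and validates the configuration of the profile-cohort
#' generator.  Defaults encode the study conditions: 6 profiles of 40
#' patients each, NCI probability elevated in profiles 1 and 3, weak
#' positive equicorrelation (`within_block_rho`) among markers of one
#' lineage, 2\% sporadic missingness plus two high-missingness markers, and
#' two planted near-duplicate marker pairs (CD38hi as a 0.96-0.97
#' correlated copy of CD38+ within each T lineage).
#'
#' @param n_per_profile integer vector of 6 profile sizes (default 40 each).
#' @param baseline_table per-marker baseline moments, see [default_baseline()].
#' @param profile_effect_table per-(profile, marker) overrides, see
#'   [default_profile_effects()].
#' @param nci_prob 6 per-profile NCI probabilities.
#' @param within_block_rho equicorrelation among markers of one lineage.
#' @param sporadic_missing_rate MCAR missingness rate applied to all cells.
#' @param n_high_missing_markers number of markers with concentrated
#'   missingness at `high_missing_rate`.
#' @param high_missing_rate missingness rate for those markers.
#' @param duplicate_pairs list of `list(src=, dst=, r=)` duplicate specs.
#' @param fazekas_marginals list with elements `pv` and `deep`: two
#'   4-vectors of category probabilities for scores 0-3.
#' @param seed integer seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_per_profile = rep(40L, 6),
                             baseline_table = default_baseline(),
                             profile_effect_table = default_profile_effects(),
                             nci_prob = c(0.60, 0.20, 0.53, 0.20, 0.20, 0.20),
                             within_block_rho = 0.1,
                             sporadic_missing_rate = 0.02,
                             n_high_missing_markers = 2L,
                             high_missing_rate = 0.15,
                             duplicate_pairs = list(
                               list(src = "t8_cd38_pct", dst = "t8_cd38hi_pct", r = 0.97),
                               list(src = "t4_cd38_pct", dst = "t4_cd38hi_pct", r = 0.96)),
                             fazekas_marginals = list(
                               pv = c(0.12, 0.54, 0.25, 0.09),
                               deep = c(0.09, 0.59, 0.16, 0.16)),
                             seed = 1L) {
  stopifnot(length(n_per_profile) == 6, all(n_per_profile >= 1),
            length(nci_prob) == 6, all(nci_prob >= 0 & nci_prob <= 1),
            within_block_rho >= 0, within_block_rho < 1,
            sporadic_missing_rate >= 0, sporadic_missing_rate < 1,
            high_missing_rate >= 0, high_missing_rate < 1,
            all(baseline_table$sd > 0), all(profile_effect_table$sd > 0))
  for (mg in fazekas_marginals) {
    stopifnot(length(mg) == 4, all(mg >= 0))
    if (abs(sum(mg) - 1) > 1e-8) stop2("Fazekas marginals must sum to 1")
  }
  for (dp in duplicate_pairs) {
    stopifnot(is.character(dp$src), is.character(dp$dst),
              dp$r >= 0.95, dp$r < 1)
  }
  structure(list(n_per_profile = as.integer(n_per_profile),
                 baseline_table = baseline_table,
                 profile_effect_table = profile_effect_table,
                 nci_prob = nci_prob,
                 within_block_rho = within_block_rho,
                 sporadic_missing_rate = sporadic_missing_rate,
                 n_high_missing_markers = as.integer(n_high_missing_markers),
                 high_missing_rate = high_missing_rate,
                 duplicate_pairs = duplicate_pairs,
                 fazekas_marginals = fazekas_marginals,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' Key-value fields map onto the arguments of [generator_config()]; tables
#' (`baseline_table`, `profile_effect_table`) may be given as lists of
#' records.  Omitted fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_per_profile", "nci_prob", "within_block_rho",
               "sporadic_missing_rate", "n_high_missing_markers",
               "high_missing_rate", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$fazekas_marginals)) args$fazekas_marginals <- y$fazekas_marginals
  if (!is.null(y$duplicate_pairs)) args$duplicate_pairs <- y$duplicate_pairs
  to_df <- function(recs) do.call(rbind, lapply(recs, as.data.frame))
  if (!is.null(y$baseline_table)) args$baseline_table <- to_df(y$baseline_table)
  if (!is.null(y$profile_effect_table)) {
    args$profile_effect_table <- to_df(y$profile_effect_table)
  }
  do.call(generator_config, args)
}

# Clamp simulated values to the physiologic range of each marker: percent
# markers to [0, 100], counts and concentrations to [0, Inf).  Censoring at
# the bounds (rather than resampling) preserves the planted correlation
# structure.
clamp_to_range <- function(vals, markers) {
  for (j in seq_len(ncol(vals))) {
    lo <- 0
    hi <- if (markers$measure[j] == "percent") 100 else Inf
    vals[, j] <- pmin(pmax(vals[, j], lo), hi)
  }
  vals
}

# Draw n patients for one stratum: lineage-blocked equicorrelated normals
# with per-marker means/sds, clamped to range.  `markers` must carry
# columns id, lineage, measure, mean, sd.
draw_block_normal <- function(n, markers, rho) {
  p <- nrow(markers)
  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, markers$id))
  for (block in unique(markers$lineage)) {
    idx <- which(markers$lineage == block)
    g <- stats::rnorm(n)                       # shared within-lineage factor
    for (j in idx) {
      e <- stats::rnorm(n)
      z <- sqrt(rho) * g + sqrt(1 - rho) * e
      vals[, j] <- markers$mean[j] + markers$sd[j] * z
    }
  }
  clamp_to_range(vals, markers)
}

# Overwrite each duplicate target column with a correlation-controlled noisy
# copy of its source column; retries the noise until the planted sample
# correlation is achieved (|r| >= 0.95 whenever n >= 100).
plant_duplicates <- function(vals, markers, duplicate_pairs, max_retry = 20L) {
  for (dp in duplicate_pairs) {
    si <- match(dp$src, colnames(vals))
    di <- match(dp$dst, colnames(vals))
    if (is.na(si) || is.na(di)) {
      stop2("duplicate pair references unknown marker: ", dp$src, " -> ", dp$dst)
    }
    n <- nrow(vals)
    z <- as.numeric(scale(vals[, si]))
    mj <- markers[di, ]
    for (attempt in seq_len(max_retry)) {
      eps <- stats::rnorm(n)
      x <- mj$mean + mj$sd * (dp$r * z + sqrt(1 - dp$r^2) * eps)
      x <- clamp_to_range(matrix(x, ncol = 1),
                          markers[di, , drop = FALSE])[, 1]
      if (n < 100 || abs(stats::cor(vals[, si], x)) >= 0.95) break
    }
    vals[, di] <- x
  }
  vals
}

# Apply MCAR missingness: a sporadic rate everywhere plus concentrated
# missingness on randomly chosen uninformative markers.
apply_missingness <- function(vals, config, protect) {
  mask <- matrix(stats::runif(length(vals)) < config$sporadic_missing_rate,
                 nrow(vals), ncol(vals), dimnames = dimnames(vals))
  eligible <- setdiff(colnames(vals), protect)
  n_high <- min(config$n_high_missing_markers, length(eligible))
  high <- if (n_high > 0) sample(eligible, n_high) else character(0)
  for (id in high) {
    extra <- stats::runif(nrow(vals)) < config$high_missing_rate
    mask[, id] <- mask[, id] | extra
  }
  list(mask = mask, high_missing = high)
}

# Marker descriptor table (registry + auxiliary markers) merged with
# per-marker moments; `overrides` is a data.frame(id, mean, sd).
moments_for <- function(overrides = NULL) {
  mk <- known_markers()
  base <- default_baseline()
  mk$mean <- base$mean[match(mk$id, base$id)]
  mk$sd <- base$sd[match(mk$id, base$id)]
  if (!is.null(overrides) && nrow(overrides)) {
    bad <- setdiff(overrides$id, mk$id)
    if (length(bad)) stop2("effect table references unknown marker id: ",
                           paste(bad, collapse = ", "))
    i <- match(overrides$id, mk$id)
    mk$mean[i] <- overrides$mean
    mk$sd[i] <- overrides$sd
  }
  mk
}

#' Generate a profile-structured synthetic cohort
#'
#' Draws a cohort of (by default) 240 patients carrying the 59-marker
#' activation panel plus the auxiliary CD4 count and CD8 percentage, with
#' six planted immune-activation profiles, profile-dependent NCI
#' probability, lineage-blocked correlation, near-duplicate marker pairs
#' and MCAR missingness.  Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return A list with elements `table` ([cohort_table()]), `ann`
#'   ([clinical_annotations()]) and `truth` (per-patient true profile,
#'   planted probabilities and informative marker ids, the seed).
#' @export
generate_profile_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(config$seed, 4)
  eff <- config$profile_effect_table
  # validate effect ids against the marker set once, before drawing
  mk_all <- moments_for()
  bad <- setdiff(eff$id, mk_all$id)
  if (length(bad)) stop2("effect table references unknown marker id: ",
                         paste(bad, collapse = ", "))
  if (!is.null(config$baseline_table)) {
    b <- config$baseline_table
    i <- match(b$id, mk_all$id)
    if (anyNA(i)) stop2("baseline table references unknown marker id: ",
                        paste(b$id[is.na(i)], collapse = ", "))
  }

  profiles <- rep(seq_len(6L), config$n_per_profile)
  n <- length(profiles)
  vals <- with_seed(seeds[1], {
    out <- NULL
    for (p in 1:6) {
      ov <- eff[eff$profile == p, c("id", "mean", "sd")]
      mk <- moments_for(ov)
      if (!is.null(config$baseline_table)) {
        b <- config$baseline_table
        miss <- !(mk$id %in% ov$id)
        i <- match(mk$id[miss], b$id)
        mk$mean[miss][!is.na(i)] <- b$mean[i[!is.na(i)]]
        mk$sd[miss][!is.na(i)] <- b$sd[i[!is.na(i)]]
      }
      out <- rbind(out, draw_block_normal(config$n_per_profile[p], mk,
                                          config$within_block_rho))
    }
    out
  })
  rownames(vals) <- sprintf("P%03d", seq_len(n))
  vals <- with_seed(seeds[2],
                    plant_duplicates(vals, mk_all, config$duplicate_pairs))

  nci <- with_seed(seeds[3], {
    flag <- stats::runif(n) < config$nci_prob[profiles]
    cls <- ifelse(flag, ifelse(stats::runif(n) < 16 / 25, "ANI", "MND"), "none")
    cls
  })

  protect <- unique(c(eff$id, vapply(config$duplicate_pairs, `[[`, "", "dst"),
                      vapply(config$duplicate_pairs, `[[`, "", "src"),
                      nci_substudy_effects()$id))
  ms <- with_seed(seeds[4], apply_missingness(vals, config, protect))
  vals[ms$mask] <- NA_real_

  table <- cohort_table(vals, ms$mask, mk_all[, 1:5])
  ann <- clinical_annotations(rownames(vals), nci_class = nci)
  truth <- list(true_profile = stats::setNames(profiles, rownames(vals)),
                nci_prob = config$nci_prob,
                informative_markers = unique(eff$id),
                high_missing_markers = ms$high_missing,
                seed = config$seed)
  list(table = table, ann = ann, truth = truth)
}

#' Generate the two-group NCI substudy cohort
#'
#' Draws a cohort (by default 40 NCI-negative and 25 NCI-positive patients,
#' the positives split 16 ANI / 9 MND) in which the six NCI-discriminating
#' markers (percentage of HLA-DR+ T4 cells, percentage of CD8+ T cells,
#' HLA-DR+ T8 count, HLA-DR+CD38+ T8 count, CD57+CD28- T4 count,
#' CD57+CD28-CD27- T8 count) are drawn group-conditionally from their
#' published means and SDs; every other marker is drawn from the baseline
#' table in both groups.  No missingness is introduced, so the cohort is
#' directly usable by the discriminant stage.
#'
#' @param seed integer seed.
#' @param n_nci_neg,n_nci_pos group sizes (default 40 and 25).
#' @param within_block_rho within-lineage equicorrelation (default 0.1).
#' @return A list with elements `table`, `ann`, `truth` as in
#'   [generate_profile_cohort()]; `truth$informative_markers` names the six
#'   planted markers.
#' @export
generate_nci_substudy <- function(seed = 1L, n_nci_neg = 40L, n_nci_pos = 25L,
                                  within_block_rho = 0.1) {
  stopifnot(n_nci_neg >= 0, n_nci_pos >= 0, n_nci_neg + n_nci_pos >= 2)
  eff <- nci_substudy_effects()
  draw_group <- function(n, positive) {
    if (n == 0) return(NULL)
    ov <- data.frame(id = eff$id,
                     mean = if (positive) eff$mean_pos else eff$mean_neg,
                     sd = if (positive) eff$sd_pos else eff$sd_neg,
                     stringsAsFactors = FALSE)
    draw_block_normal(n, moments_for(ov), within_block_rho)
  }
  vals <- with_seed(seed, rbind(draw_group(n_nci_neg, FALSE),
                                draw_group(n_nci_pos, TRUE)))
  n <- nrow(vals)
  rownames(vals) <- sprintf("S%03d", seq_len(n))
  # split the positives into ANI and MND in the published 16:9 proportion
  n_ani <- round(n_nci_pos * 16 / 25)
  cls <- c(rep("none", n_nci_neg),
           rep("ANI", n_ani), rep("MND", n_nci_pos - n_ani))
  table <- cohort_table(vals, markers = moments_for()[, 1:5])
  ann <- clinical_annotations(rownames(vals), nci_class = cls)
  truth <- list(true_profile = NULL,
                informative_markers = eff$id,
                group_moments = eff,
                seed = seed)
  list(table = table, ann = ann, truth = truth)
}

#' Attach white-matter-hyperintensity (Fazekas) annotations
#'
#' Assigns each patient a correlated pair of ordinal Fazekas scores
#' (periventricular and deep, each 0-3) by thresholding a shared latent
#' Gaussian at cut-points matching the configured marginal distributions.
#' The two scores share a latent correlation (`latent_r`, default 0.9), and
#' the latent severity is negatively coupled to the patient's percentage of
#' HLA-DR+ T4 cells (`coupling`, default 0.55) so that patients with higher
#' WMH burden show depressed marker values.  A configurable number of
#' patients is marked as lacking MRI.
#'
#' @param table a [cohort_table()] containing marker `t4_hladr_pct`.
#' @param ann matching [clinical_annotations()].
#' @param marginals list with 4-vectors `pv` and `deep` of category
#'   probabilities for scores 0-3 (must each sum to 1).
#' @param latent_r latent correlation between the two scores.
#' @param coupling strength in `[0, 1)` of the negative coupling between
#'   latent WMH severity and the (standardised) HLA-DR+ T4 percentage.
#' @param n_missing_mri number of randomly chosen patients whose scores are
#'   set missing (default 0).
#' @param seed integer seed.
#' @return The annotations with `fazekas_pv` and `fazekas_deep` filled in.
#' @export
generate_wmh_annotations <- function(table, ann,
                                     marginals = list(
                                       pv = c(0.12, 0.54, 0.25, 0.09),
                                       deep = c(0.09, 0.59, 0.16, 0.16)),
                                     latent_r = 0.9, coupling = 0.55,
                                     n_missing_mri = 0L, seed = 1L) {
  for (mg in marginals) {
    if (abs(sum(mg) - 1) > 1e-8) stop2("Fazekas marginals must sum to 1")
  }
  j <- match("t4_hladr_pct", marker_ids(table))
  if (is.na(j)) stop2("cohort lacks marker 't4_hladr_pct'")
  x <- table$values[, j]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  z <- as.numeric(scale(x))
  n <- nrow(table$values)
  with_seed(seed, {
    lat <- -coupling * z + sqrt(1 - coupling^2) * stats::rnorm(n)
    lat2 <- latent_r * lat + sqrt(1 - latent_r^2) * stats::rnorm(n)
    cutp <- function(mg) stats::qnorm(cumsum(mg)[1:3])
    score <- function(l, mg) findInterval(l, cutp(mg))
    pv <- score(lat, marginals$pv)
    dp <- score(lat2, marginals$deep)
    if (n_missing_mri > 0) {
      drop <- sample.int(n, min(n_missing_mri, n))
      pv[drop] <- NA_integer_
      dp[drop] <- NA_integer_
    }
    clinical_annotations(ann$patient_id, nci_class = ann$nci_class,
                         fazekas_pv = pv, fazekas_deep = dp)
  })
}

#' Write a generator truth record as CSV
#'
#' @param truth the `truth` element returned by the generators.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (is.null(truth$true_profile)) {
    df <- data.frame(key = "informative_markers",
                     value = paste(truth$informative_markers, collapse = ";"))
  } else {
    df <- data.frame(patient_id = names(truth$true_profile),
                     true_profile = as.integer(truth$true_profile))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
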
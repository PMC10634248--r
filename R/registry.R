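#' Marker descriptors
#'
#' A marker descriptor records the identity of one activation marker: a
#' short unique id, the cell lineage or compartment it reports on, the
#' phenotype label used in flow cytometry or ELISA, whether it is measured
#' as a percentage of a parent population, an absolute count, or a soluble
#' concentration, and its units.
#'
#' @param id short unique identifier, e.g. `"t4_hladr_pct"`.
#' @param lineage one of `"CD4_T"`, `"CD8_T"`, `"NK"`, `"monocyte"`,
#'   `"inflammation"`, `"endothelium"`, `"global"`.
#' @param phenotype surface or soluble phenotype label, e.g. `"HLA-DR+"`.
#' @param measure one of `"percent"`, `"count"`, `"concentration"`.
#' @param units `"%"`, `"cells/uL"`, `"pg/mL"` or `"ng/mL"`.
#' @return A one-row `data.frame` with columns `id`, `lineage`,
#'   `phenotype`, `measure`, `units`.
#' @export
marker_descriptor <- function(id, lineage, phenotype, measure, units) {
  lineage <- match.arg(lineage, c("CD4_T", "CD8_T", "NK", "monocyte",
                                  "inflammation", "endothelium", "global"))
  measure <- match.arg(measure, c("percent", "count", "concentration"))
  units <- match.arg(units, c("%", "cells/uL", "pg/mL", "ng/mL"))
  data.frame(id = id, lineage = lineage, phenotype = phenotype,
             measure = measure, units = units, stringsAsFactors = FALSE)
}

.t_phenotypes <- function() {
  data.frame(
    code = c("hladr", "cd38", "cd38hi", "hladr_cd38", "hladr_cd38neg",
             "pd1", "cd57", "cd57_cd28neg", "cd57_cd28neg_cd27neg",
             "naive", "cm", "em"),
    label = c("HLA-DR+", "CD38+", "CD38hi", "HLA-DR+CD38+", "HLA-DR+CD38-",
              "PD-1+", "CD57+", "CD57+CD28-", "CD57+CD28-CD27-",
              "CD45RA+CD27+", "CD45RA-CD27+", "CD45RA-CD27-"),
    stringsAsFactors = FALSE
  )
}

#' Canonical 59-marker activation panel
#'
#' Builds the canonical registry of the 59 activation markers quantified in
#' the cohort: twelve T-cell phenotypes (activation: HLA-DR+, CD38+,
#' CD38hi, HLA-DR+CD38+, HLA-DR+CD38-; exhaustion: PD-1+; senescence:
#' CD57+, CD57+CD28-, CD57+CD28-CD27-; naive and memory subsets) each as a
#' percentage and an absolute count for both CD4+ and CD8+ T cells (48
#' markers); three NK-cell phenotypes (HLA-DR+, CD56-, CD57+) as
#' percentage and count (6); four soluble markers (sCD163 for monocyte
#' activation, sTNFRI for inflammation, tPA and sEPCR for endothelial
#' activation); and the absolute lymphocyte count.
#'
#' The ordering is fixed and identical across calls.
#'
#' @return A `data.frame` of 59 marker descriptors (see
#'   [marker_descriptor()]), one row per marker.
#' @export
#' @examples
#' reg <- build_registry()
#' nrow(reg)  # 59
build_registry <- function() {
  ph <- .t_phenotypes()
  rows <- list()
  for (lin in c("t4", "t8")) {
    lineage <- if (lin == "t4") "CD4_T" else "CD8_T"
    tname <- if (lin == "t4") "T4" else "T8"
    for (i in seq_len(nrow(ph))) {
      rows[[length(rows) + 1L]] <- marker_descriptor(
        paste0(lin, "_", ph$code[i], "_pct"), lineage,
        paste0(ph$label[i], " ", tname), "percent", "%")
      rows[[length(rows) + 1L]] <- marker_descriptor(
        paste0(lin, "_", ph$code[i], "_abs"), lineage,
        paste0(ph$label[i], " ", tname), "count", "cells/uL")
    }
  }
  nk <- data.frame(code = c("hladr", "cd56neg", "cd57"),
                   label = c("HLA-DR+", "CD56-", "CD57+"),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(nk))) {
    rows[[length(rows) + 1L]] <- marker_descriptor(
      paste0("nk_", nk$code[i], "_pct"), "NK",
      paste0(nk$label[i], " NK"), "percent", "%")
    rows[[length(rows) + 1L]] <- marker_descriptor(
      paste0("nk_", nk$code[i], "_abs"), "NK",
      paste0(nk$label[i], " NK"), "count", "cells/uL")
  }
  rows[[length(rows) + 1L]] <-
    marker_descriptor("scd163", "monocyte", "sCD163", "concentration", "pg/mL")
  rows[[length(rows) + 1L]] <-
    marker_descriptor("stnfri", "inflammation", "sTNFRI", "concentration", "pg/mL")
  rows[[length(rows) + 1L]] <-
    marker_descriptor("tpa", "endothelium", "tPA", "concentration", "ng/mL")
  rows[[length(rows) + 1L]] <-
    marker_descriptor("sepcr", "endothelium", "sEPCR", "concentration", "ng/mL")
  rows[[length(rows) + 1L]] <-
    marker_descriptor("lymphocytes_abs", "global", "lymphocytes", "count",
                      "cells/uL")
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 59L, !anyDuplicated(reg$id))
  reg
}

#' Auxiliary clinical markers
#'
#' Two cell-count summary measures that accompany the activation panel in
#' cohort files without belonging to the canonical 59-marker registry: the
#' percentage of CD8+ T cells among lymphocytes and the absolute CD4+
#' T-cell count.
#'
#' @return A marker-descriptor `data.frame` with two rows.
#' @export
aux_markers <- function() {
  rbind(
    marker_descriptor("cd8_pct", "CD8_T", "CD8+ T", "percent", "%"),
    marker_descriptor("cd4_abs", "CD4_T", "CD4+ T", "count", "cells/uL")
  )
}

# All marker ids the package knows how to annotate.
known_markers <- function() rbind(build_registry(), aux_markers())

#' Export a marker registry as TSV
#'
#' Writes a two-column (id, units) tab-separated file describing a registry,
#' for use in documentation and external tools.
#'
#' @param registry a marker-descriptor `data.frame`, e.g. [build_registry()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
registry_to_tsv <- function(registry, path) {
  utils::write.table(registry[, c("id", "units")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
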
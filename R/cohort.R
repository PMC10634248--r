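#' Cohort tables
#'
#' A cohort table holds the participants-by-markers numeric matrix together
#' with an explicit missingness mask and the descriptors of its marker
#' columns.  Masked cells carry no value semantics: they are stored as `NA`
#' in `values` and flagged `TRUE` in `mask`.
#'
#' @param values numeric matrix, patients in rows (rownames = patient ids),
#'   markers in columns (colnames = marker ids).
#' @param mask logical matrix of the same shape; `TRUE` marks a missing
#'   cell.  Defaults to `is.na(values)`.
#' @param markers marker-descriptor `data.frame` covering every column of
#'   `values`, in column order.  Defaults to looking ids up in the
#'   canonical registry and auxiliary markers.
#' @return An object of class `cohort_table`: a list with elements
#'   `values`, `mask`, `markers`.
#' @export
cohort_table <- function(values, mask = NULL, markers = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    if (is.data.frame(values)) values <- as.matrix(values)
    if (!is.numeric(values)) stop2("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) stop2("duplicated patient id")
  if (is.null(colnames(values))) stop2("marker columns must be named")
  if (anyDuplicated(colnames(values))) stop2("duplicated marker id")
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  dimnames(mask) <- dimnames(values)
  values[mask] <- NA_real_
  if (any(is.na(values) & !mask)) stop2("NA value in an unmasked cell")
  if (is.null(markers)) {
    km <- known_markers()
    idx <- match(colnames(values), km$id)
    markers <- km[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    markers$id <- colnames(values)
    markers$phenotype[is.na(idx)] <- colnames(values)[is.na(idx)]
    markers$lineage[is.na(idx)] <- "global"
    # unknown columns default to unconstrained concentration-like markers
    markers$measure[is.na(idx)] <- "concentration"
    markers$units[is.na(idx)] <- "ng/mL"
    rownames(markers) <- NULL
  }
  stopifnot(nrow(markers) == ncol(values),
            identical(markers$id, colnames(values)))
  structure(list(values = values, mask = mask, markers = markers),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients x %d markers (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

patient_ids <- function(table) rownames(table$values)
marker_ids <- function(table) colnames(table$values)

# Restrict a cohort table to a subset of marker columns (by id).
subset_markers <- function(table, ids) {
  keep <- match(ids, marker_ids(table))
  if (anyNA(keep)) stop2("unknown marker id: ",
                         paste(ids[is.na(keep)], collapse = ", "))
  cohort_table(table$values[, keep, drop = FALSE],
               table$mask[, keep, drop = FALSE],
               table$markers[keep, , drop = FALSE])
}

.ann_cols <- c("patient_id", "nci_class", "fazekas_pv", "fazekas_deep")
.nci_levels <- c("none", "ANI", "MND", "unknown")

#' Clinical annotations
#'
#' Per-patient clinical annotation: neurocognitive impairment class under
#' the Frascati research criteria (`none`, `ANI` = asymptomatic
#' neurocognitive impairment, `MND` = mild neurocognitive disorder, or
#' `unknown` when neurocognition was not evaluated) and the two Fazekas
#' white-matter-hyperintensity scores (0-3, periventricular and deep), `NA`
#' when no MRI is available.  `nci_flag` is derived: `TRUE` iff the class
#' is ANI or MND, `NA` for unknown.
#'
#' @param patient_id character vector of unique patient ids.
#' @param nci_class character vector in `none`/`ANI`/`MND`/`unknown`.
#' @param fazekas_pv,fazekas_deep integer scores in 0..3 or `NA`.
#' @return A `data.frame` of class `clinical_annotations` with columns
#'   `patient_id`, `nci_class`, `nci_flag`, `fazekas_pv`, `fazekas_deep`.
#' @export
clinical_annotations <- function(patient_id,
                                 nci_class = rep("unknown", length(patient_id)),
                                 fazekas_pv = rep(NA_integer_, length(patient_id)),
                                 fazekas_deep = rep(NA_integer_, length(patient_id))) {
  if (anyDuplicated(patient_id)) stop2("duplicated patient id")
  nci_class <- as.character(nci_class)
  nci_class[is.na(nci_class)] <- "unknown"
  bad <- setdiff(unique(nci_class), .nci_levels)
  if (length(bad)) stop2("invalid nci_class value: ", paste(bad, collapse = ", "))
  chk_faz <- function(x) {
    x <- suppressWarnings(as.integer(x))
    if (any(!is.na(x) & (x < 0L | x > 3L))) stop2("Fazekas scores must be in 0..3")
    x
  }
  ann <- data.frame(patient_id = as.character(patient_id),
                    nci_class = nci_class,
                    nci_flag = ifelse(nci_class == "unknown", NA,
                                      nci_class %in% c("ANI", "MND")),
                    fazekas_pv = chk_faz(fazekas_pv),
                    fazekas_deep = chk_faz(fazekas_deep),
                    stringsAsFactors = FALSE)
  class(ann) <- c("clinical_annotations", "data.frame")
  ann
}

#' Read a cohort file
#'
#' Reads a CSV or TSV cohort file with one row per participant.  The
#' reserved columns `patient_id`, `nci_class`, `fazekas_pv` and
#' `fazekas_deep` are split off into the clinical annotations; every other
#' column is parsed as a numeric marker.  Empty cells and `NA` denote
#' missing values and are recorded in the missingness mask.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"tsv"`; default guessed from the extension.
#' @return A list with elements `table` ([cohort_table()]) and `ann`
#'   ([clinical_annotations()]).
#' @export
load_cohort <- function(path, format = c("guess", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), comment.char = "#")
  if (!"patient_id" %in% names(raw)) {
    raw$patient_id <- sprintf("P%03d", seq_len(nrow(raw)))
  }
  if (anyDuplicated(raw$patient_id)) stop2("duplicate patient id in ", path)
  mk_cols <- setdiff(names(raw), .ann_cols)
  vals <- matrix(NA_real_, nrow(raw), length(mk_cols),
                 dimnames = list(raw$patient_id, mk_cols))
  for (j in seq_along(mk_cols)) {
    txt <- raw[[mk_cols[j]]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad)) {
      stop2(sprintf("non-numeric value '%s' for marker '%s' (patient '%s')",
                    txt[bad[1]], mk_cols[j], raw$patient_id[bad[1]]))
    }
    vals[, j] <- num
  }
  unknown <- setdiff(mk_cols, known_markers()$id)
  if (length(unknown)) {
    warning("unknown marker columns retained: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  ann <- clinical_annotations(
    raw$patient_id,
    nci_class = raw$nci_class %||% rep("unknown", nrow(raw)),
    fazekas_pv = raw$fazekas_pv %||% rep(NA_integer_, nrow(raw)),
    fazekas_deep = raw$fazekas_deep %||% rep(NA_integer_, nrow(raw)))
  list(table = cohort_table(vals), ann = ann)
}

#' Write a cohort file
#'
#' Writes a cohort table and its annotations as CSV (or TSV): patient id
#' column first, then the annotation columns, then the marker columns in
#' table order.  Missing (masked) cells are written as empty fields.
#' Values are formatted with 6 significant digits.
#'
#' @param table a [cohort_table()].
#' @param ann matching [clinical_annotations()] (optional).
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_cohort <- function(table, ann = NULL, path, format = c("guess", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  ids <- patient_ids(table) %||% character(0)
  if (is.null(ann)) ann <- clinical_annotations(ids)
  if (!identical(as.character(ann$patient_id), as.character(ids))) {
    stop2("annotation patient ids do not match the cohort table")
  }
  vals <- table$values
  out <- data.frame(patient_id = ids,
                    nci_class = ann$nci_class,
                    fazekas_pv = ann$fazekas_pv,
                    fazekas_deep = ann$fazekas_deep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(vals))) {
    col <- ifelse(table$mask[, j], "", signif(vals[, j], 6))
    out[[colnames(vals)[j]]] <- col
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop2("cannot write cohort file '", path, "': ",
                         conditionMessage(ok))
  invisible(path)
}
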
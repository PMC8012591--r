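## Delimited-text IO for the three study tables.  Extension decides the
## delimiter: .csv -> comma, anything else (.tsv, .txt) -> tab.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a metabolite abundance matrix
#'
#' Reads a delimited text file (comma for `.csv`, tab otherwise) into a
#' metabolites x samples intensity matrix.  The canonical layout has samples
#' as rows and metabolites as columns; set `samples_as_rows = FALSE` for the
#' transposed layout.  Cells equal to `missing_marker` (empty by default)
#' become `NA`, the below-detection marker.
#'
#' @param path file to read.
#' @param missing_marker string marking a below-detection cell.
#' @param samples_as_rows `TRUE` if file rows are samples (canonical).
#' @return A [MetabExperiment-class] on the `raw` scale with empty metadata
#'   and annotation; the number of missing cells is reported via `message()`.
#' @export
readMetaboliteMatrix <- function(path, missing_marker = "",
                                 samples_as_rows = TRUE) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   row.names = NULL, check.names = FALSE,
                   na.strings = missing_marker, colClasses = NA,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated %s id(s) in '%s': %s",
                 if (samples_as_rows) "sample" else "metabolite",
                 path, paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (samples_as_rows) m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicated metabolite id(s) in '%s': %s", path,
                 paste(unique(rownames(m)[duplicated(rownames(m))]),
                       collapse = ", ")), call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative raw intensity at metabolite '%s', sample '%s'",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  message(sum(is.na(m)), " missing cell(s) in ", basename(path))
  MetabExperiment(m)
}

.check_levels <- function(x, field, levels) {
  bad <- setdiff(unique(as.character(x)), c(levels, NA))
  if (length(bad))
    stop(sprintf("unknown %s label(s) %s; allowed values: %s", field,
                 paste(sQuote(bad), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read a sample-metadata table
#'
#' Expects at least a `sample_id` column; recognised categorical fields
#' (`group`, `cohort`, `timepoint`, `site`) are validated against their
#' controlled vocabularies.  Any further columns (covariates such as `age`,
#' `sex`, `bmi`, `creatinine`, `bilirubin`, drug-class indicator columns
#' prefixed `drug_`, and clinical variables such as `mRAP`, `mPAP`, `PVR`,
#' `cardiac_output`, `walk_6m`) pass through unchanged.
#'
#' @param path file to read.
#' @return A [S4Vectors::DataFrame-class] keyed by `sample_id`.
#' @export
readSampleMetadata <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicated sample id(s): %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")), call. = FALSE)
  .check_levels(df$group, "group", .GROUP_LEVELS)
  .check_levels(df$cohort, "cohort", .COHORT_LEVELS)
  .check_levels(df$timepoint, "timepoint", .TIMEPOINT_LEVELS)
  .check_levels(df$site, "site", .SITE_LEVELS)
  out <- S4Vectors::DataFrame(df, check.names = FALSE)
  rownames(out) <- df$sample_id
  out
}

#' Read a metabolite annotation table
#'
#' Expects columns `metabolite_id`, `subpathway`, `superpathway` and logical
#' `identity_confirmed` and `xenobiotic` flags.
#'
#' @param path file to read.
#' @return A [S4Vectors::DataFrame-class] keyed by `metabolite_id`.
#' @export
readMetaboliteAnnotation <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = .delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "subpathway", "superpathway")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$metabolite_id))
    stop(sprintf("duplicated metabolite id(s): %s",
                 paste(unique(df$metabolite_id[duplicated(df$metabolite_id)]),
                       collapse = ", ")), call. = FALSE)
  for (fld in c("identity_confirmed", "xenobiotic"))
    if (fld %in% colnames(df)) df[[fld]] <- as.logical(df[[fld]])
  out <- S4Vectors::DataFrame(df, check.names = FALSE)
  rownames(out) <- df$metabolite_id
  out
}

#' Assemble a study from its three tables
#'
#' Binds a raw intensity matrix to sample metadata and metabolite annotation.
#' Samples and metabolites are matched by id; metabolites without an
#' annotation row are reported via `message()` and kept with `NA` annotation.
#'
#' @param matrix_path,metadata_path,annotation_path paths to the three
#'   delimited tables ([readMetaboliteMatrix()], [readSampleMetadata()],
#'   [readMetaboliteAnnotation()]).
#' @param missing_marker,samples_as_rows passed to [readMetaboliteMatrix()].
#' @return A [MetabExperiment-class] on the `raw` scale.
#' @export
readStudy <- function(matrix_path, metadata_path, annotation_path,
                      missing_marker = "", samples_as_rows = TRUE) {
  me <- readMetaboliteMatrix(matrix_path, missing_marker, samples_as_rows)
  md <- readSampleMetadata(metadata_path)
  an <- readMetaboliteAnnotation(annotation_path)
  missing_samples <- setdiff(colnames(me), rownames(md))
  if (length(missing_samples))
    stop("samples absent from metadata: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  unannotated <- setdiff(rownames(me), rownames(an))
  if (length(unannotated))
    message(length(unannotated), " metabolite(s) without annotation: ",
            paste(head(unannotated, 5L), collapse = ", "),
            if (length(unannotated) > 5L) ", ...")
  an_full <- an[match(rownames(me), rownames(an)), , drop = FALSE]
  rownames(an_full) <- rownames(me)
  an_full$metabolite_id <- rownames(me)
  MetabExperiment(intensity(me), colData = md[colnames(me), , drop = FALSE],
                  rowData = an_full)
}

#' Write a table or study component to delimited text
#'
#' Writes a data.frame/DataFrame as CSV (`.csv`) or TSV (otherwise), without
#' row names and with `NA` rendered as the empty string so a round-trip
#' through [readSampleMetadata()] / [readMetaboliteAnnotation()] restores an
#' equal table.
#'
#' @param x data.frame or DataFrame.
#' @param path destination file.
#' @return `invisible(path)`
#' @export
writeTable <- function(x, path) {
  if (is(x, "DataFrame")) x <- as.data.frame(x)
  write.table(x, path, sep = .delim_for(path), row.names = FALSE,
              col.names = TRUE, quote = TRUE, na = "")
  invisible(path)
}

#' Write the intensity matrix of a study
#'
#' Canonical layout: samples as rows, metabolites as columns, first column
#' `sample_id`.  `NA` cells are written as `missing_marker`.
#'
#' @param x a [MetabExperiment-class].
#' @param path destination file.
#' @param missing_marker string to write for below-detection cells.
#' @return `invisible(path)`
#' @export
writeMatrix <- function(x, path, missing_marker = "") {
  m <- t(intensity(x))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = .delim_for(path), row.names = FALSE,
              col.names = TRUE, quote = TRUE, na = missing_marker)
  invisible(path)
}
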
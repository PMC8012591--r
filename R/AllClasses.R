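#' @import methods
#' @importFrom stats median qnorm pnorm pt quantile rnorm runif rgamma sd var
#'   complete.cases lm.fit p.adjust fisher.test cor cor.test setNames
#'   dhyper ave rlnorm
#' @importFrom utils read.delim write.table packageVersion combn head
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom igraph graph_from_data_frame components
#' @importFrom jsonlite write_json
NULL

## ---- controlled vocabularies ------------------------------------------------

.SCALE_LEVELS <- c("raw", "imputed", "boxcox", "zscore", "quantile_normalised")
.GROUP_LEVELS <- c("HC", "DC", "CTED", "IPAH_HPAH", "CTEPH")
.COHORT_LEVELS <- c("discovery", "replication", "gradient", "none")
.TIMEPOINT_LEVELS <- c("pre_PEA", "post_PEA", "none")
.SITE_LEVELS <- c("SVC", "PA", "ART", "none")
.TIER_LEVELS <- c("vs_all_including_IPAH", "vs_HC_DC_CTED", "vs_HC_DC",
                  "vs_HC_only", "none")
.SITE_PAIRS <- c("SVC_PA", "PA_ART", "ART_SVC")

#' Container for a metabolomics study
#'
#' `MetabExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with metabolites as rows
#' and samples as columns.  The single assay `"intensity"` holds raw or
#' transformed abundances with `NA` marking values below the limit of
#' detection.  Sample metadata (group, cohort, batch, timepoint, anatomical
#' site, covariates, clinical haemodynamics) lives in `colData`; metabolite
#' annotation (subpathway, superpathway, identity-confidence and xenobiotic
#' flags) in `rowData`.  The provenance of the values is tracked by a scale
#' tag (one of `r paste(.SCALE_LEVELS, collapse = ", ")`) that preprocessing
#' operations advance strictly forwards.
#'
#' @slot scale_tag character(1), the current scale of the assay values.
#'
#' @seealso [MetabExperiment()] for construction, [scaleTag()],
#'   [imputeMinDetected()], [detectionFilter()], [applyBoxCox()],
#'   [zscoreToReference()], [quantileNormalise()]
#' @export
setClass("MetabExperiment",
  contains = "SummarizedExperiment",
  slots = c(scale_tag = "character")
)

setValidity("MetabExperiment", function(object) {
  msg <- character()
  if (length(object@scale_tag) != 1L || !object@scale_tag %in% .SCALE_LEVELS)
    msg <- c(msg, sprintf("scale_tag must be one of: %s",
                          paste(.SCALE_LEVELS, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicated sample id(s): %s",
      paste(unique(colnames(object)[duplicated(colnames(object))]),
            collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated metabolite id(s): %s",
      paste(unique(rownames(object)[duplicated(rownames(object))]),
            collapse = ", ")))
  a <- SummarizedExperiment::assay(object, "intensity")
  if (identical(object@scale_tag, "raw") && any(a < 0, na.rm = TRUE)) {
    bad <- which(a < 0, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "negative raw intensity at metabolite '%s', sample '%s'",
      rownames(a)[bad[1L]], colnames(a)[bad[2L]]))
  }
  cd <- SummarizedExperiment::colData(object)
  for (fld in c(group = "group", cohort = "cohort",
                timepoint = "timepoint", site = "site")) {
    if (fld %in% colnames(cd)) {
      lev <- switch(fld, group = .GROUP_LEVELS, cohort = .COHORT_LEVELS,
                    timepoint = .TIMEPOINT_LEVELS, site = .SITE_LEVELS)
      bad <- setdiff(unique(as.character(cd[[fld]])), c(lev, NA))
      if (length(bad))
        msg <- c(msg, sprintf("unknown %s label(s) %s; allowed: %s", fld,
                              paste(sQuote(bad), collapse = ", "),
                              paste(lev, collapse = ", ")))
    }
  }
  ## one sample per (subject, timepoint) and (subject, site)
  if (all(c("subject_id", "timepoint") %in% colnames(cd))) {
    key <- paste(cd$subject_id, cd$timepoint, cd$site %||% "none")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (subject_id, timepoint, site) combination")
  }
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a MetabExperiment
#'
#' @param intensity numeric matrix, metabolites x samples; `NA` marks values
#'   below the limit of detection.
#' @param colData `DataFrame`/data.frame of per-sample metadata (see
#'   [readSampleMetadata()] for the expected fields).
#' @param rowData `DataFrame`/data.frame of metabolite annotation.
#' @param scale_tag scale of `intensity`; new objects are normally `"raw"`.
#' @return A [MetabExperiment-class] object.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(paste0("met", 1:3), paste0("s", 1:4)))
#' me <- MetabExperiment(m)
#' scaleTag(me)
#' @export
MetabExperiment <- function(intensity, colData = NULL, rowData = NULL,
                            scale_tag = "raw") {
  if (!is.matrix(intensity)) intensity <- as.matrix(intensity)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(intensity))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = colData,
    rowData = rowData %||% S4Vectors::DataFrame(row.names = rownames(intensity)))
  new("MetabExperiment", se, scale_tag = scale_tag)
}

#' Planted ground truth of a synthetic study
#'
#' Records everything the synthetic-cohort generator planted so recovery and
#' calibration tests can compare estimates against truth: per-comparison
#' affected metabolites with effect sizes (in sd units on the log scale),
#' confounder effect sizes, per-batch offsets, per-metabolite post-surgery
#' correction fractions, per-site-pair gradient offsets, the pathway
#' assignment, and the seed.
#'
#' @slot affected data.frame with columns `metabolite`, `comparison`,
#'   `effect` (sd units).
#' @slot confounder_effects data.frame with columns `metabolite`,
#'   `covariate`, `effect`.
#' @slot batch_offsets data.frame with columns `metabolite`, `batch`,
#'   `offset`.
#' @slot correction_fractions named numeric in `[0, 1]`, fraction of the
#'   case-vs-healthy perturbation removed after surgery.
#' @slot site_gradients data.frame with columns `metabolite`, `site_pair`,
#'   `offset` (z-units, downstream minus upstream).
#' @slot pathway_assignments data.frame mapping metabolites to sub- and
#'   superpathways.
#' @slot seed integer seed the study was generated under.
#' @export
setClass("TruthLedger", slots = c(
  affected = "data.frame",
  confounder_effects = "data.frame",
  batch_offsets = "data.frame",
  correction_fractions = "numeric",
  site_gradients = "data.frame",
  pathway_assignments = "data.frame",
  seed = "integer"
))

setValidity("TruthLedger", function(object) {
  msg <- character()
  cf <- object@correction_fractions
  if (length(cf) && (any(!is.finite(cf)) || any(cf < 0 | cf > 1)))
    msg <- c(msg, "correction_fractions must lie in [0, 1]")
  if (nrow(object@affected) && any(!is.finite(object@affected$effect)))
    msg <- c(msg, "planted effect sizes must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname TruthLedger-class
#' @param affected,confounder_effects,batch_offsets,correction_fractions,site_gradients,pathway_assignments,seed slot values (see slots above); all default to empty.
#' @export
TruthLedger <- function(affected = .empty_affected(),
                        confounder_effects = .empty_confounders(),
                        batch_offsets = .empty_batch(),
                        correction_fractions = numeric(),
                        site_gradients = .empty_gradients(),
                        pathway_assignments = data.frame(),
                        seed = NA_integer_) {
  new("TruthLedger", affected = affected,
      confounder_effects = confounder_effects, batch_offsets = batch_offsets,
      correction_fractions = correction_fractions,
      site_gradients = site_gradients,
      pathway_assignments = pathway_assignments, seed = as.integer(seed))
}

.empty_affected <- function()
  data.frame(metabolite = character(), comparison = character(),
             effect = numeric())
.empty_confounders <- function()
  data.frame(metabolite = character(), covariate = character(),
             effect = numeric())
.empty_batch <- function()
  data.frame(metabolite = character(), batch = character(),
             offset = numeric())
.empty_gradients <- function()
  data.frame(metabolite = character(), site_pair = character(),
             offset = numeric())

#' @describeIn TruthLedger-class compact display
#' @param object a `TruthLedger`
#' @export
setMethod("show", "TruthLedger", function(object) {
  cat("TruthLedger (seed ", object@seed, ")\n", sep = "")
  cat("  planted effects      :", nrow(object@affected), "\n")
  cat("  confounder effects   :", nrow(object@confounder_effects), "\n")
  cat("  correction fractions :", length(object@correction_fractions), "\n")
  cat("  site gradients       :", nrow(object@site_gradients), "\n")
})

#' @describeIn MetabExperiment-class compact display
#' @param object a `MetabExperiment`
#' @export
setMethod("show", "MetabExperiment", function(object) {
  cat("MetabExperiment:", nrow(object), "metabolites x", ncol(object),
      "samples [scale:", object@scale_tag, "]\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "intensity")))
  cat("  missing cells:", nmiss, "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("group" %in% colnames(cd))
    cat("  groups:", paste(names(table(cd$group)), table(cd$group),
                           sep = "=", collapse = ", "), "\n")
})
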
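#' Scale tag of a MetabExperiment
#'
#' The scale tag records where the assay values stand in the preprocessing
#' chain: `raw` intensities, `imputed` (missing cells filled with the minimum
#' detected level), `boxcox` (per-metabolite power transform), `zscore`
#' (standardised to healthy controls) and `quantile_normalised`.  Operations
#' only move the tag forwards along this chain.
#'
#' @param x a [MetabExperiment-class]
#' @return character(1)
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname scaleTag
#' @export
setMethod("scaleTag", "MetabExperiment", function(x) x@scale_tag)

#' Intensity matrix of a MetabExperiment
#'
#' @param x a [MetabExperiment-class]
#' @return numeric matrix, metabolites x samples
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname intensity
#' @export
setMethod("intensity", "MetabExperiment",
          function(x) SummarizedExperiment::assay(x, "intensity"))

## internal: advance the provenance chain, refusing backwards moves
.advance_scale <- function(x, to) {
  from <- x@scale_tag
  if (match(to, .SCALE_LEVELS) <= match(from, .SCALE_LEVELS))
    stop(sprintf("cannot move scale backwards or in place: %s -> %s",
                 from, to), call. = FALSE)
  x@scale_tag <- to
  x
}

.require_scale <- function(x, allowed, op) {
  if (!x@scale_tag %in% allowed)
    stop(sprintf("%s expects scale %s, got '%s'", op,
                 paste(sQuote(allowed), collapse = " or "), x@scale_tag),
         call. = FALSE)
  invisible(TRUE)
}

#' Detection mask of a MetabExperiment
#'
#' Logical matrix marking which cells were measured above the limit of
#' detection in the raw data.  Before imputation this is simply
#' `!is.na(intensity(x))`; [imputeMinDetected()] stores the mask so that the
#' detection filter can still be applied afterwards.
#'
#' @param x a [MetabExperiment-class]
#' @return logical matrix, metabolites x samples
#' @export
setGeneric("detectionMask", function(x) standardGeneric("detectionMask"))

#' @rdname detectionMask
#' @export
setMethod("detectionMask", "MetabExperiment", function(x) {
  if ("detected" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "detected")
  else
    !is.na(SummarizedExperiment::assay(x, "intensity"))
})

#' Healthy-control reference statistics
#'
#' Per-metabolite healthy-control mean and standard deviation (on the
#' Box-Cox scale) stored by [zscoreToReference()].
#'
#' @param x a [MetabExperiment-class]
#' @return data.frame with columns `metabolite`, `mean_hc`, `sd_hc`, or
#'   `NULL` if the object has not been z-scored.
#' @export
setGeneric("referenceStats", function(x) standardGeneric("referenceStats"))

#' @rdname referenceStats
#' @export
setMethod("referenceStats", "MetabExperiment",
          function(x) S4Vectors::metadata(x)$reference_stats)

#' Processing log of a MetabExperiment
#'
#' Character vector of messages recorded by preprocessing operations
#' (exclusions, dropped metabolites, complete-case counts).
#'
#' @param x a [MetabExperiment-class]
#' @return character vector
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' @rdname processingLog
#' @export
setMethod("processingLog", "MetabExperiment",
          function(x) S4Vectors::metadata(x)$log %||% character())

.log_step <- function(x, msg) {
  S4Vectors::metadata(x)$log <- c(processingLog(x), msg)
  x
}
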
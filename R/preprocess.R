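## Preprocessing chain: impute -> detection filter -> Box-Cox -> z-score to
## healthy controls -> quantile normalisation.  Each step advances the scale
## tag and refuses to run out of order.

#' Impute below-detection cells with the minimum detected level
#'
#' Every missing cell of a metabolite is replaced by the minimum detected
#' intensity of that metabolite, the standard treatment for left-censored
#' limit-of-detection missingness.  Metabolites with no detected value at all
#' cannot be imputed and are dropped with a warning.  The pre-imputation
#' detection mask is stored so that [detectionFilter()] still sees it.
#'
#' @param x a [MetabExperiment-class] on the `raw` scale.
#' @return The imputed object (`scale_tag = "imputed"`).
#' @export
imputeMinDetected <- function(x) {
  .require_scale(x, "raw", "imputeMinDetected")
  m <- intensity(x)
  mask <- !is.na(m)
  all_missing <- rowSums(mask) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " metabolite(s) with no detected value dropped: ",
            paste(head(rownames(m)[all_missing], 5L), collapse = ", "),
            call. = FALSE)
    x <- x[!all_missing, ]
    x <- .log_step(x, paste0("imputeMinDetected: dropped ",
                             sum(all_missing), " all-missing metabolite(s)"))
    m <- intensity(x); mask <- !is.na(m)
  }
  mins <- apply(m, 1L, min, na.rm = TRUE)
  idx <- which(!mask, arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mins[idx[, 1L]]
  SummarizedExperiment::assay(x, "intensity") <- m
  SummarizedExperiment::assay(x, "detected") <- mask
  .advance_scale(x, "imputed")
}

#' Filter metabolites by detection rate and xenobiotic status
#'
#' Keeps metabolites that are non-xenobiotic and were detected (above the
#' limit of detection, judged on the pre-imputation mask) in at least
#' `threshold` of samples; the boundary is inclusive, so a metabolite
#' detected in exactly 95% of samples is retained.
#'
#' @param x a [MetabExperiment-class] on the `raw` or `imputed` scale with a
#'   logical `xenobiotic` column in `rowData` (metabolites with `NA` there
#'   are treated as non-xenobiotic).
#' @param threshold minimum detection fraction, in (0, 1].
#' @return The filtered object; the scale tag is unchanged.
#' @export
detectionFilter <- function(x, threshold = 0.95) {
  .require_scale(x, c("raw", "imputed"), "detectionFilter")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  mask <- detectionMask(x)
  det_frac <- rowMeans(mask)
  xeno <- SummarizedExperiment::rowData(x)$xenobiotic
  if (is.null(xeno)) xeno <- rep(FALSE, nrow(x))
  xeno[is.na(xeno)] <- FALSE
  keep <- !xeno & det_frac >= threshold
  x2 <- x[keep, ]
  .log_step(x2, sprintf(
    "detectionFilter: kept %d/%d (removed %d xenobiotic, %d below %.0f%% detection)",
    sum(keep), length(keep), sum(xeno), sum(!xeno & det_frac < threshold),
    100 * threshold))
}

.boxcox_transform <- function(v, lambda, shift) {
  v <- v + shift
  if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
}

#' Fit per-metabolite Box-Cox parameters
#'
#' Chooses, for every metabolite, the power `lambda` maximising the Box-Cox
#' profile log-likelihood over a grid, with a shift `c` added beforehand
#' when non-positive values are present (`c = 1e-6 + |min|`).  The profile
#' log-likelihood for a transformed vector `y` is
#' `-n/2 * log(var_n(y)) + (lambda - 1) * sum(log(x + c))`.
#'
#' @param x a [MetabExperiment-class] on the `imputed` scale.
#' @param lambda_grid candidate powers (default -2 to 2 in steps of 0.1).
#' @return data.frame with columns `metabolite`, `lambda`, `shift`.
#' @export
fitBoxCox <- function(x, lambda_grid = seq(-2, 2, by = 0.1)) {
  .require_scale(x, "imputed", "fitBoxCox")
  m <- intensity(x)
  res <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    shift <- if (min(v) <= 0) 1e-6 + abs(min(v)) else 0
    lx <- sum(log(v + shift))
    n <- length(v)
    ll <- vapply(lambda_grid, function(l) {
      y <- .boxcox_transform(v, l, shift)
      s2 <- mean((y - mean(y))^2)
      if (s2 <= 0) return(-Inf)
      -n / 2 * log(s2) + (l - 1) * lx
    }, numeric(1))
    c(lambda = lambda_grid[which.max(ll)], shift = shift)
  })
  res <- do.call(rbind, res)
  data.frame(metabolite = rownames(m), lambda = res[, "lambda"],
             shift = res[, "shift"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Apply a Box-Cox transform
#'
#' @param x a [MetabExperiment-class] on the `imputed` scale.
#' @param params data.frame from [fitBoxCox()] (fitted from `x` when `NULL`).
#' @return The transformed object (`scale_tag = "boxcox"`); the parameters
#'   are stored in `metadata(x)$boxcox_params`.
#' @export
applyBoxCox <- function(x, params = NULL) {
  .require_scale(x, "imputed", "applyBoxCox")
  if (is.null(params)) params <- fitBoxCox(x)
  stopifnot(all(rownames(x) %in% params$metabolite))
  params <- params[match(rownames(x), params$metabolite), ]
  m <- intensity(x)
  for (i in seq_len(nrow(m))) {
    if (any(m[i, ] + params$shift[i] <= 0))
      stop(sprintf("non-positive value after shift for metabolite '%s'",
                   rownames(m)[i]), call. = FALSE)
    m[i, ] <- .boxcox_transform(m[i, ], params$lambda[i], params$shift[i])
  }
  SummarizedExperiment::assay(x, "intensity") <- m
  S4Vectors::metadata(x)$boxcox_params <- params
  .advance_scale(x, "boxcox")
}

#' Standardise to the healthy-control reference
#'
#' Transforms every metabolite to `z = (y - mean_HC) / sd_HC` so that values
#' read as sd-deviations from health; within the reference samples each
#' metabolite then has mean 0 and sd 1 exactly.  Metabolites whose reference
#' sd is zero cannot be standardised and are dropped with a warning.
#'
#' @param x a [MetabExperiment-class] on the `boxcox` scale (accepted from
#'   `imputed` too, for pipelines that skip the power transform).
#' @param reference sample ids of the healthy-control reference; defaults to
#'   samples with `group == "HC"`.
#' @return The standardised object (`scale_tag = "zscore"`), with
#'   [referenceStats()] recording the per-metabolite reference mean and sd.
#' @export
zscoreToReference <- function(x, reference = NULL) {
  .require_scale(x, c("imputed", "boxcox"), "zscoreToReference")
  if (is.null(reference)) {
    cd <- SummarizedExperiment::colData(x)
    if (!"group" %in% colnames(cd))
      stop("no 'group' metadata; supply reference sample ids", call. = FALSE)
    reference <- colnames(x)[cd$group == "HC"]
  }
  if (!length(reference) || !all(reference %in% colnames(x)))
    stop("reference samples missing from the experiment", call. = FALSE)
  m <- intensity(x)
  ref <- m[, reference, drop = FALSE]
  mu <- rowMeans(ref)
  sdv <- apply(ref, 1L, sd)
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad)) {
    warning(sum(bad), " metabolite(s) with zero reference sd dropped",
            call. = FALSE)
    x <- x[!bad, ]
    x <- .log_step(x, paste0("zscoreToReference: dropped ", sum(bad),
                             " zero-reference-sd metabolite(s)"))
    m <- m[!bad, , drop = FALSE]; mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  m <- (m - mu) / sdv
  SummarizedExperiment::assay(x, "intensity") <- m
  S4Vectors::metadata(x)$reference_stats <- data.frame(
    metabolite = rownames(m), mean_hc = mu, sd_hc = sdv, row.names = NULL,
    stringsAsFactors = FALSE)
  .advance_scale(x, "zscore")
}

#' Quantile-normalise samples to a common distribution
#'
#' Replaces each sample's values rank-wise by the mean order statistics
#' across all samples, so every sample ends with the identical sorted value
#' vector (the average distribution).  Tied values within a sample receive
#' the mean of the reference values their ranks span, which preserves sample
#' means under ties.  Used to remove between-batch distributional shifts.
#'
#' @param x a complete (post-imputation) [MetabExperiment-class]; any scale
#'   from `imputed` onwards is accepted.
#' @return The normalised object (`scale_tag = "quantile_normalised"`).
#' @export
quantileNormalise <- function(x) {
  .require_scale(x, c("imputed", "boxcox", "zscore"), "quantileNormalise")
  m <- intensity(x)
  if (anyNA(m)) stop("quantile normalisation needs a complete matrix",
                     call. = FALSE)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(v) {
    pos <- rank(v, ties.method = "first")
    ave(ref[pos], match(v, v))            # mean of spanned reference values
  })
  dimnames(out) <- dimnames(m)
  SummarizedExperiment::assay(x, "intensity") <- out
  .advance_scale(x, "quantile_normalised")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper executing minimum-detected imputation, the
#' non-xenobiotic >= 95% detection filter, per-metabolite Box-Cox,
#' z-scoring to healthy controls and (optionally) quantile normalisation, in
#' that order.  Quantile normalisation defaults to last; set
#' `qn_position = "before_zscore"` to normalise on the Box-Cox scale
#' instead.
#'
#' @param x a [MetabExperiment-class] on the `raw` scale.
#' @param detection_threshold passed to [detectionFilter()].
#' @param qn run quantile normalisation.
#' @param qn_position `"last"` or `"before_zscore"`.
#' @param reference passed to [zscoreToReference()].
#' @return The fully processed object.
#' @export
preprocess <- function(x, detection_threshold = 0.95, qn = TRUE,
                       qn_position = c("last", "before_zscore"),
                       reference = NULL) {
  qn_position <- match.arg(qn_position)
  x <- imputeMinDetected(x)
  x <- detectionFilter(x, detection_threshold)
  x <- applyBoxCox(x)
  if (qn && qn_position == "before_zscore") {
    ## normalise on the boxcox scale, then standardise; the scale tag ends at
    ## zscore conceptually but the chain is linear, so we standardise the
    ## normalised values directly
    m <- intensity(quantileNormalise(x))
    SummarizedExperiment::assay(x, "intensity") <- m
    x <- zscoreToReference(x, reference)
  } else {
    x <- zscoreToReference(x, reference)
    if (qn) x <- quantileNormalise(x)
  }
  x
}
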
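## Single-marker ROC evaluation: empirical curve, trapezoidal AUC (equal to
## the Mann-Whitney probability of superiority), Youden best cut-off, and
## DeLong confidence intervals.

#' Empirical ROC curve
#'
#' One point per distinct threshold of the marker, with endpoints (0, 0) and
#' (1, 1); a sample is called a case when its (oriented) marker value
#' exceeds the threshold.  If the raw AUC is below 0.5 the marker is negated
#' so the curve always sits on or above the diagonal, and the flip is
#' recorded.
#'
#' @param cases,controls marker values for the two classes.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`; the
#'   thresholds are on the oriented marker scale, endpoints `Inf`/`-Inf`),
#'   `auc` (trapezoidal) and `flipped`.
#' @export
rocCurve <- function(cases, controls) {
  cases <- cases[!is.na(cases)]; controls <- controls[!is.na(controls)]
  stopifnot(length(cases) >= 1L, length(controls) >= 1L)
  flip <- mannWhitney(cases, controls, exact_limit = 0L)$auc < 0.5
  if (flip) { cases <- -cases; controls <- -controls }
  thr <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc, flipped = flip)
}

#' Best cut-off by Youden's J
#'
#' Scans every threshold of an ROC curve and returns the one maximising
#' `J = sensitivity + specificity - 1`; ties are broken toward higher
#' sensitivity.
#'
#' @param curve result of [rocCurve()].
#' @return list with `threshold` (oriented marker scale), `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
bestCutoff <- function(curve) {
  pts <- curve$points
  j <- pts$tpr - pts$fpr
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(pts$tpr[best])]
  list(threshold = pts$threshold[best], sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best], youden_j = j[best])
}

#' AUC confidence interval and p-value
#'
#' DeLong placement-variance 95% confidence interval for the AUC (truncated
#' to [0, 1]) and a p-value against AUC = 0.5 from the tie-corrected normal
#' approximation of the Mann-Whitney U statistic (so it equals the
#' [mannWhitney()] p-value on the same data when that test uses the normal
#' path).
#'
#' @param cases,controls marker values for the two classes (original
#'   orientation; the AUC reported follows it).
#' @param conf_level confidence level.
#' @return list with `auc`, `ci` (length 2), `se`, `p`.
#' @export
aucInference <- function(cases, controls, conf_level = 0.95) {
  cases <- cases[!is.na(cases)]; controls <- controls[!is.na(controls)]
  n1 <- length(cases); n0 <- length(controls)
  stopifnot(n1 >= 2L, n0 >= 2L)
  ## DeLong placements
  v10 <- vapply(cases, function(a)
    (sum(a > controls) + 0.5 * sum(a == controls)) / n0, numeric(1))
  v01 <- vapply(controls, function(b)
    (sum(cases > b) + 0.5 * sum(cases == b)) / n1, numeric(1))
  auc <- mean(v10)
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  p <- mannWhitney(cases, controls, exact_limit = 0L)$p
  list(auc = auc, ci = ci, se = se, p = p)
}

#' ROC records for a set of markers
#'
#' Builds one [rocCurve()] + [bestCutoff()] + [aucInference()] record per
#' metabolite for a case/control contrast.
#'
#' @param x a z-scored [MetabExperiment-class].
#' @param metabolites metabolite ids to evaluate.
#' @param case_group,control_group group labels.
#' @param cohort optional cohort restriction (`NULL` pools cohorts).
#' @return data.frame: metabolite, comparison, `auc` (oriented so >= 0.5),
#'   `flipped`, `ci_lo`, `ci_hi`, `p`, `cutoff` (z-units, oriented scale),
#'   `sensitivity`, `specificity`.
#' @export
rocTable <- function(x, metabolites = rownames(x), case_group = "CTEPH",
                     control_group = "HC", cohort = NULL) {
  m <- intensity(x)
  cases <- .group_samples(x, case_group, cohort)
  ctrls <- .group_samples(x, control_group, cohort)
  rows <- lapply(metabolites, function(mm) {
    a <- m[mm, cases]; b <- m[mm, ctrls]
    cv <- rocCurve(a, b)
    bc <- bestCutoff(cv)
    inf <- aucInference(if (cv$flipped) -a else a,
                        if (cv$flipped) -b else b)
    data.frame(metabolite = mm,
               comparison = paste0(case_group, "_vs_", control_group),
               auc = cv$auc, flipped = cv$flipped,
               ci_lo = inf$ci[1], ci_hi = inf$ci[2], p = inf$p,
               cutoff = bc$threshold, sensitivity = bc$sensitivity,
               specificity = bc$specificity, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
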
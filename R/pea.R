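## Response to pulmonary endarterectomy: unpaired pre-vs-post screen,
## paired validation, percent correction of the perturbation from
## healthy-control levels, and direction-consistency flagging.

#' Percent correction of the perturbation from healthy-control levels
#'
#' On the healthy-control-referenced z scale (HC centre at 0 by
#' construction), the fraction of the pre-surgery perturbation removed after
#' surgery: `100 * (median(pre) - median(post)) / median(pre)`.  100 means
#' full return to healthy-control level, 0 no change; values outside
#' [-100, 200] are clamped for reporting with the raw value kept.  The
#' statistic is undefined (flagged) when the baseline perturbation is
#' negligible (|median(pre)| < 0.1 z-units).
#'
#' @param pre_z,post_z z-scored values for the pre- and post-surgery
#'   samples (not necessarily paired).
#' @return list with `percent` (clamped), `percent_raw`, `defined`,
#'   `median_pre`, `median_post`.
#' @export
percentCorrection <- function(pre_z, post_z) {
  pre_z <- pre_z[!is.na(pre_z)]; post_z <- post_z[!is.na(post_z)]
  if (!length(pre_z) || !length(post_z))
    stop("percentCorrection needs non-empty pre and post values",
         call. = FALSE)
  mp <- median(pre_z); mq <- median(post_z)
  defined <- abs(mp) >= 0.1
  raw <- if (defined) 100 * (mp - mq) / mp else NA_real_
  list(percent = if (defined) min(200, max(-100, raw)) else NA_real_,
       percent_raw = raw, defined = defined,
       median_pre = mp, median_post = mq)
}

#' Two-stage screen for metabolite response to surgery
#'
#' Stage 1 contrasts independent pre-surgery and post-surgery patient groups
#' (subjects sampled at one timepoint only) with unpaired Mann-Whitney tests
#' under Bonferroni control over the tested metabolites.  Stage 2 validates
#' the stage-1 hits on subjects sampled at both timepoints with the paired
#' Wilcoxon signed-rank test, reporting the nominal (p < 0.05) flag and a
#' Benjamini-Hochberg FDR < `fdr` flag over the stage-1 hits.  Hits whose
#' unpaired and paired directions of change disagree are flagged as probable
#' false positives.  Percent correction is computed from the paired samples.
#'
#' @param x a z-scored [MetabExperiment-class] whose `colData` carries
#'   `subject_id` and `timepoint` (`pre_PEA` / `post_PEA`).
#' @param alpha stage-1 family-wise error rate (Bonferroni) and stage-2
#'   nominal level.
#' @param fdr stage-2 false-discovery-rate level.
#' @return data.frame (one row per stage-1 hit): unpaired and paired
#'   p-values, significance flags, directions of change (`up`/`down`, sign
#'   of the post-minus-pre shift), `consistent`, and percent correction.
#'   The full stage-1 scan is attached as attribute `"stage1"`.
#' @export
peaScreen <- function(x, alpha = 0.05, fdr = 0.05) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("subject_id", "timepoint") %in% colnames(cd)))
    stop("colData must contain 'subject_id' and 'timepoint'", call. = FALSE)
  m <- intensity(x)
  is_pre <- cd$timepoint == "pre_PEA"
  is_post <- cd$timepoint == "post_PEA"
  subj_pre <- cd$subject_id[is_pre]
  subj_post <- cd$subject_id[is_post]
  paired_subj <- intersect(subj_pre, subj_post)
  unpaired_pre <- colnames(x)[is_pre & !cd$subject_id %in% paired_subj]
  unpaired_post <- colnames(x)[is_post & !cd$subject_id %in% paired_subj]
  if (!length(unpaired_pre) || !length(unpaired_post))
    stop("no unpaired pre/post samples for the stage-1 screen",
         call. = FALSE)
  if (!length(paired_subj))
    stop("no paired subjects for the stage-2 validation", call. = FALSE)
  pre_id <- colnames(x)[is_pre][match(paired_subj, subj_pre)]
  post_id <- colnames(x)[is_post][match(paired_subj, subj_post)]
  mets <- rownames(m)
  thr <- bonferroniThreshold(alpha, length(mets))
  stage1 <- t(vapply(mets, function(mm) {
    mw <- mannWhitney(m[mm, unpaired_post], m[mm, unpaired_pre])
    c(p = mw$p,
      shift = median(m[mm, unpaired_post]) - median(m[mm, unpaired_pre]))
  }, numeric(2)))
  stage1_df <- data.frame(metabolite = mets, p_unpaired = stage1[, "p"],
                          shift_unpaired = stage1[, "shift"],
                          significant_unpaired = stage1[, "p"] < thr,
                          row.names = NULL, stringsAsFactors = FALSE)
  hits <- stage1_df$metabolite[stage1_df$significant_unpaired]
  if (!length(hits)) {
    out <- data.frame(metabolite = character(), p_unpaired = numeric(),
                      p_paired = numeric(), p_paired_adj = numeric(),
                      significant_nominal = logical(),
                      significant_fdr = logical(),
                      direction_unpaired = character(),
                      direction_paired = character(),
                      consistent = logical(), percent_correction = numeric(),
                      percent_correction_raw = numeric(),
                      correction_defined = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "stage1") <- stage1_df
    return(out)
  }
  rows <- lapply(hits, function(mm) {
    pre <- m[mm, pre_id]; post <- m[mm, post_id]
    w <- wilcoxonSignedRank(pre, post)
    pc <- percentCorrection(pre, post)
    s1 <- stage1_df[stage1_df$metabolite == mm, ]
    data.frame(metabolite = mm, p_unpaired = s1$p_unpaired,
               p_paired = w$p, p_paired_adj = NA_real_,
               significant_nominal = w$p < alpha,
               significant_fdr = NA,
               direction_unpaired = ifelse(s1$shift_unpaired > 0, "up",
                                           "down"),
               direction_paired = ifelse(pc$median_post - pc$median_pre > 0,
                                         "up", "down"),
               consistent = NA,
               percent_correction = pc$percent,
               percent_correction_raw = pc$percent_raw,
               correction_defined = pc$defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_paired_adj <- benjaminiHochberg(out$p_paired)
  out$significant_fdr <- out$p_paired_adj < fdr
  out$consistent <- out$direction_unpaired == out$direction_paired
  attr(out, "stage1") <- stage1_df
  out
}
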
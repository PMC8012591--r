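## Discovery/replication differential testing, confounder-adjusted
## regression, and comparator-group specificity tiers.

.group_samples <- function(x, group, cohort = NULL) {
  cd <- SummarizedExperiment::colData(x)
  sel <- cd$group == group
  if (!is.null(cohort)) sel <- sel & cd$cohort == cohort
  colnames(x)[sel]
}

#' Discovery/replication differential screen
#'
#' Tests every metabolite with a two-sided Mann-Whitney U-test, case group
#' versus control group, independently in the discovery and replication
#' cohorts.  A metabolite passes iff its p-value beats the Bonferroni
#' threshold `alpha / m` in both cohorts with a consistent effect direction
#' (the sign of `AUC - 0.5`).
#'
#' @param x a z-scored [MetabExperiment-class] whose `colData` carries
#'   `group` and `cohort` labels.
#' @param case_group,control_group group labels to contrast.
#' @param alpha family-wise error rate for the Bonferroni screen.
#' @return data.frame (one row per metabolite): group means and sds per
#'   cohort (z-units), `U`, `p` and `auc` per cohort, directions, the
#'   Bonferroni threshold used, and `passed`.
#' @export
discoveryReplication <- function(x, case_group = "CTEPH",
                                 control_group = "HC", alpha = 0.05) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("group", "cohort") %in% colnames(cd)))
    stop("colData must contain 'group' and 'cohort'", call. = FALSE)
  m <- intensity(x)
  res <- lapply(c("discovery", "replication"), function(ch) {
    cases <- .group_samples(x, case_group, ch)
    ctrls <- .group_samples(x, control_group, ch)
    if (!length(cases) || !length(ctrls))
      stop(sprintf("no %s samples for group %s", ch,
                   if (!length(cases)) case_group else control_group),
           call. = FALSE)
    t(vapply(rownames(m), function(mm) {
      a <- m[mm, cases]; b <- m[mm, ctrls]
      mw <- mannWhitney(a, b)
      c(mean_case = mean(a), sd_case = sd(a), mean_ctrl = mean(b),
        sd_ctrl = sd(b), U = mw$U, p = mw$p, auc = mw$auc)
    }, numeric(7)))
  })
  names(res) <- c("disc", "rep")
  thr <- bonferroniThreshold(alpha, nrow(m))
  dir_disc <- sign(res$disc[, "auc"] - 0.5)
  dir_rep <- sign(res$rep[, "auc"] - 0.5)
  passed <- res$disc[, "p"] < thr & res$rep[, "p"] < thr &
    dir_disc == dir_rep & dir_disc != 0
  out <- data.frame(
    metabolite = rownames(m),
    comparison = paste0(case_group, "_vs_", control_group),
    res$disc[, c("mean_case", "sd_case", "mean_ctrl", "sd_ctrl")],
    U_disc = res$disc[, "U"], p_disc = res$disc[, "p"],
    auc_disc = res$disc[, "auc"],
    U_rep = res$rep[, "U"], p_rep = res$rep[, "p"],
    auc_rep = res$rep[, "auc"],
    direction = ifelse(dir_disc > 0, "up", ifelse(dir_disc < 0, "down",
                                                  "none")),
    bonferroni_threshold = thr,
    passed = passed,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

## design matrix for the confounder regression: group indicator plus the
## adjustment set; creatinine/bilirubin enter as the preserved-function
## indicators, assumed preserved for healthy controls (no assay data)
.confounder_design <- function(cd, case_group, control_group) {
  keep <- cd$group %in% c(case_group, control_group)
  cd <- cd[keep, , drop = FALSE]
  preserved_renal <- ifelse(cd$group == "HC" & is.na(cd$creatinine), TRUE,
                            cd$creatinine < 75)
  preserved_liver <- ifelse(cd$group == "HC" & is.na(cd$bilirubin), TRUE,
                            cd$bilirubin < 21)
  df <- data.frame(
    is_case = as.numeric(cd$group == case_group),
    age = cd$age,
    sex_female = as.numeric(cd$sex == "female"),
    bmi = cd$bmi,
    preserved_renal = as.numeric(preserved_renal),
    preserved_liver = as.numeric(preserved_liver),
    row.names = rownames(cd))
  if ("ethnicity" %in% colnames(cd)) {
    eth <- factor(cd$ethnicity)
    if (nlevels(eth) > 1L)
      for (lv in levels(eth)[-1L])
        df[[paste0("ethnicity_", lv)]] <- as.numeric(eth == lv)
  }
  for (dc in grep("^drug_", colnames(cd), value = TRUE))
    df[[dc]] <- as.numeric(cd[[dc]])
  df
}

#' Confounder-adjusted group effect per metabolite
#'
#' Ordinary least-squares regression of each metabolite's z-score on the
#' case/control indicator adjusted for age, sex, ethnicity, BMI, the
#' preserved-renal-function indicator (creatinine < 75 umol/L), the
#' preserved-liver-function indicator (bilirubin < 21 umol/L) and drug-class
#' indicators.  Healthy controls with no assay data are assumed to have
#' preserved renal and hepatic function.  Complete-case analysis; degenerate
#' (constant or collinear) design columns are dropped with a warning, and
#' metabolites with fewer than 10 complete cases are skipped.  Also reports
#' the effect-ratio diagnostics |beta_group| / |beta_age| and
#' |beta_group| / |beta_sex|.
#'
#' @param x a z-scored [MetabExperiment-class].
#' @param metabolites metabolite ids to fit (default: all).
#' @param case_group,control_group group labels to contrast.
#' @param alpha retention threshold on the group-coefficient p-value.
#' @return data.frame per metabolite: `beta_group`, `p_group`, `beta_age`,
#'   `p_age`, `beta_sex`, `p_sex`, `ratio_age`, `ratio_sex`, `n_complete`,
#'   `retained`.
#' @export
confounderAdjust <- function(x, metabolites = rownames(x),
                             case_group = "CTEPH", control_group = "HC",
                             alpha = 0.05) {
  cd <- SummarizedExperiment::colData(x)
  des <- .confounder_design(cd, case_group, control_group)
  cc <- complete.cases(des)
  if (any(!cc))
    message(sum(!cc), " sample(s) dropped for missing covariates")
  des <- des[cc, , drop = FALSE]
  ## drop degenerate columns (constant after complete-case restriction)
  const <- vapply(des, function(v) length(unique(v)) == 1L, logical(1))
  const["is_case"] <- FALSE
  if (any(const)) {
    warning("dropping degenerate design column(s): ",
            paste(names(des)[const], collapse = ", "), call. = FALSE)
    des <- des[, !const, drop = FALSE]
  }
  m <- intensity(x)[metabolites, rownames(des), drop = FALSE]
  X <- cbind(intercept = 1, as.matrix(des))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    warning("dropping collinear design column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
  }
  fit_one <- function(y) {
    if (length(y) < 10L) return(NULL)
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dfr <- length(y) - fit$rank
    sigma2 <- rss / dfr
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- fit$coefficients / se
    pval <- 2 * stats::pt(-abs(tval), dfr)
    list(beta = fit$coefficients, p = pval)
  }
  grab <- function(f, nm) {
    if (is.null(f) || !nm %in% names(f$beta)) c(NA_real_, NA_real_)
    else c(f$beta[[nm]], f$p[[nm]])
  }
  rows <- lapply(metabolites, function(mm) {
    f <- fit_one(m[mm, ])
    if (is.null(f)) {
      warning("metabolite '", mm, "' skipped: < 10 complete cases",
              call. = FALSE)
      return(data.frame(metabolite = mm, beta_group = NA_real_,
                        p_group = NA_real_, beta_age = NA_real_,
                        p_age = NA_real_, beta_sex = NA_real_,
                        p_sex = NA_real_, ratio_age = NA_real_,
                        ratio_sex = NA_real_, n_complete = nrow(X),
                        retained = FALSE, stringsAsFactors = FALSE))
    }
    bg <- grab(f, "is_case"); ba <- grab(f, "age"); bs <- grab(f, "sex_female")
    data.frame(metabolite = mm, beta_group = bg[1], p_group = bg[2],
               beta_age = ba[1], p_age = ba[2], beta_sex = bs[1],
               p_sex = bs[2],
               ratio_age = abs(bg[1]) / abs(ba[1]),
               ratio_sex = abs(bg[1]) / abs(bs[1]),
               n_complete = nrow(X),
               retained = !is.na(bg[2]) && bg[2] < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Specificity tiers across comparator groups
#'
#' Runs the full differential cascade for the case group: the
#' discovery/replication Bonferroni screen against healthy controls plus the
#' confounder-adjusted regression (the base criterion), then
#' confounder-adjusted contrasts against disease controls, chronic
#' thromboembolic disease without PH, and idiopathic/heritable PAH.  Each
#' metabolite is assigned the highest tier whose full nested criterion set
#' it meets: `vs_HC_only` (base), `vs_HC_DC` (+ DC), `vs_HC_DC_CTED`
#' (+ CTED), `vs_all_including_IPAH` (+ IPAH), else `none`.
#'
#' @param x a z-scored [MetabExperiment-class] containing all groups.
#' @param case_group the case label.
#' @param alpha significance level for the Bonferroni family and the
#'   adjusted models.
#' @return list with `tiers` (data.frame: metabolite, tier and the component
#'   booleans), `differential` (the discovery/replication table) and
#'   `adjusted` (named list of confounder-adjusted tables per comparator).
#' @export
tierClassify <- function(x, case_group = "CTEPH", alpha = 0.05) {
  dr <- discoveryReplication(x, case_group, "HC", alpha)
  base_ids <- dr$metabolite[dr$passed]
  adj <- list()
  adj[["HC"]] <- if (length(base_ids))
    confounderAdjust(x, base_ids, case_group, "HC", alpha)
  else NULL
  ok_hc <- if (length(base_ids)) {
    r <- adj[["HC"]]
    setNames(r$retained, r$metabolite)
  } else setNames(logical(0), character(0))
  hc_ids <- names(ok_hc)[ok_hc]
  for (g in c("DC", "CTED", "IPAH_HPAH")) {
    adj[[g]] <- if (length(hc_ids))
      confounderAdjust(x, hc_ids, case_group, g, alpha)
    else NULL
  }
  ok <- function(g, ids) {
    r <- adj[[g]]
    if (is.null(r)) return(setNames(rep(FALSE, length(ids)), ids))
    setNames(r$retained[match(ids, r$metabolite)], ids)
  }
  all_ids <- rownames(x)
  pass_base <- all_ids %in% hc_ids
  pass_dc <- pass_base & all_ids %in% names(which(ok("DC", hc_ids)))
  pass_cted <- pass_dc & all_ids %in% names(which(ok("CTED", hc_ids)))
  pass_ipah <- pass_cted & all_ids %in% names(which(ok("IPAH_HPAH", hc_ids)))
  tier <- rep("none", length(all_ids))
  tier[pass_base] <- "vs_HC_only"
  tier[pass_dc] <- "vs_HC_DC"
  tier[pass_cted] <- "vs_HC_DC_CTED"
  tier[pass_ipah] <- "vs_all_including_IPAH"
  tiers <- data.frame(metabolite = all_ids,
                      tier = factor(tier, levels = .TIER_LEVELS),
                      vs_HC = pass_base, vs_DC = pass_dc,
                      vs_CTED = pass_cted, vs_IPAH = pass_ipah,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(tiers = tiers, differential = dr, adjusted = adj)
}
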
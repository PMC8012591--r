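## Synthetic-cohort generator.  Emulates the statistical structure the
## downstream analyses assume: log-normal intensities with subpathway
## correlation blocks, group effects on the log scale, covariate and batch
## effects, left-censoring at a per-metabolite detection limit, paired
## pre/post-surgery designs and tri-site sampling with subject random
## effects.  Everything planted is recorded in a TruthLedger.

#' Configuration for the synthetic-study generator
#'
#' Returns a validated configuration whose defaults are the study conditions
#' of the emulated cohort design: discovery 108 cases vs 58 healthy
#' controls, replication 92 vs 63, disease controls 132, chronic
#' thromboembolic disease without PH 63, idiopathic/heritable PAH 433; 64
#' pre-surgery vs 82 post-surgery unpaired patients plus 43 paired subjects;
#' 68 + 18 subjects sampled at three anatomical sites.  Group effects are
#' drawn on the scale of the reported perturbations (downs 0.33-1.53 sd, ups
#' 0.84-2 sd), age effects are 1/75 of the group effect and sex effects
#' 1/2.2 (the reported 50-100x and 1.5-3.2x ratios), post-surgery correction
#' fractions span 0.15-1 and site gradients 0.2-0.45 z-units.
#'
#' @param m number of metabolites generated (before filtering).
#' @param n_hc_discovery,n_hc_replication,n_cteph_discovery,n_cteph_replication,n_dc,n_cted,n_ipah group sizes for the main cohort arm.
#' @param fraction_affected fraction of metabolites with a planted
#'   case-vs-healthy effect.
#' @param effect_up,effect_down ranges (absolute values) for up/down planted
#'   effects, in sd units on the log scale.
#' @param prob_up probability a planted effect is an increase.
#' @param tier_probs named probabilities over specificity tiers for planted
#'   metabolites (`vs_all_including_IPAH`, `vs_HC_DC_CTED`, `vs_HC_DC`,
#'   `vs_HC_only`): a metabolite in a lower tier shares its effect with the
#'   comparator groups above it, so the case-vs-comparator contrast is null.
#' @param confounder_ratio named vector: group-effect / covariate-effect
#'   ratios for `age` and `sex`.
#' @param confounder_fraction named vector: fraction of affected metabolites
#'   also carrying each covariate effect.
#' @param n_batches,batch_sd number of measurement batches and the sd of the
#'   per-metabolite per-batch offset (log scale).
#' @param censor_quantile per-metabolite limit-of-detection quantile for
#'   left-censoring.
#' @param fraction_low_detect,low_detect_range fraction of metabolites with
#'   a much higher detection limit (censoring quantile drawn from the range),
#'   i.e. the metabolites the 95% detection filter removes.
#' @param xenobiotic_fraction fraction of metabolites annotated xenobiotic.
#' @param n_subpathways,n_superpathways annotation granularity.
#' @param subpath_correlation within-subpathway correlation of the latent
#'   biological signal.
#' @param sigma_range range of per-metabolite log-scale sds.
#' @param n_pre_unpaired,n_post_unpaired,n_paired sizes for the surgery arm.
#' @param fraction_responsive fraction of affected metabolites whose
#'   perturbation is (partly) corrected after surgery.
#' @param correction_range range of planted correction fractions, in [0, 1].
#' @param plant_inconsistent plant one metabolite whose unpaired and paired
#'   post-surgery shifts disagree in direction (a screening false positive).
#' @param pea_noise_sd within-subject sd between the pre and post samples,
#'   in units of the metabolite sd.
#' @param n_trisite_cteph,n_trisite_ipah subjects sampled at all three sites.
#' @param fraction_gradient fraction of metabolites with a planted gradient,
#'   independently for the SVC-to-PA and PA-to-ART segments.
#' @param gradient_range range of planted gradient magnitudes (z-units).
#' @param site_residual_sd within-subject between-site residual sd, in units
#'   of the metabolite sd.
#' @param clinical_assoc_fraction fraction of metabolites whose
#'   subject-level signal loads on the latent disease-severity score that
#'   also drives the clinical variables.
#' @param clinical_assoc_rho loading of those metabolites on severity.
#' @param seed default seed used by the generators.
#' @return object of class `SynthConfig` (a validated parameter list).
#' @export
synthConfig <- function(m = 340,
                        n_hc_discovery = 58, n_hc_replication = 63,
                        n_cteph_discovery = 108, n_cteph_replication = 92,
                        n_dc = 132, n_cted = 63, n_ipah = 433,
                        fraction_affected = 0.17,
                        effect_up = c(0.84, 2.0),
                        effect_down = c(0.33, 1.53),
                        prob_up = 0.5,
                        tier_probs = c(vs_all_including_IPAH = 0.10,
                                       vs_HC_DC_CTED = 0.25,
                                       vs_HC_DC = 0.25,
                                       vs_HC_only = 0.40),
                        confounder_ratio = c(age = 75, sex = 2.2),
                        confounder_fraction = c(age = 0.5, sex = 0.3),
                        n_batches = 2, batch_sd = 0.2,
                        censor_quantile = 0.02,
                        fraction_low_detect = 0.05,
                        low_detect_range = c(0.1, 0.5),
                        xenobiotic_fraction = 0.06,
                        n_subpathways = 40, n_superpathways = 8,
                        subpath_correlation = 0.3,
                        sigma_range = c(0.3, 1),
                        n_pre_unpaired = 64, n_post_unpaired = 82,
                        n_paired = 43,
                        fraction_responsive = 0.7,
                        correction_range = c(0.15, 1),
                        plant_inconsistent = TRUE,
                        pea_noise_sd = 0.4,
                        n_trisite_cteph = 68, n_trisite_ipah = 18,
                        fraction_gradient = 0.15,
                        gradient_range = c(0.2, 0.45),
                        site_residual_sd = 0.15,
                        clinical_assoc_fraction = 0.1,
                        clinical_assoc_rho = 0.4,
                        seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("m", "n_hc_discovery", "n_hc_replication", "n_cteph_discovery",
              "n_cteph_replication", "n_dc", "n_cted", "n_ipah", "n_batches",
              "n_subpathways", "n_superpathways", "n_pre_unpaired",
              "n_post_unpaired", "n_paired", "n_trisite_cteph",
              "n_trisite_ipah")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(nm, " must be positive", call. = FALSE)
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("censor_quantile must lie in [0, 1)", call. = FALSE)
  if (any(correction_range < 0 | correction_range > 1))
    stop("correction_range must lie in [0, 1]", call. = FALSE)
  if (fraction_affected < 0 || fraction_affected > 1)
    stop("fraction_affected must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "SynthConfig")
}

#' @export
print.SynthConfig <- function(x, ...) {
  cat("SynthConfig:", x$m, "metabolites; cohort n =",
      x$n_cteph_discovery, "+", x$n_cteph_replication, "cases /",
      x$n_hc_discovery, "+", x$n_hc_replication, "controls;",
      x$n_paired, "paired;", x$n_trisite_cteph + x$n_trisite_ipah,
      "tri-site subjects; seed", x$seed, "\n")
  invisible(x)
}

.met_ids <- function(m) sprintf("met%03d", seq_len(m))

.SUPERPATHWAYS <- c("Lipid", "Amino acid", "Nucleotide", "Carbohydrate",
                    "Energy", "Cofactors and vitamins", "Peptide",
                    "Xenobiotics")

## one shared annotation per seed: ~n_subpathways subpathways nested in
## superpathways, a xenobiotic tail, and an identity-confidence flag
.make_annotation <- function(cfg) {
  m <- cfg$m
  ids <- .met_ids(m)
  n_xeno <- round(cfg$xenobiotic_fraction * m)
  supers <- .SUPERPATHWAYS[seq_len(min(cfg$n_superpathways,
                                       length(.SUPERPATHWAYS)))]
  supers_nonxeno <- setdiff(supers, "Xenobiotics")
  n_sub <- max(cfg$n_subpathways - 2L, length(supers_nonxeno))
  sub_super <- sample(supers_nonxeno, n_sub, replace = TRUE)
  sub_names <- sprintf("%s subpathway %02d", sub_super, seq_len(n_sub))
  ## draw subpathway sizes once: Dirichlet-ish via normalised gamma weights
  w <- rgamma(n_sub, shape = 2)
  sub_of <- sample(seq_len(n_sub), m - n_xeno, replace = TRUE,
                   prob = w / sum(w))
  subpath <- character(m); superpath <- character(m)
  subpath[seq_len(m - n_xeno)] <- sub_names[sub_of]
  superpath[seq_len(m - n_xeno)] <- sub_super[sub_of]
  if (n_xeno > 0) {
    xeno_sub <- sample(c("Drug metabolite", "Food component"), n_xeno,
                       replace = TRUE)
    subpath[(m - n_xeno + 1L):m] <- xeno_sub
    superpath[(m - n_xeno + 1L):m] <- "Xenobiotics"
  }
  data.frame(metabolite_id = ids, subpathway = subpath,
             superpathway = superpath,
             identity_confirmed = runif(m) < 0.9,
             xenobiotic = superpath == "Xenobiotics",
             stringsAsFactors = FALSE)
}

## covariates per group, loosely on the scale of the emulated cohorts:
## healthy controls younger, patients older; creatinine/bilirubin missing
## for healthy controls (assumed preserved downstream)
.group_cov_params <- list(
  HC        = list(age = c(45, 14), female = 0.55, bmi = c(25, 4)),
  DC        = list(age = c(58, 15), female = 0.60, bmi = c(29, 6)),
  CTED      = list(age = c(63, 13), female = 0.50, bmi = c(28, 5)),
  IPAH_HPAH = list(age = c(53, 17), female = 0.70, bmi = c(28, 6)),
  CTEPH     = list(age = c(63, 14), female = 0.48, bmi = c(28, 5)))

.make_metadata <- function(group, cohort, n, prefix, batch_ids,
                           timepoint = "none", site = "none",
                           subject_id = NULL) {
  p <- .group_cov_params[[group]]
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  data.frame(
    sample_id = ids,
    subject_id = subject_id %||% ids,
    group = group, cohort = cohort,
    batch = sample(batch_ids, n, replace = TRUE),
    timepoint = timepoint, site = site,
    age = round(pmin(90, pmax(18, rnorm(n, p$age[1], p$age[2])))),
    sex = ifelse(runif(n) < p$female, "female", "male"),
    ethnicity = sample(c("white", "asian", "black", "other"), n,
                       replace = TRUE, prob = c(0.8, 0.1, 0.05, 0.05)),
    bmi = round(pmax(16, rnorm(n, p$bmi[1], p$bmi[2])), 1),
    creatinine = if (group == "HC") NA_real_ else
      round(pmax(40, rnorm(n, 85, 22)), 1),
    bilirubin = if (group == "HC") NA_real_ else
      round(pmax(3, rnorm(n, 12, 6)), 1),
    drug_anticoagulant = if (group == "HC") 0L else
      as.integer(runif(n) < switch(group, DC = 0.33, CTED = 0.84,
                                   IPAH_HPAH = 0.67, CTEPH = 0.95)),
    drug_diuretic = if (group == "HC") 0L else
      as.integer(runif(n) < switch(group, DC = 0.18, CTED = 0.08,
                                   IPAH_HPAH = 0.53, CTEPH = 0.47)),
    drug_statin = if (group == "HC") 0L else
      as.integer(runif(n) < switch(group, DC = 0.30, CTED = 0.22,
                                   IPAH_HPAH = 0.26, CTEPH = 0.40)),
    stringsAsFactors = FALSE)
}

## planted group-effect matrix (sd units) for the cohort arm.  Comparator
## groups "above" a metabolite's specificity tier share the case effect, so
## the case-vs-comparator contrast is null for them.
.plant_effects <- function(cfg) {
  m <- cfg$m
  ids <- .met_ids(m)
  n_aff <- round(cfg$fraction_affected * m)
  eff <- matrix(0, nrow = m, ncol = 4,
                dimnames = list(ids, c("DC", "CTED", "IPAH_HPAH", "CTEPH")))
  if (cfg$fraction_affected > 0 && n_aff < 1) {
    warning("fraction_affected * m < 1; no effects planted", call. = FALSE)
    n_aff <- 0L
  }
  tier <- character(0)
  if (n_aff > 0) {
    aff <- sample(ids, n_aff)
    up <- runif(n_aff) < cfg$prob_up
    delta <- ifelse(up,
                    runif(n_aff, cfg$effect_up[1], cfg$effect_up[2]),
                    -runif(n_aff, cfg$effect_down[1], cfg$effect_down[2]))
    tier <- sample(names(cfg$tier_probs), n_aff, replace = TRUE,
                   prob = cfg$tier_probs)
    names(tier) <- aff
    eff[aff, "CTEPH"] <- delta
    share_ipah <- tier %in% c("vs_HC_DC_CTED", "vs_HC_DC", "vs_HC_only")
    share_cted <- tier %in% c("vs_HC_DC", "vs_HC_only")
    share_dc <- tier %in% "vs_HC_only"
    eff[aff[share_ipah], "IPAH_HPAH"] <- delta[share_ipah]
    eff[aff[share_cted], "CTED"] <- delta[share_cted]
    eff[aff[share_dc], "DC"] <- delta[share_dc]
  }
  list(effects = eff, tier = tier)
}

## planted covariate effects (sd units of the metabolite, per sd of the
## standardised covariate / per female indicator)
.plant_confounders <- function(cfg, effects) {
  ids <- rownames(effects)
  aff <- ids[effects[, "CTEPH"] != 0]
  mean_abs <- if (length(aff)) mean(abs(effects[aff, "CTEPH"])) else 1
  out <- list()
  for (cv in names(cfg$confounder_ratio)) {
    frac <- cfg$confounder_fraction[[cv]]
    ratio <- cfg$confounder_ratio[[cv]]
    hit_aff <- aff[runif(length(aff)) < frac]
    n_null <- round(frac * length(aff))
    pool <- setdiff(ids, aff)
    hit_null <- if (n_null > 0 && length(pool))
      sample(pool, min(n_null, length(pool))) else character()
    beta <- c(abs(effects[hit_aff, "CTEPH"]) / ratio,
              rep(mean_abs / ratio, length(hit_null)))
    sgn <- sample(c(-1, 1), length(beta), replace = TRUE)
    if (length(beta))
      out[[cv]] <- data.frame(metabolite = c(hit_aff, hit_null),
                              covariate = cv, effect = sgn * beta,
                              stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else .empty_confounders()
}

## core log-scale matrix builder shared by the three arms
.build_matrix <- function(cfg, md, ann, mu, sigma, extra_sd_units,
                          batch_offsets = NULL, subject_noise = NULL) {
  m <- cfg$m; n <- nrow(md)
  ids <- .met_ids(m)
  rho <- cfg$subpath_correlation
  sub_f <- factor(ann$subpathway)
  F_lat <- matrix(rnorm(nlevels(sub_f) * n), nlevels(sub_f), n)
  eps <- matrix(rnorm(m * n), m, n)
  bio <- sqrt(rho) * F_lat[as.integer(sub_f), , drop = FALSE] +
    sqrt(1 - rho) * eps
  if (!is.null(subject_noise)) bio <- subject_noise
  logx <- mu + sigma * (bio + extra_sd_units)
  if (!is.null(batch_offsets))
    logx <- logx + batch_offsets[, md$batch, drop = FALSE]
  dimnames(logx) <- list(ids, md$sample_id)
  exp(logx)
}

## left-censor below the per-metabolite detection-limit quantile
.censor <- function(cfg, x) {
  m <- nrow(x)
  q <- rep(cfg$censor_quantile, m)
  n_low <- round(cfg$fraction_low_detect * m)
  if (n_low > 0) {
    low <- sample(seq_len(m), n_low)
    q[low] <- runif(n_low, cfg$low_detect_range[1], cfg$low_detect_range[2])
  }
  for (i in seq_len(m)) {
    if (q[i] <= 0) next
    lod <- quantile(x[i, ], q[i], names = FALSE)
    x[i, x[i, ] < lod] <- NA_real_
  }
  x
}

.affected_table <- function(effects) {
  ids <- rownames(effects)
  out <- list()
  for (g in colnames(effects)) {
    contrast <- effects[, "CTEPH"] - effects[, g]
    if (g == "CTEPH") {
      hit <- effects[, "CTEPH"] != 0
      if (any(hit))
        out[[g]] <- data.frame(metabolite = ids[hit],
                               comparison = "CTEPH_vs_HC",
                               effect = effects[hit, "CTEPH"],
                               stringsAsFactors = FALSE)
    } else {
      hit <- contrast != 0
      if (any(hit))
        out[[g]] <- data.frame(metabolite = ids[hit],
                               comparison = paste0("CTEPH_vs_", g),
                               effect = contrast[hit],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else .empty_affected()
}

#' Generate the main synthetic cohort
#'
#' Builds the discovery/replication case-control arm plus the three
#' comparator groups, with log-normal intensities, subpathway correlation
#' blocks, planted group effects whose specificity tier decides which
#' comparator groups share them, covariate (age, sex) effects, per-batch
#' offsets, and left-censored limit-of-detection missingness.
#'
#' @param cfg a [synthConfig()] configuration.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with `experiment` (a raw-scale [MetabExperiment-class]) and
#'   `truth` (a [TruthLedger-class]).
#' @export
generateCohort <- function(cfg = synthConfig(), seed = cfg$seed) {
  set.seed(seed)
  ann <- .make_annotation(cfg)
  pl <- .plant_effects(cfg)
  conf <- .plant_confounders(cfg, pl$effects)
  batch_ids <- sprintf("B%d", seq_len(cfg$n_batches))
  md <- rbind(
    .make_metadata("CTEPH", "discovery", cfg$n_cteph_discovery, "cd",
                   batch_ids),
    .make_metadata("HC", "discovery", cfg$n_hc_discovery, "hd", batch_ids),
    .make_metadata("CTEPH", "replication", cfg$n_cteph_replication, "cr",
                   batch_ids),
    .make_metadata("HC", "replication", cfg$n_hc_replication, "hr",
                   batch_ids),
    .make_metadata("DC", "none", cfg$n_dc, "dc", batch_ids),
    .make_metadata("CTED", "none", cfg$n_cted, "ct", batch_ids),
    .make_metadata("IPAH_HPAH", "none", cfg$n_ipah, "ip", batch_ids))
  m <- cfg$m; n <- nrow(md)
  ids <- .met_ids(m)
  mu <- rnorm(m, 7, 1.5)
  sigma <- runif(m, cfg$sigma_range[1], cfg$sigma_range[2])
  ## per-sample effect in sd units: group + covariates
  grp_eff <- matrix(0, m, n)
  for (g in colnames(pl$effects)) {
    sel <- md$group == g
    if (any(sel)) grp_eff[, sel] <- pl$effects[, g]
  }
  cov_eff <- matrix(0, m, n)
  if (nrow(conf)) {
    age_std <- (md$age - mean(md$age)) / sd(md$age)
    fem <- as.numeric(md$sex == "female")
    for (k in seq_len(nrow(conf))) {
      i <- match(conf$metabolite[k], ids)
      v <- switch(conf$covariate[k], age = age_std, sex = fem)
      cov_eff[i, ] <- cov_eff[i, ] + conf$effect[k] * v
    }
  }
  batch_off <- matrix(rnorm(m * cfg$n_batches, 0, cfg$batch_sd),
                      m, cfg$n_batches, dimnames = list(ids, batch_ids))
  x <- .build_matrix(cfg, md, ann, mu, sigma, grp_eff + cov_eff, batch_off)
  x <- .censor(cfg, x)
  truth <- TruthLedger(
    affected = .affected_table(pl$effects),
    confounder_effects = conf,
    batch_offsets = data.frame(
      metabolite = rep(ids, cfg$n_batches),
      batch = rep(batch_ids, each = m),
      offset = as.vector(batch_off), stringsAsFactors = FALSE),
    pathway_assignments = ann, seed = seed)
  rd <- S4Vectors::DataFrame(ann, row.names = ann$metabolite_id)
  cd <- S4Vectors::DataFrame(md, row.names = md$sample_id)
  list(experiment = MetabExperiment(x, colData = cd, rowData = rd),
       truth = truth)
}

#' Generate the paired surgery (pre/post) arm
#'
#' Builds a healthy-control reference group, independent pre-surgery and
#' post-surgery patient groups, and paired subjects sampled at both
#' timepoints.  For responsive metabolites the post-surgery value moves
#' toward the healthy-control mean by the planted correction fraction;
#' optionally one metabolite is planted with opposite unpaired and paired
#' shifts (the screening false-positive scenario).
#'
#' @inheritParams generateCohort
#' @return list with `experiment` and `truth`; `truth@correction_fractions`
#'   holds the planted per-metabolite fractions (responsive metabolites
#'   only) and the inconsistent metabolite, if planted, is recorded in
#'   `truth@affected` under comparison `"PEA_inconsistent"`.
#' @export
generatePairedPEA <- function(cfg = synthConfig(), seed = cfg$seed) {
  set.seed(seed)
  ann <- .make_annotation(cfg)
  m <- cfg$m; ids <- .met_ids(m)
  n_aff <- round(cfg$fraction_affected * m)
  if (cfg$fraction_affected > 0 && n_aff < 1) {
    warning("fraction_affected * m < 1; no effects planted", call. = FALSE)
    n_aff <- 0L
  }
  delta <- setNames(numeric(m), ids)
  frac <- setNames(numeric(m), ids)
  aff <- character(0)
  if (n_aff > 0) {
    aff <- sample(ids, n_aff)
    up <- runif(n_aff) < cfg$prob_up
    delta[aff] <- ifelse(up,
                         runif(n_aff, cfg$effect_up[1], cfg$effect_up[2]),
                         -runif(n_aff, cfg$effect_down[1],
                                cfg$effect_down[2]))
    resp <- aff[runif(n_aff) < cfg$fraction_responsive]
    frac[resp] <- runif(length(resp), cfg$correction_range[1],
                        cfg$correction_range[2])
  }
  inconsistent <- character(0)
  if (cfg$plant_inconsistent && length(aff))
    inconsistent <- aff[which.max(abs(delta[aff]))]
  batch_ids <- sprintf("B%d", seq_len(cfg$n_batches))
  md_hc <- .make_metadata("HC", "none", cfg$n_hc_discovery, "hc", batch_ids)
  md_pre <- .make_metadata("CTEPH", "none", cfg$n_pre_unpaired, "pu",
                           batch_ids, timepoint = "pre_PEA")
  md_post <- .make_metadata("CTEPH", "none", cfg$n_post_unpaired, "qu",
                            batch_ids, timepoint = "post_PEA")
  subj <- sprintf("pp%03d", seq_len(cfg$n_paired))
  md_ppre <- .make_metadata("CTEPH", "none", cfg$n_paired, "pa", batch_ids,
                            timepoint = "pre_PEA", subject_id = subj)
  md_ppost <- .make_metadata("CTEPH", "none", cfg$n_paired, "pb", batch_ids,
                             timepoint = "post_PEA", subject_id = subj)
  ## paired samples share the subject's covariates
  cov_cols <- c("age", "sex", "ethnicity", "bmi", "creatinine", "bilirubin",
                "drug_anticoagulant", "drug_diuretic", "drug_statin")
  md_ppost[cov_cols] <- md_ppre[cov_cols]
  md <- rbind(md_hc, md_pre, md_post, md_ppre, md_ppost)
  n <- nrow(md)
  mu <- rnorm(m, 7, 1.5)
  sigma <- runif(m, cfg$sigma_range[1], cfg$sigma_range[2])
  ## perturbation in sd units per sample: pre full, post residual
  pert <- matrix(0, m, n)
  is_pre <- md$timepoint == "pre_PEA"
  is_post <- md$timepoint == "post_PEA"
  pert[, is_pre] <- delta
  pert[, is_post] <- delta * (1 - frac)
  if (length(inconsistent)) {
    ## unpaired post group shifts the wrong way; paired post keeps the
    ## planted correction
    i <- match(inconsistent, ids)
    unpaired_post <- is_post & !(md$subject_id %in% subj)
    pert[i, unpaired_post] <- delta[inconsistent] +
      0.8 * sign(delta[inconsistent])
  }
  ## biological noise: unpaired samples independent; paired samples share a
  ## subject effect, with within-subject sd pea_noise_sd
  rho <- cfg$subpath_correlation
  sub_f <- factor(ann$subpathway)
  F_lat <- matrix(rnorm(nlevels(sub_f) * n), nlevels(sub_f), n)
  eps <- matrix(rnorm(m * n), m, n)
  bio <- sqrt(rho) * F_lat[as.integer(sub_f), , drop = FALSE] +
    sqrt(1 - rho) * eps
  su <- sqrt(max(0, 1 - cfg$pea_noise_sd^2))
  pre_idx <- match(paste0("pa", sprintf("%03d", seq_len(cfg$n_paired))),
                   md$sample_id)
  post_idx <- match(paste0("pb", sprintf("%03d", seq_len(cfg$n_paired))),
                    md$sample_id)
  subj_eff <- su * bio[, pre_idx, drop = FALSE]
  bio[, pre_idx] <- subj_eff +
    cfg$pea_noise_sd * matrix(rnorm(m * cfg$n_paired), m)
  bio[, post_idx] <- subj_eff +
    cfg$pea_noise_sd * matrix(rnorm(m * cfg$n_paired), m)
  logx <- mu + sigma * (bio + pert)
  dimnames(logx) <- list(ids, md$sample_id)
  x <- .censor(cfg, exp(logx))
  affected <- if (length(aff))
    data.frame(metabolite = aff, comparison = "CTEPH_vs_HC",
               effect = delta[aff], stringsAsFactors = FALSE)
  else .empty_affected()
  if (length(inconsistent))
    affected <- rbind(affected, data.frame(
      metabolite = inconsistent, comparison = "PEA_inconsistent",
      effect = 0.8 * sign(delta[inconsistent]), stringsAsFactors = FALSE))
  truth <- TruthLedger(
    affected = affected,
    correction_fractions = frac[aff[frac[aff] > 0]],
    pathway_assignments = ann, seed = seed)
  rd <- S4Vectors::DataFrame(ann, row.names = ann$metabolite_id)
  cd <- S4Vectors::DataFrame(md, row.names = md$sample_id)
  list(experiment = MetabExperiment(x, colData = cd, rowData = rd),
       truth = truth)
}

#' Generate the tri-site (SVC, PA, ART) arm
#'
#' Builds subjects sampled simultaneously at the superior vena cava,
#' pulmonary artery and radial artery, sharing a subject-level random
#' effect, with planted per-metabolite site offsets accumulating along the
#' flow direction (SVC to PA to ART), plus a healthy-control reference group
#' for standardisation.  A latent severity score drives the clinical
#' variables and, for a subset of metabolites, the subject-level signal, so
#' that metabolite-severity correlations exist by construction.
#'
#' @inheritParams generateCohort
#' @return list with `experiment` and `truth`; `truth@site_gradients` holds
#'   the planted downstream-minus-upstream offsets per site pair (z-units),
#'   including the implied return-segment (`ART_SVC`) offset.
#' @export
generateTriSite <- function(cfg = synthConfig(), seed = cfg$seed) {
  set.seed(seed)
  ann <- .make_annotation(cfg)
  m <- cfg$m; ids <- .met_ids(m)
  g1 <- setNames(numeric(m), ids)   # SVC -> PA offset
  g2 <- setNames(numeric(m), ids)   # PA -> ART offset
  pick <- function() {
    hit <- runif(m) < cfg$fraction_gradient
    val <- numeric(m)
    val[hit] <- sample(c(-1, 1), sum(hit), TRUE) *
      runif(sum(hit), cfg$gradient_range[1], cfg$gradient_range[2])
    val
  }
  g1[] <- pick(); g2[] <- pick()
  n_sub <- cfg$n_trisite_cteph + cfg$n_trisite_ipah
  subj <- sprintf("ts%03d", seq_len(n_sub))
  grp <- rep(c("CTEPH", "IPAH_HPAH"),
             c(cfg$n_trisite_cteph, cfg$n_trisite_ipah))
  batch_ids <- sprintf("B%d", seq_len(cfg$n_batches))
  md_hc <- .make_metadata("HC", "none", cfg$n_hc_discovery, "gh", batch_ids)
  severity <- rnorm(n_sub)
  md_site <- do.call(rbind, lapply(c("SVC", "PA", "ART"), function(s) {
    md <- .make_metadata("CTEPH", "gradient", n_sub,
                         paste0("g", tolower(s)), batch_ids,
                         site = s, subject_id = subj)
    md$group <- grp
    md
  }))
  ## subjects keep one covariate draw across their three samples
  cov_cols <- c("age", "sex", "ethnicity", "bmi", "creatinine", "bilirubin",
                "drug_anticoagulant", "drug_diuretic", "drug_statin")
  first <- md_site[seq_len(n_sub), cov_cols]
  md_site[cov_cols] <- first[rep(seq_len(n_sub), 3L), ]
  ## clinical severity variables (patients only)
  clin <- data.frame(
    mRAP = round(9 + 4 * severity + rnorm(n_sub, 0, 2), 1),
    mPAP = round(45 + 9 * severity + rnorm(n_sub, 0, 5), 1),
    PVR = round(pmax(1, 7 + 2.5 * severity + rnorm(n_sub, 0, 1.5)), 1),
    cardiac_output = round(pmax(1.5, 4.5 - 0.8 * severity +
                                  rnorm(n_sub, 0, 0.7)), 2),
    walk_6m = round(pmax(30, 350 - 70 * severity + rnorm(n_sub, 0, 60))))
  md_site <- cbind(md_site, clin[rep(seq_len(n_sub), 3L), ])
  md_hc[names(clin)] <- NA_real_
  md <- rbind(md_hc, md_site)
  mu <- rnorm(m, 7, 1.5)
  sigma <- runif(m, cfg$sigma_range[1], cfg$sigma_range[2])
  ## subject-level biology, partly loading on severity for a subset
  n_assoc <- round(cfg$clinical_assoc_fraction * m)
  assoc <- if (n_assoc > 0) sample(ids, n_assoc) else character()
  lam <- setNames(numeric(m), ids)
  lam[assoc] <- cfg$clinical_assoc_rho *
    sample(c(-1, 1), n_assoc, replace = TRUE)
  z_sub <- matrix(rnorm(m * n_sub), m, n_sub)
  u <- sqrt(1 - lam^2) * z_sub +
    lam %o% severity                     # m x n_sub subject effects
  rs <- cfg$site_residual_sd
  val_at <- function(site_units) {
    eps <- matrix(rnorm(m * n_sub, 0, rs), m, n_sub)
    mu + sigma * (u + site_units + eps)
  }
  log_svc <- val_at(0)
  log_pa <- val_at(g1)
  log_art <- val_at(g1 + g2)
  n_hc <- cfg$n_hc_discovery
  bio_hc <- matrix(rnorm(m * n_hc), m, n_hc)
  log_hc <- mu + sigma * bio_hc
  logx <- cbind(log_hc, log_svc, log_pa, log_art)
  dimnames(logx) <- list(ids, md$sample_id)
  x <- .censor(cfg, exp(logx))
  grad_rows <- function(v, pair) {
    hit <- v != 0
    if (!any(hit)) return(.empty_gradients())
    data.frame(metabolite = ids[hit], site_pair = pair,
               offset = unname(v[hit]), stringsAsFactors = FALSE)
  }
  grad <- rbind(grad_rows(g1, "SVC_PA"), grad_rows(g2, "PA_ART"),
                grad_rows(-(g1 + g2), "ART_SVC"))
  truth <- TruthLedger(
    site_gradients = grad,
    confounder_effects = if (length(assoc))
      data.frame(metabolite = assoc, covariate = "severity",
                 effect = lam[assoc], stringsAsFactors = FALSE)
    else .empty_confounders(),
    pathway_assignments = ann, seed = seed)
  rd <- S4Vectors::DataFrame(ann, row.names = ann$metabolite_id)
  cd <- S4Vectors::DataFrame(md, row.names = md$sample_id)
  list(experiment = MetabExperiment(x, colData = cd, rowData = rd),
       truth = truth)
}
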
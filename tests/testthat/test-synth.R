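test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- generateCohort(cfg, seed = 5)
  b <- generateCohort(cfg, seed = 5)
  expect_identical(intensity(a$experiment), intensity(b$experiment))
  expect_identical(a$truth@affected, b$truth@affected)
  c1 <- generateTriSite(cfg, seed = 5)
  c2 <- generateTriSite(cfg, seed = 5)
  expect_identical(intensity(c1$experiment), intensity(c2$experiment))
  ## different seed, different data
  d <- generateCohort(cfg, seed = 6)
  expect_false(identical(intensity(a$experiment), intensity(d$experiment)))
})

test_that("a global-null configuration plants nothing", {
  g <- generateCohort(small_cfg(fraction_affected = 0))
  expect_identical(nrow(g$truth@affected), 0L)
  expect_identical(length(g$truth@correction_fractions), 0L)
})

test_that("censoring is left-tail only: missing cells sit below detected", {
  g <- generateCohort(small_cfg())
  m <- intensity(g$experiment)
  for (i in seq_len(nrow(m))) {
    if (!anyNA(m[i, ])) next
    expect_true(all(is.na(m[i, ]) | m[i, ] >= 0))
  }
  ## every metabolite's detected minimum exceeds nothing that was censored:
  ## regenerating with no censoring and comparing tails is overkill here;
  ## the structural property is that missingness concentrates at low
  ## intensities, i.e. imputed values are the per-metabolite minima
  imp <- suppressWarnings(imputeMinDetected(g$experiment))
  filled <- intensity(imp)[!detectionMask(imp)]
  mins <- apply(intensity(imp), 1, min)[row(intensity(imp))[!detectionMask(imp)]]
  expect_equal(unname(filled), unname(mins))
})

test_that("planted effects reproduce the configured standardised difference", {
  ## +1.5 sd effects, 100 cases vs 100 controls per cohort: the mean
  ## empirical standardised mean difference over planted metabolites lands
  ## within 0.2 of the plant (Monte-Carlo)
  cfg <- synthConfig(m = 80, n_hc_discovery = 100, n_hc_replication = 10,
                     n_cteph_discovery = 100, n_cteph_replication = 10,
                     n_dc = 5, n_cted = 5, n_ipah = 5,
                     fraction_affected = 0.2, prob_up = 1,
                     effect_up = c(1.5, 1.5),
                     tier_probs = c(vs_all_including_IPAH = 1),
                     seed = 30)
  smds <- c()
  for (r in 1:12) {
    g <- generateCohort(cfg, seed = 30 + r)
    z <- quiet_preprocess(g$experiment, qn = FALSE)
    cd <- SummarizedExperiment::colData(z)
    cases <- colnames(z)[cd$group == "CTEPH" & cd$cohort == "discovery"]
    ctrls <- colnames(z)[cd$group == "HC" & cd$cohort == "discovery"]
    planted <- intersect(unique(g$truth@affected$metabolite), rownames(z))
    m <- intensity(z)
    smds <- c(smds, vapply(planted, function(mm) {
      a <- m[mm, cases]; b <- m[mm, ctrls]
      (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
    }, numeric(1)))
  }
  expect_equal(mean(smds), 1.5, tolerance = 0.2 / 1.5)
})

test_that("paired surgery arm encodes the planted correction fractions", {
  ## full correction returns the post group to the healthy-control level;
  ## zero correction leaves pre and post alike
  cfg <- small_cfg(fraction_responsive = 1, correction_range = c(1, 1),
                   plant_inconsistent = FALSE)
  g <- generatePairedPEA(cfg, seed = 40)
  z <- quiet_preprocess(g$experiment, qn = FALSE)
  cd <- SummarizedExperiment::colData(z)
  post <- colnames(z)[cd$timepoint == "post_PEA"]
  hc <- colnames(z)[cd$group == "HC"]
  planted <- intersect(names(g$truth@correction_fractions), rownames(z))
  m <- intensity(z)
  gap <- vapply(planted, function(mm)
    abs(median(m[mm, post]) - median(m[mm, hc])), numeric(1))
  expect_lt(mean(gap), 0.35)   # within noise of the healthy-control centre

  cfg0 <- small_cfg(fraction_responsive = 0, plant_inconsistent = FALSE)
  g0 <- generatePairedPEA(cfg0, seed = 41)
  z0 <- quiet_preprocess(g0$experiment, qn = FALSE)
  cd0 <- SummarizedExperiment::colData(z0)
  aff <- intersect(unique(g0$truth@affected$metabolite), rownames(z0))
  m0 <- intensity(z0)
  pre0 <- colnames(z0)[cd0$timepoint == "pre_PEA"]
  post0 <- colnames(z0)[cd0$timepoint == "post_PEA"]
  gap0 <- vapply(aff, function(mm)
    median(m0[mm, post0]) - median(m0[mm, pre0]), numeric(1))
  expect_lt(mean(abs(gap0)), 0.35)  # pre and post identical up to noise
})

test_that("tri-site arm plants recoverable gradients with shared subjects", {
  cfg <- small_cfg(n_trisite_cteph = 68, n_trisite_ipah = 18)
  reps <- 8
  est <- truthv <- c()
  for (r in seq_len(reps)) {
    g <- generateTriSite(cfg, seed = 50 + r)
    z <- quiet_preprocess(g$experiment, qn = FALSE)
    cd <- SummarizedExperiment::colData(z)
    tr <- g$truth@site_gradients
    tr <- tr[tr$site_pair == "SVC_PA" & tr$metabolite %in% rownames(z), ]
    svc <- colnames(z)[cd$site == "SVC"]
    pa <- colnames(z)[cd$site == "PA"]
    pa <- pa[match(cd[svc, "subject_id"], cd[pa, "subject_id"])]
    m <- intensity(z)
    est <- c(est, vapply(tr$metabolite, function(mm)
      median(m[mm, pa] - m[mm, svc]), numeric(1)))
    truthv <- c(truthv, tr$offset)
  }
  ## planted SVC->PA offsets recovered within 0.1 on average
  expect_lt(mean(abs(est - truthv)), 0.1)

  ## zero planted gradients: paired differences centred at zero
  g0 <- generateTriSite(small_cfg(fraction_gradient = 0), seed = 60)
  z0 <- quiet_preprocess(g0$experiment, qn = FALSE)
  cd0 <- SummarizedExperiment::colData(z0)
  m0 <- intensity(z0)
  svc <- colnames(z0)[cd0$site == "SVC"]
  pa <- colnames(z0)[cd0$site == "PA"]
  pa <- pa[match(cd0[svc, "subject_id"], cd0[pa, "subject_id"])]
  expect_lt(abs(mean(m0[, pa] - m0[, svc])), 0.05)
  expect_identical(nrow(g0$truth@site_gradients), 0L)
})

test_that("subject effects give paired tests power that unpaired tests lack", {
  ## small offsets against large between-subject variation: the paired test
  ## detects them, the unpaired test on the same samples does not
  cfg <- small_cfg(fraction_gradient = 0.3, gradient_range = c(0.12, 0.12),
                   site_residual_sd = 0.05,
                   n_trisite_cteph = 60, n_trisite_ipah = 15)
  g <- generateTriSite(cfg, seed = 70)
  z <- quiet_preprocess(g$experiment, qn = FALSE)
  cd <- SummarizedExperiment::colData(z)
  tr <- g$truth@site_gradients
  planted <- tr$metabolite[tr$site_pair == "SVC_PA"]
  planted <- intersect(planted, rownames(z))
  svc <- colnames(z)[cd$site == "SVC"]
  pa <- colnames(z)[cd$site == "PA"]
  pa <- pa[match(cd[svc, "subject_id"], cd[pa, "subject_id"])]
  m <- intensity(z)
  p_paired <- vapply(planted, function(mm)
    wilcoxonSignedRank(m[mm, svc], m[mm, pa])$p, numeric(1))
  p_unpaired <- vapply(planted, function(mm)
    mannWhitney(m[mm, pa], m[mm, svc])$p, numeric(1))
  expect_gt(mean(p_paired < 0.05), mean(p_unpaired < 0.05) + 0.3)
})
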
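mk_raw <- function(m, colData = NULL, rowData = NULL)
  MetabExperiment(m, colData = colData, rowData = rowData)

test_that("minimum-detected imputation fills censored cells per metabolite", {
  m <- rbind(metA = c(5, NA, 7), metB = c(1, 2, 3), metC = c(NA, NA, NA))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(imp <- imputeMinDetected(mk_raw(m)), "no detected value")
  expect_equal(unname(intensity(imp)["metA", ]), c(5, 5, 7))
  expect_equal(unname(intensity(imp)["metB", ]), c(1, 2, 3))
  expect_false("metC" %in% rownames(imp))
  ## the pre-imputation mask survives for the detection filter
  expect_equal(sum(!detectionMask(imp)), 1L)
  expect_match(processingLog(imp), "all-missing", all = FALSE)
})

test_that("detection filter keeps non-xenobiotics at or above threshold", {
  ## 20 samples: metA 19/20 = 95% (kept, inclusive boundary);
  ## 100 samples would give 94%: use metB 94/100 via a second experiment
  m <- matrix(rlnorm(3 * 20), 3, 20,
              dimnames = list(c("metA", "metB", "metX"), paste0("s", 1:20)))
  m["metA", 1] <- NA
  rd <- S4Vectors::DataFrame(xenobiotic = c(FALSE, FALSE, TRUE),
                             row.names = rownames(m))
  kept <- detectionFilter(imputeMinDetected(mk_raw(m, rowData = rd)))
  expect_true("metA" %in% rownames(kept))   # exactly 95% detected
  expect_true("metB" %in% rownames(kept))
  expect_false("metX" %in% rownames(kept))  # xenobiotic at 100% detection

  m2 <- matrix(rlnorm(100), 1, 100,
               dimnames = list("metB", paste0("s", 1:100)))
  m2[1, 1:6] <- NA                          # 94% detected
  kept2 <- detectionFilter(imputeMinDetected(mk_raw(m2)))
  expect_identical(nrow(kept2), 0L)

  expect_error(detectionFilter(imputeMinDetected(mk_raw(m)), threshold = 0),
               "threshold")
})

test_that("Box-Cox transform has the right closed forms and likelihood fit", {
  m <- rbind(metA = c(3, 4, 5), metB = exp(c(1, 2, 3)))
  colnames(m) <- paste0("s", 1:3)
  e <- toy_experiment(m)
  p1 <- data.frame(metabolite = c("metA", "metB"), lambda = c(1, 0),
                   shift = c(0, 0))
  tr <- applyBoxCox(e, p1)
  expect_equal(unname(intensity(tr)["metA", ]), c(2, 3, 4))  # (x-1)/1
  expect_equal(unname(intensity(tr)["metB", ]), c(1, 2, 3))  # ln x

  ## log-normal data: profile-likelihood argmax lands on lambda = 0,
  ## matching a dense-grid reference fit
  set.seed(21)
  v <- matrix(rlnorm(500, 2, 0.5), 1,
              dimnames = list("m1", paste0("s", 1:500)))
  fit <- fitBoxCox(toy_experiment(v))
  expect_equal(fit$lambda, 0, tolerance = 0.1 + 1e-9)
  bx_df <- data.frame(y = as.vector(v))
  ref <- MASS::boxcox(y ~ 1, data = bx_df, lambda = seq(-2, 2, 0.1),
                      plotit = FALSE)
  expect_equal(fit$lambda, ref$x[which.max(ref$y)])

  ## monotonicity: rank order of samples preserved for every metabolite,
  ## so rank tests are invariant to the fitted lambda
  set.seed(22)
  mm <- matrix(rlnorm(200, 3, 1), 4,
               dimnames = list(paste0("m", 1:4), paste0("s", 1:50)))
  ee <- toy_experiment(mm)
  tt <- applyBoxCox(ee)
  for (i in 1:4)
    expect_identical(order(intensity(tt)[i, ]), order(mm[i, ]))
})

test_that("z-scoring to healthy controls gives exact reference moments", {
  m <- rbind(metA = c(1, 2, 3, 4), metB = c(10, 20, 30, 2))
  colnames(m) <- c("h1", "h2", "h3", "p1")
  cd <- S4Vectors::DataFrame(group = c("HC", "HC", "HC", "CTEPH"),
                             row.names = colnames(m))
  z <- zscoreToReference(toy_experiment(m, colData = cd))
  ## HC values (1,2,3): patient 4 -> z = 2
  expect_equal(unname(intensity(z)["metA", "p1"]), 2)
  hc <- intensity(z)[, c("h1", "h2", "h3")]
  expect_equal(unname(rowMeans(hc)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(hc, 1, sd)), c(1, 1), tolerance = 1e-12)
  st <- referenceStats(z)
  expect_equal(st$mean_hc, c(2, 20))

  ## constant-reference metabolite excluded
  m2 <- rbind(metC = c(5, 5, 5, 9), m)
  cd2 <- cd
  expect_warning(z2 <- zscoreToReference(
    toy_experiment(m2, colData = cd2)), "zero reference sd")
  expect_false("metC" %in% rownames(z2))
})

test_that("quantile normalisation maps samples onto mean order statistics", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("met", 1:3)
  q <- intensity(quantileNormalise(toy_experiment(m)))
  expect_equal(unname(q[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "s2"]), c(2.5, 3.5, 4.5))

  ## identical samples are a fixed point
  m2 <- cbind(s1 = c(2, 7, 4), s2 = c(2, 7, 4))
  rownames(m2) <- paste0("met", 1:3)
  expect_equal(intensity(quantileNormalise(toy_experiment(m2))), m2)

  ## defining property: every sample shares the sorted value vector, and
  ## normalising twice equals once
  set.seed(23)
  m3 <- matrix(rnorm(15 * 8), 15, 8,
               dimnames = list(paste0("m", 1:15), paste0("s", 1:8)))
  q3 <- quantileNormalise(toy_experiment(m3))
  sorted <- apply(intensity(q3), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  q3b <- quantileNormalise(toy_experiment(intensity(q3)))
  expect_equal(intensity(q3b), intensity(q3), tolerance = 1e-12)

  ## agrees with the limma reference implementation on continuous data
  expect_equal(intensity(q3), limma::normalizeQuantiles(m3),
               tolerance = 1e-12)

  ## tie handling: mean of spanned reference values preserves sample means
  m4 <- cbind(s1 = c(1, 1, 5), s2 = c(2, 4, 9))
  rownames(m4) <- paste0("m", 1:3)
  q4 <- intensity(quantileNormalise(toy_experiment(m4)))
  expect_equal(unname(q4[1:2, "s1"]), rep(mean(c(1.5, 2.5)), 2))
})

test_that("the full chain enforces order and preserves rank-test results", {
  cfg <- small_cfg()
  g <- generateCohort(cfg)
  z <- quiet_preprocess(g$experiment)
  expect_identical(scaleTag(z), "quantile_normalised")
  ## filtered object only contains non-xenobiotic, well-detected metabolites
  rd <- SummarizedExperiment::rowData(z)
  expect_true(all(!rd$xenobiotic))
  ## a Mann-Whitney on the boxcox scale equals one computed on z-scores
  ## (strictly monotone per-metabolite maps)
  z_noqn <- quiet_preprocess(g$experiment, qn = FALSE)
  cases <- colnames(z_noqn)[SummarizedExperiment::colData(z_noqn)$group == "CTEPH"]
  ctrls <- colnames(z_noqn)[SummarizedExperiment::colData(z_noqn)$group == "HC"]
  mm <- rownames(z_noqn)[1]
  raw_vals <- intensity(imputeMinDetected(g$experiment))[mm, ]
  p_raw <- mannWhitney(raw_vals[cases], raw_vals[ctrls])$p
  p_z <- mannWhitney(intensity(z_noqn)[mm, cases],
                     intensity(z_noqn)[mm, ctrls])$p
  expect_equal(p_raw, p_z)
})
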
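site_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generateTriSite(small_cfg(), seed = 120)
      z <- quiet_preprocess(g$experiment, qn = FALSE)
      cache <<- list(g = g, z = z, gt = siteGradients(z))
    }
    cache
  }
})

test_that("gradients are detected in the planted site pairs", {
  fx <- site_fixture()
  gt <- fx$gt
  tr <- fx$g$truth@site_gradients
  key_t <- paste(tr$metabolite, tr$site_pair)
  key_g <- paste(gt$metabolite, gt$site_pair)
  is_true <- key_g %in% key_t
  ## sensitivity high where planted, significance rare elsewhere
  expect_gt(mean(gt$significant[is_true]), 0.8)
  expect_lt(mean(gt$significant[!is_true]), 0.1)
  ## median differences track the planted offsets
  m <- merge(gt, tr, by = c("metabolite", "site_pair"))
  expect_gt(cor(m$median_diff, m$offset), 0.9)
  ## a metabolite planted in both segments is significant in all three
  both <- intersect(tr$metabolite[tr$site_pair == "SVC_PA"],
                    tr$metabolite[tr$site_pair == "PA_ART"])
  both <- intersect(both, gt$metabolite)
  if (length(both)) {
    tri <- gt[gt$metabolite %in% both & gt$significant, ]
    expect_gt(mean(table(tri$metabolite) == 3), 0.4)
  }
})

test_that("permuting sites within subject destroys gradient significance", {
  fx <- site_fixture()
  z <- fx$z
  cd <- SummarizedExperiment::colData(z)
  set.seed(121)
  patient <- which(cd$site != "none")
  ## shuffle site labels within each subject
  new_site <- as.character(cd$site)
  for (s in unique(cd$subject_id[patient])) {
    idx <- patient[cd$subject_id[patient] == s]
    new_site[idx] <- sample(new_site[idx])
  }
  cd$site <- new_site
  SummarizedExperiment::colData(z) <- cd
  gt_perm <- siteGradients(z)
  expect_lt(mean(gt_perm$significant), 0.07)
})

test_that("mean site differences close the three-site cycle exactly", {
  fx <- site_fixture()
  z <- fx$z
  cd <- SummarizedExperiment::colData(z)
  m <- intensity(z)
  ids <- function(s) colnames(z)[cd$site == s]
  svc <- ids("SVC"); subj <- cd[svc, "subject_id"]
  pa <- ids("PA")[match(subj, cd[ids("PA"), "subject_id"])]
  art <- ids("ART")[match(subj, cd[ids("ART"), "subject_id"])]
  cyc <- rowMeans(m[, pa] - m[, svc]) + rowMeans(m[, art] - m[, pa]) +
    rowMeans(m[, svc] - m[, art])
  expect_lt(max(abs(cyc)), 1e-12)
})

test_that("site pairs with too few complete pairs are skipped", {
  fx <- site_fixture()
  z <- fx$z
  cd <- SummarizedExperiment::colData(z)
  keep <- cd$site != "ART"
  ws <- testthat::capture_warnings(gt <- siteGradients(z[, keep]))
  expect_match(ws, "skipped", all = TRUE)
  expect_length(ws, 2)   # both ART-containing pairs
  expect_identical(sort(unique(gt$site_pair)), "SVC_PA")
})

test_that("pathway enrichment equals the hypergeometric tail", {
  ## pathway entirely significant, nothing else: p = 1 / C(100, 5)
  ann <- data.frame(metabolite_id = sprintf("m%03d", 1:100),
                    subpathway = c(rep("P1", 5), rep("P0", 95)),
                    superpathway = "S", stringsAsFactors = FALSE)
  gt <- data.frame(metabolite = ann$metabolite_id, site_pair = "SVC_PA",
                   significant = c(rep(TRUE, 5), rep(FALSE, 95)),
                   stringsAsFactors = FALSE)
  er <- pathwayEnrichment(gt, ann, min_size = 4)
  expect_equal(er$p[er$pathway == "P1"], 1 / choose(100, 5),
               tolerance = 1e-12)
  ## empty significant set: all p = 1
  gt0 <- gt; gt0$significant <- FALSE
  expect_true(all(pathwayEnrichment(gt0, ann)$p == 1))
  ## pathways under the size floor are excluded
  ann3 <- ann; ann3$subpathway[1:5] <- c(rep("P1", 3), "P0", "P0")
  er3 <- pathwayEnrichment(gt, ann3, min_size = 4)
  expect_false("P1" %in% er3$pathway)
  ## random tables match the dhyper oracle
  set.seed(122)
  for (rep in 1:30) {
    N <- sample(10:60, 1); K <- sample(4:(N - 1), 1)
    n <- sample(0:N, 1)
    ann_r <- data.frame(metabolite_id = sprintf("m%03d", 1:N),
                        subpathway = c(rep("P1", K), rep("P0", N - K)),
                        superpathway = "S", stringsAsFactors = FALSE)
    sig <- rep(FALSE, N); sig[sample(N, n)] <- TRUE
    gt_r <- data.frame(metabolite = ann_r$metabolite_id,
                       site_pair = "PA_ART", significant = sig,
                       stringsAsFactors = FALSE)
    er_r <- pathwayEnrichment(gt_r, ann_r, min_size = 4)
    k <- sum(sig[1:K])
    expect_equal(er_r$p[er_r$pathway == "P1"], fisher_oracle(k, K, n, N),
                 tolerance = 1e-9)
  }
})

test_that("relevance network equals a brute-force correlation scan", {
  fx <- site_fixture()
  z <- fx$z
  mets <- rownames(z)[1:30]
  net <- relevanceNetwork(z, mets, rho_threshold = 0.5)
  m <- intensity(z)[mets, ]
  ## brute force over all pairs
  expected <- list()
  for (i in seq_along(mets)) for (j in seq_along(mets)) {
    if (i >= j) next
    rho <- cor(m[i, ], m[j, ], method = "spearman")
    if (rho > 0.5)
      expected[[length(expected) + 1L]] <-
        data.frame(from = mets[i], to = mets[j], rho = rho)
  }
  expected <- if (length(expected)) do.call(rbind, expected) else
    data.frame(from = character(), to = character(), rho = numeric())
  expected <- expected[order(expected$from, expected$to), ]
  rownames(expected) <- NULL
  expect_equal(net$edges, expected, tolerance = 1e-12)
  ## a duplicated metabolite is a guaranteed rho = 1 edge
  m2 <- intensity(z)[mets[1:2], ]
  m2 <- rbind(m2, dup = m2[1, ])
  rownames(m2)[3] <- "dup"
  e2 <- MetabExperiment(m2, scale_tag = "zscore")
  net2 <- relevanceNetwork(e2, rownames(m2), rho_threshold = 0.9)
  expect_true(any(net2$edges$from == mets[1] & net2$edges$to == "dup" |
                    net2$edges$from == "dup" & net2$edges$to == mets[1]))
  ## components: connected nodes share a label
  if (nrow(net2$edges)) {
    comp <- net2$components
    lab <- setNames(comp$component, comp$metabolite)
    expect_true(all(lab[net2$edges$from] == lab[net2$edges$to]))
  }
})

test_that("independent noise at cohort scale yields no spurious edges", {
  set.seed(123)
  m <- matrix(rnorm(40 * 258), 40, 258,
              dimnames = list(sprintf("m%02d", 1:40), sprintf("s%03d", 1:258)))
  e <- MetabExperiment(m, scale_tag = "zscore")
  net <- relevanceNetwork(e, rownames(e), rho_threshold = 0.9)
  expect_identical(nrow(net$edges), 0L)
})

test_that("clinical correlations match the closed-form rank statistic", {
  ## monotone construction: rho = 1
  n <- 20
  walk <- seq(100, 480, length.out = n)
  m <- matrix(log(walk) + 2, 1, n,
              dimnames = list("met_mono", sprintf("s%02d", 1:n)))
  cd <- S4Vectors::DataFrame(walk_6m = walk, row.names = colnames(m))
  e <- MetabExperiment(m, colData = cd, scale_tag = "zscore")
  cc <- clinicalCorrelations(e, "met_mono", "walk_6m")
  expect_equal(cc$rho, 1)
  ## 10-sample no-ties fixture vs 1 - 6 sum d^2 / (n (n^2-1))
  set.seed(124)
  y <- sample(10); v <- sample(10) + runif(10, 0, 0.1)
  m2 <- matrix(y, 1, 10, dimnames = list("met_a", sprintf("t%02d", 1:10)))
  cd2 <- S4Vectors::DataFrame(mRAP = v, row.names = colnames(m2))
  e2 <- MetabExperiment(m2, colData = cd2, scale_tag = "zscore")
  cc2 <- clinicalCorrelations(e2, "met_a", "mRAP")
  d <- rank(y) - rank(v)
  expect_equal(cc2$rho, 1 - 6 * sum(d^2) / (10 * (100 - 1)),
               tolerance = 1e-12)
  ## symmetry of the correlation
  expect_equal(cc2$rho, cor(v, y, method = "spearman"), tolerance = 1e-12)
})
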
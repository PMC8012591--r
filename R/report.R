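## Orchestration: full synthetic-study pipeline, cross-analysis overlap
## sets, CSV outputs and a JSON run manifest.

#' Overlap of named metabolite sets
#'
#' Exact set algebra over named metabolite sets: all pairwise and triple
#' intersections with counts and sorted member lists.
#'
#' @param sets named list of character vectors.
#' @return list with `sets` (sorted, deduplicated inputs), `counts`,
#'   `intersections` (named list over pairs and triples, names joined with
#'   `" & "`).
#' @export
overlapSets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  nm <- names(sets)
  inter <- list()
  for (k in 2:3) {
    if (length(sets) < k) break
    for (ix in as.data.frame(combn(length(sets), k))) {
      members <- Reduce(intersect, sets[ix])
      inter[[paste(nm[ix], collapse = " & ")]] <- members
    }
  }
  list(sets = sets,
       counts = vapply(sets, length, integer(1)),
       intersections = inter,
       intersection_counts = vapply(inter, length, integer(1)))
}

#' Run the full synthetic-study pipeline
#'
#' Generates the three synthetic arms (main cohort, surgery, tri-site) from
#' one configuration, preprocesses each, and runs the complete analysis
#' cascade: discovery/replication tiers, ROC evaluation of the tier
#' metabolites, the two-stage surgery screen with percent correction, site
#' gradients with pathway enrichment, the relevance network and
#' clinical-severity correlations, and the cross-analysis overlap sets.
#' With `out_dir` set, every table is written as CSV together with a JSON
#' run manifest recording the configuration, seed, package version, the
#' documented analysis decisions and an md5 of every file; identical
#' configuration and seed give identical outputs.
#'
#' @param cfg a [synthConfig()] configuration.
#' @param seed integer seed; the three arms use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param out_dir optional output directory.
#' @param qn,qn_position,detection_threshold passed to [preprocess()].
#' @param alpha,fdr significance levels for the cascades.
#' @return list with `tiers`, `differential`, `roc`, `pea`, `gradients`,
#'   `enrichment`, `network`, `clinical`, `overlap`, `truth` (the three
#'   ledgers) and `manifest`.
#' @export
runPipeline <- function(cfg = synthConfig(), seed = cfg$seed,
                        out_dir = NULL, qn = TRUE,
                        qn_position = "last", detection_threshold = 0.95,
                        alpha = 0.05, fdr = 0.05) {
  arm_cohort <- generateCohort(cfg, seed)
  arm_pea <- generatePairedPEA(cfg, seed + 1L)
  arm_site <- generateTriSite(cfg, seed + 2L)
  pp <- function(e) preprocess(e, detection_threshold, qn = qn,
                               qn_position = qn_position)
  z_cohort <- pp(arm_cohort$experiment)
  z_pea <- pp(arm_pea$experiment)
  z_site <- pp(arm_site$experiment)

  tiers <- tierClassify(z_cohort, alpha = alpha)
  tier_ids <- tiers$tiers$metabolite[tiers$tiers$tier != "none"]
  roc_tab <- if (length(tier_ids)) rocTable(z_cohort, tier_ids) else NULL
  pea_tab <- peaScreen(z_pea, alpha = alpha, fdr = fdr)
  grad_tab <- siteGradients(z_site, fdr = fdr)
  enrich <- pathwayEnrichment(grad_tab,
                              SummarizedExperiment::rowData(z_site))
  sig_grad <- unique(grad_tab$metabolite[grad_tab$significant])
  patient_samples <- colnames(z_site)[
    SummarizedExperiment::colData(z_site)$site != "none"]
  net <- if (length(sig_grad) >= 2L)
    relevanceNetwork(z_site, sig_grad, samples = patient_samples)
  else list(edges = data.frame(from = character(), to = character(),
                               rho = numeric()),
            components = data.frame(metabolite = character(),
                                    component = integer()))
  clin <- if (length(sig_grad))
    clinicalCorrelations(z_site[, patient_samples], sig_grad)
  else NULL
  grad_sets <- split(grad_tab$metabolite[grad_tab$significant],
                     grad_tab$site_pair[grad_tab$significant])
  overlap <- overlapSets(c(
    list(cteph_associated = tier_ids,
         pea_responsive = pea_tab$metabolite[pea_tab$significant_nominal]),
    lapply(.SITE_PAIRS, function(p)
      grad_sets[[p]] %||% character()) |> setNames(
        paste0("gradient_", .SITE_PAIRS))))

  manifest <- list(
    package = "metabograd",
    version = as.character(packageVersion("metabograd")),
    seed = seed,
    config = unclass(cfg),
    decisions = list(
      qn = qn, qn_position = qn_position,
      detection_threshold = detection_threshold,
      alpha = alpha, fdr = fdr,
      gradient_sign = "downstream_minus_upstream",
      cutoff_criterion = "youden_j",
      auc_ci = "delong",
      stage1_correction = "bonferroni",
      stage2_correction = "benjamini_hochberg",
      renal_cutoff_umol_l = 75, liver_cutoff_umol_l = 21))

  res <- list(tiers = tiers$tiers, differential = tiers$differential,
              adjusted = tiers$adjusted, roc = roc_tab, pea = pea_tab,
              gradients = grad_tab, enrichment = enrich, network = net,
              clinical = clin, overlap = overlap,
              truth = list(cohort = arm_cohort$truth, pea = arm_pea$truth,
                           trisite = arm_site$truth),
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name) {
      if (is.null(tab) || !nrow(tab)) return(invisible(NULL))
      writeTable(tab, file.path(out_dir, paste0(name, ".csv")))
    }
    wr(res$tiers, "tiers"); wr(res$differential, "differential")
    wr(res$roc, "roc"); wr(res$pea, "pea"); wr(res$gradients, "gradients")
    wr(res$enrichment, "enrichment"); wr(res$network$edges, "network_edges")
    wr(res$network$components, "network_components")
    wr(res$clinical, "clinical_correlations")
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$files <- lapply(setNames(files, basename(files)),
                             function(f) unname(tools::md5sum(f)))
    manifest$overlap_counts <- as.list(res$overlap$intersection_counts)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    res$manifest <- manifest
  }
  res
}
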
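## Tri-site gradient analysis: paired Wilcoxon tests of between-site
## differences with FDR control per site pair, Fisher's-exact pathway
## enrichment, Spearman relevance networks, and clinical-severity
## correlations.

## downstream minus upstream following flow SVC -> PA -> ART -> (systemic
## return to) SVC
.PAIR_DEF <- list(SVC_PA = c(up = "SVC", down = "PA"),
                  PA_ART = c(up = "PA", down = "ART"),
                  ART_SVC = c(up = "ART", down = "SVC"))

#' Between-site metabolite gradients
#'
#' For each metabolite and each site pair (SVC to PA, PA to ART, ART back to
#' SVC), the paired Wilcoxon signed-rank test on downstream-minus-upstream
#' differences over subjects sampled at both sites, with Benjamini-Hochberg
#' adjustment across metabolites within each site pair.  The effect reported
#' is the median paired difference (z-units).  Site pairs with fewer than 5
#' complete subject pairs are skipped with a warning.
#'
#' @param x a z-scored [MetabExperiment-class] whose `colData` carries
#'   `subject_id` and `site` (`SVC`/`PA`/`ART`).
#' @param fdr significance level on the adjusted p-values.
#' @return data.frame (one row per metabolite x site pair): `median_diff`,
#'   `p`, `p_adj`, `significant`, `n_pairs`.
#' @export
siteGradients <- function(x, fdr = 0.05) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("subject_id", "site") %in% colnames(cd)))
    stop("colData must contain 'subject_id' and 'site'", call. = FALSE)
  m <- intensity(x)
  site_of <- function(s) colnames(x)[cd$site == s]
  out <- list()
  for (pair in names(.PAIR_DEF)) {
    up_site <- .PAIR_DEF[[pair]][["up"]]
    down_site <- .PAIR_DEF[[pair]][["down"]]
    up_ids <- site_of(up_site); down_ids <- site_of(down_site)
    common <- intersect(cd$subject_id[match(up_ids, colnames(x))],
                        cd$subject_id[match(down_ids, colnames(x))])
    if (length(common) < 5L) {
      warning("site pair ", pair, " skipped: only ", length(common),
              " complete pair(s)", call. = FALSE)
      next
    }
    up_use <- up_ids[match(common, cd$subject_id[match(up_ids,
                                                       colnames(x))])]
    down_use <- down_ids[match(common, cd$subject_id[match(down_ids,
                                                           colnames(x))])]
    res <- t(vapply(rownames(m), function(mm) {
      up_v <- m[mm, up_use]; down_v <- m[mm, down_use]
      w <- wilcoxonSignedRank(up_v, down_v)   # differences down - up
      c(median_diff = median(down_v - up_v), p = w$p)
    }, numeric(2)))
    out[[pair]] <- data.frame(
      metabolite = rownames(m), site_pair = pair,
      median_diff = res[, "median_diff"], p = res[, "p"],
      p_adj = benjaminiHochberg(res[, "p"]),
      n_pairs = length(common), row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out$significant <- out$p_adj < fdr
  out
}

#' Pathway enrichment of gradient metabolites
#'
#' Per site pair, a two-sided Fisher's exact test on the 2x2 table
#' significant-gradient x pathway-membership, with all metabolites tested in
#' that pair as background.  Pathways represented by fewer than `min_size`
#' detected metabolites are excluded.
#'
#' @param gradient_table output of [siteGradients()].
#' @param annotation data.frame/DataFrame with `metabolite_id` and the
#'   pathway column named by `level`.
#' @param level `"subpathway"` or `"superpathway"`.
#' @param min_size minimum number of detected metabolites per pathway.
#' @return data.frame: `site_pair`, `pathway`, `k` (significant in pathway),
#'   `K` (pathway size among detected), `n` (significant total), `N`
#'   (detected total), `p`.
#' @export
pathwayEnrichment <- function(gradient_table, annotation,
                              level = c("subpathway", "superpathway"),
                              min_size = 4L) {
  level <- match.arg(level)
  annotation <- as.data.frame(annotation)
  rows <- list()
  for (pair in unique(gradient_table$site_pair)) {
    gt <- gradient_table[gradient_table$site_pair == pair, ]
    path <- annotation[[level]][match(gt$metabolite,
                                      annotation$metabolite_id)]
    keep <- !is.na(path)
    gt <- gt[keep, ]; path <- path[keep]
    N <- nrow(gt)
    n <- sum(gt$significant)
    for (pw in sort(unique(path))) {
      K <- sum(path == pw)
      if (K < min_size) next
      k <- sum(gt$significant & path == pw)
      tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2L)
      p <- fisher.test(tab)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        site_pair = pair, pathway = pw, k = k, K = K, n = n, N = N, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(site_pair = character(), pathway = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Spearman relevance network
#'
#' Undirected graph over a metabolite set, connecting pairs whose Spearman
#' rank correlation across the chosen samples exceeds `rho_threshold`
#' (strictly; set `absolute = TRUE` to threshold |rho| instead), with
#' connected components labelled.
#'
#' @param x a [MetabExperiment-class].
#' @param metabolites node set (e.g. the significant-gradient metabolites).
#' @param samples sample ids to correlate over (default: all).
#' @param rho_threshold edge threshold.
#' @param absolute threshold on |rho| rather than rho.
#' @return list with `edges` (data.frame `from`, `to`, `rho`), `components`
#'   (data.frame `metabolite`, `component`) and the [igraph::graph] object.
#' @export
relevanceNetwork <- function(x, metabolites = rownames(x), samples = NULL,
                             rho_threshold = 0.9, absolute = FALSE) {
  m <- intensity(x)[metabolites, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  rho <- cor(t(m), method = "spearman", use = "pairwise.complete.obs")
  score <- if (absolute) abs(rho) else rho
  score[lower.tri(score, diag = TRUE)] <- -Inf
  idx <- which(score > rho_threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(rho)[idx[, 1L]],
                      to = colnames(rho)[idx[, 2L]],
                      rho = rho[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = metabolites)
  comp <- igraph::components(g)
  list(edges = edges,
       components = data.frame(metabolite = names(comp$membership),
                               component = unname(comp$membership),
                               stringsAsFactors = FALSE),
       graph = g)
}

#' Metabolite-clinical severity correlations
#'
#' Spearman correlation between each metabolite and each clinical variable
#' over the samples where the variable is present.  Variables are
#' rank-normalised (normal scores) first; Spearman's rho is invariant to
#' this, so it only affects reporting scales elsewhere.
#'
#' @param x a z-scored [MetabExperiment-class].
#' @param metabolites metabolite ids to test.
#' @param variables clinical `colData` columns (default: the haemodynamic
#'   and exercise variables present).
#' @return data.frame: `metabolite`, `variable`, `rho`, `p`, `n`.
#' @export
clinicalCorrelations <- function(x, metabolites = rownames(x),
                                 variables = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(variables))
    variables <- intersect(c("mRAP", "mPAP", "PVR", "cardiac_output",
                             "walk_6m"), colnames(cd))
  if (!length(variables)) stop("no clinical variables found", call. = FALSE)
  m <- intensity(x)
  rows <- list()
  for (v in variables) {
    vals <- cd[[v]]
    ok <- !is.na(vals)
    if (sum(ok) < 3L) next
    r <- rank(vals[ok])
    vn <- qnorm((r - 0.5) / length(r))    # rank-normalised variable
    for (mm in metabolites) {
      y <- m[mm, ok]
      ct <- suppressWarnings(cor.test(y, vn, method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = mm, variable = v, rho = unname(ct$estimate),
        p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
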
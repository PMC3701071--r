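## Deterministic sample ordering for heat-map display. Agglomerative
## clustering (stats::dist + stats::hclust) on beta profiles; missing beta
## values are imputed with the probe-wise median for distance computation
## only. Determinism: samples are pre-sorted lexicographically by id so tie
## handling inside hclust is reproducible across input orderings.

#' Cluster samples by methylation profile
#'
#' @param beta probes x samples beta matrix.
#' @param metric distance metric, one of `"euclidean"`, `"manhattan"`,
#'   `"maximum"`.
#' @param linkage agglomeration method, one of `"complete"`, `"average"`,
#'   `"single"`, `"ward.D2"`.
#' @return list of class `clusterResult`: `order` (sample ids, leaf order),
#'   `merge`, `height`, `labels`, `metric`, `linkage`, `hclust` (the
#'   underlying [stats::hclust] object, e.g. for dendrogram export via
#'   [stats::as.dendrogram] or [ape::as.phylo]).
#' @export
clusterSamples <- function(beta, metric = "euclidean", linkage = "complete") {
  metrics <- c("euclidean", "manhattan", "maximum")
  linkages <- c("complete", "average", "single", "ward.D2")
  if (!metric %in% metrics)
    stop("unknown metric '", metric, "'; supported: ",
         paste(metrics, collapse = ", "))
  if (!linkage %in% linkages)
    stop("unknown linkage '", linkage, "'; supported: ",
         paste(linkages, collapse = ", "))
  if (ncol(beta) < 2L) stop("need >= 2 samples to cluster")
  beta <- beta[, order(colnames(beta)), drop = FALSE]
  ## probe-wise median imputation, distances only
  for (i in seq_len(nrow(beta))) {
    miss <- is.na(beta[i, ])
    if (any(miss)) beta[i, miss] <- stats::median(beta[i, ], na.rm = TRUE)
  }
  if (anyNA(beta)) stop("probe(s) with all values missing cannot be imputed")
  hc <- stats::hclust(stats::dist(t(beta), method = metric), method = linkage)
  structure(list(order = hc$labels[hc$order], merge = hc$merge,
                 height = hc$height, labels = hc$labels, metric = metric,
                 linkage = linkage, hclust = hc),
            class = "clusterResult")
}

#' @export
print.clusterResult <- function(x, ...) {
  cat("clusterResult:", length(x$order), "samples,", x$metric, "distance,",
      x$linkage, "linkage\n")
  invisible(x)
}

#' Export aligned heat-map tracks in cluster order
#'
#' Produces the display bundle: the beta matrix with columns in cluster
#' order, the expression track, and the sample annotation track (tissue,
#' ER/HER2 status), all sharing one column order. Normal samples can be
#' displayed as their own unclustered block after the ordered tumors.
#'
#' @param cohort a [MethylCohort-class].
#' @param order a `clusterResult` (or character vector of sample ids) whose
#'   samples all belong to the cohort.
#' @param calls optional [MethylCalls-class]; adds an island-site-count row
#'   to the annotation track for tumor samples.
#' @param normalsSeparate append normal samples as a trailing unclustered
#'   block (only meaningful when `order` covers the tumors alone).
#' @return list: `beta` (ordered matrix), `expression` (named vector),
#'   `annotation` (`data.frame`, one row per sample, same order).
#' @export
exportHeatmapTable <- function(cohort, order, calls = NULL,
                               normalsSeparate = FALSE) {
  stopifnot(is(cohort, "MethylCohort"))
  ord <- if (inherits(order, "clusterResult")) order$order else order
  if (!all(ord %in% colnames(cohort)))
    stop("ordering contains sample(s) not in the cohort: ",
         paste(setdiff(ord, colnames(cohort)), collapse = ", "))
  if (anyDuplicated(ord)) stop("ordering repeats sample id(s)")
  if (normalsSeparate) {
    ord <- c(setdiff(ord, normalSamples(cohort)),
             sort(intersect(normalSamples(cohort), colnames(cohort))))
  }
  smp <- sampleInfo(cohort)
  ann <- smp[match(ord, smp$sample_id),
             c("sample_id", "tissue", "er_status", "her2_status"),
             drop = FALSE]
  rownames(ann) <- NULL
  if (!is.null(calls)) {
    cnt <- islandSiteCounts(calls)
    ann$island_site_count <- unname(cnt[ann$sample_id])
  }
  list(beta = betaValues(cohort)[, ord, drop = FALSE],
       expression = geneExpression(cohort)[ord],
       annotation = ann)
}

#' Tumor/normal box-plot summaries per island probe
#'
#' For each island probe and tissue group: median, quartiles (R default
#' type-7 quantiles), whisker bounds under the 1.5 x IQR rule (most extreme
#' observation inside the fences), and the outliers beyond them.
#'
#' @param beta probes x samples beta matrix.
#' @param samples sample `data.frame` with `sample_id`, `tissue`.
#' @param regions a [ProbeRegions-class]; summaries cover its island probes.
#' @return `data.frame` with columns `probe_id`, `tissue`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers`
#'   (comma-separated values as character).
#' @export
groupwiseBoxplotTable <- function(beta, samples, regions) {
  stopifnot(is(regions, "ProbeRegions"))
  samples <- .normalizeSampleTable(samples)
  isl <- intersect(regions@island, rownames(beta))
  tis <- stats::setNames(samples$tissue, samples$sample_id)
  rows <- list()
  for (p in isl) for (g in c("tumor", "normal")) {
    v <- beta[p, names(tis)[tis == g]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lowFence <- q[1] - 1.5 * iqr
    highFence <- q[3] + 1.5 * iqr
    inside <- v[v >= lowFence & v <= highFence]
    out <- sort(v[v < lowFence | v > highFence])
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = p, tissue = g, n = length(v), median = q[2],
      q1 = q[1], q3 = q[3],
      whisker_low = min(inside), whisker_high = max(inside),
      outliers = paste(.fmtNum(out), collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
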
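#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' Cohort container: beta values, expression, sample and probe metadata
#'
#' A `MethylCohort` is a [SummarizedExperiment::SummarizedExperiment] holding
#' one `"beta"` assay (probes x samples, values in \[0, 1\], `NA` permitted),
#' probe annotation as `rowData` (`distance_from_tss`, `in_cpg_island`,
#' `snp_flagged`), and sample metadata as `colData` (`tissue`, `pair_id`,
#' `er_status`, `her2_status`, plus the per-sample `expression` score for the
#' gene under study).
#'
#' Expression values are consumed as-is (platform-normalised, log scale);
#' the pipeline treats them as an opaque monotone score.
#'
#' @export
setClass("MethylCohort", contains = "SummarizedExperiment")

setValidity("MethylCohort", function(object) {
  msgs <- character()
  if (!"beta" %in% names(assays(object)))
    msgs <- c(msgs, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- !is.na(b) & (b < 0 | b > 1)
    if (any(bad))
      msgs <- c(msgs, sprintf("%d beta value(s) outside [0, 1]", sum(bad)))
  }
  rd <- rowData(object)
  need_rd <- c("distance_from_tss", "in_cpg_island", "snp_flagged")
  miss <- setdiff(need_rd, colnames(rd))
  if (length(miss))
    msgs <- c(msgs, paste0("rowData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  cd <- colData(object)
  need_cd <- c("tissue", "er_status", "her2_status", "expression")
  miss <- setdiff(need_cd, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if ("tissue" %in% colnames(cd) &&
      !all(cd$tissue %in% c("tumor", "normal")))
    msgs <- c(msgs, "tissue must be 'tumor' or 'normal'")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "probe ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylCohort
#'
#' @param beta numeric matrix of beta values, probes x samples, rownames =
#'   probe ids, colnames = sample ids.
#' @param expression named numeric vector of per-sample expression for the
#'   gene under study; names must cover the samples of `beta`.
#' @param samples `data.frame` with columns `sample_id`, `tissue`
#'   (`tumor`/`normal`), and optionally `pair_id`, `er_status`, `her2_status`.
#' @param annotation `data.frame` with columns `probe_id`,
#'   `distance_from_tss`, `in_cpg_island`, `snp_flagged` (and optionally
#'   `chromosome`, `position`).
#'
#' @return A [MethylCohort-class] object.
#' @seealso [alignCohort()] to build a cohort from partially overlapping
#'   sources.
#' @export
MethylCohort <- function(beta, expression, samples, annotation) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  annotation <- .normalizeAnnotation(annotation)
  samples <- .normalizeSampleTable(samples)
  sid <- colnames(beta)
  if (!all(sid %in% samples$sample_id))
    stop("samples missing from sample table: ",
         paste(setdiff(sid, samples$sample_id), collapse = ", "))
  if (!all(sid %in% names(expression)))
    stop("samples missing from expression vector: ",
         paste(setdiff(sid, names(expression)), collapse = ", "))
  if (!all(rownames(beta) %in% annotation$probe_id))
    stop("probes missing from annotation: ",
         paste(setdiff(rownames(beta), annotation$probe_id), collapse = ", "))
  ann <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  smp <- samples[match(sid, samples$sample_id), , drop = FALSE]
  cd <- DataFrame(smp[setdiff(colnames(smp), "sample_id")],
                  row.names = smp$sample_id)
  cd$expression <- unname(expression[sid])
  rd <- DataFrame(ann[setdiff(colnames(ann), "probe_id")],
                  row.names = ann$probe_id)
  se <- SummarizedExperiment(assays = list(beta = beta),
                             rowData = rd, colData = cd)
  new("MethylCohort", se)
}

#' @describeIn MethylCohort-class beta-value matrix (probes x samples)
#' @param object,x a `MethylCohort`
#' @export
betaValues <- function(x) assay(x, "beta")

#' @describeIn MethylCohort-class per-sample expression, named numeric vector
#' @export
geneExpression <- function(x) {
  e <- colData(x)$expression
  names(e) <- colnames(x)
  e
}

#' @describeIn MethylCohort-class sample metadata as a data.frame with a
#'   `sample_id` column
#' @export
sampleInfo <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample_id = rownames(cd), cd[setdiff(colnames(cd), "expression")],
        row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn MethylCohort-class probe annotation as a data.frame with a
#'   `probe_id` column
#' @export
probeInfo <- function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(probe_id = rownames(rd), rd, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' @describeIn MethylCohort-class sample ids of tumor samples
#' @export
tumorSamples <- function(x) colnames(x)[colData(x)$tissue == "tumor"]

#' @describeIn MethylCohort-class sample ids of normal samples
#' @export
normalSamples <- function(x) colnames(x)[colData(x)$tissue == "normal"]

setMethod("show", "MethylCohort", function(object) {
  cat("MethylCohort:", nrow(object), "probes x", ncol(object), "samples\n")
  tis <- colData(object)$tissue
  cat("  tumors:", sum(tis == "tumor"), " normals:", sum(tis == "normal"), "\n")
  cat("  island probes:", sum(rowData(object)$in_cpg_island),
      " SNP-flagged:", sum(rowData(object)$snp_flagged), "\n")
  cat("  missing beta:", sum(is.na(assay(object, "beta"))), "\n")
})

#' Normal-tissue reference: per-probe mean, SD and calling threshold
#'
#' Holds, for each probe, the mean and standard deviation of beta values in
#' normal tissue and the derived calling threshold
#' `mean + nSD * sd` (default `nSD = 3`). Probes with fewer than two normal
#' observations are retained but marked uncallable (`NA` threshold).
#'
#' @slot stats `DataFrame` with columns `n_normal`, `mean`, `sd`, `threshold`,
#'   row names = probe ids.
#' @slot nSD number of standard deviations above the normal mean defining
#'   the threshold.
#' @export
setClass("NormalReference",
         representation(stats = "DataFrame", nSD = "numeric"))

setValidity("NormalReference", function(object) {
  st <- object@stats
  msgs <- character()
  need <- c("n_normal", "mean", "sd", "threshold")
  miss <- setdiff(need, colnames(st))
  if (length(miss))
    return(paste0("stats lacks column(s): ", paste(miss, collapse = ", ")))
  ok <- !is.na(st$threshold)
  if (any(st$n_normal[ok] < 2))
    msgs <- c(msgs, "threshold present for probe with < 2 normals")
  if (any(st$threshold[ok] < st$mean[ok] - 1e-12))
    msgs <- c(msgs, "threshold below normal mean")
  if (length(object@nSD) != 1L || object@nSD < 0)
    msgs <- c(msgs, "nSD must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn NormalReference-class named vector of per-probe thresholds
#'   (`NA` for uncallable probes)
#' @param object,x a `NormalReference`
#' @export
thresholds <- function(x) {
  th <- x@stats$threshold
  names(th) <- rownames(x@stats)
  th
}

#' @describeIn NormalReference-class reference statistics as a data.frame
#'   with a `probe_id` column
#' @export
referenceStats <- function(x) {
  st <- as.data.frame(x@stats)
  cbind(probe_id = rownames(st), st, row.names = NULL,
        stringsAsFactors = FALSE)
}

setMethod("show", "NormalReference", function(object) {
  st <- object@stats
  cat("NormalReference:", nrow(st), "probes, threshold = mean +",
      object@nSD, "x SD\n")
  cat("  callable:", sum(!is.na(st$threshold)),
      " uncallable:", sum(is.na(st$threshold)), "\n")
})

#' Binary methylation calls with island-site counts
#'
#' Probes x tumor-samples matrix of 0/1 calls (`NA` where beta was missing or
#' the probe uncallable), the identity of the retained CpG-island probes used
#' for site counting, the per-sample count of methylated island sites, and a
#' flag for samples with incomplete island data.
#'
#' @slot calls integer matrix, probes x tumor samples, values 0/1/NA.
#' @slot islandProbes character, retained island probe ids (post SNP
#'   exclusion) present in `calls`.
#' @slot siteCounts named integer, per tumor sample, methylated island sites
#'   among observed island probes.
#' @slot observedIslandProbes named integer, per tumor sample, number of
#'   island probes with a non-missing call.
#' @slot rule calling rule: `"greater"` (strictly above threshold) or
#'   `"geq"`.
#' @export
setClass("MethylCalls",
         representation(calls = "matrix", islandProbes = "character",
                        siteCounts = "integer",
                        observedIslandProbes = "integer", rule = "character"))

setValidity("MethylCalls", function(object) {
  cl <- object@calls
  msgs <- character()
  if (!all(cl[!is.na(cl)] %in% c(0L, 1L)))
    msgs <- c(msgs, "calls must be 0, 1 or NA")
  if (!all(object@islandProbes %in% rownames(cl)))
    msgs <- c(msgs, "islandProbes must be rows of the call matrix")
  if (!identical(names(object@siteCounts), colnames(cl)))
    msgs <- c(msgs, "siteCounts must be named by the call-matrix samples")
  isl <- cl[object@islandProbes, , drop = FALSE]
  expected <- as.integer(colSums(isl, na.rm = TRUE))
  if (!identical(unname(object@siteCounts), expected))
    msgs <- c(msgs, "siteCounts must equal island-probe column sums")
  if (!object@rule %in% c("greater", "geq"))
    msgs <- c(msgs, "rule must be 'greater' or 'geq'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MethylCalls-class the 0/1 call matrix
#' @param object,x a `MethylCalls`
#' @export
callMatrix <- function(x) x@calls

#' @describeIn MethylCalls-class per-sample methylated island-site counts
#' @export
islandSiteCounts <- function(x) x@siteCounts

#' @describeIn MethylCalls-class retained island probe ids used for counting
#' @export
islandProbes <- function(x) x@islandProbes

setMethod("show", "MethylCalls", function(object) {
  cat("MethylCalls:", nrow(object@calls), "probes x", ncol(object@calls),
      "tumor samples (rule: beta", if (object@rule == "greater") ">" else ">=",
      "threshold)\n")
  cat("  island probes:", length(object@islandProbes), "\n")
  tab <- table(factor(pmin(object@siteCounts, 3L), levels = 0:3))
  cat("  samples by methylated island sites (0/1/2/3+):",
      paste(tab, collapse = "/"), "\n")
})

#' Probe classification into island, flanking and excluded sets
#'
#' @slot island character, island probe ids ordered by decreasing
#'   `distance_from_tss` (downstream first, matching the promoter map).
#' @slot flanking character, non-island probe ids, same ordering.
#' @slot excluded `data.frame` with columns `probe_id`, `reason`.
#' @export
setClass("ProbeRegions",
         representation(island = "character", flanking = "character",
                        excluded = "data.frame"))

setValidity("ProbeRegions", function(object) {
  ids <- c(object@island, object@flanking, object@excluded$probe_id)
  if (anyDuplicated(ids))
    return("island, flanking and excluded sets must be disjoint")
  if (!all(c("probe_id", "reason") %in% colnames(object@excluded)))
    return("excluded must have columns probe_id, reason")
  TRUE
})

setMethod("show", "ProbeRegions", function(object) {
  cat("ProbeRegions:", length(object@island), "island,",
      length(object@flanking), "flanking,",
      nrow(object@excluded), "excluded\n")
  if (length(object@island))
    cat("  island:", paste(object@island, collapse = ", "), "\n")
})

#' Ground truth of a simulated cohort
#'
#' @slot states integer matrix, island probes x tumor samples, latent
#'   methylation state (1 = methylated) before measurement noise.
#' @slot silenced named logical, per tumor sample, latent epigenetic
#'   silencing indicator driving the island probes.
#' @slot siteCounts named integer, per tumor sample, true methylated island
#'   site count (column sums of `states`).
#' @slot config the `SimulationConfig` used.
#' @slot seed integer seed the cohort was generated from.
#' @export
setClass("SyntheticTruth",
         representation(states = "matrix", silenced = "logical",
                        siteCounts = "integer", config = "list",
                        seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msgs <- character()
  if (!identical(unname(object@siteCounts),
                 as.integer(colSums(object@states))))
    msgs <- c(msgs, "siteCounts must equal column sums of states")
  if (!identical(names(object@siteCounts), colnames(object@states)))
    msgs <- c(msgs, "siteCounts names must match state columns")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@states), "island probes x",
      ncol(object@states), "tumors; silenced:",
      sum(object@silenced), "; seed:", object@seed, "\n")
})

#' @describeIn SyntheticTruth-class latent per-probe methylation states
#' @param object,x a `SyntheticTruth`
#' @export
truthStates <- function(x) x@states

#' @describeIn SyntheticTruth-class true per-sample methylated site counts
#' @export
truthSiteCounts <- function(x) x@siteCounts
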
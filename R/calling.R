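## Threshold-based methylation calling. A tumor sample is called methylated
## at a probe when its beta value exceeds the normal-tissue mean by more
## than nSD standard deviations (strict inequality by default); thresholds
## are established individually for each probe from the normal samples.

#' Build the normal-tissue reference
#'
#' Computes, for every probe, the sample mean and unbiased (n - 1) standard
#' deviation of beta over the cohort's normal samples, and the calling
#' threshold `mean + nSD * sd`. A probe with fewer than two non-missing
#' normal observations is marked uncallable (`NA` threshold) with a warning.
#'
#' @param cohort a [MethylCohort-class].
#' @param nSD standard-deviation multiplier (default 3).
#' @return [NormalReference-class].
#' @export
buildNormalReference <- function(cohort, nSD = 3) {
  stopifnot(is(cohort, "MethylCohort"), nSD >= 0)
  nrm <- normalSamples(cohort)
  if (length(nrm) < 2L)
    stop("need at least two normal samples to build a reference")
  b <- betaValues(cohort)[, nrm, drop = FALSE]
  n <- rowSums(!is.na(b))
  mu <- rowMeans(b, na.rm = TRUE)
  sdv <- apply(b, 1L, stats::sd, na.rm = TRUE)
  mu[n < 1L] <- NA_real_
  sdv[n < 2L] <- NA_real_
  thr <- mu + nSD * sdv
  uncallable <- n < 2L
  if (any(uncallable))
    warning(sum(uncallable), " probe(s) uncallable (< 2 normal values): ",
            paste(rownames(b)[uncallable], collapse = ", "))
  stats <- DataFrame(n_normal = as.integer(n), mean = unname(mu),
                     sd = unname(sdv), threshold = unname(thr),
                     row.names = rownames(b))
  new("NormalReference", stats = stats, nSD = nSD)
}

.newMethylCalls <- function(calls, islandProbes, rule) {
  isl <- calls[islandProbes, , drop = FALSE]
  new("MethylCalls", calls = calls, islandProbes = islandProbes,
      siteCounts = stats::setNames(as.integer(colSums(isl, na.rm = TRUE)),
                                   colnames(calls)),
      observedIslandProbes = stats::setNames(
        as.integer(colSums(!is.na(isl))), colnames(calls)),
      rule = rule)
}

#' Call methylation in tumor samples against the normal reference
#'
#' A call is 1 when the tumor beta value is strictly greater than the
#' probe's threshold (`rule = "greater"`, the default, reading the threshold
#' as "exceeding by more than nSD standard deviations"); `rule = "geq"` uses
#' `>=` for sensitivity analysis. Missing beta gives a missing call. Island
#' site counts are taken over the retained island probes of `regions` only.
#'
#' @param cohort a [MethylCohort-class].
#' @param reference a [NormalReference-class] built on the same probes.
#' @param regions a [ProbeRegions-class] giving the retained island probes;
#'   probes excluded there (e.g. SNP-flagged) are left out of the call
#'   matrix.
#' @param rule `"greater"` (default) or `"geq"`.
#' @return [MethylCalls-class] over the cohort's tumor samples.
#' @export
callMethylation <- function(cohort, reference, regions,
                            rule = c("greater", "geq")) {
  rule <- match.arg(rule)
  stopifnot(is(cohort, "MethylCohort"), is(reference, "NormalReference"),
            is(regions, "ProbeRegions"))
  tum <- tumorSamples(cohort)
  if (length(tum) == 0L) stop("cohort has no tumor samples")
  keep <- intersect(rownames(cohort), c(regions@island, regions@flanking))
  b <- betaValues(cohort)[keep, tum, drop = FALSE]
  th <- thresholds(reference)
  miss <- setdiff(keep, names(th))
  if (length(miss))
    stop("no reference threshold for probe(s): ", paste(miss, collapse = ", "))
  th <- th[keep]
  cmp <- if (rule == "greater") `>` else `>=`
  calls <- matrix(NA_integer_, nrow(b), ncol(b), dimnames = dimnames(b))
  ok <- !is.na(b) & !is.na(th)[row(b)]
  calls[ok] <- as.integer(cmp(b[ok], th[row(b)][ok]))
  .newMethylCalls(calls, intersect(regions@island, keep), rule)
}

#' Cohort methylation frequency at >= minSites island sites
#'
#' Fraction of tumor samples whose methylated island-site count reaches
#' `minSites`. The denominator is every tumor with at least one observed
#' (non-missing) island probe; samples with incomplete island data are
#' counted over their observed probes and flagged in [writeCalls()] output.
#'
#' @param calls a [MethylCalls-class].
#' @param minSites positive integer (or vector of them); must not exceed the
#'   number of retained island probes.
#' @return `data.frame` with columns `min_sites`, `n_methylated`,
#'   `n_samples`, `fraction`.
#' @export
methylatedFraction <- function(calls, minSites = 1L) {
  stopifnot(is(calls, "MethylCalls"))
  minSites <- as.integer(minSites)
  if (any(minSites < 1L)) stop("minSites must be >= 1")
  if (any(minSites > length(islandProbes(calls))))
    stop("minSites exceeds the number of retained island probes (",
         length(islandProbes(calls)), ")")
  observed <- calls@observedIslandProbes >= 1L
  counts <- islandSiteCounts(calls)[observed]
  do.call(rbind, lapply(minSites, function(k) {
    data.frame(min_sites = k, n_methylated = sum(counts >= k),
               n_samples = length(counts),
               fraction = sum(counts >= k) / length(counts))
  }))
}

#' Per-probe fraction of methylated tumors
#'
#' For each probe in the call matrix, the fraction of tumors called
#' methylated among tumors with a non-missing call at that probe
#' (pairwise-complete).
#'
#' @param calls a [MethylCalls-class].
#' @return `data.frame` with columns `probe_id`, `n_methylated`,
#'   `n_observed`, `fraction`.
#' @export
perProbeMethylatedFraction <- function(calls) {
  stopifnot(is(calls, "MethylCalls"))
  cl <- callMatrix(calls)
  nObs <- rowSums(!is.na(cl))
  nMet <- rowSums(cl == 1L, na.rm = TRUE)
  data.frame(probe_id = rownames(cl), n_methylated = unname(nMet),
             n_observed = unname(nObs),
             fraction = unname(ifelse(nObs > 0, nMet / nObs, NA_real_)),
             stringsAsFactors = FALSE)
}
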
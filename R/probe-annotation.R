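## Promoter probe classification. Island membership comes from the
## annotation (array manifest convention), never from sequence; SNP
## exclusion is annotation-driven via the snp_flagged column.

#' Remove SNP-flagged probes
#'
#' Drops probes whose target sequence carries a SNP (the `snp_flagged`
#' column) and reports each exclusion. An annotation left empty after
#' filtering is allowed, with a warning.
#'
#' @param annotation probe annotation `data.frame`.
#' @return list with `retained` (filtered annotation) and `excluded`
#'   (`data.frame` of `probe_id`, `reason`).
#' @export
filterSnpProbes <- function(annotation) {
  ann <- .normalizeAnnotation(annotation)
  flagged <- ann$probe_id[ann$snp_flagged]
  retained <- ann[!ann$snp_flagged, , drop = FALSE]
  rownames(retained) <- NULL
  if (nrow(retained) == 0L)
    warning("all probes SNP-flagged; nothing retained")
  list(retained = retained,
       excluded = data.frame(probe_id = flagged,
                             reason = rep("SNP", length(flagged)),
                             stringsAsFactors = FALSE))
}

#' Classify probes into CpG-island and flanking sets
#'
#' Splits an annotation (normally already SNP-filtered via
#' [filterSnpProbes()]) into island and flanking probe lists, each ordered by
#' decreasing signed distance from the TSS so the most downstream probe comes
#' first, matching the promoter-map layout. Classification is a pure function
#' of the annotation: input order is irrelevant.
#'
#' @param annotation probe annotation `data.frame`.
#' @param excluded optional exclusion `data.frame` (`probe_id`, `reason`) to
#'   carry through, e.g. from [filterSnpProbes()].
#' @return [ProbeRegions-class].
#' @export
classifyRegions <- function(annotation, excluded = NULL) {
  ann <- .normalizeAnnotation(annotation)
  ord <- order(-ann$distance_from_tss, ann$probe_id)
  ann <- ann[ord, , drop = FALSE]
  island <- ann$probe_id[ann$in_cpg_island]
  flanking <- ann$probe_id[!ann$in_cpg_island]
  if (length(island) == 0L)
    warning("annotation contains no CpG-island probes")
  if (is.null(excluded))
    excluded <- data.frame(probe_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  new("ProbeRegions", island = island, flanking = flanking,
      excluded = as.data.frame(excluded, stringsAsFactors = FALSE))
}

#' Write the exclusion report of a [ProbeRegions-class]
#'
#' @param regions a `ProbeRegions`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeExclusionReport <- function(regions, path) {
  utils::write.table(regions@excluded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
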
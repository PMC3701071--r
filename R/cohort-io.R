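## Tabular I/O: TSV matrices ('.' decimal, "NA" missing), CSV/TSV sample
## sheets, probe annotation mirroring the Illumina 450K manifest fields,
## JSON for model fits. Numeric output fixed at 10 significant digits so a
## write -> read round trip is stable to that precision.

.SIGDIG <- 10L

.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = .SIGDIG, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
  out
}

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

.normalizeAnnotation <- function(annotation) {
  ann <- as.data.frame(annotation, stringsAsFactors = FALSE)
  ## accept Illumina manifest column names
  ren <- c(IlmnID = "probe_id", MAPINFO = "position", CHR = "chromosome",
           Relation_to_UCSC_CpG_Island = "in_cpg_island",
           SNP = "snp_flagged")
  for (from in names(ren))
    if (from %in% colnames(ann) && !(ren[[from]] %in% colnames(ann)))
      colnames(ann)[colnames(ann) == from] <- ren[[from]]
  need <- c("probe_id", "distance_from_tss", "in_cpg_island", "snp_flagged")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("probe annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe_id in annotation: ",
         paste(unique(ann$probe_id[duplicated(ann$probe_id)]), collapse = ", "))
  ann$distance_from_tss <- as.integer(ann$distance_from_tss)
  if (anyNA(ann$distance_from_tss))
    stop("distance_from_tss must be finite integers")
  if (is.character(ann$in_cpg_island))
    ann$in_cpg_island <- ann$in_cpg_island %in% c("TRUE", "Island", "island",
                                                  "1", "yes")
  ann$in_cpg_island <- as.logical(ann$in_cpg_island)
  if (is.character(ann$snp_flagged))
    ann$snp_flagged <- !(ann$snp_flagged %in% c("", "FALSE", "0", "no", "NA"))
  ann$snp_flagged <- as.logical(ann$snp_flagged)
  if (anyNA(ann$in_cpg_island) || anyNA(ann$snp_flagged))
    stop("in_cpg_island and snp_flagged must be interpretable as logical")
  ann
}

.normalizeSampleTable <- function(samples) {
  smp <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% colnames(smp)))
    stop("sample sheet needs at least columns sample_id and tissue")
  if (nrow(smp) == 0L) stop("sample sheet is empty")
  if (anyDuplicated(smp$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(smp$sample_id[duplicated(smp$sample_id)]),
               collapse = ", "))
  tis <- tolower(trimws(smp$tissue))
  tis[tis %in% c("tumour", "t", "cancer")] <- "tumor"
  tis[tis %in% c("n", "normal tissue")] <- "normal"
  bad <- !tis %in% c("tumor", "normal")
  if (any(bad))
    stop("unrecognised tissue value(s): ",
         paste(unique(smp$tissue[bad]), collapse = ", "))
  smp$tissue <- tis
  if (!"pair_id" %in% colnames(smp)) smp$pair_id <- NA_character_
  smp$pair_id[smp$pair_id %in% c("", "NA")] <- NA_character_
  paired <- smp[!is.na(smp$pair_id), , drop = FALSE]
  if (nrow(paired)) {
    byPair <- split(paired$tissue, paired$pair_id)
    bad <- names(byPair)[!vapply(byPair, function(g)
      length(g) == 2L && setequal(g, c("tumor", "normal")), logical(1))]
    if (length(bad))
      stop("pair_id must link exactly one tumor and one normal; offending: ",
           paste(bad, collapse = ", "))
  }
  for (col in c("er_status", "her2_status")) {
    if (!col %in% colnames(smp)) smp[[col]] <- "unknown"
    v <- tolower(trimws(as.character(smp[[col]])))
    v[v %in% c("pos", "+", "positive")] <- "positive"
    v[v %in% c("neg", "-", "negative")] <- "negative"
    v[v %in% c("", "na", "nd", "unknown") | is.na(v)] <- "unknown"
    bad <- !v %in% c("positive", "negative", "unknown")
    if (any(bad))
      stop("unrecognised ", col, " value(s): ",
           paste(unique(smp[[col]][bad]), collapse = ", "))
    smp[[col]] <- v
  }
  smp
}

#' Read a probe annotation table
#'
#' Reads a TSV/CSV of probe metadata. Canonical columns are `probe_id`,
#' `distance_from_tss` (signed nucleotides, negative = upstream of the TSS),
#' `in_cpg_island`, `snp_flagged`, with optional `chromosome` and 1-based
#' `position`; Illumina manifest spellings (`IlmnID`, `MAPINFO`, `CHR`,
#' `Relation_to_UCSC_CpG_Island`, `SNP`) are accepted.
#'
#' @param path file path.
#' @return `data.frame` with the canonical columns.
#' @export
readProbeAnnotation <- function(path) {
  ann <- utils::read.delim(path, sep = .sniffSep(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  .normalizeAnnotation(ann)
}

#' Read a beta-value matrix
#'
#' Reads a tab-delimited probes x samples matrix (first column probe ids,
#' header row sample ids, `NA` for missing). Every non-missing value must lie
#' in \[0, 1\]; the matrix is restricted to probes present in `annotation`,
#' with a warning listing dropped unknown probes.
#'
#' @param path file path.
#' @param annotation probe annotation `data.frame` (see
#'   [readProbeAnnotation()]); used to restrict and validate probe ids.
#' @return numeric matrix with probe-id rownames and sample-id colnames.
#' @export
readBetaMatrix <- function(path, annotation) {
  annotation <- .normalizeAnnotation(annotation)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed beta matrix: need a probe-id column plus >= 1 sample")
  if (anyDuplicated(colnames(tab)[-1]))
    stop("malformed header: duplicate sample ids")
  probes <- as.character(tab[[1]])
  if (anyDuplicated(probes)) stop("duplicate probe ids in beta matrix")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!is.na(tab[, -1, drop = FALSE]) &
                   is.na(suppressWarnings(
                     apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric beta value, e.g. probe ", probes[bad[1, 1]],
         " sample ", colnames(tab)[-1][bad[1, 2]])
  }
  rownames(mat) <- probes
  oob <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(oob))
    stop(sprintf("beta value %g outside [0, 1] at probe %s, sample %s",
                 mat[oob[1, 1], oob[1, 2]], rownames(mat)[oob[1, 1]],
                 colnames(mat)[oob[1, 2]]))
  unknown <- setdiff(rownames(mat), annotation$probe_id)
  if (length(unknown)) {
    warning("dropping ", length(unknown), " probe(s) absent from annotation: ",
            paste(unknown, collapse = ", "))
    mat <- mat[setdiff(rownames(mat), unknown), , drop = FALSE]
  }
  mat
}

#' Read a sample sheet
#'
#' Reads a CSV/TSV sample sheet with columns `sample_id`, `tissue` and
#' optionally `pair_id`, `er_status`, `her2_status`. Tissue labels are
#' case-normalised to `tumor`/`normal`; receptor status to
#' `positive`/`negative`/`unknown`. Duplicate sample ids, malformed
#' tumor/normal pairs, and empty files are errors.
#'
#' @param path file path.
#' @return validated `data.frame`.
#' @export
readSampleSheet <- function(path) {
  if (file.size(path) == 0L) stop("sample sheet file is empty")
  smp <- utils::read.delim(path, sep = .sniffSep(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  .normalizeSampleTable(smp)
}

#' Read a genes x samples expression matrix
#'
#' Tab-delimited, first column gene ids, header row sample ids; values are
#' platform-normalised log-scale expression, `NA` for missing.
#'
#' @param path file path.
#' @param gene optional gene id; when given, the single row is returned as a
#'   named numeric vector.
#' @return numeric matrix, or named vector when `gene` is given.
#' @export
readExpressionMatrix <- function(path, gene = NULL) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("malformed expression matrix")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  storage.mode(mat) <- "double"
  if (is.null(gene)) return(mat)
  if (!gene %in% rownames(mat)) stop("gene not found: ", gene)
  mat[gene, ]
}

#' Align beta, expression and sample metadata into one cohort
#'
#' Restricts all three sample-keyed inputs to their common samples and the
#' beta matrix to annotated probes, reporting what was dropped from each
#' source. A disjoint sample set is an error.
#'
#' @param beta probes x samples beta matrix.
#' @param expression named numeric vector of per-sample expression.
#' @param samples sample `data.frame` (see [readSampleSheet()]).
#' @param annotation probe annotation `data.frame`.
#' @return [MethylCohort-class]; the drop report is in
#'   `metadata(cohort)$alignment`.
#' @export
alignCohort <- function(beta, expression, samples, annotation) {
  samples <- .normalizeSampleTable(samples)
  annotation <- .normalizeAnnotation(annotation)
  keep <- Reduce(intersect, list(colnames(beta), names(expression),
                                 samples$sample_id))
  if (length(keep) == 0L)
    stop("no samples shared between beta, expression and sample sheet")
  dropped <- list(beta = setdiff(colnames(beta), keep),
                  expression = setdiff(names(expression), keep),
                  samples = setdiff(samples$sample_id, keep),
                  probes = setdiff(rownames(beta), annotation$probe_id))
  b <- beta[intersect(rownames(beta), annotation$probe_id), keep,
            drop = FALSE]
  cohort <- MethylCohort(b, expression[keep],
                         samples[samples$sample_id %in% keep, , drop = FALSE],
                         annotation)
  metadata(cohort)$alignment <- dropped
  cohort
}

#' Write a numeric matrix as TSV (probe ids in the first column)
#'
#' @param mat numeric matrix with rownames and colnames.
#' @param path output path.
#' @param idColumn name of the first (id) column.
#' @return `path`, invisibly.
#' @export
writeBetaMatrix <- function(mat, path, idColumn = "probe_id") {
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- idColumn
  for (j in colnames(mat)) df[[j]] <- .fmtNum(mat[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a methylation call matrix and per-sample summary
#'
#' Emits the 0/1 call matrix as TSV and, alongside it
#' (`<path base>_samples.tsv`), the per-sample island-site counts with a flag
#' for samples missing island probes.
#'
#' @param calls a [MethylCalls-class] object.
#' @param path output path for the call matrix.
#' @return `path`, invisibly.
#' @export
writeCalls <- function(calls, path) {
  cl <- callMatrix(calls)
  df <- data.frame(probe_id = rownames(cl), stringsAsFactors = FALSE)
  for (j in colnames(cl)) df[[j]] <- ifelse(is.na(cl[, j]), "NA", cl[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  smp <- data.frame(sample_id = colnames(cl),
                    island_site_count = unname(islandSiteCounts(calls)),
                    observed_island_probes =
                      unname(calls@observedIslandProbes),
                    incomplete_island_data =
                      unname(calls@observedIslandProbes) <
                        length(islandProbes(calls)),
                    stringsAsFactors = FALSE)
  utils::write.table(smp, sub("(\\.tsv)?$", "_samples.tsv", path, perl = TRUE),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a call matrix written by [writeCalls()]
#'
#' @param path path of the call-matrix TSV.
#' @param islandProbes island probe ids to count sites over.
#' @return [MethylCalls-class].
#' @export
readCalls <- function(path, islandProbes) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  cl <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cl) <- tab[[1]]
  storage.mode(cl) <- "integer"
  .newMethylCalls(cl, intersect(islandProbes, rownames(cl)), rule = "greater")
}

#' Write / read the normal reference table
#'
#' TSV columns: `probe_id`, `n_normal`, `mean`, `sd`, `threshold`.
#'
#' @param reference a [NormalReference-class].
#' @param path file path.
#' @return `path` (write) or a [NormalReference-class] (read).
#' @export
writeNormalReference <- function(reference, path) {
  st <- referenceStats(reference)
  for (col in c("mean", "sd", "threshold")) st[[col]] <- .fmtNum(st[[col]])
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNormalReference
#' @param nSD the multiplier the thresholds were built with.
#' @export
readNormalReference <- function(path, nSD = 3) {
  st <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats <- DataFrame(n_normal = as.integer(st$n_normal), mean = st$mean,
                     sd = st$sd, threshold = st$threshold,
                     row.names = st$probe_id)
  new("NormalReference", stats = stats, nSD = nSD)
}

#' Serialise a results object
#'
#' Matrices and data frames go to TSV; lists (model fits, summaries) go to
#' JSON together with run metadata (package version, timestamp-free).
#' Output is bit-stable for fixed input.
#'
#' @param results matrix, data.frame or list.
#' @param path output path.
#' @param metadata optional named list recorded under `"run_metadata"` in
#'   JSON output (e.g. parameters and seed).
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path, metadata = list()) {
  if (is.matrix(results)) {
    writeBetaMatrix(results, path)
  } else if (is.data.frame(results)) {
    df <- results
    for (j in colnames(df)) if (is.numeric(df[[j]])) df[[j]] <- .fmtNum(df[[j]])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.list(results)) {
    payload <- c(results, list(run_metadata = c(
      list(package = "methylGate",
           version = as.character(utils::packageVersion("methylGate"))),
      metadata)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else stop("unsupported results type: ", class(results)[1])
  invisible(path)
}
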
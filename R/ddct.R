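## Relative qRT-PCR quantification by the 2^-ddCt method: target Ct
## normalised to an endogenous control, then to a calibrator sample,
## assuming 100% amplification efficiency. Replicates are averaged on the
## Ct scale before differencing.

#' Read a Ct table
#'
#' CSV/TSV with columns `sample_id`, `condition`, `target_ct`, `control_ct`
#' and optionally `replicate`. Ct values must be positive and finite; a
#' missing control Ct is an error naming the row.
#'
#' @param path file path.
#' @return validated `data.frame`.
#' @export
readCtTable <- function(path) {
  ct <- utils::read.delim(path, sep = .sniffSep(path),
                          stringsAsFactors = FALSE)
  .validateCtTable(ct)
}

.validateCtTable <- function(ct) {
  ct <- as.data.frame(ct, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "target_ct", "control_ct")
  miss <- setdiff(need, colnames(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"replicate" %in% colnames(ct)) ct$replicate <- 1L
  for (col in c("target_ct", "control_ct")) {
    v <- ct[[col]]
    bad <- which(is.na(v) | !is.finite(v) | v <= 0)
    if (length(bad))
      stop(col, " must be positive and finite; offending row ", bad[1],
           " (sample ", ct$sample_id[bad[1]], ", condition ",
           ct$condition[bad[1]], ")")
  }
  ct
}

#' Relative expression by 2^-ddCt
#'
#' Per (sample, condition): `dCt = mean(target_ct) - mean(control_ct)` over
#' replicates; `ddCt = dCt - dCt(calibrator)`; relative quantity
#' `RQ = 2^-ddCt`, reported as percent of the calibrator (which is 100% by
#' construction). Where a sample was assayed both untreated and treated,
#' the fold change `RQ(condition) / RQ(reference condition)` is added.
#'
#' @param ct Ct `data.frame` (see [readCtTable()]).
#' @param calibrator sample id of the calibrator (e.g. a non-tumorigenic
#'   reference line); must be present in the table.
#' @param calibratorCondition condition of the calibrator rows; defaults to
#'   `referenceCondition`.
#' @param referenceCondition condition used as the fold-change denominator
#'   (default `"untreated"`).
#' @return `data.frame`: `sample_id`, `condition`, `dct`, `ddct`,
#'   `percent_of_calibrator`, `fold_change` (`NA` where no reference-
#'   condition measurement exists).
#' @export
relativeExpression <- function(ct, calibrator,
                               calibratorCondition = referenceCondition,
                               referenceCondition = "untreated") {
  ct <- .validateCtTable(ct)
  key <- interaction(ct$sample_id, ct$condition, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(g) {
    data.frame(sample_id = g$sample_id[1], condition = g$condition[1],
               dct = mean(g$target_ct) - mean(g$control_ct),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  cal <- agg$dct[agg$sample_id == calibrator &
                   agg$condition == calibratorCondition]
  if (length(cal) != 1L)
    stop("calibrator '", calibrator, "' (condition '", calibratorCondition,
         "') not found exactly once in the Ct table")
  agg$ddct <- agg$dct - cal
  agg$percent_of_calibrator <- 100 * 2^(-agg$ddct)
  refRQ <- stats::setNames(
    agg$percent_of_calibrator[agg$condition == referenceCondition],
    agg$sample_id[agg$condition == referenceCondition])
  agg$fold_change <- ifelse(
    agg$sample_id %in% names(refRQ),
    agg$percent_of_calibrator / refRQ[agg$sample_id], NA_real_)
  agg[order(agg$sample_id, agg$condition), ]
}
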
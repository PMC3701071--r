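## Methylation-expression association: per-probe Spearman rank correlation
## (average ranks for ties; two-sided p from the t approximation on n - 2
## df), tumor-vs-normal two-sample t-tests (pooled variance by default), and
## a per-probe logistic model P(methylated) ~ expression with the logit
## link, summarised as the fitted probability of methylation at the lowest,
## median and highest observed expression.

#' Spearman rank correlation between a probe's beta values and expression
#'
#' Computed on pairwise-complete pairs with average ranks for ties; the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' A constant input gives an undefined (NA) rho with `constant = TRUE`
#' rather than an error.
#'
#' @param beta named numeric vector of beta values (one probe).
#' @param expression named numeric vector of expression; matched by names
#'   when both are named, by position otherwise.
#' @return one-row `data.frame`: `rho`, `p`, `n`, `constant`.
#' @export
spearmanAssociation <- function(beta, expression) {
  if (!is.null(names(beta)) && !is.null(names(expression))) {
    common <- intersect(names(beta), names(expression))
    beta <- beta[common]; expression <- expression[common]
  } else stopifnot(length(beta) == length(expression))
  ok <- !is.na(beta) & !is.na(expression)
  x <- beta[ok]; y <- expression[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 pairwise-complete pairs, got ", n)
  constant <- length(unique(x)) < 2L || length(unique(y)) < 2L
  if (constant)
    return(data.frame(rho = NA_real_, p = NA_real_, n = n, constant = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  data.frame(rho = rho, p = p, n = n, constant = FALSE)
}

#' Tumor-versus-normal two-sample t-test at one probe
#'
#' Student's t-test on beta values, pooled variance by default
#' (`welch = TRUE` for the Welch variant), two-sided. A group with fewer
#' than two non-missing observations makes the probe uncallable (`NA`
#' statistics, flagged) rather than an error.
#'
#' @param beta named numeric vector of beta values (one probe).
#' @param tissue character vector (`tumor`/`normal`) aligned to `beta`, or a
#'   sample `data.frame` with `sample_id` and `tissue` columns.
#' @param welch use the Welch (unequal-variance) test.
#' @return one-row `data.frame`: `t`, `p`, `df`, `n_tumor`, `n_normal`,
#'   `uncallable`.
#' @export
tumorNormalTest <- function(beta, tissue, welch = FALSE) {
  if (is.data.frame(tissue)) {
    tissue <- stats::setNames(tissue$tissue, tissue$sample_id)[names(beta)]
  }
  stopifnot(length(beta) == length(tissue))
  ok <- !is.na(beta) & !is.na(tissue)
  x <- beta[ok & tissue == "tumor"]
  y <- beta[ok & tissue == "normal"]
  if (length(x) < 2L || length(y) < 2L)
    return(data.frame(t = NA_real_, p = NA_real_, df = NA_real_,
                      n_tumor = length(x), n_normal = length(y),
                      uncallable = TRUE))
  tt <- stats::t.test(x, y, var.equal = !welch)
  data.frame(t = unname(tt$statistic), p = tt$p.value,
             df = unname(tt$parameter), n_tumor = length(x),
             n_normal = length(y), uncallable = FALSE)
}

#' Logistic model of methylation probability as a function of expression
#'
#' Maximum-likelihood fit of `P(call = 1) = plogis(intercept +
#' slope * expression)` (binomial family, logit link) on pairwise-complete
#' pairs. Complete or quasi-complete separation and single-class outcomes
#' are detected and flagged; coefficients are reported only for converged,
#' non-separated fits.
#'
#' @param calls named 0/1 vector of methylation calls at one probe.
#' @param expression named numeric expression vector; matched by names when
#'   both are named.
#' @param minN minimum number of complete pairs (default 10).
#' @return list of class `methylLogit`: `intercept`, `slope`, `converged`,
#'   `separation`, `n`, `n_methylated`.
#' @export
fitMethylationLogit <- function(calls, expression, minN = 10L) {
  if (!is.null(names(calls)) && !is.null(names(expression))) {
    common <- intersect(names(calls), names(expression))
    calls <- calls[common]; expression <- expression[common]
  } else stopifnot(length(calls) == length(expression))
  ok <- !is.na(calls) & !is.na(expression)
  y <- as.integer(calls[ok]); x <- as.numeric(expression[ok])
  n <- length(y)
  if (n < minN) stop("need >= ", minN, " complete pairs, got ", n)
  if (!all(y %in% c(0L, 1L))) stop("calls must be 0/1")
  out <- list(intercept = NA_real_, slope = NA_real_, converged = FALSE,
              separation = FALSE, n = n, n_methylated = sum(y))
  class(out) <- "methylLogit"
  if (length(unique(y)) < 2L) {           # single-class outcome
    out$separation <- TRUE
    return(out)
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(link = "logit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- unname(stats::coef(fit))
  separated <- sep_warned && max(abs(co)) > 10 * (1 + stats::sd(x))
  out$separation <- separated
  out$converged <- isTRUE(fit$converged) && !separated
  if (out$converged) {
    out$intercept <- co[1]
    out$slope <- co[2]
  }
  out
}

#' @export
print.methylLogit <- function(x, ...) {
  cat("Logistic methylation model (logit link), n =", x$n,
      "(", x$n_methylated, "methylated )\n")
  if (x$separation) cat("  separation detected; coefficients unreliable\n")
  if (x$converged)
    cat(sprintf("  intercept %.4f  slope %.4f\n", x$intercept, x$slope))
  invisible(x)
}

#' Methylation attribution at low, median and high expression
#'
#' Evaluates the fitted probability of methylation at the minimum, median
#' and maximum observed expression values: the share of tumors at each
#' expression level whose state the model attributes to promoter
#' methylation.
#'
#' @param fit a converged `methylLogit` (see [fitMethylationLogit()]).
#' @param expression numeric expression vector defining the observed min,
#'   median and max.
#' @return named numeric of length 3 (`min`, `median`, `max`), values in
#'   \[0, 1\].
#' @export
attributionSummary <- function(fit, expression) {
  stopifnot(inherits(fit, "methylLogit"))
  if (!isTRUE(fit$converged))
    stop("attribution requires a converged, non-separated fit")
  e <- expression[!is.na(expression)]
  at <- c(min = min(e), median = stats::median(e), max = max(e))
  stats::setNames(stats::plogis(fit$intercept + fit$slope * at), names(at))
}

#' Per-probe association table for the retained island probes
#'
#' One row per retained island probe, ordered by decreasing distance from
#' the TSS: distance, normal and tumor mean +/- SD of beta, percent of
#' tumors called methylated, and the Spearman correlation of beta with
#' expression (tumors only by default) with its p-value. Optionally a
#' Benjamini-Hochberg adjusted column (off by default; raw p-values are the
#' primary report).
#'
#' @param cohort a [MethylCohort-class].
#' @param calls a [MethylCalls-class] from [callMethylation()].
#' @param regions a [ProbeRegions-class].
#' @param population samples used for the correlation: `"tumors"` (default)
#'   or `"all"`.
#' @param adjust add a BH-adjusted p-value column.
#' @return `data.frame`, one row per island probe (empty with a warning if
#'   there are none).
#' @export
associationTable <- function(cohort, calls, regions,
                             population = c("tumors", "all"),
                             adjust = FALSE) {
  population <- match.arg(population)
  stopifnot(is(cohort, "MethylCohort"), is(calls, "MethylCalls"),
            is(regions, "ProbeRegions"))
  isl <- intersect(regions@island, rownames(cohort))
  if (length(isl) == 0L) {
    warning("no island probes; returning empty association table")
    return(data.frame(probe_id = character(), distance_from_tss = integer(),
                      normal_mean = numeric(), normal_sd = numeric(),
                      tumor_mean = numeric(), tumor_sd = numeric(),
                      pct_methylated = numeric(), rho = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  ann <- probeInfo(cohort)
  dist <- stats::setNames(ann$distance_from_tss, ann$probe_id)[isl]
  isl <- isl[order(-dist, isl)]
  b <- betaValues(cohort)
  expr <- geneExpression(cohort)
  tum <- tumorSamples(cohort); nrm <- normalSamples(cohort)
  assoc_samples <- if (population == "tumors") tum else colnames(cohort)
  ppm <- perProbeMethylatedFraction(calls)
  pct <- stats::setNames(ppm$fraction, ppm$probe_id)
  rows <- lapply(isl, function(p) {
    sp <- spearmanAssociation(b[p, assoc_samples], expr[assoc_samples])
    data.frame(probe_id = p,
               distance_from_tss = unname(dist[p]),
               normal_mean = mean(b[p, nrm], na.rm = TRUE),
               normal_sd = stats::sd(b[p, nrm], na.rm = TRUE),
               tumor_mean = mean(b[p, tum], na.rm = TRUE),
               tumor_sd = stats::sd(b[p, tum], na.rm = TRUE),
               pct_methylated = 100 * unname(pct[p]),
               rho = sp$rho, p = sp$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
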
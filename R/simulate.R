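## Synthetic single-gene methylation cohorts with recorded ground truth.
## Normals draw beta from per-probe Beta distributions; tumors carry a
## latent "silenced" Bernoulli state that drives methylation events across
## all island probes (with per-probe dropout), so multi-site methylation is
## correlated rather than independent; expression decreases linearly with
## the true methylated-site count plus Gaussian noise. Everything is
## reproducible bit-for-bit from the seed.

#' Default promoter probe layout (13 probes)
#'
#' Six CpG-island probes spanning the TSS -- the five retained island probes
#' of the claudin-1 promoter at signed TSS distances +300, +54, +12, -8, -15
#' plus the SNP-flagged island probe cg24550865 -- and seven flanking
#' probes: one upstream of the island and six downstream, the most distal at
#' +15470 nt. Flanking probe ids (and the SNP probe's position) are
#' synthetic placeholders (`cgSIM*` / +120) standing in for manifest entries
#' not reproduced here.
#'
#' @return annotation `data.frame` (see [readProbeAnnotation()]).
#' @export
defaultProbeLayout <- function() {
  data.frame(
    probe_id = c("cg15105660", "cg08770122", "cg14310674", "cg21919136",
                 "cg07661818", "cg24550865",
                 "cgSIM00001", "cgSIM00002", "cgSIM00003", "cgSIM00004",
                 "cgSIM00005", "cgSIM00006", "cgSIM00007"),
    distance_from_tss = c(300L, 54L, 12L, -8L, -15L, 120L,
                          -1500L, 800L, 1600L, 3200L, 6400L, 10000L, 15470L),
    in_cpg_island = c(rep(TRUE, 6L), rep(FALSE, 7L)),
    snp_flagged = c(rep(FALSE, 5L), TRUE, rep(FALSE, 7L)),
    stringsAsFactors = FALSE)
}

.defaultNormalParams <- function(layout) {
  ## island moments on the scale of the published normal-tissue summaries;
  ## flanking probes high-methylated as expected outside a promoter island
  island <- data.frame(
    probe_id = c("cg15105660", "cg08770122", "cg14310674", "cg21919136",
                 "cg07661818", "cg24550865"),
    mean = c(0.15, 0.03, 0.02, 0.05, 0.02, 0.04),
    sd   = c(0.05, 0.01, 0.005, 0.02, 0.005, 0.015),
    stringsAsFactors = FALSE)
  flank <- layout[!layout$in_cpg_island, "probe_id"]
  rbind(island,
        data.frame(probe_id = flank,
                   mean = c(0.75, 0.80, 0.70, 0.85, 0.80, 0.65, 0.70),
                   sd = rep(0.08, length(flank)),
                   stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulateCohort()]. Defaults
#' emulate a TCGA-scale breast-carcinoma cohort: 217 tumors, 40 matched
#' normals, the [defaultProbeLayout()] with island normal beta means/SDs on
#' the scale of reported per-probe cohort summaries, and a silenced-tumor
#' fraction and per-probe event probabilities calibrated so the frequency of
#' methylation at >= 1 island site is near 38.5% and the per-probe
#' methylated-tumor fractions near 26/21/13/12/14%. Under the single-latent
#' silencing model those constraints imply a >= 2-site frequency of ~25%,
#' higher than the 17.4% observed in real tumors, whose site counts are more
#' dispersed (see the vignette). Expression falls linearly with the true
#' methylated-site count.
#'
#' @param n_tumor,n_normal cohort sizes.
#' @param layout probe annotation `data.frame`.
#' @param normal_params `data.frame` (`probe_id`, `mean`, `sd`): normal-
#'   tissue Beta moments per probe.
#' @param pi_silenced probability a tumor carries the latent silencing
#'   state.
#' @param event_prob named numeric: per island probe, probability of a
#'   methylation event given the silenced state (1 - dropout).
#' @param meth_shift increase of the mean beta at methylated island sites
#'   (beta units); infeasible if it pushes any island mean to >= 0.98.
#' @param meth_sd SD of beta at methylated sites.
#' @param tumor_dispersion multiplier on the normal SD for non-methylated
#'   tumor beta (tumors are noisier than normals).
#' @param expr_mean,expr_sd baseline expression mean and noise SD (log-scale
#'   arbitrary units).
#' @param silencing_effect expression drop per true methylated island site.
#' @param er_positive_frac fraction of ER+ tumors.
#' @param er_silencing_or odds ratio of the silenced state for ER+ versus
#'   ER- tumors (marginal silenced fraction kept at `pi_silenced`).
#' @param her2_positive_frac fraction of HER2+ tumors (no effect on
#'   silencing).
#' @param missing_rate per-cell probability of a missing beta value.
#' @param seed default seed (publication-date integer).
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_tumor = 217L, n_normal = 40L,
                             layout = defaultProbeLayout(),
                             normal_params = NULL,
                             pi_silenced = 0.28,
                             event_prob = NULL,
                             meth_shift = 0.35, meth_sd = 0.10,
                             tumor_dispersion = 1.4,
                             expr_mean = 10, expr_sd = 1.5,
                             silencing_effect = 0.3,
                             er_positive_frac = 0.75,
                             er_silencing_or = 3,
                             her2_positive_frac = 0.2,
                             missing_rate = 0,
                             seed = 20130703L) {
  layout <- .normalizeAnnotation(layout)
  if (is.null(normal_params)) normal_params <- .defaultNormalParams(layout)
  if (!all(layout$probe_id %in% normal_params$probe_id))
    stop("normal_params must cover every probe in the layout")
  island <- layout$probe_id[layout$in_cpg_island]
  if (is.null(event_prob)) {
    event_prob <- stats::setNames(rep(0.5, length(island)), island)
    defaults <- c(cg15105660 = 0.858, cg08770122 = 0.651, cg14310674 = 0.361,
                  cg21919136 = 0.335, cg07661818 = 0.395, cg24550865 = 0.600)
    hit <- intersect(names(defaults), island)
    event_prob[hit] <- defaults[hit]
  }
  if (!all(island %in% names(event_prob)))
    stop("event_prob must name every island probe")
  np <- normal_params[match(layout$probe_id, normal_params$probe_id), ]
  if (any(np$sd^2 >= np$mean * (1 - np$mean)))
    stop("normal_params imply an invalid Beta distribution")
  methMean <- np$mean[match(island, np$probe_id)] + meth_shift
  if (any(methMean >= 0.98))
    stop("meth_shift pushes methylated beta mass out of [0, 1]")
  stopifnot(n_tumor >= 1L, n_normal >= 2L,
            pi_silenced >= 0, pi_silenced <= 1,
            all(event_prob >= 0 & event_prob <= 1),
            meth_sd > 0, tumor_dispersion > 0, expr_sd > 0,
            er_positive_frac >= 0, er_positive_frac <= 1,
            er_silencing_or > 0, missing_rate >= 0, missing_rate < 1)
  structure(list(n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal), layout = layout,
                 normal_params = np, pi_silenced = pi_silenced,
                 event_prob = event_prob[island], meth_shift = meth_shift,
                 meth_sd = meth_sd, tumor_dispersion = tumor_dispersion,
                 expr_mean = expr_mean, expr_sd = expr_sd,
                 silencing_effect = silencing_effect,
                 er_positive_frac = er_positive_frac,
                 er_silencing_or = er_silencing_or,
                 her2_positive_frac = her2_positive_frac,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Designed perfect-separation configuration
#'
#' A scenario in which normal and methylated beta distributions are
#' separated by far more than six normal SDs and non-methylated tumor beta
#' is tighter than in normals, so threshold calls recover the latent states
#' without error: every island event is called (sensitivity 1) and no
#' baseline tumor crosses the normal mean + 3 SD (specificity 1).
#'
#' @param n_tumor,n_normal cohort sizes.
#' @param seed seed.
#' @return `SimulationConfig`.
#' @export
separationConfig <- function(n_tumor = 400L, n_normal = 40L,
                             seed = 20130703L) {
  layout <- defaultProbeLayout()
  island <- layout$probe_id[layout$in_cpg_island]
  np <- data.frame(probe_id = layout$probe_id,
                   mean = ifelse(layout$in_cpg_island, 0.05, 0.70),
                   sd = ifelse(layout$in_cpg_island, 0.01, 0.05),
                   stringsAsFactors = FALSE)
  simulationConfig(n_tumor = n_tumor, n_normal = n_normal, layout = layout,
                   normal_params = np, pi_silenced = 0.25,
                   event_prob = stats::setNames(rep(1, length(island)),
                                                island),
                   meth_shift = 0.65, meth_sd = 0.05,
                   tumor_dispersion = 0.5, silencing_effect = 1.0,
                   expr_sd = 1.0, seed = seed)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$n_tumor, "tumors,", x$n_normal, "normals,",
      nrow(x$layout), "probes (", sum(x$layout$in_cpg_island), "island )\n")
  cat("  silenced fraction:", x$pi_silenced,
      " silencing effect:", x$silencing_effect, " seed:", x$seed, "\n")
  invisible(x)
}

.rbetaMoments <- function(n, mean, sd) {
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

.silencedProbByEr <- function(pi, frac_pos, or) {
  if (or == 1 || frac_pos %in% c(0, 1) || pi %in% c(0, 1))
    return(c(positive = pi, negative = pi))
  f <- function(x) {
    pneg <- x / (1 + x); ppos <- or * x / (1 + or * x)
    frac_pos * ppos + (1 - frac_pos) * pneg - pi
  }
  x <- stats::uniroot(f, c(1e-9, 1e9), tol = 1e-12)$root
  c(positive = or * x / (1 + or * x), negative = x / (1 + x))
}

#' Simulate a cohort with ground truth
#'
#' Normals: beta ~ Beta(mean, sd) per probe. Tumors: a latent silenced state
#' `S ~ Bernoulli(pi)` (odds tilted by ER status at fixed marginal `pi`);
#' given `S = 1`, each island probe methylates with its `event_prob`, and
#' methylated cells draw beta from the shifted distribution; all other
#' tumor cells draw from the baseline distribution (normal mean, dispersion-
#' inflated SD). Expression = `expr_mean - silencing_effect * (true site
#' count) + Normal(0, expr_sd)`; normals have no methylation events.
#'
#' @param config a `SimulationConfig`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list: `cohort` ([MethylCohort-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @export
simulateCohort <- function(config = simulationConfig(), seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)
  set.seed(seed)
  lay <- config$layout
  probes <- lay$probe_id
  island <- lay$probe_id[lay$in_cpg_island]
  np <- config$normal_params
  nT <- config$n_tumor; nN <- config$n_normal
  tumorIds <- sprintf("TUM%04d", seq_len(nT))
  normalIds <- sprintf("NRM%04d", seq_len(nN))
  nPaired <- min(nN, nT)

  ## sample covariates and latent states
  er <- ifelse(stats::runif(nT) < config$er_positive_frac,
               "positive", "negative")
  her2 <- ifelse(stats::runif(nT) < config$her2_positive_frac,
                 "positive", "negative")
  pSil <- .silencedProbByEr(config$pi_silenced, config$er_positive_frac,
                            config$er_silencing_or)
  silenced <- stats::runif(nT) < pSil[er]
  states <- matrix(0L, length(island), nT,
                   dimnames = list(island, tumorIds))
  for (p in island)
    states[p, silenced] <- as.integer(
      stats::runif(sum(silenced)) < config$event_prob[[p]])
  siteCounts <- as.integer(colSums(states))

  ## beta values
  beta <- matrix(NA_real_, length(probes), nT + nN,
                 dimnames = list(probes, c(tumorIds, normalIds)))
  for (i in seq_along(probes)) {
    p <- probes[i]
    m <- np$mean[i]; s <- np$sd[i]
    beta[p, normalIds] <- .rbetaMoments(nN, m, s)
    base <- .rbetaMoments(nT, m, min(s * config$tumor_dispersion,
                                     0.95 * sqrt(m * (1 - m))))
    if (p %in% island) {
      meth <- states[p, ] == 1L
      if (any(meth))
        base[meth] <- .rbetaMoments(sum(meth), m + config$meth_shift,
                                    config$meth_sd)
    }
    beta[p, tumorIds] <- base
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(beta)) < config$missing_rate
    beta[drop] <- NA_real_
  }

  ## expression: silencing acts through the true site count
  expr <- c(config$expr_mean - config$silencing_effect * siteCounts +
              stats::rnorm(nT, 0, config$expr_sd),
            config$expr_mean + stats::rnorm(nN, 0, config$expr_sd))
  names(expr) <- c(tumorIds, normalIds)

  samples <- data.frame(
    sample_id = c(tumorIds, normalIds),
    tissue = c(rep("tumor", nT), rep("normal", nN)),
    pair_id = c(ifelse(seq_len(nT) <= nPaired,
                       sprintf("PAIR%04d", seq_len(nT)), NA_character_),
                ifelse(seq_len(nN) <= nPaired,
                       sprintf("PAIR%04d", seq_len(nN)), NA_character_)),
    er_status = c(er, rep("unknown", nN)),
    her2_status = c(her2, rep("unknown", nN)),
    stringsAsFactors = FALSE)

  cohort <- MethylCohort(beta, expr, samples, lay)
  metadata(cohort)$simulation <- list(seed = seed)
  truth <- new("SyntheticTruth", states = states,
               silenced = stats::setNames(silenced, tumorIds),
               siteCounts = stats::setNames(siteCounts, tumorIds),
               config = unclass(config), seed = seed)
  list(cohort = cohort, truth = truth)
}

#' Compare pipeline output with simulation ground truth
#'
#' Cell-level sensitivity and specificity of threshold calls against the
#' latent methylation states (retained island probes, tumors), the error of
#' the estimated >= minSites methylated fraction against the truth-count
#' fraction with its binomial standard error, and sign agreement of the
#' association estimates with the simulated silencing direction.
#'
#' @param calls a [MethylCalls-class] from the simulated cohort.
#' @param truth the matching [SyntheticTruth-class].
#' @param association optional output of [associationTable()]; adds the
#'   fraction of island probes with negative Spearman rho.
#' @param fits optional list of `methylLogit` fits; adds the fraction of
#'   converged fits with negative slope.
#' @param minSites site thresholds for the fraction comparison.
#' @return list of recovery metrics.
#' @export
recoveryReport <- function(calls, truth, association = NULL, fits = NULL,
                           minSites = c(1L, 2L)) {
  stopifnot(is(calls, "MethylCalls"), is(truth, "SyntheticTruth"))
  isl <- intersect(islandProbes(calls), rownames(truthStates(truth)))
  smp <- intersect(colnames(callMatrix(calls)), colnames(truthStates(truth)))
  if (length(isl) == 0L || length(smp) == 0L)
    stop("calls and truth share no island probes/samples")
  cl <- callMatrix(calls)[isl, smp, drop = FALSE]
  st <- truthStates(truth)[isl, smp, drop = FALSE]
  ok <- !is.na(cl)
  tp <- sum(cl == 1L & st == 1L & ok); fn <- sum(cl == 0L & st == 1L & ok)
  tn <- sum(cl == 0L & st == 0L & ok); fp <- sum(cl == 1L & st == 0L & ok)
  frac <- methylatedFraction(calls, minSites)
  trueCounts <- truthSiteCounts(truth)[smp]
  fracCmp <- do.call(rbind, lapply(seq_along(minSites), function(i) {
    k <- minSites[i]
    pTrue <- mean(trueCounts >= k)
    pEst <- frac$fraction[i]
    n <- frac$n_samples[i]
    data.frame(min_sites = k, true_fraction = pTrue,
               estimated_fraction = pEst, error = pEst - pTrue,
               binomial_se = sqrt(pTrue * (1 - pTrue) / n))
  }))
  out <- list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              n_cells = sum(ok), fraction_recovery = fracCmp)
  if (!is.null(association))
    out$negative_rho_fraction <- mean(association$rho < 0, na.rm = TRUE)
  if (!is.null(fits)) {
    conv <- Filter(function(f) isTRUE(f$converged), fits)
    out$negative_slope_fraction <-
      if (length(conv)) mean(vapply(conv, `[[`, numeric(1), "slope") < 0)
      else NA_real_
  }
  out
}
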
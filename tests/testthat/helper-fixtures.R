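## Shared fixtures and independent brute-force oracles.

toyAnnotation <- function() {
  data.frame(
    probe_id = paste0("cgT", 1:5),
    distance_from_tss = c(300L, 54L, 12L, -8L, -15L),
    in_cpg_island = TRUE,
    snp_flagged = FALSE,
    stringsAsFactors = FALSE)
}

## small cohort with known normals/tumors; beta filled by caller or random
toyCohort <- function(beta, nTumor, nNormal, expression = NULL) {
  ids <- colnames(beta)
  stopifnot(length(ids) == nTumor + nNormal)
  smp <- data.frame(sample_id = ids,
                    tissue = c(rep("tumor", nTumor), rep("normal", nNormal)),
                    stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = rownames(beta),
                    distance_from_tss = seq(300L, by = -50L,
                                            length.out = nrow(beta)),
                    in_cpg_island = TRUE, snp_flagged = FALSE,
                    stringsAsFactors = FALSE)
  if (is.null(expression))
    expression <- stats::setNames(rep(0, length(ids)), ids)
  MethylCohort(beta, expression, smp, ann)
}

## naive per-cell threshold calling (loop oracle)
naiveCalls <- function(beta, thr, strict = TRUE) {
  out <- matrix(NA_integer_, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  for (i in seq_len(nrow(beta))) for (j in seq_len(ncol(beta))) {
    b <- beta[i, j]; t <- thr[rownames(beta)[i]]
    if (!is.na(b) && !is.na(t))
      out[i, j] <- if (strict) as.integer(b > t) else as.integer(b >= t)
  }
  out
}

## naive cohort fraction at >= k sites over island probes (loop oracle)
naiveFraction <- function(calls, islandProbes, k) {
  num <- 0L; den <- 0L
  for (j in seq_len(ncol(calls))) {
    cnt <- 0L; obs <- 0L
    for (p in islandProbes) {
      v <- calls[p, j]
      if (!is.na(v)) { obs <- obs + 1L; cnt <- cnt + v }
    }
    if (obs >= 1L) {
      den <- den + 1L
      if (cnt >= k) num <- num + 1L
    }
  }
  c(num = num, den = den, fraction = num / den)
}

naivePerProbe <- function(calls) {
  sapply(rownames(calls), function(p) {
    v <- calls[p, ]; v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
}

## all permutations of a small vector (for exact Spearman p)
allPerms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], allPerms(v[-i]), deparse.level = 0)))
}

## exact two-sided permutation p-value for Spearman rho, no ties
exactSpearmanP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rhoObs <- stats::cor(rx, ry)
  P <- allPerms(seq_len(n))
  rhos <- 1 - 6 * colSums((t(P) - rx)^2) / (n * (n^2 - 1))
  ## P rows are permutations of positions assigned to ranks of y; using
  ## uniform permutations of ranks against fixed rx is the exact null
  mean(abs(rhos) >= abs(rhoObs) - 1e-12)
}

## naive O(n^3) agglomerative clustering; returns successive merge heights
## and the partition (as canonical signatures) after each merge
naiveAgglomerative <- function(d, linkage = c("complete", "average",
                                              "single")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  clusters <- as.list(rownames(dm))
  heights <- numeric(0)
  partitions <- list()
  clusterDist <- function(a, b) {
    dd <- dm[a, b, drop = FALSE]
    switch(linkage, complete = max(dd), average = mean(dd),
           single = min(dd))
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      h <- clusterDist(clusters[[i]], clusters[[j]])
      if (h < best[1]) best <- c(h, j, i)
    }
    i <- best[3]; j <- best[2]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[-c(i, j)], list(merged))
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1L]] <-
      paste(sort(vapply(clusters, paste, "", collapse = "+")),
            collapse = " | ")
  }
  list(heights = heights, partitions = partitions)
}

## partition signatures from an hclust at each merge step
hclustPartitions <- function(hc) {
  n <- length(hc$labels)
  lapply(seq_len(n - 1L), function(k) {
    grp <- stats::cutree(hc, k = n - k)
    paste(sort(vapply(split(names(grp), grp), function(g)
      paste(sort(g), collapse = "+"), "")), collapse = " | ")
  })
}

## run the full calling pipeline on a simulated cohort
runPipeline <- function(sim, rule = "greater") {
  fl <- filterSnpProbes(probeInfo(sim$cohort))
  reg <- classifyRegions(fl$retained, fl$excluded)
  ref <- buildNormalReference(sim$cohort)
  calls <- callMethylation(sim$cohort, ref, reg, rule = rule)
  list(regions = reg, reference = ref, calls = calls)
}
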
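test_that("simulation is bit-identical for a fixed config and seed", {
  cfg <- simulationConfig(n_tumor = 50L, n_normal = 12L)
  a <- simulateCohort(cfg, seed = 99)
  b <- simulateCohort(cfg, seed = 99)
  expect_identical(betaValues(a$cohort), betaValues(b$cohort))
  expect_identical(geneExpression(a$cohort), geneExpression(b$cohort))
  expect_identical(truthStates(a$truth), truthStates(b$truth))
  c <- simulateCohort(cfg, seed = 100)
  expect_false(identical(betaValues(a$cohort), betaValues(c$cohort)))
})

test_that("emitted values respect the generative contract", {
  sim <- simulateCohort(simulationConfig(n_tumor = 80L, n_normal = 20L))
  beta <- betaValues(sim$cohort)
  expect_true(all(beta >= 0 & beta <= 1))
  expect_identical(unname(truthSiteCounts(sim$truth)),
                   unname(as.integer(colSums(truthStates(sim$truth)))))
  expect_identical(dim(beta), c(13L, 100L))
  expect_identical(sum(sampleInfo(sim$cohort)$tissue == "normal"), 20L)
  ## matched pairs link exactly one tumor and one normal (validated on read)
  expect_silent(methylGate:::.normalizeSampleTable(sampleInfo(sim$cohort)))

  ## non-silenced tumors carry no island events
  st <- truthStates(sim$truth)
  expect_true(all(st[, !sim$truth@silenced] == 0L))
})

test_that("a null cohort produces no calls under clear separation", {
  cfg <- separationConfig(n_tumor = 120L)
  cfgNull <- simulationConfig(
    n_tumor = 120L, n_normal = 40L, layout = cfg$layout,
    normal_params = cfg$normal_params, pi_silenced = 0,
    event_prob = cfg$event_prob, meth_shift = cfg$meth_shift,
    meth_sd = cfg$meth_sd, tumor_dispersion = cfg$tumor_dispersion)
  sim <- simulateCohort(cfgNull)
  pipe <- runPipeline(sim)
  expect_identical(sum(islandSiteCounts(pipe$calls)), 0L)
  expect_equal(methylatedFraction(pipe$calls, 1L)$fraction, 0)
})

test_that("infeasible methylation shifts are rejected", {
  expect_error(simulationConfig(meth_shift = 0.97), "out of \\[0, 1\\]")
  expect_error(simulationConfig(normal_params = data.frame(
    probe_id = defaultProbeLayout()$probe_id, mean = 0.5, sd = 0.6)),
    "invalid Beta")
})

test_that("silencing is enriched in ER-positive tumors at the set odds", {
  cfg <- simulationConfig(n_tumor = 6000L, n_normal = 10L,
                          er_silencing_or = 3)
  sim <- simulateCohort(cfg, seed = 7)
  smp <- sampleInfo(sim$cohort)
  tum <- smp[smp$tissue == "tumor", ]
  sil <- sim$truth@silenced[tum$sample_id]
  pPos <- mean(sil[tum$er_status == "positive"])
  pNeg <- mean(sil[tum$er_status == "negative"])
  orHat <- (pPos / (1 - pPos)) / (pNeg / (1 - pNeg))
  expect_gt(pPos, pNeg)
  expect_lt(abs(orHat - 3), 1)
  ## marginal silenced fraction stays at pi
  expect_lt(abs(mean(sil) - cfg$pi_silenced),
            3 * sqrt(0.28 * 0.72 / 6000))
})

test_that("the generator's files round-trip through cohort_io unchanged", {
  dir <- withr::local_tempdir()
  sim <- simulateCohort(simulationConfig(n_tumor = 30L, n_normal = 8L))
  cohort <- sim$cohort
  writeBetaMatrix(betaValues(cohort), file.path(dir, "beta.tsv"))
  writeBetaMatrix(matrix(geneExpression(cohort), 1,
                         dimnames = list("GENE", colnames(cohort))),
                  file.path(dir, "expr.tsv"), idColumn = "gene_id")
  writeResults(sampleInfo(cohort), file.path(dir, "samples.tsv"))
  writeResults(probeInfo(cohort), file.path(dir, "annotation.tsv"))

  ann <- readProbeAnnotation(file.path(dir, "annotation.tsv"))
  beta <- readBetaMatrix(file.path(dir, "beta.tsv"), ann)
  expr <- readExpressionMatrix(file.path(dir, "expr.tsv"), gene = "GENE")
  smp <- readSampleSheet(file.path(dir, "samples.tsv"))
  back <- alignCohort(beta, expr, smp, ann)
  expect_identical(colnames(back), colnames(cohort))
  expect_equal(betaValues(back), betaValues(cohort), tolerance = 1e-9)
  expect_equal(geneExpression(back), geneExpression(cohort),
               tolerance = 1e-9)
  expect_identical(probeInfo(back)$snp_flagged, probeInfo(cohort)$snp_flagged)
})

test_that("large-n reference recovers the configured Beta moments", {
  cfg <- simulationConfig(n_tumor = 2L, n_normal = 4000L)
  sim <- simulateCohort(cfg, seed = 12)
  st <- referenceStats(buildNormalReference(sim$cohort))
  np <- cfg$normal_params
  for (i in seq_len(nrow(np))) {
    seMean <- np$sd[i] / sqrt(4000)
    seSD <- np$sd[i] / sqrt(2 * 3999)
    expect_lt(abs(st$mean[i] - np$mean[i]), 4 * seMean)
    expect_lt(abs(st$sd[i] - np$sd[i]), 5 * seSD)
  }
})

test_that("recovery report measures calls against the latent truth", {
  sim <- simulateCohort(separationConfig(n_tumor = 200L))
  pipe <- runPipeline(sim)
  at <- associationTable(sim$cohort, pipe$calls, pipe$regions)
  expr <- geneExpression(sim$cohort)[tumorSamples(sim$cohort)]
  fits <- lapply(islandProbes(pipe$calls), function(p)
    fitMethylationLogit(callMatrix(pipe$calls)[p, ], expr))
  rep <- recoveryReport(pipe$calls, sim$truth, association = at, fits = fits)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_true(all(abs(rep$fraction_recovery$error) <=
                    2 * rep$fraction_recovery$binomial_se))
  expect_true(all(is.finite(rep$fraction_recovery$binomial_se)))
  expect_equal(rep$negative_rho_fraction, 1)
  ## under this cleanly separated design the per-probe logits are perfectly
  ## separated, so no fit converges and the slope fraction is undefined
  expect_true(all(vapply(fits, `[[`, logical(1), "separation")))
  expect_true(is.na(rep$negative_slope_fraction))

  ## with the moderate default effect the logits converge and slopes are
  ## uniformly negative
  sim2 <- simulateCohort(simulationConfig(n_tumor = 1000L, n_normal = 40L))
  pipe2 <- runPipeline(sim2)
  expr2 <- geneExpression(sim2$cohort)[tumorSamples(sim2$cohort)]
  fits2 <- lapply(islandProbes(pipe2$calls), function(p)
    fitMethylationLogit(callMatrix(pipe2$calls)[p, ], expr2))
  rep2 <- recoveryReport(pipe2$calls, sim2$truth, fits = fits2)
  expect_true(all(vapply(fits2, `[[`, logical(1), "converged")))
  expect_equal(rep2$negative_slope_fraction, 1)
})
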
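test_that("Spearman correlation handles monotone, tied and constant input", {
  sp <- spearmanAssociation(c(0.1, 0.2, 0.3, 0.4), c(4, 3, 2, 1))
  expect_equal(sp$rho, -1)
  expect_equal(sp$p, 0)
  sp2 <- spearmanAssociation(c(0.1, 0.2, 0.3, 0.4), c(10, 20, 30, 40))
  expect_equal(sp2$rho, 1)

  ## average ranks for ties: agree with stats::cor(method = "spearman")
  x <- c(0.1, 0.1, 0.3, 0.5, 0.5, 0.7)
  y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(spearmanAssociation(x, y)$rho,
               cor(x, y, method = "spearman"))

  const <- spearmanAssociation(rep(0.2, 5), 1:5)
  expect_true(const$constant)
  expect_true(is.na(const$rho))

  expect_error(spearmanAssociation(c(0.1, 0.2), c(1, 2)), ">= 3")
})

test_that("Spearman is monotone-invariant, symmetric and sign-flipping", {
  set.seed(31)
  for (i in 1:10) {
    x <- runif(15); y <- runif(15)
    base <- spearmanAssociation(x, y)$rho
    expect_equal(spearmanAssociation(exp(3 * x), y)$rho, base)
    expect_equal(spearmanAssociation(x, qlogis(y))$rho, base)
    expect_equal(spearmanAssociation(y, x)$rho, base)
    expect_equal(spearmanAssociation(-x, y)$rho, -base)
  }
})

test_that("t-approximation p-value tracks the exact permutation null at n=8", {
  set.seed(17)
  x <- runif(8)
  for (rho_target in c(0.3, 0.6, 0.85)) {
    y <- rho_target * x + (1 - rho_target) * runif(8)
    sp <- spearmanAssociation(x, y)
    pExact <- exactSpearmanP(x, y)
    ## the measured worst-case |p_t - p_exact| over random untied draws at
    ## n = 8 is about 0.024, so 0.04 leaves honest headroom
    expect_lt(abs(sp$p - pExact), 0.04)
  }
})

test_that("tumor-normal t-test matches hand arithmetic and flags tiny groups", {
  b <- c(T1 = 0.1, T2 = 0.2, T3 = 0.3, N1 = 0.4, N2 = 0.5, N3 = 0.6)
  tis <- c(rep("tumor", 3), rep("normal", 3))
  tt <- tumorNormalTest(b, tis)
  ## pooled two-sample t by hand
  sp2 <- (2 * var(c(0.1, 0.2, 0.3)) + 2 * var(c(0.4, 0.5, 0.6))) / 4
  tHand <- (0.2 - 0.5) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, tHand)
  expect_equal(tt$df, 4)

  same <- tumorNormalTest(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), tis)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  tiny <- tumorNormalTest(c(0.1, NA, NA, 0.4, 0.5, 0.6), tis)
  expect_true(tiny$uncallable)

  tw <- tumorNormalTest(b, tis, welch = TRUE)
  expect_equal(tw$t, t.test(b[1:3], b[4:6])$statistic, ignore_attr = TRUE)
})

test_that("methylation shift is detected with high power", {
  ## +0.3 beta shift at an island probe, 100 tumors vs 40 normals
  set.seed(53)
  reject <- logical(200)
  for (i in 1:200) {
    tum <- pmin(rbeta(100, 5, 28) + 0.3, 1)
    nrm <- rbeta(40, 5, 28)
    tt <- tumorNormalTest(c(tum, nrm),
                          c(rep("tumor", 100), rep("normal", 40)))
    reject[i] <- tt$p < 1e-5
  }
  expect_gte(mean(reject), 0.95)
})

test_that("logistic fit recovers parameters and flags separation", {
  set.seed(4001)
  x <- rnorm(5000)
  y <- as.integer(runif(5000) < plogis(1 - 2 * x))
  fit <- fitMethylationLogit(y, x)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - 1) / 1, 0.1)
  expect_lt(abs(fit$slope - (-2)) / 2, 0.1)

  ## perfectly separated toy data
  xs <- c(seq(-2, -0.1, length.out = 10), seq(0.1, 2, length.out = 10))
  ys <- as.integer(xs > 0)
  sepFit <- fitMethylationLogit(ys, xs)
  expect_true(sepFit$separation)
  expect_false(fit$separation)

  ## single-class outcome
  oneClass <- fitMethylationLogit(rep(0L, 20), rnorm(20))
  expect_true(oneClass$separation)
  expect_false(oneClass$converged)

  expect_error(fitMethylationLogit(c(0L, 1L), c(0, 1)), ">= 10")
})

test_that("fitted coefficients sit at a local likelihood optimum", {
  set.seed(4002)
  x <- rnorm(400)
  y <- as.integer(runif(400) < plogis(0.5 - x))
  fit <- fitMethylationLogit(y, x)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log1p(-p))
  }
  llHat <- ll(fit$intercept, fit$slope)
  grid <- expand.grid(b0 = fit$intercept + seq(-0.5, 0.5, length.out = 21),
                      b1 = fit$slope + seq(-0.5, 0.5, length.out = 21))
  llGrid <- mapply(ll, grid$b0, grid$b1)
  expect_true(all(llGrid <= llHat + 1e-8))
})

test_that("attribution summary is the inverse-logit at min/median/max", {
  flat <- structure(list(intercept = 0, slope = 0, converged = TRUE,
                         separation = FALSE, n = 50, n_methylated = 25),
                    class = "methylLogit")
  expect_equal(unname(attributionSummary(flat, rnorm(50))), rep(0.5, 3))

  set.seed(4003)
  x <- rnorm(1000, 10, 2)
  y <- as.integer(runif(1000) < plogis(5 - 0.6 * x))
  fit <- fitMethylationLogit(y, x)
  at <- attributionSummary(fit, x)
  expect_identical(unname(at),
                   unname(plogis(fit$intercept + fit$slope *
                                   c(min(x), median(x), max(x)))))
  expect_true(all(diff(at) <= 0))      # negative slope: monotone decreasing
  expect_true(all(at >= 0 & at <= 1))

  bad <- structure(list(converged = FALSE, separation = TRUE),
                   class = "methylLogit")
  expect_error(attributionSummary(bad, x), "converged")
})

test_that("association table has one ordered row per retained island probe", {
  sim <- simulateCohort(simulationConfig(n_tumor = 120L, n_normal = 30L))
  pipe <- runPipeline(sim)
  tab <- associationTable(sim$cohort, pipe$calls, pipe$regions)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$distance_from_tss, c(300L, 54L, 12L, -8L, -15L))
  expect_true(all(c("probe_id", "distance_from_tss", "normal_mean",
                    "normal_sd", "tumor_mean", "tumor_sd", "pct_methylated",
                    "rho", "p") %in% colnames(tab)))
  ## SNP-flagged island probe is not reported
  expect_false("cg24550865" %in% tab$probe_id)

  withBH <- associationTable(sim$cohort, pipe$calls, pipe$regions,
                             adjust = TRUE)
  expect_true("p_bh" %in% colnames(withBH))
  expect_true(all(withBH$p_bh >= withBH$p))

  emptyReg <- new("ProbeRegions", island = character(),
                  flanking = pipe$regions@flanking,
                  excluded = data.frame(probe_id = character(),
                                        reason = character()))
  expect_warning(empty <- associationTable(sim$cohort, pipe$calls, emptyReg),
                 "empty")
  expect_identical(nrow(empty), 0L)
})
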
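# Global fitting: native-fraction interpolation, three-state and two-state
# fits, species-fraction curves.

test_that("native-fraction interpolation is linear, clipped and bounded", {
  ser <- DenaturationSeries(c(2, 3, 4), c(1.0, 0.5, 0.1), normalized = TRUE)
  expect_equal(interpolateFractionNative(ser, c(2, 3, 4)), c(1.0, 0.5, 0.1))
  expect_equal(interpolateFractionNative(ser, 2.5), 0.75)  # linear midpoint
  ## noisy values above 1 are clipped to a valid fraction
  noisy <- DenaturationSeries(c(0, 2, 4), c(1.04, 0.5, -0.02), normalized = TRUE)
  expect_equal(interpolateFractionNative(noisy, c(0, 4)), c(1, 0))
  expect_error(interpolateFractionNative(ser, 4.5), "outside")
})

test_that("noiseless three-state data are recovered exactly", {
  cfg <- GeneratorConfig(noiseSd = 0)
  ds <- generateDenaturationDataset(cfg)
  fit <- fitThreeState(ds$fluorNorm, ds$cdNorm, ds$scatterNorm)
  expect_true(isConverged(fit))
  expect_lt(max(abs(coef(fit) - c(c50 = 3.0, d = 0.45, a = 0.81, b = 0.24))), 1e-6)
  expect_lt(residualSS(fit), 1e-12)
})

test_that("fit results are invariant to input row order", {
  res <- fitSyntheticDataset(11)
  ds <- res$ds
  shuffle <- function(s) {
    ord <- sample(seq_along(s@urea))
    DenaturationSeries(s@urea[ord], s@mean[ord], s@sd[ord], s@nRep[ord],
                       probeLabel = s@probeLabel, normalized = s@normalized)
  }
  set.seed(99)
  fit2 <- fitThreeState(shuffle(ds$fluorNorm), shuffle(ds$cdNorm),
                        shuffle(ds$scatterNorm))
  expect_equal(coef(fit2), coef(res$fit), tolerance = 1e-12)
})

test_that("fixing b at zero degrades the fit on data generated with b > 0", {
  res <- fitSyntheticDataset(5)
  ds <- res$ds
  fitB0 <- fitThreeState(ds$fluorNorm, ds$cdNorm, ds$scatterNorm, fixBZero = TRUE)
  expect_true(fitB0@fixedBZero)
  expect_equal(unname(coef(fitB0)["b"]), 0)
  expect_false("b" %in% names(standardErrors(fitB0)))
  expect_gte(residualSS(fitB0), residualSS(res$fit))
})

test_that("inverse-SD weighting runs and degenerate data error out", {
  res <- fitSyntheticDataset(3)
  ds <- res$ds
  fitW <- fitThreeState(ds$fluorNorm, ds$cdNorm, ds$scatterNorm,
                        weights = "inverse_sd")
  expect_true(isConverged(fitW))
  expect_equal(unname(coef(fitW)["c50"]), 3.0, tolerance = 0.2)
  flat <- DenaturationSeries(seq(0, 7, 0.5), rep(0.5, 15), normalized = TRUE)
  expect_error(fitThreeState(flat, ds$cdNorm, ds$scatterNorm), "flat")
  short <- DenaturationSeries(c(0, 3, 7), c(1, 0.5, 0), normalized = TRUE)
  expect_error(fitThreeState(short, ds$cdNorm, ds$scatterNorm), "at least 6")
})

test_that("two-state fits recover noiseless LEM parameters exactly", {
  u <- seq(0, 7, by = 0.5)
  for (dir in c("native_referenced", "unfolded_referenced")) {
    pr <- predictTwoState(LEMParams(2.65, 0.4), u)
    y <- if (dir == "native_referenced") pr$Fnorm else pr$Dnorm
    fit <- fitTwoState(DenaturationSeries(u, y, normalized = TRUE), direction = dir)
    expect_true(isConverged(fit))
    expect_lt(max(abs(coef(fit) - c(c50 = 2.65, d = 0.4))), 1e-6)
  }
})

test_that("two-state fit flags midpoints outside the measured window", {
  u <- seq(0, 2, by = 0.25)  # transition at 4 M is far outside
  pr <- predictTwoState(LEMParams(4, 0.4), u)
  y <- pr$Fnorm + rnorm(length(u), 0, 0.01)
  fit <- suppressWarnings(fitTwoState(DenaturationSeries(u, y, normalized = TRUE)))
  expect_true(!isConverged(fit) || length(fit@warnings) > 0)
  expect_error(fitTwoState(DenaturationSeries(u, rep(1, length(u)), normalized = TRUE)),
               "flat")
})

test_that("species-fraction curves conserve mass and pin fN to scattering", {
  ## scattering plateau before the midpoint, so fN = 0 at the fitted c50
  res <- fitSyntheticDataset(2, noiseSd = 0, scatterBreakpoint = 2.5)
  grid <- seq(0, 7, by = 0.1)
  tab <- speciesFractionCurves(res$fit, res$ds$scatterNorm, grid)
  expect_equal(tab$fN + tab$fI + tab$fU, rep(1, nrow(tab)), tolerance = 1e-9)
  expect_equal(tab$fN, interpolateFractionNative(res$ds$scatterNorm, grid))
  expect_equal(tab$fN[1], 1)
  expect_equal(c(tab$fI[1], tab$fU[1]), c(0, 0))
  ## with fN = 0 at the midpoint, I and U are present in equal amounts
  atC50 <- tab[which.min(abs(tab$urea - coef(res$fit)["c50"])), ]
  expect_equal(atC50$fI, 0.5, tolerance = 0.01)
  expect_equal(atC50$fU, 0.5, tolerance = 0.01)
  ## the I/U ratio equals K wherever protein has left the barrel
  lem <- fitParams(res$fit)@lem
  nn <- tab$fN < 1
  expect_equal(tab$fU[nn] / tab$fI[nn], equilibriumK(lem, tab$urea[nn]),
               tolerance = 1e-9)
  ## the intermediate maximum is reported
  mx <- attr(tab, "maxI")
  expect_equal(mx$fI, max(tab$fI))
  expect_equal(tab$fI[tab$urea == mx$urea], mx$fI)
  expect_error(speciesFractionCurves(res$fit, res$ds$scatterNorm, seq(0, 8, 0.5)),
               "outside")
})

test_that("parameter standard errors are positive and finite on noisy data", {
  res <- fitSyntheticDataset(8)
  se <- standardErrors(res$fit)
  expect_true(all(is.finite(se)))
  expect_true(all(se > 0))
  expect_named(se, c("c50", "d", "a", "b"))
  expect_true(all(dim(res$fit@covariance) == c(4, 4)))
  ## covariance symmetric with non-negative diagonal
  expect_equal(res$fit@covariance, t(res$fit@covariance))
})
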
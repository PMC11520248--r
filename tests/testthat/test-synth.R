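# Synthetic-data generator: scattering profile, dataset construction,
# spectra, determinism, and the end-to-end preprocessing property.

test_that("scattering profile decays linearly to a six-fold lower plateau", {
  cfg <- GeneratorConfig(noiseSd = 0, ureaGrid = seq(0, 7, by = 0.25))
  ser <- generateScatteringProfile(cfg)
  sg <- cfg@signals
  expect_equal(sg@SN / sg@SIU, 6)
  u <- ureaValues(ser)
  ## plateau at and beyond the breakpoint
  expect_equal(signalMeans(ser)[u >= 3.5], rep(sg@SIU, sum(u >= 3.5)))
  ## linear midpoint at half the breakpoint
  expect_equal(signalMeans(ser)[u == 1.75], (sg@SN + sg@SIU) / 2)
  expect_equal(signalMeans(ser)[u == 0], sg@SN)
})

test_that("generator output is bit-identical under identical seeds", {
  cfgA <- GeneratorConfig(seed = 17L)
  cfgB <- GeneratorConfig(seed = 17L)
  dsA <- generateDenaturationDataset(cfgA)
  dsB <- generateDenaturationDataset(cfgB)
  expect_identical(signalMeans(dsA$fluor), signalMeans(dsB$fluor))
  expect_identical(signalMeans(dsA$cd), signalMeans(dsB$cd))
  expect_identical(signalMeans(dsA$scatter), signalMeans(dsB$scatter))
  dsC <- generateDenaturationDataset(GeneratorConfig(seed = 18L))
  expect_false(identical(signalMeans(dsA$fluor), signalMeans(dsC$fluor)))
  ## the generator must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generateDenaturationDataset(cfgA)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("dataset structure matches the replicate and monotonicity contracts", {
  cfg <- GeneratorConfig(nRep = 3L)
  ds <- generateDenaturationDataset(cfg)
  expect_equal(nReplicates(ds$fluor), rep(3L, 15))
  expect_equal(nReplicates(ds$cd), rep(3L, 15))
  ## noiseless normalized curves are monotone in urea
  nl <- generateDenaturationDataset(GeneratorConfig(noiseSd = 0))
  expect_true(all(diff(signalMeans(nl$fluorNorm)) <= 1e-12))
  expect_true(all(diff(signalMeans(nl$cdNorm)) >= -1e-12))
  ## truth record carries the generating parameters
  expect_equal(coef(nl$truth$params), c(c50 = 3.0, d = 0.45, a = 0.81, b = 0.24))
})

test_that("forcing a fully native system gives flat anchor signals", {
  cfg <- GeneratorConfig(noiseSd = 0, scatterBreakpoint = 1e9)  # fN ~ 1
  ds <- generateDenaturationDataset(cfg)
  expect_equal(signalMeans(ds$fluorNorm), rep(1, 15), tolerance = 1e-8)
  expect_equal(signalMeans(ds$cdNorm), rep(0, 15), tolerance = 1e-8)
})

test_that("emission spectra shift from 335 to 344 nm across the transition", {
  cfg <- GeneratorConfig(noiseSd = 0, nRep = 1L)
  sp <- generateSpectraSet(cfg)
  u <- vapply(sp$emission, ureaValues, numeric(1))
  lm <- vapply(sp$emission, function(s) lambdaMax(movingAverage(s, 5)), numeric(1))
  expect_lte(abs(lm[u == 0] - 335), 1)        # native-like maximum
  expect_lte(abs(lm[u == 7] - 344), 1)        # unfolded maximum, red-shifted
  expect_true(all(diff(lm) >= 0))             # monotone red shift
})

test_that("native CD spectra show the helix minima at 208 and 222 nm", {
  cfg <- GeneratorConfig(noiseSd = 0, nRep = 1L)
  sp <- generateSpectraSet(cfg)
  cd0 <- sp$cd[[1]]
  expect_equal(ureaValues(cd0), 0)
  wl <- wavelengths(cd0); v <- signalValues(cd0)
  isLocalMin <- function(nm) {
    i <- which(wl == nm)
    v[i] < v[i - 2] && v[i] < v[i + 2]
  }
  expect_true(isLocalMin(208))
  expect_true(isLocalMin(222))
  expect_true(all(v[wl %in% 205:225] < 0))
  ## unfolded spectrum: single coil band, no 222 minimum structure
  cdU <- sp$cd[[length(sp$cd)]]
  expect_gt(signalValues(cdU)[wl == 222], v[wl == 222])  # much weaker helix signal
})

test_that("preprocessing spectra reproduces the generated series", {
  cfg <- GeneratorConfig(noiseSd = 0, nRep = 1L)
  sp <- generateSpectraSet(cfg)
  ds <- generateDenaturationDataset(cfg)
  extract <- function(specs, fun) {
    data.frame(urea = vapply(specs, ureaValues, numeric(1)),
               value = vapply(specs, function(s) fun(movingAverage(s, 5)), numeric(1)))
  }
  i335 <- buildDenaturationSeries(extract(sp$emission, function(s) extractSignal(s, 335)), "I335")
  cd222 <- buildDenaturationSeries(extract(sp$cd, function(s) extractSignal(s, 222)), "CD222")
  ## normalize both routes with the same plateau rule and compare
  nF1 <- normalizeSeries(i335)
  nF2 <- normalizeSeries(ds$fluor)
  nD1 <- normalizeSeries(cd222, nativeRange = c(6.5, 7), unfoldedRange = c(0, 0.5))
  nD2 <- normalizeSeries(ds$cd, nativeRange = c(6.5, 7), unfoldedRange = c(0, 0.5))
  expect_equal(signalMeans(nF1), signalMeans(nF2), tolerance = 0.02)
  expect_equal(signalMeans(nD1), signalMeans(nD2), tolerance = 0.02)
})

test_that("plateau normalization of raw series approximates the truth scale", {
  ds <- generateDenaturationDataset(GeneratorConfig(noiseSd = 0))
  nrm <- normalizeSeries(ds$fluor)
  ## plateau-based normalization differs from truth normalization only by a
  ## small affine distortion (the model plateaus are not exactly 0/1)
  expect_equal(signalMeans(nrm), signalMeans(ds$fluorNorm), tolerance = 0.02)
})
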
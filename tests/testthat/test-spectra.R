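# Spectral preprocessing: reading, smoothing, probe extraction, series
# assembly and normalization.

makeSpectrumFile <- function(wl, v, header = TRUE, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  lines <- paste(wl, v, sep = sep)
  if (header) lines <- c("wavelength\tsignal", lines)
  writeLines(lines, path)
  path
}

test_that("spectral tables round-trip through readSpectrumTable", {
  wl <- 300:450
  v <- dnorm(wl, 335, 15)
  p <- makeSpectrumFile(wl, v)
  sp <- readSpectrumTable(p, probe = "fluorescence", urea = 2)
  expect_s4_class(sp, "Spectrum")
  expect_length(wavelengths(sp), 151)
  expect_equal(signalValues(sp), v)
  expect_equal(ureaValues(sp), 2)

  ## rows out of order are sorted to the same spectrum
  ord <- sample(seq_along(wl))
  p2 <- makeSpectrumFile(wl[ord], v[ord])
  expect_equal(readSpectrumTable(p2)@values, v)

  ## duplicated wavelength is a parse error naming the line
  p3 <- makeSpectrumFile(c(300, 335, 335, 336), c(1, 2, 3, 4))
  expect_error(readSpectrumTable(p3), "duplicated wavelength 335.*line")
  expect_error(readSpectrumTable(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("non-numeric data rows are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wl\tv", "300\t1.0", "301\toops\tx", "302\t2.0"), path)
  ## second column not numeric -> error (row has NA in first two fields)
  expect_error(readSpectrumTable(path), "non-numeric row at line 3")
})

test_that("moving average uses a truncated window and preserves constants", {
  wl <- 300:360
  const <- Spectrum(wl, rep(7, length(wl)))
  expect_equal(signalValues(movingAverage(const, 5)), rep(7, 61))

  ## unit spike: hand convolution gives 1/11 at the 11 points within +/-5 nm
  v <- rep(0, 61); v[31] <- 11
  sm <- movingAverage(Spectrum(wl, v), 5)
  expected <- rep(0, 61); expected[26:36] <- 1
  expect_equal(signalValues(sm), expected)

  ## first grid point: mean of the 6 available points
  v2 <- seq_along(wl)  # values 1..61
  sm2 <- movingAverage(Spectrum(wl, v2), 5)
  expect_equal(signalValues(sm2)[1], mean(1:6))
  expect_equal(signalValues(sm2)[61], mean(56:61))

  expect_error(movingAverage(Spectrum(c(300, 301, 303), c(1, 2, 3)), 5),
               "uniform")
})

test_that("signal extraction uses the nearest grid point within range", {
  sp <- Spectrum(300:450, as.numeric(300:450))
  sp@values[sp@wavelengths == 335] <- 42
  expect_equal(extractSignal(sp, 335), 42)
  expect_equal(extractSignal(sp, 335.4), 42)  # nearest-point rule
  expect_error(extractSignal(sp, 299), "outside grid range")
})

test_that("lambdaMax finds the global maximum with low-wavelength tie-break", {
  wl <- 300:450
  expect_equal(lambdaMax(Spectrum(wl, dnorm(wl, 335, 10))), 335)
  ## flat-top plateau spanning 340-344 nm resolves to 340
  v <- rep(0, length(wl)); v[wl >= 340 & wl <= 344] <- 5
  expect_equal(lambdaMax(Spectrum(wl, v)), 340)
  ## monotone decreasing spectrum peaks at the first grid point
  expect_equal(lambdaMax(Spectrum(wl, rev(seq_along(wl)))), 300)
  ## row-order invariance
  ord <- sample(seq_along(wl))
  expect_equal(lambdaMax(Spectrum(wl[ord], dnorm(wl, 344, 9)[ord])), 344)
})

test_that("rayleighScatter averages the 295-305 nm window", {
  wl <- 280:320
  expect_equal(rayleighScatter(Spectrum(wl, rep(100, 41), probe = "scattering")), 100)
  ## values equal to wavelength average to 300 over 295..305
  expect_equal(rayleighScatter(Spectrum(wl, as.numeric(wl), probe = "scattering")), 300)
  ## point-symmetric spectrum about (300, v(300)) equals its value at 300
  sym <- Spectrum(wl, 50 + (wl - 300)^3 / 100, probe = "scattering")
  expect_equal(rayleighScatter(sym), extractSignal(sym, 300))
  expect_error(rayleighScatter(Spectrum(301:450, rep(1, 150))), "295-305")
})

test_that("CD 222/208 ratio detects coiled-coil signatures and flags noise", {
  wl <- 190:250
  mk <- function(v222, v208, urea = 0) {
    v <- rep(-1, length(wl)); v[wl == 222] <- v222; v[wl == 208] <- v208
    Spectrum(wl, v, probe = "cd", urea = urea)
  }
  expect_equal(as.numeric(cdRatio222208(mk(-10, -10))), 1.0)
  r <- cdRatio222208(mk(-11, -10))
  expect_equal(as.numeric(r), 1.1)   # ratio > 1: interacting helices
  expect_true(attr(r, "usable"))
  expect_false(attr(cdRatio222208(mk(-11, -10, urea = 5)), "usable"))
  expect_error(cdRatio222208(mk(-11, 0)), "unusable")
})

test_that("denaturation series aggregate replicates with sample SD", {
  pts <- data.frame(urea = c(0, 0, 0, 1, 2, 2),
                    value = c(1, 2, 3, 5, 4, 6))
  ser <- buildDenaturationSeries(pts, "I335")
  expect_equal(ureaValues(ser), c(0, 1, 2))
  expect_equal(signalMeans(ser), c(2, 5, 5))
  expect_equal(signalSds(ser), c(1, 0, sd(c(4, 6))))  # single replicate: sd 0
  expect_equal(nReplicates(ser), c(3L, 1L, 2L))
  ## unsorted input comes out sorted
  ser2 <- buildDenaturationSeries(pts[c(5, 1, 4, 2, 6, 3), ], "I335")
  expect_equal(signalMeans(ser2), signalMeans(ser))
  expect_error(buildDenaturationSeries(data.frame(urea = numeric(), value = numeric())),
               "no measurements")
})

test_that("plateau normalization maps native to 1 and unfolded to 0", {
  u <- seq(0, 7, by = 0.5)
  v <- c(10, 10, 8, 7, 6, 5.5, 5, 4.5, 4, 3.5, 3, 2.5, 2.2, 2, 2)
  ser <- DenaturationSeries(u, v, sd = rep(0.5, 15))
  nrm <- normalizeSeries(ser)
  expect_true(isNormalized(nrm))
  expect_equal(signalMeans(nrm)[1], 1)        # point equal to native mean
  ## linear map: native mean 10, unfolded mean 2, value 6 -> 0.5
  expect_equal((6 - 2) / (10 - 2), 0.5)
  expect_equal(signalMeans(nrm)[5], (6 - 2) / (10 - 2))
  ## inverse affine map reproduces the input to near machine precision
  back <- signalMeans(nrm) * (10 - 2) + 2
  expect_equal(back, v, tolerance = 1e-12)
  ## SDs scale by the amplitude
  expect_equal(signalSds(nrm), rep(0.5 / 8, 15))
  ## equal plateau means cannot be normalized
  flat <- DenaturationSeries(u, rep(3, 15))
  expect_error(normalizeSeries(flat), "equal")
})

test_that("out-of-[0,1] normalized points are flagged, not dropped", {
  u <- seq(0, 7, by = 0.5)
  v <- c(10.4, 10, 8, 7, 6, 5.5, 5, 4.5, 4, 3.5, 3, 2.5, 2.2, 2, 2)
  nrm <- normalizeSeries(DenaturationSeries(u, v))
  expect_true(length(attr(nrm, "outside01")) >= 1)
  expect_equal(length(signalMeans(nrm)), 15)
})

test_that("kinetic normalization anchors 6 ms to 1 and 100 s to 0", {
  tr <- simulateKineticTrace(rate = 0.05, amplitude = 40, plateau = 10)
  nrm <- normalizeKinetics(tr)
  tt <- tr@time
  expect_equal(signalValues(nrm)[which.min(abs(tt - 0.006))], 1)
  expect_equal(signalValues(nrm)[which.min(abs(tt - 100))], 0)
  ## affine map: value(6ms)=50, value(100s)=10 -> a reading of 30 maps to 0.5
  expect_equal((30 - 10) / (50 - 10), 0.5)
  ## idempotence: renormalizing an already-normalized trace is a no-op
  expect_equal(signalValues(normalizeKinetics(nrm)), signalValues(nrm))
  ## equal anchors are an error
  flat <- KineticTrace(tr@time, rep(2, length(tr@time)))
  expect_error(normalizeKinetics(flat), "equal")
})
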
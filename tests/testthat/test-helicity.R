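# Dihedral computation, the helical window, triplet assignment, propensity
# profiles, region aggregation and the H-bond potential.

test_that("dihedrals from ideal helix coordinates recover the inputs", {
  co <- idealHelixCoords(12, phi = -57, psi = -47)
  dh <- computeDihedrals(co)
  interior <- 3:10
  expect_equal(unname(dh@phi[1, interior]), rep(-57, 8), tolerance = 1e-6)
  expect_equal(unname(dh@psi[1, interior]), rep(-47, 8), tolerance = 1e-6)
  ## termini are undefined
  expect_true(is.na(dh@phi[1, 1]))
  expect_true(is.na(dh@psi[1, 12]))
  ## agreement with an independent torsion implementation
  p <- rbind(c(0.3, -1.2, 0.5), c(1.4, 0.1, 0.2), c(2.2, 1.1, 1.0), c(3.6, 1.0, 0.4))
  expect_equal(im30unfold:::.dihedral4(p[1, ], p[2, ], p[3, ], p[4, ]),
               bio3d::torsion.xyz(as.numeric(t(p))), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate and missing geometry yields NA, not silence", {
  co <- idealHelixCoords(5)
  co[1, 3, 2, ] <- NA  # knock out one Ca
  dh <- computeDihedrals(co)
  expect_true(is.na(dh@phi[1, 3]))
  expect_true(is.na(dh@psi[1, 3]))
  ## colinear atoms have no defined torsion
  expect_true(is.na(im30unfold:::.dihedral4(c(0, 0, 0), c(1, 0, 0),
                                            c(2, 0, 0), c(3, 0, 0))))
  expect_error(computeDihedrals(idealHelixCoords(2)), "at least 3")
})

test_that("the helical window is open on all boundaries", {
  expect_true(isHelicalForm(-60, -45))     # canonical alpha-helix
  expect_false(isHelicalForm(-170, -45))   # phi outside
  expect_false(isHelicalForm(-60, 60))     # psi outside
  ## boundaries themselves are excluded
  expect_false(isHelicalForm(-160, -45))
  expect_false(isHelicalForm(-20, -45))
  expect_false(isHelicalForm(-60, -120))
  expect_false(isHelicalForm(-60, 50))
  expect_false(isHelicalForm(NA, -45))
  ## vectorized
  expect_equal(isHelicalForm(c(-60, -170), c(-45, -45)), c(TRUE, FALSE))
})

test_that("triplet assignment matches brute force on random flag strings", {
  expect_equal(assignAlphaHelix(c(FALSE, TRUE, TRUE, TRUE, FALSE)),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(assignAlphaHelix(rep(TRUE, 5)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(assignAlphaHelix(c(TRUE, TRUE)), c(FALSE, FALSE))
  set.seed(7)
  for (i in 1:500) {
    n <- sample(1:20, 1)
    flags <- runif(n) < 0.6
    got <- assignAlphaHelix(flags)
    expect_identical(got, bruteForceTriplet(flags))
    expect_true(all(got <= flags))  # assignment never adds helicity
  }
})

test_that("propensity profiles average the triplet rule over frames", {
  co <- idealHelixCoords(10, nFrames = 4)
  prof <- helicalPropensityProfile(computeDihedrals(co))
  expect_equal(unname(propensity(prof))[3:8], rep(1, 6))
  expect_equal(unname(propensity(prof))[c(1, 2, 9, 10)], rep(0, 4))
  expect_equal(nFrames(prof), 4L)

  ## helical in exactly half the frames -> 0.5
  helix <- idealHelixCoords(10)[1, , , ]
  coil <- idealHelixCoords(10, phi = 70, psi = 120)[1, , , ]
  co2 <- array(NA_real_, c(2, 10, 3, 3))
  co2[1, , , ] <- helix; co2[2, , , ] <- coil
  prof2 <- helicalPropensityProfile(computeDihedrals(co2))
  expect_equal(unname(propensity(prof2))[5], 0.5)

  ## frame-order invariance
  co3 <- co2[2:1, , , , drop = FALSE]
  expect_equal(propensity(helicalPropensityProfile(computeDihedrals(co3))),
               propensity(prof2))
})

test_that("random-coil propensity approaches the window probability cubed", {
  ## under independent uniform angles, P(triplet) = p^3 with
  ## p = (140/360) * (170/360); Monte Carlo against direct simulation
  set.seed(11)
  nf <- 4000; nr <- 5
  phi <- matrix(runif(nf * nr, -180, 180), nf)
  psi <- matrix(runif(nf * nr, -180, 180), nf)
  prof <- helicalPropensityProfile(DihedralSeries(phi, psi))
  p <- (140 / 360) * (170 / 360)
  expect_equal(unname(propensity(prof))[3], p^3, tolerance = 0.25)
  expect_equal(unname(propensity(prof))[c(1, nr)], c(0, 0))  # termini never helical
})

test_that("region helicity is an unweighted mean over residue ranges", {
  prof <- new("HelicityProfile", propensity = c(0.2, 0.8, 0.6, 0.6),
              nFrames = 10L, residueIds = 1:4)
  expect_equal(unname(regionHelicity(prof, list(r = c(1, 2)))), 0.5)
  expect_equal(unname(regionHelicity(prof, list(all = c(1, 4)))), 0.55)
  both <- regionHelicity(prof, list(a = c(1, 2), b = c(3, 4)))
  expect_equal(unname(both), c(0.5, 0.6))
  ## region mean never exceeds the regional maximum
  expect_lte(both[["a"]], max(prof@propensity[1:2]))
  expect_error(regionHelicity(prof, list(bad = c(5, 8))), "no residues")
  expect_error(regionHelicity(prof, list(bad = c(3, 9))), "beyond")
})

test_that("the H-bond potential has its minimum at sigma with depth lambda*eps", {
  hp <- HBondParams(lambda = 1, epsilonHb = 2, sigmaHb = 1.5)
  expect_equal(hbondPotential(1.5, hp), -2)
  ## 5(s/r)^12 - 6(s/r)^10 = -1 at r = s; global minimum on a fine grid
  r <- seq(0.8, 8, by = 1e-4)
  v <- hbondPotential(r, hp)
  expect_equal(min(v), -2, tolerance = 1e-6)
  expect_equal(r[which.min(v)], 1.5, tolerance = 1e-3)
  expect_lt(abs(v[length(v)]), 1e-3)              # decays to zero
  ## angular domain: zero at or beyond 90 degrees
  expect_equal(hbondPotential(1.5, hp, thetaN = 95), 0)
  expect_equal(hbondPotential(1.5, hp, thetaC = 90), 0)
  ## cosine-squared modulation and linear lambda scaling
  expect_equal(hbondPotential(1.5, hp, thetaN = 60), -2 * cos(pi / 3)^2)
  hp75 <- HBondParams(lambda = 0.75, epsilonHb = 2, sigmaHb = 1.5)
  expect_equal(hbondPotential(1.5, hp75), -0.75 * 2)
  expect_equal(hbondPotential(r, hp75), 0.75 * v)  # monotone in lambda
  expect_error(hbondPotential(-1, hp), "positive")
})

test_that("dihedral tables read from text preserve angles and gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- expand.grid(frame = 1:3, residue = 1:4)
  tab$phi <- -57 + tab$residue
  tab$psi <- -47 - tab$frame
  tab <- tab[-5, ]  # drop one (frame, residue) combination
  write.csv(tab, path, row.names = FALSE)
  dh <- readDihedralTable(path)
  expect_equal(dim(dh@phi), c(3, 4))
  expect_equal(dh@phi[1, 2], -55)
  expect_true(any(is.na(dh@phi)))
})
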
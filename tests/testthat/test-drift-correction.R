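test_that("inverse-square weights match hand arithmetic", {
  expect_equal(unname(tipWeights(c(0, 0, 0), rbind(c(5, 0, 0)))), 1)
  w <- tipWeights(c(0, 0, 0), rbind(c(1, 0, 0), c(2, 0, 0)))
  expect_equal(unname(w), c(0.8, 0.2))
  w3 <- tipWeights(c(0, 0, 0),
                   rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)))
  expect_equal(unname(w3), rep(1 / 3, 3))
  # coincidence takes the limit: full weight on the touching tip
  wc <- tipWeights(c(1, 1, 1), rbind(c(1, 1, 1), c(9, 9, 9)))
  expect_equal(unname(wc), c(1, 0))
  expect_true(all(w >= 0) && abs(sum(w) - 1) < 1e-12)
})

test_that("weight on a tip tends to 1 as the cell approaches it", {
  tips <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  wprev <- 0
  for (d in c(5, 1, 0.1, 0.01)) {
    w <- tipWeights(c(d, 0, 0), tips)[1]
    expect_gt(w, wprev)
    wprev <- w
  }
  expect_gt(wprev, 0.999)
})

test_that("corrected movement subtracts weighted tip drift, xy only", {
  got <- correctedMovement(c(3, 1, 2), rbind(c(2, 0, 0), c(0, 2, 0)),
                           c(0.75, 0.25))
  expect_equal(got, c(1.5, 0.5, 2))
  # riding a single tip exactly -> zero horizontal movement
  ride <- correctedMovement(c(2, -1, 0.3), rbind(c(2, -1, 0)), 1)
  expect_equal(ride, c(0, 0, 0.3))
  # static tips -> correction is the identity
  stat <- correctedMovement(c(1, 2, 3), rbind(c(0, 0, 0), c(0, 0, 0)),
                            c(0.5, 0.5))
  expect_equal(stat, c(1, 2, 3))
})

test_that("positions rebuild as cumulative sums anchored at the raw start", {
  pos <- cbind(0:4, 2 * (0:4), c(1, 2, 1, 2, 1))
  zero <- reconstructPositions(pos, matrix(0, 4, 3))
  expect_equal(zero[, 1], rep(0, 5))
  expect_equal(zero[, 2], rep(0, 5))
  expect_equal(zero[, 3], pos[, 3])  # z always raw
  ident <- reconstructPositions(pos, diff(pos))
  expect_equal(ident, pos)
})

test_that("static tips leave tracks unchanged; riding cells are zeroed", {
  sc <- smallScenario(tipSpeed = 0, sigma = 1.2,
                      profile = kProfile(0, 1, 0, 0), divisionProb = 0,
                      zJitterSd = 0)
  sim <- simulateTracks(sc, seed = 41)
  cc <- driftCorrect(resolveBranches(sim$dataset))
  expect_equal(cc$corr_x, cc$pos_x, tolerance = 1e-10)
  expect_equal(cc$corr_y, cc$pos_y, tolerance = 1e-10)
  expect_identical(cc$corr_z, cc$pos_z)

  # sigma = 0, k = 0, one moving tip: cells ride the tip exactly
  sc2 <- syntheticScenario(nTips = 1L, nCells = 20L, nSteps = 15L,
                           sigma = 0, profile = kProfile(0, 1, 0, 0),
                           divisionProb = 0, zJitterSd = 0, tipSpeed = 0.5,
                           cloudPoints = 20L,
                           bounds = c(-100, 260, -100, 260, -90, 150))
  sim2 <- simulateTracks(sc2, seed = 42)
  cc2 <- driftCorrect(resolveBranches(sim2$dataset))
  step_x <- with(cc2, ave(corr_x, segment, FUN = function(x) c(0, diff(x))))
  step_y <- with(cc2, ave(corr_y, segment, FUN = function(x) c(0, diff(x))))
  expect_lt(max(abs(c(step_x, step_y))), 1e-9)
})

test_that("uniform bulk drift is removed exactly", {
  sim <- simulateTracks(smallScenario(zJitterSd = 0, divisionProb = 0),
                        seed = 43)
  ds <- resolveBranches(sim$dataset)
  cc1 <- driftCorrect(ds)

  # translate cells and tips by the same per-step drift vector
  drift_per_step <- c(0.7, -0.4)
  sp <- spots(ds); te <- tipEnds(ds)
  sp$pos_x <- sp$pos_x + drift_per_step[1] * sp$time
  sp$pos_y <- sp$pos_y + drift_per_step[2] * sp$time
  te$pos_x <- te$pos_x + drift_per_step[1] * te$time
  te$pos_y <- te$pos_y + drift_per_step[2] * te$time
  si <- sampleInfo(ds)
  si$x_min <- si$x_min - 100; si$x_max <- si$x_max + 100
  si$y_min <- si$y_min - 100; si$y_max <- si$y_max + 100
  ds2 <- trackDataset(sp, tipClouds = tipClouds(ds), tipEnds = te,
                      sampleInfo = si)
  cc2 <- driftCorrect(ds2)
  o1 <- order(cc1$segment, cc1$time); o2 <- order(cc2$segment, cc2$time)
  d1 <- with(cc1[o1, ], ave(corr_x, segment, FUN = function(x) c(0, diff(x))))
  d2 <- with(cc2[o2, ], ave(corr_x, segment, FUN = function(x) c(0, diff(x))))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("correction recovers intrinsic Brownian motion under tip advection", {
  sc <- syntheticScenario(nTips = 2L, nCells = 80L, nSteps = 50L,
                          sigma = 1.5, profile = kProfile(0, 1, 0, 0),
                          divisionProb = 0, zJitterSd = 0, tipSpeed = 0.8,
                          cloudPoints = 20L,
                          bounds = c(0, 400, 0, 400, -100, 200))
  sim <- simulateTracks(sc, seed = 44)
  ds <- resolveBranches(sim$dataset)
  cc <- driftCorrect(ds)
  si <- sampleInfo(ds)
  cc$step_minutes <- si$step_minutes[1]
  taus <- 1:8
  m_raw <- aggregateMsd(cc, taus, "raw")
  m_cor <- aggregateMsd(cc, taus, "corrected")
  # corrected MSD is linear with slope ~ 3 sigma^2 (3D Brownian)
  slope <- stats::coef(stats::lm(value ~ 0 + tau, data = m_cor))[[1]]
  expect_lt(abs(slope - 3 * 1.5^2) / (3 * 1.5^2), 0.15)
  fit_cor <- stats::lm(value ~ tau + I(tau^2), data = m_cor)
  expect_gt(summary(fit_cor)$coefficients["I(tau^2)", "Pr(>|t|)"], 0.01)
  # raw MSD curves upward (persistent advection): significant quadratic term
  fit_raw <- stats::lm(value ~ tau + I(tau^2), data = m_raw)
  expect_lt(summary(fit_raw)$coefficients["I(tau^2)", "Pr(>|t|)"], 0.01)
  expect_gt(stats::coef(fit_raw)[["I(tau^2)"]], 0)
})
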
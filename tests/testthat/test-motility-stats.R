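test_that("MSD closed forms: static, ballistic, Brownian", {
  static <- matrix(5, 10, 3)
  for (tau in 1:4) expect_equal(msd(static, tau), 0)

  v <- 1.3
  ballistic <- cbind(v * (0:20), 0, 0)
  for (tau in c(1, 3, 7)) expect_equal(msd(ballistic, tau), (v * tau)^2)

  # too-short tracks are excluded, not zero
  expect_true(is.na(msd(ballistic[1:3, ], 5)))

  set.seed(51)
  sigma <- 0.8
  taus <- 1:5
  vals <- sapply(1:500, function(i) {
    p <- apply(matrix(stats::rnorm(40 * 3, 0, sigma), ncol = 3), 2, cumsum)
    vapply(taus, function(tau) msd(p, tau), numeric(1))
  })
  pooled <- rowMeans(vals)
  expect_equal(pooled, 3 * sigma^2 * taus, tolerance = 0.05)
})

test_that("MSD is invariant under rigid motion of the whole field", {
  set.seed(52)
  p <- apply(matrix(stats::rnorm(60), ncol = 3), 2, cumsum)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(p %*% t(R), 2, c(10, -3, 7), "+")
  for (tau in 1:3) {
    expect_equal(msd(moved, tau), msd(p, tau))
    expect_equal(velocityAutocorrelation(moved, tau),
                 velocityAutocorrelation(p, tau))
  }
})

test_that("velocity autocorrelation canonical values", {
  const <- cbind(2 * (0:10), 3 * (0:10), 0)
  for (tau in 1:4) expect_equal(velocityAutocorrelation(const, tau), 1)

  alt <- cbind(c(0, 1, 0, 1, 0, 1, 0), 0, 0)  # steps +1,-1,+1,...
  expect_equal(velocityAutocorrelation(alt, 1), -1)
  expect_equal(velocityAutocorrelation(alt, 2), 1)

  set.seed(53)
  m <- mean(replicate(500, {
    p <- apply(matrix(stats::rnorm(30 * 2), ncol = 2), 2, cumsum)
    velocityAutocorrelation(cbind(p, 0), 1)
  }))
  expect_lt(abs(m), 0.02)

  expect_warning(
    out <- velocityAutocorrelation(matrix(1, 10, 3), 1), "undefined")
  expect_true(is.na(out))
})

test_that("aggregation averages per track and separates time-step groups", {
  tr <- data.frame(sample = "s", segment = "s.1.a.1", time = 0:9,
                   pos_x = as.numeric(0:9), pos_y = 0, pos_z = 0,
                   step_minutes = 20)
  curve <- aggregateMsd(tr, 1:3, "raw")
  expect_equal(curve$value, c(1, 4, 9))
  expect_equal(curve$n_tracks, rep(1L, 3))
  # two identical tracks: same mean, n = 2
  tr2 <- tr; tr2$segment <- "s.1.b.1"
  curve2 <- aggregateMsd(rbind(tr, tr2), 1:3, "raw")
  expect_equal(curve2$value, curve$value)
  expect_equal(curve2$n_tracks, rep(2L, 3))
  # 15- and 20-minute data aggregate separately
  tr3 <- tr; tr3$segment <- "s.1.c.1"; tr3$step_minutes <- 15
  curve3 <- aggregateMsd(rbind(tr, tr2, tr3), 1, "raw")
  expect_equal(nrow(curve3), 2L)
  expect_setequal(curve3$step_minutes, c(15, 20))
  expect_error(aggregateMsd(tr[, setdiff(names(tr), "step_minutes")], 1),
               "step_minutes")
})

test_that("speed heterogeneity recovers a planned variance fraction", {
  # all-equal speeds: no reduction
  eq <- data.frame(sample = "s", segment = rep(c("a", "b"), each = 5),
                   speed = 1)
  out <- speedHeterogeneity(eq)
  expect_equal(out$rss_reduction_percent, 0)

  set.seed(54)
  f <- 0.3   # planned fraction of within-sample variance due to track
  sigma2 <- 1; tau2 <- sigma2 * f / (1 - f)
  sp <- do.call(rbind, lapply(1:2, function(s) {
    do.call(rbind, lapply(1:40, function(tr) {
      mu <- stats::rnorm(1, s, sqrt(tau2))
      data.frame(sample = paste0("s", s),
                 segment = sprintf("s%d.t%02d", s, tr),
                 speed = stats::rnorm(60, mu, sqrt(sigma2)))
    }))
  }))
  got <- speedHeterogeneity(sp)
  expect_lt(got$p, 1e-10)
  expect_equal(got$rss_reduction_percent, 100 * f, tolerance = 0.2)
  # single-observation tracks are retained without breaking the fit
  sp1 <- rbind(sp, data.frame(sample = "s1", segment = "s1.solo", speed = 2))
  expect_no_error(speedHeterogeneity(sp1))
})

test_that("edge exclusion is strict at 1 µm in xy only", {
  bounds <- data.frame(sample = "s", crop = "1", x_min = 0, x_max = 100,
                       y_min = 0, y_max = 100)
  sp <- data.frame(sample = "s", crop = "1",
                   pos_x = c(50, 0.5, 1.0, 99.2, 50),
                   pos_y = c(50, 50, 50, 50, 99.5),
                   pos_z = c(0.1, 50, 50, 50, 50))  # z never excludes
  kept <- excludeNearEdge(sp, bounds, margin = 1)
  expect_equal(kept$pos_x, c(50, 1.0))
  sp_bad <- sp; sp_bad$crop <- "2"
  expect_error(excludeNearEdge(sp_bad, bounds), "bounds")
})

test_that("tip-directed projection follows the dot-product arithmetic", {
  mk <- function(u, mv, d = 5) {
    data.frame(sample = "s", crop = "1", segment = "g", time = 0:1,
               tip_dx = u[1], tip_dy = u[2], tip_dz = u[3],
               tip_distance = d,
               corr_x = c(0, mv[1]), corr_y = c(0, mv[2]),
               corr_z = c(0, mv[3]))
  }
  along <- tipDirectedMovement(mk(c(1, 0, 0), c(2, 0, 0)))
  expect_equal(along$m, 2)
  ortho <- tipDirectedMovement(mk(c(1, 0, 0), c(0, 3, 0)))
  expect_equal(ortho$m, 0)
  oblique <- tipDirectedMovement(mk(c(0, 0.6, 0.8) * 7, c(1, 2, 2)))
  expect_equal(oblique$m, 2.8)
  # |m| <= |movement| always
  expect_lte(abs(oblique$m), oblique$move_norm + 1e-12)
  expect_warning(tipDirectedMovement(mk(c(0, 0, 0), c(1, 1, 1))),
                 "zero tip vector")
})

test_that("attraction tests detect a known bias and group correctly", {
  set.seed(55)
  n <- 800
  d <- stats::runif(n, 11, 30)
  moves <- data.frame(d = d, m = stats::rnorm(n, 0.2, 1),
                      move_norm = abs(stats::rnorm(n, 3, 0.5)) + 1)
  near <- data.frame(d = stats::runif(300, 1, 9),
                     m = stats::rnorm(300, -0.3, 1), move_norm = 3)
  res <- attractionRepulsionTests(rbind(moves, near), split = 10)
  far <- res[res$group == "d>10", ]; nr <- res[res$group == "d<10", ]
  expect_equal(far$n, n); expect_equal(nr$n, 300)
  expect_lt(abs(far$mean_m - 0.2), 0.12)
  expect_lt(far$p, 0.01)
  expect_lt(nr$mean_m, 0)
  # projection inequality per group
  expect_true(all(res$mean_move_norm >= abs(res$mean_m)))
})

test_that("far-field regression recovers a linear trend and flags nulls", {
  set.seed(56)
  d <- stats::runif(2000, 15.5, 40)
  trended <- data.frame(d = d, m = 0.01 * d + stats::rnorm(2000, 0, 0.3))
  got <- distanceTrendRegression(trended, threshold = 15)
  expect_equal(got$slope, 0.01, tolerance = 0.35)
  expect_lt(got$p, 0.01)

  null <- data.frame(d = d, m = stats::rnorm(2000, 0.1, 0.3))
  got0 <- distanceTrendRegression(null, threshold = 15)
  expect_lt(abs(got0$slope), 0.005)

  degen <- data.frame(d = rep(20, 10), m = stats::rnorm(10))
  expect_error(distanceTrendRegression(degen), "all distances equal")
  expect_error(distanceTrendRegression(trended[1:2, ]), "at least 3")
})

test_that("z perturbations leave horizontal statistics unchanged", {
  sim <- simulateTracks(smallScenario(), seed = 57)
  cc <- driftCorrect(resolveBranches(sim$dataset))
  si <- sampleInfo(sim$dataset)
  cc$step_minutes <- si$step_minutes[1]
  ac1 <- aggregateAutocorrelation(cc, 1:3, "corrected")
  sp1 <- instantaneousSpeeds(cc, "corrected")
  cc$corr_z <- cc$corr_z + stats::rnorm(nrow(cc), 0, 5)
  cc$pos_z <- cc$pos_z + stats::rnorm(nrow(cc), 0, 5)
  expect_equal(aggregateAutocorrelation(cc, 1:3, "corrected"), ac1)
  expect_equal(instantaneousSpeeds(cc, "corrected"), sp1)
})

test_that("inflated z noise produces the negative z-only jitter signature", {
  sim <- simulateTracks(smallScenario(zJitterSd = 2, divisionProb = 0),
                        seed = 58)
  sp <- spots(resolveBranches(sim$dataset))
  zac <- function(p) {
    v <- diff(p)
    mean(v[-length(v)] * v[-1]) / mean(v^2)
  }
  segs <- split(sp[order(sp$segment, sp$time), ], sp$segment[order(sp$segment, sp$time)])
  z_ac <- mean(vapply(segs, function(s) zac(s$pos_z), numeric(1)))
  xy_ac <- mean(vapply(segs, function(s)
    velocityAutocorrelation(cbind(s$pos_x, s$pos_y, 0), 1), numeric(1)))
  expect_lt(z_ac, -0.15)        # jitter: strong negative single-step z autocorr
  expect_gt(xy_ac, -0.1)        # horizontal motion unaffected
})
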
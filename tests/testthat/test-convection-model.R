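simplified <- kProfile(0, 14.95, 0.293, -0.098)

test_that("k(d) evaluates the fitted piecewise profile", {
  expect_equal(kOfD(simplified, 0), 0.293)
  expect_equal(kOfD(simplified, 20), -0.098)
  # printed two-decimal slope arithmetic: 0.293 - 0.026 * 5
  expect_equal(kOfD(simplified, 5), 0.163, tolerance = 1e-2)
  expect_equal(kOfD(simplified, 5),
               0.293 + (-0.098 - 0.293) * 5 / 14.95)
  # continuity at the breakpoints
  eps <- 1e-9
  expect_equal(kOfD(simplified, 14.95 - eps), kOfD(simplified, 14.95 + eps),
               tolerance = 1e-6)
  p2 <- kProfile(3, 10, 0.2, -0.1)
  expect_equal(kOfD(p2, 3 - eps), kOfD(p2, 3 + eps), tolerance = 1e-6)
})

test_that("cumulative k matches closed forms and adaptive quadrature", {
  const <- kProfile(0, 0, 0.17, 0.17)
  expect_equal(cumulativeK(const, 7), 0.17 * 7)
  step <- kProfile(4, 4, 0.3, -0.1)   # d1 = d2: step profile
  d <- c(1, 4, 9)
  expect_equal(cumulativeK(step, d),
               0.3 * pmin(d, 4) + -0.1 * pmax(0, d - 4))
  expect_equal(cumulativeK(step, 0), 0)
  set.seed(61)
  for (i in 1:20) {
    d1 <- stats::runif(1, 0, 10); d2 <- d1 + stats::runif(1, 0, 15)
    p <- kProfile(d1, d2, stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.3))
    x <- stats::runif(1, 0, 40)
    expect_equal(cumulativeK(p, x), quadCumK(p, x), tolerance = 1e-8)
  }
})

test_that("log-likelihood matches uniform and truncated-exponential forms", {
  set.seed(62)
  d <- stats::runif(200, 0, 30)
  flat <- kProfile(0, 0, 0, 0)
  expect_equal(logLikKProfile(flat, d, 30), -200 * log(30), tolerance = 1e-8)

  cc <- -0.15; dmax <- 50
  expc <- kProfile(0, 0, cc, cc)
  x <- stats::runif(300, 0, dmax)
  want <- sum(cc * x) - 300 * log((exp(cc * dmax) - 1) / cc)
  expect_equal(logLikKProfile(expc, x, dmax), want, tolerance = 1e-6)

  # general profile against a quadrature-normalized density
  p <- kProfile(2, 12, 0.25, -0.12)
  z <- stats::integrate(function(u) exp(vapply(u, function(v)
    quadCumK(p, v), numeric(1))), 0, dmax, rel.tol = 1e-10)$value
  want2 <- sum(vapply(x, function(v) quadCumK(p, v), numeric(1))) -
    300 * log(z)
  expect_equal(logLikKProfile(p, x, dmax), want2, tolerance = 1e-6)
  expect_error(logLikKProfile(p, c(x, 60), dmax), "outside")
})

test_that("steady-state density normalizes and obeys the shift property", {
  set.seed(63)
  for (i in 1:5) {
    p <- kProfile(stats::runif(1, 0, 5), stats::runif(1, 6, 20),
                  stats::rnorm(1, 0, 0.25), stats::rnorm(1, 0, 0.25))
    ss <- steadyStateDensity(p, 40)
    total <- stats::integrate(ss$density, 0, 40, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    # adding c to k multiplies the unnormalized density by exp(c d)
    cshift <- 0.07
    p2 <- kProfile(p@d1, p@d2, p@k1 + cshift, p@k2 + cshift)
    ss2 <- steadyStateDensity(p2, 40)
    dd <- c(1, 7, 19, 33)
    ratio <- ss2$density(dd) / ss$density(dd)
    want <- exp(cshift * dd) * exp(ss$log_z - ss2$log_z)
    expect_equal(ratio, want, tolerance = 1e-8)
  }
})

test_that("steady-state sampling matches closed-form distributions", {
  set.seed(64)
  u <- sampleSteadyState(kProfile(0, 0, 0, 0), 10000, 25)
  expect_gt(stats::ks.test(u, "punif", 0, 25)$p.value, 0.01)

  cc <- -0.2; dmax <- 40
  e <- sampleSteadyState(kProfile(0, 0, cc, cc), 10000, dmax)
  ptrunc <- function(q) (1 - exp(cc * q)) / (1 - exp(cc * dmax))
  expect_gt(stats::ks.test(e, ptrunc)$p.value, 0.01)

  # simplified profile: log-density slope beyond d2 approximates k2
  s <- sampleSteadyState(simplified, 40000, 60)
  h <- graphics::hist(s[s > 20 & s < 50], breaks = 30, plot = FALSE)
  slope <- stats::coef(stats::lm(log(h$density) ~ h$mids))[[2]]
  expect_equal(slope, -0.098, tolerance = 0.01)
  # density peaks where k crosses zero (near 11.3 µm for this profile)
  dens <- stats::density(s, from = 0, to = 60)
  expect_lt(abs(dens$x[which.max(dens$y)] - 0.293 * 14.95 / (0.293 + 0.098)),
            1.5)
})

test_that("likelihood at the truth dominates perturbed parameters", {
  set.seed(65)
  d <- sampleSteadyState(simplified, 30000, 60)
  ll0 <- logLikKProfile(simplified, d, 60)
  for (delta in list(c(0, 0, 0.05, 0), c(0, 2, 0, 0), c(0, 0, 0, 0.02))) {
    p <- kProfile(simplified@d1 + delta[1], simplified@d2 + delta[2],
                  simplified@k1 + delta[3], simplified@k2 + delta[4])
    expect_gt(ll0, logLikKProfile(p, d, 60))
  }
})

test_that("a flat-profile sample fits an essentially flat k", {
  set.seed(66)
  d <- sampleSteadyState(kProfile(0, 0, -0.1, -0.1), 5000, 50)
  f <- fitConvectionDiffusion(d, d_max = 50)
  expect_true(f@converged)
  # far-field rate recovered; fitted k stays near -0.1 over the data range
  expect_lt(abs(f@estimates[["k2"]] + 0.1), 0.02)
  kd <- kOfD(f@profile, seq(5, 40, by = 5))
  expect_lt(max(abs(kd + 0.1)), 0.05)
})

test_that("standard errors agree with bootstrap spread when identified", {
  set.seed(67)
  truth <- kProfile(3, 12, 0.35, -0.15)
  d <- sampleSteadyState(truth, 4000, 50)
  f <- fitConvectionDiffusion(d, d_max = 50)
  expect_true(f@converged)
  boots <- replicate(25, {
    db <- sample(d, replace = TRUE)
    fb <- fitConvectionDiffusion(db, d_max = 50, init = f@estimates,
                                 n_starts = 1L)
    fb@estimates[c("d2", "k2")]
  })
  bsd <- apply(boots, 1, stats::sd)
  for (par in c("d2", "k2"))
    expect_lt(abs(f@se[[par]] - bsd[[par]]) / bsd[[par]], 0.5)
})

test_that("profile simplification applies the significance rule", {
  mkfit <- function(d1, se1) methods::new(
    "ConvectionFit", profile = kProfile(d1, 14.95, 0.293, -0.098),
    estimates = c(d1 = d1, d2 = 14.95, k1 = 0.293, k2 = -0.098),
    se = c(d1 = se1, d2 = 0.18, k1 = 0.010, k2 = 0.001),
    logLik = -1, converged = TRUE, dMax = 60, n = 1000L)
  # d1 indistinguishable from 0: collapse to the two-piece linear model
  simp <- simplifyProfile(mkfit(0.005, 0.381))
  expect_equal(simp@d1, 0)
  expect_equal(simp@d2, 14.95)
  # implied linear slope rounds to the printed 0.026 per µm
  expect_equal(round((simp@k1 - simp@k2) / simp@d2, 3), 0.026)
  # significant d1 is kept
  keep <- simplifyProfile(mkfit(5, 0.1))
  expect_equal(keep@d1, 5)
  # idempotent at d1 = 0
  expect_equal(simplifyProfile(mkfit(0, 0.381))@d1, 0)
  # zero SE: keep as fitted, with a warning
  expect_warning(z <- simplifyProfile(mkfit(0.005, 0)), "SE")
  expect_equal(z@d1, 0.005)
})

test_that("invalid profiles are rejected", {
  expect_error(kProfile(5, 2, 0.1, -0.1), "d1 must be <= d2")
  expect_error(kProfile(-1, 2, 0.1, -0.1), "d1 must be >= 0")
})
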
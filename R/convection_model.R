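#' Construct a KProfile
#'
#' @param d1,d2 breakpoints (µm), `0 <= d1 <= d2`.
#' @param k1,k2 convection-to-diffusion ratios (per µm) below `d1` and above
#'   `d2`; linear in between. Positive = repulsion from the tip.
#' @return a [KProfile-class].
#' @examples
#' kProfile(0, 14.95, 0.293, -0.098)
#' @export
kProfile <- function(d1, d2, k1, k2)
  methods::new("KProfile", d1 = as.numeric(d1), d2 = as.numeric(d2),
               k1 = as.numeric(k1), k2 = as.numeric(k2))

## piecewise evaluation on raw parameters (no d1 >= 0 assumption, so the
## likelihood stays smooth when a numeric Hessian probes d1 slightly below 0)
.k_eval <- function(d1, d2, k1, k2, d) {
  out <- numeric(length(d))
  lo <- d < d1
  hi <- d > d2
  mid <- !lo & !hi
  out[lo] <- k1
  out[hi] <- k2
  if (any(mid))
    out[mid] <- if (d2 > d1)
      k1 + (k2 - k1) * (d[mid] - d1) / (d2 - d1) else k1
  out
}

## antiderivative of the piecewise-linear profile; cumulative = G(d) - G(0)
.k_anti <- function(d1, d2, k1, k2, x) {
  out <- numeric(length(x))
  lo <- x <= d1
  hi <- x > d2
  mid <- !lo & !hi
  out[lo] <- k1 * x[lo]
  gd1 <- k1 * d1
  if (d2 > d1) {
    if (any(mid)) {
      s <- x[mid] - d1
      out[mid] <- gd1 + k1 * s + 0.5 * (k2 - k1) * s^2 / (d2 - d1)
    }
    gd2 <- gd1 + k1 * (d2 - d1) + 0.5 * (k2 - k1) * (d2 - d1)
  } else gd2 <- gd1
  out[hi] <- gd2 + k2 * (x[hi] - d2)
  out
}

#' Evaluate a k profile
#'
#' `kOfD` gives k(d); `cumulativeK` gives the closed-form (piecewise
#' quadratic) integral of k from 0 to d, the log of the unnormalized
#' steady-state density.
#'
#' @param profile a [KProfile-class].
#' @param d numeric distances (µm), `>= 0`; vectorized.
#' @return numeric, same length as `d`.
#' @examples
#' p <- kProfile(0, 14.95, 0.293, -0.098)
#' kOfD(p, c(0, 5, 20))
#' cumulativeK(p, 10)
#' @export
kOfD <- function(profile, d) {
  stopifnot(is(profile, "KProfile"), all(d >= 0))
  .k_eval(profile@d1, profile@d2, profile@k1, profile@k2, d)
}

#' @rdname kOfD
#' @export
cumulativeK <- function(profile, d) {
  stopifnot(is(profile, "KProfile"), all(d >= 0))
  .cumk(c(profile@d1, profile@d2, profile@k1, profile@k2), d)
}

.cumk <- function(th, d)
  .k_anti(th[1], th[2], th[3], th[4], d) - .k_anti(th[1], th[2], th[3],
                                                   th[4], 0)

## log of Z = \int_0^dMax exp(cumK(u)) du, stabilized by the maximum of the
## piecewise-quadratic exponent (attained at an endpoint, a breakpoint, or
## the interior vertex where k crosses 0)
.log_norm_const <- function(th, dMax) {
  cand <- c(0, th[1], th[2], dMax)
  if (th[2] > th[1] && (th[3] > 0) != (th[4] > 0)) {
    dv <- th[1] + (0 - th[3]) * (th[2] - th[1]) / (th[4] - th[3])
    cand <- c(cand, dv)
  }
  cand <- cand[cand >= 0 & cand <= dMax]
  M <- max(.cumk(th, cand))
  I <- stats::integrate(function(u) exp(.cumk(th, u) - M), 0, dMax,
                        rel.tol = 1e-10, subdivisions = 400L)
  if (!is.finite(I$value) || I$value <= 0)
    stop("non-finite normalization constant: explosive profile")
  M + log(I$value)
}

#' Steady-state tip-distance density
#'
#' The zero-flux steady state of the convection-diffusion model of distance
#' to the tip surface: y(d) proportional to exp(integral of k from 0 to d),
#' normalized on `[0, d_max]`. Only k = v/D is identifiable from the
#' distance distribution; v and D are never estimated separately.
#'
#' @param profile a [KProfile-class].
#' @param d_max domain bound (µm).
#' @return list with `profile`, `d_max`, `log_z` (log normalization
#'   constant) and `density` (vectorized function of d).
#' @export
steadyStateDensity <- function(profile, d_max) {
  stopifnot(is(profile, "KProfile"), d_max > 0)
  th <- c(profile@d1, profile@d2, profile@k1, profile@k2)
  lz <- .log_norm_const(th, d_max)
  list(profile = profile, d_max = d_max, log_z = lz,
       density = function(d) {
         stopifnot(all(d >= 0 & d <= d_max))
         exp(.cumk(th, d) - lz)
       })
}

#' Log-likelihood of observed tip distances
#'
#' Under the steady-state density: sum of cumulativeK over the distances
#' minus n times the log normalization constant (adaptive quadrature).
#'
#' @param profile a [KProfile-class].
#' @param distances observed tip distances (µm), all within `[0, d_max]`.
#' @param d_max domain bound (µm).
#' @return log-likelihood (scalar).
#' @export
logLikKProfile <- function(profile, distances, d_max = max(distances)) {
  stopifnot(is(profile, "KProfile"))
  if (any(distances < 0 | distances > d_max))
    stop("distances outside [0, d_max]")
  th <- c(profile@d1, profile@d2, profile@k1, profile@k2)
  sum(.cumk(th, distances)) - length(distances) * .log_norm_const(th, d_max)
}

.negloglik_raw <- function(th, distances, dMax) {
  # th = (d1, d2, k1, k2), d1 <= d2 assumed (may be probed slightly < 0)
  nl <- tryCatch(
    -(sum(.cumk(th, distances)) -
        length(distances) * .log_norm_const(th, dMax)),
    error = function(e) Inf)
  if (!is.finite(nl)) 1e10 else nl
}

#' Fit the steady-state convection-diffusion model by maximum likelihood
#'
#' Maximizes the steady-state likelihood of the four-parameter piecewise
#' linear k profile over (d1, d2, k1, k2) with 0 <= d1 <= d2, on transformed
#' unconstrained parameters (log d1 and log of the d1-to-d2 gap). Each start
#' runs a derivative-free simplex search followed by a quasi-Newton polish;
#' multiple starts (data-driven plus perturbations) guard against local
#' optima. Standard errors come from the inverse observed information
#' (central-difference Hessian on the original parameter scale).
#'
#' @param distances observed tip distances (µm).
#' @param d_max domain bound for the density normalization (default: the
#'   maximum observed distance).
#' @param init optional named numeric `c(d1, d2, k1, k2)` starting point.
#' @param n_starts number of optimization starts.
#' @return a [ConvectionFit-class].
#' @export
fitConvectionDiffusion <- function(distances, d_max = max(distances),
                                   init = NULL, n_starts = 4L) {
  distances <- as.numeric(distances)
  stopifnot(length(distances) >= 10L, all(is.finite(distances)),
            all(distances >= 0 & distances <= d_max))
  n <- length(distances)

  obj <- function(par) {
    d1 <- exp(par[1]); d2 <- d1 + exp(par[2])
    pen <- if (d2 > d_max) 1e3 * (d2 - d_max)^2 else 0
    .negloglik_raw(c(d1, d2, par[3], par[4]), distances, d_max) + pen
  }
  to_par <- function(th) c(log(max(th[1], 1e-6)),
                           log(max(th[2] - th[1], 1e-3)), th[3], th[4])

  starts <- list()
  if (!is.null(init)) starts[[length(starts) + 1L]] <- as.numeric(init)
  dens <- stats::density(distances, from = 0, to = d_max)
  dm <- dens$x[which.max(dens$y)]
  k2g <- .log_slope(distances, lo = min(1.3 * dm, 0.8 * d_max), hi = d_max)
  k1g <- .log_slope(distances, lo = 0, hi = max(0.7 * dm, 2))
  if (!is.finite(k2g)) k2g <- -0.1
  if (!is.finite(k1g)) k1g <- 0.1
  starts <- c(starts, list(
    c(0.1, max(dm, 1), k1g, k2g),
    c(1, max(1.5 * dm, 2), k1g, k2g),
    c(0.01, max(0.7 * dm, 1), 2 * k1g, 0.5 * k2g),
    c(2, max(2 * dm, 3), 0.5 * k1g, k2g)))
  starts <- starts[seq_len(min(length(starts), n_starts + !is.null(init)))]

  best <- NULL
  for (s in starts) {
    o1 <- stats::optim(to_par(s), obj, method = "Nelder-Mead",
                       control = list(maxit = 600))
    o2 <- tryCatch(stats::optim(o1$par, obj, method = "BFGS",
                                control = list(maxit = 200)),
                   error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  par <- best$par
  th <- c(exp(par[1]), exp(par[1]) + exp(par[2]), par[3], par[4])
  names(th) <- c("d1", "d2", "k1", "k2")
  ll <- -.negloglik_raw(th, distances, d_max)

  H <- tryCatch(
    .num_hessian(function(p) .negloglik_raw(p, distances, d_max), th),
    error = function(e) NULL)
  se <- rep(NA_real_, 4L)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
    }
  }
  names(se) <- names(th)
  converged <- best$convergence == 0L && is.finite(ll)
  if (!converged)
    warning("optimizer did not report convergence; ",
            "returning best result found, flagged unconverged")
  methods::new("ConvectionFit",
               profile = kProfile(max(th[1], 0), th[2], th[3], th[4]),
               estimates = th, se = se, logLik = ll,
               converged = converged, dMax = as.numeric(d_max),
               n = as.integer(n))
}

## central-difference Hessian with parameter-scaled steps: the objective is
## evaluated through adaptive quadrature, so steps must be large enough that
## quadrature noise (~1e-6 absolute) does not swamp h^2 in the denominator
.num_hessian <- function(f, x, rel_h = 5e-3) {
  p <- length(x)
  h <- rel_h * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j <= i) next
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

## crude log-density slope on [lo, hi] from a histogram: init heuristic only
.log_slope <- function(x, lo, hi) {
  x <- x[x >= lo & x <= hi]
  if (length(x) < 50L) return(NA_real_)
  h <- graphics::hist(x, breaks = 12, plot = FALSE)
  keep <- h$counts > 0
  if (sum(keep) < 3L) return(NA_real_)
  stats::coef(stats::lm(log(h$counts[keep]) ~ h$mids[keep]))[[2]]
}

#' Simplify a fitted profile
#'
#' If the fitted d1 is not significantly different from 0 (|d1| < 1.96
#' standard errors), returns the profile with d1 set to 0 — k then falls
#' linearly from k1 at the tip surface to k2 at d2 — otherwise returns the
#' fitted profile unchanged. Idempotent for d1 = 0.
#'
#' @param fit a [ConvectionFit-class].
#' @param z_crit significance multiple of the standard error (default 1.96).
#' @return a [KProfile-class].
#' @export
simplifyProfile <- function(fit, z_crit = 1.96) {
  stopifnot(is(fit, "ConvectionFit"))
  if (!fit@converged) stop("cannot simplify an unconverged fit")
  est <- fit@estimates
  se1 <- fit@se[["d1"]]
  if (est[["d1"]] == 0) return(fit@profile)
  if (is.na(se1) || se1 == 0) {
    warning("SE(d1) unavailable or zero; keeping d1 as fitted")
    return(fit@profile)
  }
  if (abs(est[["d1"]] / se1) < z_crit)
    kProfile(0, est[["d2"]], est[["k1"]], est[["k2"]])
  else fit@profile
}

#' Sample tip distances from the steady-state density
#'
#' Inverse-CDF sampling on a fine grid; reproducible under a fixed RNG seed.
#'
#' @param profile a [KProfile-class].
#' @param n number of draws.
#' @param d_max domain bound (µm).
#' @param grid_n grid resolution.
#' @return numeric vector of n distances in `[0, d_max]`.
#' @export
sampleSteadyState <- function(profile, n, d_max, grid_n = 16384L) {
  stopifnot(is(profile, "KProfile"), n >= 1L, d_max > 0)
  th <- c(profile@d1, profile@d2, profile@k1, profile@k2)
  g <- seq(0, d_max, length.out = grid_n)
  lf <- .cumk(th, g)
  f <- exp(lf - max(lf))
  cdf <- c(0, cumsum((f[-1] + f[-grid_n]) / 2 * diff(g)))
  cdf <- cdf / cdf[grid_n]
  stats::approx(cdf, g, xout = stats::runif(n), ties = "ordered")$y
}
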
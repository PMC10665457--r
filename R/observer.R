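#' Observer cue precisions
#'
#' Parameters of the Bayesian observer: concentration of the velocity
#' measurement distribution (`kappa_V`, 360-degree space) and of the
#' spatial-orientation measurement distribution (`kappa_O`, 180-degree
#' space). Either concentrations or the equivalent circular SDs (degrees)
#' may be given.
#'
#' @param kappa_V,kappa_O nonnegative concentrations.
#' @param sigma_V,sigma_O circular SDs in degrees (alternative to kappas).
#' @return object of class `observer_params`.
#' @export
observer_params <- function(kappa_V = NULL, kappa_O = NULL,
                            sigma_V = NULL, sigma_O = NULL) {
  if (is.null(kappa_V)) kappa_V <- sigma_to_kappa(sigma_V)
  if (is.null(kappa_O)) kappa_O <- sigma_to_kappa(sigma_O)
  if (kappa_V < 0 || kappa_O < 0) stop("precisions must be nonnegative")
  structure(list(kappa_V = kappa_V, kappa_O = kappa_O),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("observer: kappa_V = %.4g (sigma %.3g deg), kappa_O = %.4g (sigma %.3g deg)\n",
              x$kappa_V, kappa_to_sigma(x$kappa_V),
              x$kappa_O, kappa_to_sigma(x$kappa_O)))
  invisible(x)
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler; accepts elementwise `mu` and `kappa`.
#' Values of `kappa` below 1e-9 fall back to the uniform distribution.
#'
#' @param n number of draws.
#' @param mu mean direction(s) in degrees (length 1 or `n`).
#' @param kappa concentration(s) (length 1 or `n`).
#' @return angles in degrees on \eqn{[0, 360)}.
#' @export
rvm <- function(n, mu = 0, kappa = 1) {
  mu <- rep_len(mu, n) * DEG2RAD
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-9
  out[unif] <- runif(sum(unif), 0, 2 * pi)
  todo <- which(!unif)
  if (length(todo)) {
    k <- kappa[todo]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(length(todo))
    pending <- seq_along(todo)
    while (length(pending)) {
      m <- length(pending)
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[pending] * z) / (r[pending] + z)
      c_ <- k[pending] * (r[pending] - f)
      ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
      acc <- pending[ok]
      theta[acc] <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      pending <- pending[!ok]
    }
    out[todo] <- theta
  }
  wrap360((mu + out) * RAD2DEG)
}

#' Sample noisy velocity and orientation measurements
#'
#' The velocity measurement is a von Mises draw around the stimulus in the
#' full 360-degree direction space. The orientation measurement adds von
#' Mises noise to the stimulus and wraps the result into the 180-degree
#' orientation space (an orientation cannot distinguish opposite motion
#' directions).
#'
#' @param s stimulus direction(s), degrees.
#' @param params an `observer_params` (or list with `kappa_V`, `kappa_O`,
#'   possibly vectors for trial-wise precisions).
#' @param n number of trials (defaults to length of `s`).
#' @return data.frame with columns `s`, `x_V` (degrees, \eqn{[0,360)}) and
#'   `x_O` (degrees, \eqn{[0,180)}).
#' @export
sample_measurements <- function(s, params, n = length(s)) {
  s <- rep_len(wrap360(s), n)
  x_V <- rvm(n, s, params$kappa_V)
  x_O <- wrap180(s + rvm(n, 0, params$kappa_O))
  data.frame(s = s, x_V = x_V, x_O = x_O)
}

#' Cue likelihood functions over motion direction
#'
#' `velocity_likelihood` is von Mises in direction, centered at the velocity
#' measurement. `orientation_likelihood` is the 180-degree-ambiguous
#' orientation cue: equal peaks at the measured orientation and its opposite
#' direction, so `L(s) = L(s + 180)` for all `s`. Both are returned as
#' normalized distributions over the grid (the normalization constant is
#' irrelevant for posterior computation under a flat prior).
#'
#' @param x_V,x_O measurements in degrees.
#' @param kappa_V,kappa_O cue concentrations.
#' @param grid direction grid (degrees).
#' @return a `direction_distribution`.
#' @export
velocity_likelihood <- function(x_V, kappa_V, grid = direction_grid()) {
  direction_distribution(vm_pdf(grid, x_V, kappa_V), grid)
}

#' @rdname velocity_likelihood
#' @export
orientation_likelihood <- function(x_O, kappa_O, grid = direction_grid()) {
  direction_distribution(
    vm_pdf(grid, x_O, kappa_O) + vm_pdf(grid, x_O + 180, kappa_O), grid)
}

# Product-of-von-Mises identity, vectorized over trials. For each orientation
# peak o, VM(s; x_V, kV) * VM(s; o, kO) is proportional to VM(s; theta, kc)
# with kc and theta given by resultant-vector addition, and the component's
# unnormalized weight is I0(kc) / (I0(kV) I0(kO)); the shared denominator
# cancels in the two-component normalization.
posterior_mixture_components <- function(x_V, x_O, kappa_V, kappa_O) {
  n <- max(length(x_V), length(x_O), length(kappa_V), length(kappa_O))
  x_V <- rep_len(x_V, n); x_O <- rep_len(x_O, n)
  kappa_V <- rep_len(kappa_V, n); kappa_O <- rep_len(kappa_O, n)
  comp <- function(o_deg) {
    d <- (x_V - o_deg) * DEG2RAD
    kc <- sqrt(pmax(0, kappa_V^2 + kappa_O^2 + 2 * kappa_V * kappa_O * cos(d)))
    sy <- kappa_V * sin(x_V * DEG2RAD) + kappa_O * sin(o_deg * DEG2RAD)
    sx <- kappa_V * cos(x_V * DEG2RAD) + kappa_O * cos(o_deg * DEG2RAD)
    theta <- ifelse(kc < 1e-12, wrap360(x_V), wrap360(atan2(sy, sx) * RAD2DEG))
    list(theta = theta, kappa = kc, logw = log_bessel_i0(kc))
  }
  c1 <- comp(x_O)
  c2 <- comp(x_O + 180)
  mx <- pmax(c1$logw, c2$logw)
  w1 <- exp(c1$logw - mx); w2 <- exp(c2$logw - mx)
  tot <- w1 + w2
  w1 <- w1 / tot; w2 <- w2 / tot
  # component A is the one whose mean lies nearer the velocity measurement
  a_first <- abs(ang_diff(c1$theta, x_V)) <= abs(ang_diff(c2$theta, x_V))
  pick <- function(f1, f2) ifelse(a_first, f1, f2)
  data.frame(
    theta_A = pick(c1$theta, c2$theta), kappa_A = pick(c1$kappa, c2$kappa),
    w_A = pick(w1, w2),
    theta_B = pick(c2$theta, c1$theta), kappa_B = pick(c2$kappa, c1$kappa),
    w_B = pick(w2, w1))
}

#' Analytic posterior over motion direction given both cues
#'
#' Under a flat prior, the posterior is proportional to the product of the
#' velocity likelihood and the (bimodal) orientation likelihood. Using the
#' product identity for von Mises densities this is exactly a two-component
#' von Mises mixture: each orientation peak combines with the velocity cue
#' via resultant-vector addition, and the component weights follow from
#' Bessel-function normalizers. Component A is, by convention, the one whose
#' mean lies nearer the velocity measurement.
#'
#' @param m one-row data.frame (or list) with `x_V`, `x_O`; see
#'   [sample_measurements()].
#' @param params an `observer_params`.
#' @return object of class `posterior_mixture` with weights `w_A`, `w_B`,
#'   means `theta_A`, `theta_B` (degrees) and concentrations `kappa_A`,
#'   `kappa_B`.
#' @export
combined_posterior <- function(m, params) {
  comp <- posterior_mixture_components(m$x_V, m$x_O,
                                       params$kappa_V, params$kappa_O)
  structure(as.list(comp[1, ]), class = "posterior_mixture")
}

#' @export
print.posterior_mixture <- function(x, ...) {
  cat(sprintf(
    "posterior mixture: w_A=%.3f at %.1f deg (kappa %.3g); w_B=%.3f at %.1f deg (kappa %.3g)\n",
    x$w_A, x$theta_A, x$kappa_A, x$w_B, x$theta_B, x$kappa_B))
  invisible(x)
}

#' Evaluate a posterior mixture
#'
#' @param mix a `posterior_mixture`.
#' @param x angles in degrees.
#' @param grid direction grid for `as_distribution`.
#' @return `mixture_pdf`: densities per radian; `as_distribution`: a
#'   normalized `direction_distribution` on the grid.
#' @export
mixture_pdf <- function(mix, x) {
  mix$w_A * vm_pdf(x, mix$theta_A, mix$kappa_A) +
    mix$w_B * vm_pdf(x, mix$theta_B, mix$kappa_B)
}

#' @rdname mixture_pdf
#' @export
as_distribution <- function(mix, grid = direction_grid()) {
  direction_distribution(mixture_pdf(mix, grid), grid)
}

#' Posterior readouts
#'
#' `map_readout` selects the most probable direction (delta cost function)
#' by locating the maximum of the posterior on the grid; exact ties are
#' broken toward the smaller canonical angle. `velocity_only_readout`
#' ignores the orientation cue entirely: the velocity-only posterior is von
#' Mises centered at the measurement, so its maximum is the measurement
#' itself.
#'
#' @param post a `posterior_mixture`.
#' @param m measurement row/list with `x_V`.
#' @param grid direction grid.
#' @return direction estimate in degrees.
#' @export
map_readout <- function(post, grid = direction_grid()) {
  grid[which.max(mixture_pdf(post, grid))]
}

#' @rdname map_readout
#' @export
velocity_only_readout <- function(m) wrap360(m$x_V)

#' Closed-form MAP estimate in the low-velocity-noise regime
#'
#' When the second posterior component is negligible, the MAP estimate is
#' the mode of the product of the two unimodal likelihoods:
#' \deqn{\hat{s} = x_V - \mathrm{atan2}(\sin(x_V - x_O),\;
#'   \kappa_V/\kappa_O + \cos(x_V - x_O))}
#' with the orientation peak taken as the one nearer the velocity
#' measurement.
#'
#' @param x_V,x_O measurements in degrees.
#' @param kappa_V,kappa_O cue concentrations.
#' @return MAP estimate in degrees.
#' @export
map_closed_form <- function(x_V, x_O, kappa_V, kappa_O) {
  # orientation peak nearest x_V in the 360-degree space
  d180 <- ang_diff(x_O, x_V) %% 180
  d180 <- ifelse(d180 >= 90, d180 - 180, d180)
  o <- x_V + d180
  d <- (x_V - o) * DEG2RAD
  wrap360(x_V - atan2(sin(d), kappa_V / kappa_O + cos(d)) * RAD2DEG)
}

#' von Mises approximation to the across-trial MAP distribution
#'
#' In the low-velocity-noise regime (negligible second component), the
#' distribution of MAP estimates across trials is approximately von Mises,
#' centered on the stimulus with concentration \eqn{\kappa_O + \kappa_V}.
#' A warning is issued when the second component's typical weight is not
#' negligible, in which case the approximation no longer holds and
#' simulation is required.
#'
#' @param s stimulus direction, degrees.
#' @param params an `observer_params`.
#' @param w_B_tol weight above which the approximation is flagged.
#' @return list with `mu_MAP` (degrees) and `kappa_MAP`.
#' @export
map_distribution_approx <- function(s, params, w_B_tol = 1e-3) {
  kV <- params$kappa_V; kO <- params$kappa_O
  # typical-case weight of the second component (measurements at the stimulus)
  lA <- log_bessel_i0(kV + kO); lB <- log_bessel_i0(abs(kV - kO))
  w_B <- 1 / (1 + exp(lA - lB))
  if (w_B > w_B_tol)
    warning(sprintf(
      "second posterior component is non-negligible (typical w_B = %.3g); approximation invalid",
      w_B))
  list(mu_MAP = wrap360(s), kappa_MAP = kV + kO)
}
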
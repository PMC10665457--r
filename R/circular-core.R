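#' @importFrom stats optim uniroot rnorm runif sd median lm coef predict
#'   rlnorm dnorm var qlogis rgamma poly
#' @importFrom utils head tail write.csv read.csv
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles to a canonical range
#'
#' Directions live on \eqn{[0, 360)} degrees, orientations on \eqn{[0, 180)}.
#' Wrapping is idempotent.
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in degrees.
#' @export
wrap360 <- function(x) x %% 360

#' @rdname wrap360
#' @export
wrap180 <- function(x) x %% 180

#' Signed circular difference in degrees
#'
#' Returns `a - b` mapped to \eqn{[-180, 180)}.
#'
#' @param a,b angles in degrees.
#' @return signed differences in degrees.
#' @export
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}

#' The direction grid
#'
#' All posterior distributions in this package are evaluated on a uniform grid
#' over \eqn{[0, 360)} degrees. The default step of 0.5 degrees (720 bins, bin
#' centers at 0, 0.5, ...) is the resolution at which posterior maxima are
#' located throughout.
#'
#' @param step grid step in degrees; must divide 360 exactly.
#' @return numeric vector of grid angles in degrees.
#' @export
direction_grid <- function(step = 0.5) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("grid step must divide 360 exactly")
  seq(0, 360 - step, by = step)
}

#' Probability mass over a grid of motion directions
#'
#' Constructs a `direction_distribution`: nonnegative masses over a uniform
#' angular grid, normalized to sum to one.
#'
#' @param mass nonnegative weights, one per grid point.
#' @param grid grid angles in degrees (uniform step dividing 360).
#' @param normalize divide by the total mass (default `TRUE`).
#' @return object of class `direction_distribution` with fields `grid`,
#'   `mass`, `step`.
#' @export
direction_distribution <- function(mass, grid = direction_grid(), normalize = TRUE) {
  if (length(mass) != length(grid))
    stop("mass and grid lengths differ")
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("masses must be finite and nonnegative")
  step <- 360 / length(grid)
  if (max(abs(diff(grid) - step)) > 1e-9)
    stop("grid must have uniform step")
  tot <- sum(mass)
  if (normalize) {
    if (tot <= 0) stop("total mass is zero")
    mass <- mass / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop("masses do not sum to 1")
  }
  structure(list(grid = as.numeric(grid), mass = as.numeric(mass), step = step),
            class = "direction_distribution")
}

#' @export
print.direction_distribution <- function(x, ...) {
  m <- x$grid[which.max(x$mass)]
  cat(sprintf(
    "direction distribution: %d bins (%.3g deg step), mode %.1f deg, entropy %.3f bits\n",
    length(x$grid), x$step, m, entropy_bits(x)))
  invisible(x)
}

#' von Mises probability density
#'
#' Density (per radian) of the von Mises distribution with mean `mu` and
#' concentration `kappa`, evaluated at angles in degrees. Computed in log
#' space with exponentially scaled Bessel functions so large concentrations
#' remain stable.
#'
#' @param x angles in degrees at which to evaluate.
#' @param mu mean direction in degrees.
#' @param kappa concentration (precision) parameter, `kappa >= 0`.
#' @param log_scale return the log density.
#' @return densities per radian (integrates to 1 over the full circle).
#' @export
vm_pdf <- function(x, mu, kappa, log_scale = FALSE) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("kappa must be finite and nonnegative")
  lp <- kappa * (cos((x - mu) * DEG2RAD) - 1) - log(2 * pi) -
    log_bessel_i0_scaled(kappa)
  if (log_scale) lp else exp(lp)
}

# log of the exponentially scaled I0; asymptotic expansion where besselI
# underflows (kappa beyond ~1e5)
log_bessel_i0_scaled <- function(kappa) {
  ifelse(kappa > 1e4,
         -0.5 * log(2 * pi * pmax(kappa, 1)) + log1p(1 / (8 * pmax(kappa, 1))),
         log(besselI(kappa, 0, expon.scaled = TRUE)))
}

log_bessel_i0 <- function(kappa) {
  log_bessel_i0_scaled(kappa) + kappa
}

# I1/I0 Bessel ratio with large-argument asymptotics
bessel_ratio_A <- function(kappa) {
  ifelse(kappa > 1e4,
         1 - 1 / (2 * kappa) - 1 / (8 * kappa^2),
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Convert between von Mises concentration and circular SD
#'
#' The circular standard deviation implied by concentration \eqn{\kappa} is
#' \eqn{\sigma = \sqrt{-2\log(I_1(\kappa)/I_0(\kappa))}}. `sigma_to_kappa`
#' inverts this relation by root-finding.
#'
#' @param kappa concentration, `>= 0`.
#' @param sigma circular SD in degrees.
#' @return `kappa_to_sigma`: circular SD in degrees (`Inf` at `kappa = 0`);
#'   `sigma_to_kappa`: concentration.
#' @export
kappa_to_sigma <- function(kappa) {
  stopifnot(all(kappa >= 0))
  r <- ifelse(kappa == 0, 0, bessel_ratio_A(kappa))
  ifelse(r <= 0, Inf, sqrt(-2 * log(r)) * RAD2DEG)
}

#' @rdname kappa_to_sigma
#' @export
sigma_to_kappa <- function(sigma) {
  vapply(sigma, function(s) {
    if (!is.finite(s)) return(0)
    stopifnot(s > 0)
    f <- function(k) kappa_to_sigma(k) - s
    # kappa is monotone decreasing in sigma; bracket adaptively
    lo <- 1e-8; hi <- 1
    if (f(lo) < 0) return(0)  # sigma beyond the near-uniform regime
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Shannon entropy of a direction distribution, in bits
#'
#' \eqn{-\sum_i p_i \log_2 p_i} over grid masses; zero-mass bins contribute 0.
#' Lies in \eqn{[0, \log_2 N]} for an N-bin grid, with equality at the
#' uniform distribution.
#'
#' @param dist a `direction_distribution` (or a bare vector of masses
#'   summing to 1).
#' @return entropy in bits.
#' @export
entropy_bits <- function(dist) {
  p <- if (inherits(dist, "direction_distribution")) dist$mass else dist
  if (abs(sum(p) - 1) > 1e-6) stop("distribution is not normalized")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Circular mean and resultant length
#'
#' @param x angles in degrees.
#' @param w optional nonnegative weights.
#' @return `circ_mean`: mean direction in degrees on \eqn{[0, 360)};
#'   `circ_r`: mean resultant length in \eqn{[0, 1]};
#'   `circ_sd`: circular SD in degrees.
#' @export
circ_mean <- function(x, w = NULL) {
  xr <- x * DEG2RAD
  if (is.null(w)) w <- rep(1, length(x))
  wrap360(atan2(sum(w * sin(xr)), sum(w * cos(xr))) * RAD2DEG)
}

#' @rdname circ_mean
#' @export
circ_r <- function(x, w = NULL) {
  xr <- x * DEG2RAD
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  sqrt(sum(w * sin(xr))^2 + sum(w * cos(xr))^2)
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x, w = NULL) {
  r <- circ_r(x, w)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r)) * RAD2DEG
}

#' Maximum-likelihood von Mises concentration
#'
#' Inverts the ratio \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa)} at the sample
#' mean resultant length by root-finding.
#'
#' @param x angles in degrees.
#' @return estimated concentration.
#' @export
fit_vm_kappa <- function(x) {
  r <- circ_r(x)
  if (r >= 1 - 1e-12) return(Inf)
  if (r <= 0) return(0)
  hi <- 1
  while (bessel_ratio_A(hi) < r && hi < 1e8) hi <- hi * 2
  uniroot(function(k) bessel_ratio_A(k) - r, c(1e-10, hi), tol = 1e-10)$root
}

#' Circular (Fisher-Lee) correlation between paired angles
#'
#' The Fisher-Lee coefficient based on pairwise angular differences,
#' \deqn{r = \frac{\sum_{i<j}\sin(a_i-a_j)\sin(b_i-b_j)}
#'   {\sqrt{\sum_{i<j}\sin^2(a_i-a_j)\sum_{i<j}\sin^2(b_i-b_j)}},}
#' evaluated through an O(n) trigonometric identity. Unlike mean-centered
#' variants it is well defined when the marginals are uniform over the
#' circle (where the circular mean is unidentifiable). Invariant under
#' rotations of either variable; 1 when `b = a + const`.
#'
#' @param a,b equal-length angle vectors in degrees, `n >= 3`.
#' @return correlation coefficient in \eqn{[-1, 1]}.
#' @export
circ_corr <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  ar <- a * DEG2RAD; br <- b * DEG2RAD
  sa <- sin(ar); ca <- cos(ar); sb <- sin(br); cb <- cos(br)
  num <- 4 * (sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb))
  da <- n^2 - sum(cos(2 * ar))^2 - sum(sin(2 * ar))^2
  db <- n^2 - sum(cos(2 * br))^2 - sum(sin(2 * br))^2
  if (da < 1e-9 * n^2 || db < 1e-9 * n^2)
    stop("circular correlation undefined for (near-)constant input")
  num / sqrt(da * db)
}

#' Fisher z-transform for correlation coefficients
#'
#' Used to aggregate circular correlation coefficients across subjects before
#' averaging, with `fisher_z_inv` mapping back to the correlation scale.
#'
#' @param r correlation in (-1, 1).
#' @param z transformed value.
#' @return transformed value / back-transformed correlation.
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Jensen-Shannon divergence between two direction distributions
#'
#' Symmetrized Kullback-Leibler divergence, computed in base 2 so the value
#' is bounded by 1 bit; 0 iff the distributions are identical.
#'
#' @param p,q `direction_distribution`s on the same grid, or bare mass
#'   vectors of equal length.
#' @return divergence in bits, in \eqn{[0, 1]}.
#' @export
jsd <- function(p, q) {
  if (inherits(p, "direction_distribution")) {
    if (!inherits(q, "direction_distribution") ||
        length(p$grid) != length(q$grid) ||
        max(abs(p$grid - q$grid)) > 1e-9)
      stop("distributions must share the same grid")
    p <- p$mass; q <- q$mass
  }
  if (length(p) != length(q)) stop("mass vectors must have equal length")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0 & b > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Read/write a direction distribution as CSV
#'
#' Two-column CSV (`angle_deg`, `mass`); round-trips exactly at full double
#' precision.
#'
#' @param dist a `direction_distribution`.
#' @param path file path.
#' @return `read_distribution_csv` returns a `direction_distribution`.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "direction_distribution"))
  df <- data.frame(angle_deg = dist$grid, mass = dist$mass)
  # full precision so the round-trip is exact
  con <- file(path, "w")
  writeLines("angle_deg,mass", con)
  writeLines(paste(sprintf("%.17g", df$angle_deg),
                   sprintf("%.17g", df$mass), sep = ","), con)
  close(con)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  df <- read.csv(path)
  direction_distribution(df$mass, df$angle_deg, normalize = FALSE)
}
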
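# Monte-Carlo simulation of the observer's posteriors and readouts.

# Dense von Mises density matrix: one row per trial, one column per grid
# angle. Parameters recycle per row.
vm_density_matrix <- function(theta, kappa, grid) {
  lg <- kappa * (cos(outer(-theta, grid, "+") * DEG2RAD) - 1)
  exp(lg - (log(2 * pi) + log_bessel_i0_scaled(kappa)))
}

# Per-trial mixture posteriors on the grid, processed in chunks: accumulates
# the across-trial mean density and returns per-trial MAP (grid argmax, ties
# to the smaller angle) and entropy (bits).
mixture_trial_stats <- function(comp, grid = direction_grid(), chunk = 2000L) {
  n <- nrow(comp)
  step <- 360 / length(grid)
  mean_density <- numeric(length(grid))
  map <- numeric(n)
  ent <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    D <- comp$w_A[idx] * vm_density_matrix(comp$theta_A[idx], comp$kappa_A[idx], grid) +
      comp$w_B[idx] * vm_density_matrix(comp$theta_B[idx], comp$kappa_B[idx], grid)
    mean_density <- mean_density + colSums(D)
    map[idx] <- grid[max.col(D, ties.method = "first")]
    P <- D / rowSums(D)
    ent[idx] <- -rowSums(ifelse(P > 0, P * log2(P), 0))
  }
  list(mean_posterior = direction_distribution(mean_density, grid),
       map = map, entropy = ent)
}

#' Simulate the observer over a grid of cue noise levels
#'
#' For every combination of velocity and orientation circular SD, simulates
#' `n_trials` measurement pairs at a fixed stimulus (0 degrees; the model is
#' equivariant so all results are relative angles), computes the analytic
#' two-component posterior per trial, and records the across-trial mean
#' posterior, per-trial MAP and velocity-only readouts, and posterior
#' entropies for both observers.
#'
#' @param sigma_V_values,sigma_O_values circular SDs in degrees; default is
#'   the standard 8-level ladder \{3, 5, 10, 20, 30, 40, 60, 100\}.
#' @param n_trials trials per cell (default 10000).
#' @param seed RNG seed (set once for the whole grid).
#' @param s stimulus direction in degrees.
#' @param grid direction grid.
#' @return list with `cells` (one result per cell: noise levels, mean
#'   posterior, readouts, entropies, and the mean weight `mean_w_opp` and
#'   location `theta_opp` of the opposite-direction posterior component)
#'   and `summary` (one row per cell).
#' @export
run_grid_simulation <- function(sigma_V_values = c(3, 5, 10, 20, 30, 40, 60, 100),
                                sigma_O_values = sigma_V_values,
                                n_trials = 10000L, seed = NULL, s = 0,
                                grid = direction_grid()) {
  if (!is.null(seed)) set.seed(seed)
  cells <- list()
  rows <- list()
  for (sV in sigma_V_values) for (sO in sigma_O_values) {
    kV <- sigma_to_kappa(sV); kO <- sigma_to_kappa(sO)
    meas <- sample_measurements(s, list(kappa_V = kV, kappa_O = kO), n = n_trials)
    comp <- posterior_mixture_components(meas$x_V, meas$x_O, kV, kO)
    st <- mixture_trial_stats(comp, grid)
    # weight and location of the posterior component at the opposite
    # direction (zero when neither component lies within 90 degrees of it);
    # the across-trial mean weight quantifies bimodality of the mean
    # posterior without counting local maxima
    inA <- abs(ang_diff(comp$theta_A, s + 180)) < 90
    inB <- abs(ang_diff(comp$theta_B, s + 180)) < 90
    w_opp <- ifelse(inA, comp$w_A, ifelse(inB, comp$w_B, 0))
    th_opp <- ifelse(inA, comp$theta_A, ifelse(inB, comp$theta_B, NA))
    theta_opp <- if (any(w_opp > 0)) circ_mean(th_opp[w_opp > 0], w_opp[w_opp > 0])
    else NA_real_
    # velocity-only posterior: von Mises at the measurement; entropy is the
    # same for every trial at fixed kappa_V
    vel_mass <- vm_pdf(grid, 0, kV); vel_mass <- vel_mass / sum(vel_mass)
    ent_vel <- entropy_bits(vel_mass)
    cell <- list(
      sigma_V = sV, sigma_O = sO, kappa_V = kV, kappa_O = kO,
      n_trials = n_trials,
      mean_posterior = st$mean_posterior,
      map_responses = st$map,
      velocity_responses = meas$x_V,
      entropy = st$entropy,
      entropy_velocity_only = ent_vel,
      mean_w_opp = mean(w_opp),
      theta_opp = theta_opp)
    cells[[length(cells) + 1L]] <- cell
    rows[[length(rows) + 1L]] <- data.frame(
      sigma_V = sV, sigma_O = sO,
      mean_entropy = mean(st$entropy),
      mean_entropy_velocity_only = ent_vel,
      circ_sd_map = circ_sd(st$map),
      circ_sd_velocity = circ_sd(meas$x_V),
      mean_w_opp = mean(w_opp),
      theta_opp = theta_opp)
  }
  list(cells = cells, summary = do.call(rbind, rows), s = s,
       n_trials = n_trials, seed = seed)
}

#' Trial-wise noise regime matched to fMRI measurements
#'
#' Log-normal parameters (of the natural log of kappa) for the trial-wise
#' neural cue precisions and the additional MRI measurement-noise
#' precisions. Defaults are the fMRI-matched values: neural
#' \eqn{\mu = 3.8, \sigma = 0.6} for both cues; MRI velocity
#' \eqn{\mu = 0.9, \sigma = 1.1}; MRI orientation \eqn{\mu = 1.4, \sigma = 0.7}.
#'
#' @param mu_neur,sigma_neur log-normal parameters (of the natural log of
#'   kappa) for neural precision draws.
#' @param mu_mri_velocity,sigma_mri_velocity log-normal parameters for the
#'   MRI velocity-noise magnitude.
#' @param mu_mri_orientation,sigma_mri_orientation same, orientation.
#' @param mri_param_space how the MRI log-normal draws are interpreted:
#'   `"sd_deg"` (default) draws the MRI noise circular SD in degrees and
#'   converts it to a concentration; `"log_kappa"` draws the concentration
#'   directly (log-normal on kappa). The default is the interpretation
#'   under which the simulated minority-cluster fraction matches its
#'   reported order of magnitude (a fraction of a percent); drawing kappa
#'   itself log-normally with these values makes the MRI velocity offset
#'   exceed 90 degrees on roughly one trial in ten, which is incompatible
#'   with the tight three-cluster structure this regime is meant to
#'   produce.
#' @return object of class `noise_regime`.
#' @export
noise_regime <- function(mu_neur = 3.8, sigma_neur = 0.6,
                         mu_mri_velocity = 0.9, sigma_mri_velocity = 1.1,
                         mu_mri_orientation = 1.4, sigma_mri_orientation = 0.7,
                         mri_param_space = c("sd_deg", "log_kappa")) {
  stopifnot(sigma_neur > 0, sigma_mri_velocity > 0, sigma_mri_orientation > 0)
  structure(list(mu_neur = mu_neur, sigma_neur = sigma_neur,
                 mu_mri_velocity = mu_mri_velocity,
                 sigma_mri_velocity = sigma_mri_velocity,
                 mu_mri_orientation = mu_mri_orientation,
                 sigma_mri_orientation = sigma_mri_orientation,
                 mri_param_space = match.arg(mri_param_space)),
            class = "noise_regime")
}

# draw MRI noise precisions under the regime's parameterization
draw_mri_kappa <- function(n, mu, sigma, space) {
  if (space == "log_kappa") {
    pmin(rlnorm(n, mu, sigma), 1e6)
  } else {
    sigma_to_kappa(pmin(pmax(rlnorm(n, mu, sigma), 0.05), 360))
  }
}

#' Simulate behavioral responses and fMRI-noise-corrupted decoded posteriors
#'
#' Trial-wise neural precisions are drawn log-normally; the observer's
#' behavioral response is the MAP of the neural posterior (no MRI noise).
#' The "decoded" posterior additionally carries MRI measurement noise:
#' independent von Mises offsets added to each internal measurement, with
#' the decoded concentration for each cue equal to the sum of the neural and
#' MRI precisions. The decoded posterior is again an exact two-component
#' von Mises mixture; its components are disambiguated both by height (the
#' mixture density at each component mean) and by proximity to the true
#' direction.
#'
#' @param regime a [noise_regime()].
#' @param n_trials number of trials.
#' @param seed RNG seed.
#' @param s stimulus direction, degrees.
#' @param mri_noise set `FALSE` to skip MRI corruption entirely (the decoded
#'   posterior then equals the neural posterior).
#' @param grid direction grid (used for the MAP readout).
#' @return data.frame with one row per trial: measurements, precisions,
#'   behavioral readouts (`response_map`, `response_velocity`), decoded
#'   mixture parameters (`dec_*`), and disambiguated decoded peak locations
#'   (`mu_large`, `mu_small`, `mu_near_true`, `mu_near_opposite`).
#' @export
run_decoded_simulation <- function(regime = noise_regime(), n_trials = 10000L,
                                   seed = NULL, s = 0, mri_noise = TRUE,
                                   grid = direction_grid()) {
  if (!is.null(seed)) set.seed(seed)
  kV <- rlnorm(n_trials, regime$mu_neur, regime$sigma_neur)
  kO <- rlnorm(n_trials, regime$mu_neur, regime$sigma_neur)
  x_V <- rvm(n_trials, s, kV)
  x_O <- wrap180(s + rvm(n_trials, 0, kO))

  # behavioral readouts use the neural posterior only
  neur <- posterior_mixture_components(x_V, x_O, kV, kO)
  response_map <- mixture_trial_stats(neur, grid)$map
  response_velocity <- wrap360(x_V)

  if (mri_noise) {
    space <- if (is.null(regime$mri_param_space)) "sd_deg" else regime$mri_param_space
    kVp <- draw_mri_kappa(n_trials, regime$mu_mri_velocity,
                          regime$sigma_mri_velocity, space)
    kOp <- draw_mri_kappa(n_trials, regime$mu_mri_orientation,
                          regime$sigma_mri_orientation, space)
    xVp <- rvm(n_trials, 0, kVp)
    xOp <- rvm(n_trials, 0, kOp)
    # the orientation offset is added in the full direction space before the
    # 180-degree wrap
    dec <- posterior_mixture_components(wrap360(x_V + xVp),
                                        wrap180(x_O + xOp),
                                        kV + kVp, kO + kOp)
  } else {
    kVp <- kOp <- xVp <- xOp <- rep(NA_real_, n_trials)
    dec <- neur
  }

  # disambiguate decoded components by mixture height at the component means
  h_A <- dec$w_A * vm_pdf(dec$theta_A, dec$theta_A, dec$kappa_A) +
    dec$w_B * vm_pdf(dec$theta_A, dec$theta_B, dec$kappa_B)
  h_B <- dec$w_A * vm_pdf(dec$theta_B, dec$theta_A, dec$kappa_A) +
    dec$w_B * vm_pdf(dec$theta_B, dec$theta_B, dec$kappa_B)
  a_larger <- h_A >= h_B
  mu_large <- ifelse(a_larger, dec$theta_A, dec$theta_B)
  mu_small <- ifelse(a_larger, dec$theta_B, dec$theta_A)
  a_near <- abs(ang_diff(dec$theta_A, s)) <= abs(ang_diff(dec$theta_B, s))
  mu_near_true <- ifelse(a_near, dec$theta_A, dec$theta_B)
  mu_near_opposite <- ifelse(a_near, dec$theta_B, dec$theta_A)

  data.frame(
    s = rep(wrap360(s), n_trials),
    kappa_V = kV, kappa_O = kO, x_V = x_V, x_O = x_O,
    response_map = response_map, response_velocity = response_velocity,
    kappa_V_mri = kVp, kappa_O_mri = kOp, x_V_mri = xVp, x_O_mri = xOp,
    dec_theta_A = dec$theta_A, dec_kappa_A = dec$kappa_A, dec_w_A = dec$w_A,
    dec_theta_B = dec$theta_B, dec_kappa_B = dec$kappa_B, dec_w_B = dec$w_B,
    mu_large = mu_large, mu_small = mu_small,
    mu_near_true = mu_near_true, mu_near_opposite = mu_near_opposite)
}

#' Fraction of trials whose larger decoded component sits at the opposite
#' direction
#'
#' Counts trials where the larger (by height) fitted component lies within
#' 90 degrees of the direction opposite the stimulus while the smaller lies
#' within 90 degrees of the true direction.
#'
#' @param trials output of [run_decoded_simulation()].
#' @return fraction in \eqn{[0, 1]}.
#' @export
minority_cluster_fraction <- function(trials) {
  mean(abs(ang_diff(trials$mu_large, trials$s + 180)) < 90 &
         abs(ang_diff(trials$mu_small, trials$s)) < 90)
}

#' Per-peak regression of behavioral error on decoded peak locations
#'
#' Selects bimodal trials (one decoded peak within 90 degrees of the true
#' direction, the other within 90 degrees of the opposite direction),
#' re-centers the first peak on the true and the second on the opposite
#' direction, applies the sine transform \eqn{\mu' = \sin(\pi\mu/90)} that
#' linearizes the model's circular prediction, and regresses the behavioral
#' error on each transformed peak location separately -- the marginal
#' peak-error relationship that the model-prediction analysis examines.
#' (For the joint two-predictor regression used on decoded data, see
#' [peak_error_regression()]; when the first peak tracks the behavioral
#' error almost perfectly, as it does for a MAP reader with little
#' measurement noise, the joint model suppresses the second peak's shared
#' signal while the marginal relationship keeps its sign.) Permutation
#' p-values come from shuffling the errors.
#'
#' @param trials output of [run_decoded_simulation()] (or any data.frame
#'   with `s`, `mu_near_true`, `mu_near_opposite` and a response column).
#' @param readout which behavioral readout to use for the error.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `slope_peak1`, `slope_peak2`, permutation p-values and
#'   the number of selected trials.
#' @export
peak_error_correlation <- function(trials, readout = c("map", "velocity"),
                                   n_perm = 1000L, seed = NULL) {
  readout <- match.arg(readout)
  resp <- if (readout == "map") trials$response_map else trials$response_velocity
  err <- ang_diff(resp, trials$s)
  d1 <- ang_diff(trials$mu_near_true, trials$s)
  d2 <- ang_diff(trials$mu_near_opposite, trials$s + 180)
  sel <- abs(d1) < 90 & abs(d2) < 90
  if (sum(sel) < 20) stop("fewer than 20 bimodal trials selected")
  m1 <- sin(pi * d1[sel] / 90)
  m2 <- sin(pi * d2[sel] / 90)
  e <- err[sel]
  s1 <- unname(coef(lm(e ~ m1))[2])
  s2 <- unname(coef(lm(e ~ m2))[2])
  if (!is.null(seed)) set.seed(seed)
  nulls <- replicate(n_perm, {
    ep <- sample(e)
    c(coef(lm(ep ~ m1))[2], coef(lm(ep ~ m2))[2])
  })
  list(slope_peak1 = s1, slope_peak2 = s2,
       p_peak1 = (1 + sum(abs(nulls[1, ]) >= abs(s1))) / (n_perm + 1),
       p_peak2 = (1 + sum(abs(nulls[2, ]) >= abs(s2))) / (n_perm + 1),
       n_selected = sum(sel))
}

#' Two-dimensional stimulus-by-response histogram
#'
#' @param s,response paired angles in degrees.
#' @param bin_deg bin width in degrees (must divide 360).
#' @return matrix of probabilities (rows: stimulus bins; cols: response
#'   bins), with bin centers as dimnames.
#' @export
behavioral_histogram <- function(s, response, bin_deg = 10) {
  breaks <- seq(0, 360, by = bin_deg)
  cs <- cut(wrap360(s), breaks, include.lowest = TRUE, right = FALSE)
  cr <- cut(wrap360(response), breaks, include.lowest = TRUE, right = FALSE)
  h <- table(cs, cr)
  h <- h / sum(h)
  centers <- head(breaks, -1) + bin_deg / 2
  dimnames(h) <- list(stimulus = centers, response = centers)
  unclass(h)
}
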
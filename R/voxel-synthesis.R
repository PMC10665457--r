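# Synthetic voxel and behavioral datasets drawn from the decoder's own
# generative assumptions.

#' Build a run/stimulus design table
#'
#' Each run presents `trials_per_run` evenly spaced directions covering the
#' full circle, shifted by a per-run random offset and shown in random
#' order (the standard design for estimation experiments with circular
#' stimuli).
#'
#' @param n_runs number of runs.
#' @param trials_per_run trials (= distinct directions) per run; default 18,
#'   giving 20-degree spacing.
#' @param seed RNG seed.
#' @return data.frame with columns `trial`, `run`, `s_deg`.
#' @export
make_design <- function(n_runs, trials_per_run = 18L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- 360 / trials_per_run
  rows <- lapply(seq_len(n_runs), function(r) {
    offset <- runif(1, 0, spacing)
    dirs <- wrap360(offset + spacing * (seq_len(trials_per_run) - 1L))
    data.frame(run = r, s_deg = sample(dirs))
  })
  out <- do.call(rbind, rows)
  out <- cbind(trial = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Ground-truth tuning and noise parameters for synthetic voxels
#'
#' Each voxel's tuning curve is a nonnegative random mixture over the K
#' direction channels. An optional 180-degree-periodic orientation-code
#' component is built from equal-weight pairs of opposite-preferring
#' channels and mixed in with weight `ori_weight`, so that a fraction of
#' each voxel's mean response cannot distinguish opposite directions. Noise
#' follows the structured covariance
#' \eqn{\Omega = \sigma^2 W W^T + (1-\rho)\,\mathrm{diag}(\tau^2) + \rho\,\tau\tau^T}.
#'
#' @param n_voxels number of voxels.
#' @param K number of direction channels.
#' @param ori_weight mixing weight in \eqn{[0, 1]} of the 180-degree-periodic
#'   component.
#' @param amplitude overall tuning amplitude (response units per unit channel
#'   activation).
#' @param tau_log_mu,tau_log_sd log-normal parameters for per-voxel noise SD.
#' @param rho global noise correlation.
#' @param sigma2 tuning-shared noise variance scale.
#' @param seed RNG seed.
#' @return list of class `voxel_truth` with `W`, `tau`, `rho`, `sigma2`,
#'   `Omega` (generating covariance), `ori_weight`, `K`.
#' @export
voxel_truth <- function(n_voxels = 200L, K = 8L, ori_weight = 0,
                        amplitude = 1.5, tau_log_mu = log(0.7),
                        tau_log_sd = 0.3, rho = 0.05, sigma2 = 0.02,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ori_weight >= 0, ori_weight <= 1, K %% 2 == 0)
  # direction code: sparse nonnegative channel mixtures
  W_dir <- matrix(rgamma(n_voxels * K, shape = 1, rate = 1), n_voxels, K)
  W_dir <- W_dir / rowSums(W_dir) * amplitude
  # orientation code: equal weights on opposite-preferring channel pairs
  half <- K / 2
  W_axis <- matrix(rgamma(n_voxels * half, shape = 1, rate = 1), n_voxels, half)
  W_axis <- W_axis / rowSums(W_axis) * amplitude
  W_ori <- cbind(W_axis, W_axis) / 2
  W <- (1 - ori_weight) * W_dir + ori_weight * W_ori
  tau <- rlnorm(n_voxels, tau_log_mu, tau_log_sd)
  Omega <- sigma2 * tcrossprod(W) + (1 - rho) * diag(tau^2) +
    rho * tcrossprod(tau)
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("generating covariance is not positive definite (min eigenvalue %.3g)",
                 min(ev)))
  structure(list(W = W, tau = tau, rho = rho, sigma2 = sigma2,
                 Omega = Omega, ori_weight = ori_weight, K = K,
                 amplitude = amplitude),
            class = "voxel_truth")
}

#' Sample voxel response patterns from the generative model
#'
#' Trial responses are the tuned mean \eqn{W g(s)} plus multivariate normal
#' noise with the structured covariance of the truth object. Optionally
#' z-scores each voxel within run (as applied to real BOLD patterns; here
#' applied across the run's trial patterns since no time dimension is
#' simulated).
#'
#' @param design a design table from [make_design()].
#' @param truth a [voxel_truth()].
#' @param seed RNG seed.
#' @param zscore z-score voxels within each run.
#' @return list of class `voxel_dataset` with `B` (trial x voxel matrix),
#'   `design`, `truth`, `zscore`.
#' @export
sample_voxel_patterns <- function(design, truth, seed = NULL, zscore = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  G <- basis_response(design$s_deg, K = truth$K)       # n x K
  M <- G %*% t(truth$W)                                # n x voxels
  E <- MASS::mvrnorm(nrow(M), mu = rep(0, ncol(M)), Sigma = truth$Omega)
  B <- M + E
  if (zscore) {
    for (r in unique(design$run)) {
      i <- design$run == r
      B[i, ] <- scale(B[i, ])
    }
  }
  structure(list(B = B, design = design, truth = truth, zscore = zscore),
            class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("synthetic voxel dataset: %d trials x %d voxels, %d runs, ori_weight = %.2f\n",
              nrow(x$B), ncol(x$B), length(unique(x$design$run)),
              x$truth$ori_weight))
  invisible(x)
}

#' Distance to the nearest cardinal direction
#'
#' @param s directions in degrees.
#' @return distances in degrees, in \eqn{[0, 45]}.
#' @export
oblique_distance <- function(s) {
  d <- wrap360(s) %% 90
  pmin(d, 90 - d)
}

#' Simulate a behavioral dataset with oblique effect, cardinal bias and
#' lapses
#'
#' Responses are MAP readouts of the observer's posterior, with the cue
#' noise (circular SD) scaled up linearly with distance from the nearest
#' cardinal direction (the oblique effect), an additive cardinal bias
#' following the classic fourth-harmonic pattern (positive `bias_amp` =
#' repulsion from cardinals), and a uniform lapse component.
#'
#' @param design a design table from [make_design()].
#' @param observer an [observer_params()] giving baseline cue precisions.
#' @param oblique_amp fractional increase of cue SD at 45 degrees from a
#'   cardinal (0 = no oblique effect).
#' @param bias_amp amplitude in degrees of the cardinal bias on the mean.
#' @param lapse probability of a uniform random response.
#' @param seed RNG seed.
#' @param grid direction grid used for the MAP readout.
#' @return data.frame with columns `subject`, `trial`, `run`, `s_true_deg`,
#'   `response_deg`.
#' @export
make_behavioral_dataset <- function(design, observer, oblique_amp = 0,
                                    bias_amp = 0, lapse = 0, seed = NULL,
                                    grid = direction_grid()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lapse >= 0, lapse <= 1)
  s <- design$s_deg
  n <- length(s)
  scale_f <- 1 + oblique_amp * oblique_distance(s) / 45
  sV0 <- kappa_to_sigma(observer$kappa_V)
  sO0 <- kappa_to_sigma(observer$kappa_O)
  kV <- sigma_to_kappa(pmin(sV0 * scale_f, 1e4))
  kO <- sigma_to_kappa(pmin(sO0 * scale_f, 1e4))
  x_V <- rvm(n, s, kV)
  x_O <- wrap180(s + rvm(n, 0, kO))
  comp <- posterior_mixture_components(x_V, x_O, kV, kO)
  resp <- mixture_trial_stats(comp, grid)$map
  resp <- wrap360(resp + bias_amp * sin(4 * s * DEG2RAD))
  is_lapse <- runif(n) < lapse
  resp[is_lapse] <- runif(sum(is_lapse), 0, 360)
  data.frame(subject = 1L, trial = design$trial, run = design$run,
             s_true_deg = s, response_deg = resp)
}
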
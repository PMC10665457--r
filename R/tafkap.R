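# Generative-model probabilistic decoder: voxel tuning by OLS, structured
# shrinkage noise covariance, grid posterior over direction, bagging under
# leave-one-run-out cross-validation.

#' Direction channel basis responses
#'
#' K half-rectified, raised-cosine channels with preferred directions spread
#' evenly over the circle: \eqn{g_k(s) = \max(0, \cos(s - \varphi_k))^5}.
#' Each channel has one-sided support of width 180 degrees; the channel set
#' covers the whole circle.
#'
#' @param s directions in degrees.
#' @param K number of channels.
#' @param exponent power applied to the rectified cosine.
#' @param phi0 preferred direction of the first channel, degrees.
#' @return matrix, `length(s)` x `K`, values in \eqn{[0, 1]}.
#' @export
basis_response <- function(s, K = 8L, exponent = 5, phi0 = 0) {
  phi <- phi0 + 360 / K * (seq_len(K) - 1L)
  sapply(phi, function(p) pmax(0, cos((s - p) * DEG2RAD))^exponent)
}

#' Fit voxel tuning weights by ordinary least squares
#'
#' @param B trial x voxel response matrix.
#' @param s per-trial stimulus directions, degrees.
#' @param K number of channels.
#' @return list with `W` (voxel x K), `residuals` (trial x voxel), `G`
#'   (trial x K design matrix).
#' @export
fit_tuning <- function(B, s, K = 8L) {
  G <- basis_response(s, K = K)
  if (qr(G)$rank < K)
    stop("rank-deficient design: stimulus directions do not span the channel basis")
  Wt <- solve(crossprod(G), crossprod(G, B))  # K x voxels
  R <- B - G %*% Wt
  list(W = t(Wt), residuals = R, G = G)
}

# Structured covariance (tau fixed): sigma2 * W W' + (1-rho) diag(tau^2) +
# rho tau tau'
omega_structured <- function(W, tau, rho, sigma2) {
  sigma2 * tcrossprod(W) + (1 - rho) * diag(tau^2) + rho * tcrossprod(tau)
}

# Gaussian log-likelihood of residual rows under covariance Omega
gauss_loglik <- function(R, Omega) {
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  X <- backsolve(ch, t(R), transpose = TRUE)   # voxels x n
  n <- nrow(R); v <- ncol(R)
  -0.5 * (n * v * log(2 * pi) + 2 * n * sum(log(diag(ch))) + sum(X^2))
}

#' Fit the structured shrinkage noise model
#'
#' Per-voxel variances are shrunk toward their median
#' (\eqn{\tau_i^2 = \lambda_{var}\,\mathrm{median}(\tau'^2) + (1-\lambda_{var})\tau_i'^2});
#' the global correlation \eqn{\rho} and tuning-shared variance scale
#' \eqn{\sigma^2} are estimated by maximizing the Gaussian likelihood of the
#' residuals under the structured covariance with \eqn{\tau} fixed (set
#' `method = "moment"` for a cheaper moment-matching fit). The final
#' covariance blends the sample covariance with the structured one:
#' \eqn{\Omega = \lambda\,\Omega_{sample} + (1-\lambda)\,\Omega_0}. A small
#' diagonal jitter is added if the blend is not positive definite (recorded
#' in the result).
#'
#' @param residuals trial x voxel residual matrix from [fit_tuning()].
#' @param W voxel x K tuning weights.
#' @param lambda shrinkage weight toward the sample covariance, in
#'   \eqn{[0, 1]}.
#' @param lambda_var variance-shrinkage weight, in \eqn{[0, 1]}.
#' @param method how to fit (`rho`, `sigma2`).
#' @param rho,sigma2 fix these structured-covariance parameters instead of
#'   estimating them.
#' @return list with `Omega`, `tau`, `rho`, `sigma2`, `lambda`,
#'   `lambda_var`, `jitter`.
#' @export
fit_noise <- function(residuals, W, lambda = 0.2, lambda_var = 0.5,
                      method = c("ml", "moment"), rho = NULL, sigma2 = NULL) {
  method <- match.arg(method)
  if (ncol(residuals) < 2) stop("need at least 2 voxels")
  stopifnot(lambda >= 0, lambda <= 1, lambda_var >= 0, lambda_var <= 1)
  n <- nrow(residuals)
  Omega_sample <- crossprod(residuals) / n
  tau_prime2 <- diag(Omega_sample)
  tau2 <- lambda_var * median(tau_prime2) + (1 - lambda_var) * tau_prime2
  tau <- sqrt(tau2)
  if (!is.null(rho) && !is.null(sigma2)) {
    # parameters supplied by the caller; nothing to estimate
  } else if (method == "ml") {
    # alternate (rho, sigma2) likelihood maximization with a closed-form
    # tau update: diag(Omega0) = sigma2 * diag(WW') + tau^2, so the raw
    # residual variances over-state tau^2 by the tuning-shared part
    wdiag <- rowSums(W^2)
    par <- c(qlogis(0.05), log(0.1))
    for (it in 1:3) {
      nll <- function(p) {
        r <- 1 / (1 + exp(-p[1])); s2 <- exp(p[2])
        -gauss_loglik(residuals, omega_structured(W, tau, r, s2))
      }
      fit <- optim(par, nll, method = "Nelder-Mead",
                   control = list(maxit = 200))
      par <- fit$par
      rho <- 1 / (1 + exp(-par[1])); sigma2 <- exp(par[2])
      tau2_it <- pmax(tau_prime2 - sigma2 * wdiag, 1e-6)
      tau2_it <- lambda_var * median(tau2_it) + (1 - lambda_var) * tau2_it
      tau <- sqrt(tau2_it)
    }
  } else {
    # moment matching: mean off-diagonal correlation and average residual
    # covariance explained by the tuning outer product
    Cor <- Omega_sample / sqrt(tcrossprod(tau_prime2))
    rho <- max(0, min(0.99, mean(Cor[upper.tri(Cor)])))
    WW <- tcrossprod(W)
    off <- upper.tri(WW)
    sigma2 <- max(0, sum((Omega_sample[off] - rho * tcrossprod(tau)[off]) *
                           WW[off]) / sum(WW[off]^2))
  }
  Omega0 <- omega_structured(W, tau, rho, sigma2)
  Omega <- lambda * Omega_sample + (1 - lambda) * Omega0
  jitter <- 0
  ev_min <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-10) {
    jitter <- abs(ev_min) + 1e-8
    Omega <- Omega + jitter * diag(ncol(Omega))
  }
  list(Omega = Omega, tau = tau, rho = rho, sigma2 = sigma2,
       lambda = lambda, lambda_var = lambda_var, jitter = jitter)
}

#' Fit the decoder's generative model on training data
#'
#' Convenience wrapper: OLS tuning fit plus shrinkage noise fit. Returns an
#' object usable with [decode_trials()].
#'
#' @param B trial x voxel matrix.
#' @param s stimulus directions, degrees.
#' @param lambda,lambda_var shrinkage weights.
#' @param K number of channels.
#' @param noise_method passed to [fit_noise()].
#' @return object of class `tafkap` with `W`, `noise`, `K`.
#' @export
tafkap_fit <- function(B, s, lambda = 0.2, lambda_var = 0.5, K = 8L,
                       noise_method = "ml") {
  tun <- fit_tuning(B, s, K = K)
  noi <- fit_noise(tun$residuals, tun$W, lambda = lambda,
                   lambda_var = lambda_var, method = noise_method)
  structure(list(W = tun$W, noise = noi, K = K), class = "tafkap")
}

#' @export
print.tafkap <- function(x, ...) {
  cat(sprintf(
    "decoder fit: %d voxels, K=%d channels; rho=%.3f, sigma2=%.3g, lambda=%.2f, lambda_var=%.2f\n",
    nrow(x$W), x$K, x$noise$rho, x$noise$sigma2, x$noise$lambda,
    x$noise$lambda_var))
  invisible(x)
}

#' Decode posterior distributions over motion direction
#'
#' For each test pattern, evaluates the multivariate normal likelihood of
#' the pattern at every grid direction (mean \eqn{W g(s)}, covariance
#' \eqn{\Omega}) and normalizes under a flat prior. Computed in log space
#' with max-subtraction. The decoded direction is the posterior circular
#' mean by default (the posterior mode is also returned), and uncertainty
#' is the posterior entropy in bits.
#'
#' @param fit a `tafkap` object.
#' @param B_test trial x voxel matrix (a single pattern may be passed as a
#'   vector).
#' @param grid direction grid.
#' @return list with `posterior` (trial x grid matrix of masses), and a
#'   data.frame `trials` with `s_decoded` (circular mean), `s_map`,
#'   `entropy_bits`.
#' @export
decode_trials <- function(fit, B_test, grid = direction_grid()) {
  if (is.null(dim(B_test))) B_test <- matrix(B_test, nrow = 1)
  if (ncol(B_test) != nrow(fit$W))
    stop("test pattern voxel count does not match the fitted model")
  ch <- chol(fit$noise$Omega)
  Fg <- basis_response(grid, K = fit$K) %*% t(fit$W)   # grid x voxels
  Qt <- backsolve(ch, backsolve(ch, t(Fg), transpose = TRUE))  # voxels x grid
  q <- colSums(t(Fg) * Qt)                              # f' Om^-1 f per grid
  Xb <- backsolve(ch, t(B_test), transpose = TRUE)      # voxels x n
  bb <- colSums(Xb^2)
  LL <- -0.5 * (outer(bb, q, "+") - 2 * B_test %*% Qt)  # n x grid
  LL <- LL - apply(LL, 1, max)
  P <- exp(LL)
  P <- P / rowSums(P)
  sdec <- apply(P, 1, function(p) circ_mean(grid, p))
  smap <- grid[max.col(P, ties.method = "first")]
  ent <- apply(P, 1, entropy_bits)
  list(posterior = P,
       trials = data.frame(s_decoded = sdec, s_map = smap,
                           entropy_bits = ent))
}

# Select shrinkage weights by held-out likelihood within the training set:
# the last ~20% of training trials (stratified by nothing; trials are
# already shuffled within runs) form an inner validation fold.
select_shrinkage <- function(B, s, lambda_grid = c(0, 0.1, 0.2, 0.4, 0.7, 1),
                             lambda_var_grid = c(0, 0.25, 0.5, 0.75, 1),
                             K = 8L, noise_method = "ml") {
  n <- nrow(B)
  n_val <- max(10L, round(0.2 * n))
  idx_val <- (n - n_val + 1L):n
  idx_tr <- setdiff(seq_len(n), idx_val)
  tun <- fit_tuning(B[idx_tr, , drop = FALSE], s[idx_tr], K = K)
  G_val <- basis_response(s[idx_val], K = K)
  R_val <- B[idx_val, , drop = FALSE] - G_val %*% t(tun$W)
  best <- c(NA, NA); best_ll <- -Inf
  for (lv in lambda_var_grid) for (l in lambda_grid) {
    noi <- fit_noise(tun$residuals, tun$W, lambda = l, lambda_var = lv,
                     method = noise_method)
    ll <- gauss_loglik(R_val, noi$Omega)
    if (ll > best_ll) { best_ll <- ll; best <- c(l, lv) }
  }
  list(lambda = best[1], lambda_var = best[2], loglik = best_ll)
}

#' Leave-one-run-out bagged decoding
#'
#' For each held-out run, the decoder is refit `n_boot` times on bootstrap
#' resamples (with replacement, same size) of the remaining runs' trials;
#' each refit decodes the held-out trials, and the posteriors are averaged
#' across bootstraps. Resamples whose stimulus set is rank-deficient for
#' the channel basis are redrawn. Shrinkage weights are selected once per
#' fold by held-out likelihood on an inner split of the training set.
#' With `n_boot = 1` and `resample = FALSE` this reduces to a direct
#' train/test decode.
#'
#' @param dataset a `voxel_dataset` from [sample_voxel_patterns()] (or a
#'   list with `B` and `design`).
#' @param n_boot bootstrap iterations per fold.
#' @param seed RNG seed.
#' @param resample set `FALSE` to refit on the original training set.
#' @param grid direction grid.
#' @param noise_method passed to [fit_noise()].
#' @param lambda,lambda_var fix the shrinkage weights instead of selecting
#'   them per fold.
#' @return object of class `tafkap_cv`: `trials` data.frame (`trial`, `run`,
#'   `s_true`, `s_decoded`, `s_map`, `entropy_bits`), `posterior` (trial x
#'   grid matrix), `grid`, `shrinkage` (per-fold selected weights),
#'   `n_redraws`.
#' @export
crossval_decode <- function(dataset, n_boot = 50L, seed = NULL,
                            resample = TRUE, grid = direction_grid(),
                            noise_method = "ml", lambda = NULL,
                            lambda_var = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- dataset$B; design <- dataset$design
  runs <- unique(design$run)
  if (length(runs) < 2) stop("need at least 2 runs for cross-validation")
  K <- 8L
  P_all <- matrix(NA_real_, nrow(B), length(grid))
  shr <- list()
  n_redraws <- 0L
  for (r in runs) {
    test_i <- which(design$run == r)
    train_i <- which(design$run != r)
    B_tr <- B[train_i, , drop = FALSE]; s_tr <- design$s_deg[train_i]
    if (is.null(lambda)) {
      sel <- select_shrinkage(B_tr, s_tr, K = K, noise_method = noise_method)
    } else {
      sel <- list(lambda = lambda,
                  lambda_var = if (is.null(lambda_var)) 0.5 else lambda_var)
    }
    shr[[as.character(r)]] <- sel
    P_acc <- matrix(0, length(test_i), length(grid))
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- if (resample && n_boot > 1L)
          sample(length(train_i), replace = TRUE) else seq_along(train_i)
        if (qr(basis_response(s_tr[idx], K = K))$rank == K) break
        n_redraws <- n_redraws + 1L
      }
      fit <- tafkap_fit(B_tr[idx, , drop = FALSE], s_tr[idx],
                        lambda = sel$lambda, lambda_var = sel$lambda_var,
                        K = K, noise_method = noise_method)
      P_acc <- P_acc + decode_trials(fit, B[test_i, , drop = FALSE], grid)$posterior
    }
    P_all[test_i, ] <- P_acc / n_boot
  }
  sdec <- apply(P_all, 1, function(p) circ_mean(grid, p))
  smap <- grid[max.col(P_all, ties.method = "first")]
  ent <- apply(P_all, 1, entropy_bits)
  structure(list(
    trials = data.frame(trial = design$trial, run = design$run,
                        s_true = design$s_deg, s_decoded = sdec,
                        s_map = smap, entropy_bits = ent),
    posterior = P_all, grid = grid, shrinkage = shr,
    n_redraws = n_redraws), class = "tafkap_cv")
}

#' @export
print.tafkap_cv <- function(x, ...) {
  r <- circ_corr(x$trials$s_decoded, x$trials$s_true)
  cat(sprintf(
    "cross-validated decode: %d trials, %d runs; decoded-vs-true circular r = %.3f\n",
    nrow(x$trials), length(unique(x$trials$run)), r))
  invisible(x)
}
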
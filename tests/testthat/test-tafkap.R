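test_that("channel basis responses are rectified, normalized and cover the circle", {
  K <- 8
  phi <- 360 / K * (0:(K - 1))
  G <- basis_response(phi)
  expect_equal(diag(G), rep(1, K))
  # zero outside the 90-degree half-width
  expect_equal(basis_response(c(90, 135, 270))[, 1], rep(0, 3))
  g <- direction_grid(1)
  expect_true(all(rowSums(basis_response(g)) > 0))
  expect_true(all(basis_response(g) >= 0 & basis_response(g) <= 1))
})

test_that("tuning weights are recovered exactly from noiseless data and fail on degenerate designs", {
  set.seed(61)
  W <- matrix(rgamma(30 * 8, 2), 30, 8)
  s <- runif(100, 0, 360)
  B <- basis_response(s) %*% t(W)
  fit <- fit_tuning(B, s)
  expect_lt(max(abs(fit$W - W)), 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_error(fit_tuning(B, rep(45, 100)), "rank")
  # permuted labels destroy the fit
  fitp <- fit_tuning(B, sample(s))
  r2 <- 1 - sum(fitp$residuals^2) / sum(scale(B, scale = FALSE)^2)
  expect_lt(r2, 0.2)
})

test_that("shrinkage covariance obeys its limiting forms and recovers noise parameters", {
  set.seed(62)
  n <- 300; v <- 25
  R <- matrix(rnorm(n * v), n, v)
  W <- matrix(rgamma(v * 8, 2), v, 8)
  f1 <- fit_noise(R, W, lambda = 1, lambda_var = 0)
  expect_equal(f1$Omega, crossprod(R) / n, tolerance = 1e-10)
  f0 <- fit_noise(R, W, lambda = 0, lambda_var = 0, rho = 0, sigma2 = 0)
  expect_equal(f0$Omega, diag(diag(crossprod(R) / n)), tolerance = 1e-10)
  expect_error(fit_noise(R[, 1, drop = FALSE], W[1, , drop = FALSE]), "voxels")
  # parameter recovery from structured noise
  truth <- voxel_truth(n_voxels = 50, rho = 0.15, sigma2 = 0.4,
                       tau_log_sd = 0.2, seed = 63)
  E <- MASS::mvrnorm(2000, rep(0, 50), truth$Omega)
  fr <- fit_noise(E, truth$W, lambda = 0, lambda_var = 0, method = "ml")
  expect_lt(abs(fr$rho - 0.15) / 0.15, 0.2)
  expect_lt(abs(fr$sigma2 - 0.4) / 0.4, 0.2)
})

test_that("the decoded posterior matches a hand-computed Gaussian likelihood", {
  # 2 voxels, tiny closed-form check on a 3-point grid embedded in the full
  # grid evaluation
  W <- matrix(c(1, 0.2, 0.1, 0.8), 2, 2)
  W8 <- cbind(W, matrix(0, 2, 6))
  fit <- structure(list(W = W8, K = 8,
                        noise = list(Omega = diag(c(0.5, 0.8)))),
                   class = "tafkap")
  b <- c(0.7, 0.4)
  grid <- direction_grid()
  dec <- decode_trials(fit, b, grid)
  ll <- sapply(grid, function(s) {
    f <- as.numeric(basis_response(s) %*% t(W8))
    -0.5 * sum((b - f)^2 / c(0.5, 0.8))
  })
  p_oracle <- exp(ll - max(ll)); p_oracle <- p_oracle / sum(p_oracle)
  expect_equal(as.numeric(dec$posterior[1, ]), p_oracle, tolerance = 1e-9)
  expect_equal(sum(dec$posterior), 1, tolerance = 1e-9)
})

test_that("decoding a clean pattern recovers the stimulus and noise widens the posterior", {
  set.seed(64)
  truth <- voxel_truth(n_voxels = 60, seed = 64)
  fit <- structure(list(W = truth$W, K = 8,
                        noise = list(Omega = diag(0.05, 60))),
                   class = "tafkap")
  s_star <- 211.7
  b <- as.numeric(basis_response(s_star) %*% t(truth$W)) + rnorm(60, 0, 0.01)
  dec <- decode_trials(fit, b)
  expect_lt(abs(ang_diff(dec$trials$s_map, s_star)), 1)
  fit4 <- fit
  fit4$noise$Omega <- 4 * fit$noise$Omega
  dec4 <- decode_trials(fit4, b)
  expect_gt(dec4$trials$entropy_bits, dec$trials$entropy_bits)
  expect_error(decode_trials(fit, b[1:10]), "voxel count")
})

test_that("single-bootstrap cross-validation equals a direct train/test decode", {
  ds <- make_test_voxel_data(seed = 65, n_runs = 4, n_voxels = 40)
  cv <- crossval_decode(ds, n_boot = 1, seed = 66, resample = FALSE,
                        lambda = 0.2, lambda_var = 0.5)
  r <- 2L
  test_i <- which(ds$design$run == r)
  train_i <- which(ds$design$run != r)
  fit <- tafkap_fit(ds$B[train_i, ], ds$design$s_deg[train_i],
                    lambda = 0.2, lambda_var = 0.5)
  direct <- decode_trials(fit, ds$B[test_i, ])
  expect_equal(cv$posterior[test_i, ], direct$posterior, tolerance = 1e-10)
})

test_that("stimulus recovery improves along an SNR ladder and uncertainty tracks error", {
  rs <- sapply(c(0.4, 1.2, 3), function(amp) {
    ds <- make_test_voxel_data(seed = 67, n_runs = 5, n_voxels = 60,
                               amplitude = amp)
    cv <- crossval_decode(ds, n_boot = 3, seed = 68, lambda = 0.2,
                          lambda_var = 0.5)
    circ_corr(cv$trials$s_decoded, cv$trials$s_true)
  })
  expect_true(all(diff(rs) > 0))
  ds <- make_test_voxel_data(seed = 69, n_runs = 6, n_voxels = 60)
  cv <- crossval_decode(ds, n_boot = 5, seed = 70, lambda = 0.2,
                        lambda_var = 0.5)
  err <- abs(ang_diff(cv$trials$s_decoded, cv$trials$s_true))
  expect_gt(cor(cv$trials$entropy_bits, err, method = "spearman"), 0)
})
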
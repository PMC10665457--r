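test_that("descriptive mixture fitting recovers its own generating parameters", {
  truth <- list(lambda = 0.1, alpha = 0.7, mu1 = 0, kappa1 = 20,
                mu2 = 180, kappa2 = 10)
  p <- mixture_mass_oracle(truth$lambda, truth$alpha, truth$mu1, truth$kappa1,
                           truth$mu2, truth$kappa2)
  fit <- fit_descriptive_mixture(p, n_restarts = 40, seed = 71)
  d <- disambiguate(fit, 0)
  # component 1 of the truth is the larger one here
  expect_lt(abs(fit$lambda - truth$lambda), 0.02)
  a_hat <- if (abs(ang_diff(fit$mu1, 0)) < 90) fit$alpha else 1 - fit$alpha
  expect_lt(abs(a_hat - truth$alpha), 0.05)
  expect_lt(abs(ang_diff(d$mu_large, 0)), 2)
  expect_lt(abs(ang_diff(d$mu_small, 180)), 2)
  k_large <- if (abs(ang_diff(fit$mu1, 0)) < 90) fit$kappa1 else fit$kappa2
  k_small <- if (abs(ang_diff(fit$mu1, 0)) < 90) fit$kappa2 else fit$kappa1
  expect_lt(abs(k_large - 20) / 20, 0.15)
  expect_lt(abs(k_small - 10) / 10, 0.15)
  expect_lt(fit$jsd, 1e-6)
})

test_that("a uniform posterior is fit closely but flagged as unidentifiable", {
  g <- direction_grid()
  u <- rep(1 / length(g), length(g))
  fit <- fit_descriptive_mixture(u, n_restarts = 30, seed = 72)
  expect_lt(jsd(u, mixture_mass_oracle(fit$lambda, fit$alpha, fit$mu1,
                                       fit$kappa1, fit$mu2, fit$kappa2)), 1e-3)
  # location dispersion across near-optimal restarts reveals the
  # unidentifiable component locations
  expect_gt(max(fit$dispersion_large, fit$dispersion_small), 10)
})

test_that("an exactly symmetric bimodal posterior yields equal-weight components at the modes", {
  p <- mixture_mass_oracle(0, 0.5, 60, 12, 240, 12)
  fit <- fit_descriptive_mixture(p, n_restarts = 40, seed = 73)
  expect_setequal(round(sort(wrap360(c(fit$mu1, fit$mu2)))), c(60, 240))
  expect_lt(abs(fit$alpha - 0.5), 0.02)
})

test_that("fitting the analytic posterior recovers its component locations", {
  set.seed(74)
  n_ok <- 0
  for (i in 1:20) {
    kV <- runif(1, 0.5, 3); kO <- runif(1, 4, 15)
    xV <- runif(1, 0, 360); xO <- runif(1, 0, 180)
    mix <- combined_posterior(list(x_V = xV, x_O = xO),
                              list(kappa_V = kV, kappa_O = kO))
    sep <- abs(ang_diff(mix$theta_A, mix$theta_B))
    if (mix$w_B < 0.05 || sep < 90) next
    n_ok <- n_ok + 1
    fit <- fit_descriptive_mixture(as_distribution(mix), n_restarts = 25,
                                   seed = 74 + i)
    locs <- sort(c(wrap360(fit$mu1), wrap360(fit$mu2)))
    truth <- sort(wrap360(c(mix$theta_A, mix$theta_B)))
    expect_lt(max(abs(ang_diff(locs, truth))), 2)
  }
  expect_gt(n_ok, 5)
})

test_that("component disambiguation follows height with proximity as tie-break", {
  m <- list(lambda = 0, alpha = 0.9, mu1 = 10, kappa1 = 8, mu2 = 190,
            kappa2 = 8)
  d <- disambiguate(m, 0)
  expect_equal(d$mu_large, 10)
  expect_equal(d$mu_near_true, 10)
  # exactly equal heights: proximity breaks the tie
  m2 <- list(lambda = 0, alpha = 0.5, mu1 = 200, kappa1 = 5, mu2 = 20,
             kappa2 = 5)
  d2 <- disambiguate(m2, 0)
  expect_equal(d2$mu_large, 20)
  # conventions agree when the height ordering is strict and the peaks are
  # well separated and the larger is the nearer one
  set.seed(75)
  for (i in 1:50) {
    mu1 <- runif(1, 0, 360); mu2 <- wrap360(mu1 + runif(1, 100, 260))
    mr <- list(lambda = 0.1, alpha = runif(1, 0.6, 0.95), mu1 = mu1,
               kappa1 = runif(1, 3, 20), mu2 = mu2, kappa2 = runif(1, 3, 20))
    dr <- disambiguate(mr, mu1)
    expect_equal(dr$mu_large, dr$mu_near_true)
  }
})

test_that("cluster-count selection recovers the generating structure", {
  set.seed(76)
  one <- r_bvm_cluster(300, 0, 0, 8, 8)
  fit1 <- cluster_peak_pairs(one, n_clusters = c(1, 2), seed = 77,
                             method = "bic")
  expect_equal(fit1$best_k, 1)
  two <- rbind(r_bvm_cluster(150, 0, 0, 10, 10),
               r_bvm_cluster(150, 0, 180, 10, 10))
  fit2 <- cluster_peak_pairs(two, n_clusters = c(1, 2), seed = 78,
                             method = "bic")
  expect_equal(fit2$best_k, 2)
  asg <- cluster_assignments(fit2)
  expect_lt(abs(sort(asg$weights)[1] - 0.5), 0.05)
  # WAIC agrees with BIC on well-separated two-cluster data
  fitw <- cluster_peak_pairs(two, n_clusters = c(1, 2), seed = 79,
                             method = "waic", draws = 600, burn = 300)
  expect_equal(fitw$best_k, 2)
  expect_gt(fitw$comparison$waic[1] - fitw$comparison$waic[2], 10)
  expect_true(all(is.finite(fitw$comparison$rhat)))
  expect_error(cluster_peak_pairs(one[1:20, ], seed = 80), "50")
})

test_that("peak-error regression finds planted slopes and passes the permutation null", {
  set.seed(81)
  n <- 400
  d1 <- runif(n, -60, 60); d2 <- runif(n, -60, 60)
  pairs <- data.frame(mu_near_true = d1, mu_near_opposite = wrap360(180 + d2),
                      s_true = 0)
  err <- 5 * sin(pi * d1 / 90) + 2 * sin(pi * d2 / 90) + rnorm(n, 0, 2)
  res <- peak_error_regression(pairs, err, n_perm = 300, seed = 82)
  expect_gt(res$slope_peak1, 0)
  expect_gt(res$slope_peak2, 0)
  expect_lt(res$p_peak1, 0.01)
  expect_lt(res$p_peak2, 0.01)
  # independent errors: no slope detected
  res0 <- peak_error_regression(pairs, rnorm(n, 0, 3), n_perm = 300, seed = 83)
  expect_gt(res0$p_peak1, 0.01)
  expect_gt(res0$p_peak2, 0.01)
  expect_error(peak_error_regression(pairs[1:10, ], err[1:10]), "20")
})
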
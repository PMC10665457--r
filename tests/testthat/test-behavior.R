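sim_behavior <- function(n, bias_fun = function(s) 0, sd_deg = 6, seed = 1) {
  set.seed(seed)
  s <- runif(n, 0, 360)
  err <- bias_fun(s) + rnorm(n, 0, sd_deg)
  data.frame(s_true_deg = s, response_deg = wrap360(s + err))
}

test_that("bias removal leaves unbiased data untouched and centers residuals", {
  tr <- sim_behavior(12000, seed = 91)
  bm <- remove_cardinal_bias(tr)
  # fitted polynomial means stay near zero (edge bins have inflated
  # variance, hence the looser max bound)
  expect_lt(mean(abs(bm$fitted_mean)), 0.5)
  expect_lt(max(abs(bm$fitted_mean)), 1.5)
  # residuals have near-zero mean in every 15-degree direction bin
  bins <- cut(bm$s, seq(0, 360, 15), include.lowest = TRUE)
  mus <- tapply(bm$residuals, bins, mean)
  expect_lt(max(abs(mus)), 1)
  # applying the correction twice changes residuals by little
  tr2 <- tr
  tr2$response_deg <- wrap360(tr2$s_true_deg + bm$residuals)
  bm2 <- remove_cardinal_bias(tr2)
  expect_lt(sqrt(mean((bm2$residuals - bm$residuals)^2)), 0.5)
})

test_that("an injected repulsion bias selects the repulsion model", {
  # repulsion from cardinals: errors jump sign across each cardinal
  # direction (discontinuity at 0/90/180/270) and vanish at the obliques --
  # only the oblique-centered bins can represent the jump at their edges
  repulse <- function(s) {
    d <- ang_diff(s %% 90, 0)
    d <- ifelse(d >= 45, d - 90, d)
    8 * sign(d) * (45 - abs(d)) / 45
  }
  hits <- 0
  for (k in 1:20) {
    bm <- remove_cardinal_bias(sim_behavior(1500, repulse, seed = 100 + k))
    hits <- hits + (bm$kind == "repulsion")
  }
  expect_gte(hits, 19)
  # attraction bias: the jump sits at the obliques instead
  attract <- function(s) -repulse(s - 45)
  bma <- remove_cardinal_bias(sim_behavior(1500, attract, seed = 200))
  expect_equal(bma$kind, "attraction")
})

test_that("outlier flagging matches the three-sigma normal tail", {
  set.seed(92)
  r <- rnorm(200000)
  mask <- flag_outliers(r, rep(1, length(r)))
  expect_lt(abs(attr(mask, "fraction") - 0.0027), 0.0008)
  expect_false(any(flag_outliers(rep(0, 50), rep(1, 50))))
  spike <- c(rep(0.1, 99), 10)
  expect_true(flag_outliers(spike, rep(1, 100))[100])
})

test_that("distance to the nearest cardinal direction is computed correctly", {
  expect_equal(oblique_distance(c(0, 45, 100, 90, 359)), c(0, 45, 10, 0, 1))
  expect_true(all(oblique_distance(runif(100, 0, 360)) <= 45))
})

test_that("uncertainty-variability regression detects a planted link and passes the null", {
  set.seed(93)
  n <- 2000
  ent <- rnorm(n, 7.4, 0.3)
  sdv <- 4 + 3 * (ent - mean(ent))
  tr <- data.frame(error_deg = rnorm(n, 0, pmax(sdv, 0.5)),
                   entropy_bits = ent,
                   s_true_deg = runif(n, 0, 360),
                   subject = rep(1:4, each = n / 4))
  res <- uncertainty_variability_regression(tr, n_perm = 300, seed = 94)
  expect_gt(res$slope, 0)
  expect_lt(res$p, 0.01)
  # log-transformed variant gives the same sign
  res_log <- uncertainty_variability_regression(tr, log_transform = TRUE,
                                                n_perm = 100, seed = 95)
  expect_gt(res_log$slope, 0)
  # shuffled entropies: no effect
  tr0 <- tr
  set.seed(96)
  tr0$entropy_bits <- sample(tr0$entropy_bits)
  res0 <- uncertainty_variability_regression(tr0, n_perm = 300, seed = 97)
  expect_gt(res0$p, 0.01)
})

r_response_mixture <- function(n, lambda, alpha, kappa1, kappa2) {
  # errors (degrees) from the constrained response mixture
  u <- runif(n)
  out <- numeric(n)
  lapse <- u < lambda
  out[lapse] <- runif(sum(lapse), -180, 180)
  rest <- which(!lapse)
  comp1 <- runif(length(rest)) < alpha
  out[rest[comp1]] <- ang_diff(rvm(sum(comp1), 0, kappa1), 0)
  out[rest[!comp1]] <- ang_diff(rvm(sum(!comp1), 180, kappa2), 0)
  out
}

test_that("response-model comparison selects the generating model", {
  set.seed(98)
  wins_bi <- 0; wins_uni <- 0
  for (k in 1:20) {
    e_bi <- r_response_mixture(300, 0.2, 0.75, 8, 8)
    f_bi <- fit_response_models(e_bi)
    wins_bi <- wins_bi + (f_bi$delta_bic > 10)
    e_uni <- r_response_mixture(300, 0.2, 1, 8, 8)
    f_uni <- fit_response_models(e_uni)
    wins_uni <- wins_uni + (f_uni$delta_bic < 0)
  }
  expect_gte(wins_bi, 19)
  expect_gte(wins_uni, 19)
})

test_that("selection accuracy grows with sample size and guessing is a near-tie", {
  set.seed(99)
  margins <- sapply(c(100, 300, 1000), function(n)
    mean(replicate(5, fit_response_models(
      r_response_mixture(n, 0.15, 0.7, 10, 10))$delta_bic)))
  expect_true(all(diff(margins) > 0))
  # pure guessing: models differ by at most the parameter-count penalty
  e_guess <- runif(500, -180, 180)
  f <- fit_response_models(e_guess)
  expect_lt(abs(f$delta_bic), 2 * log(500))
})
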
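test_that("measurement sampling respects ranges, concentration, and the circular mean", {
  set.seed(3)
  p <- observer_params(kappa_V = 1e6, kappa_O = 5)
  m <- sample_measurements(90, p, n = 200)
  expect_true(all(abs(ang_diff(m$x_V, 90)) < 0.5))
  expect_true(all(m$x_O >= 0 & m$x_O < 180))
  p2 <- observer_params(kappa_V = 5, kappa_O = 5)
  m2 <- sample_measurements(90, p2, n = 10000)
  expect_lt(abs(ang_diff(circ_mean(m2$x_V), 90)), 2)
  # recovered concentration of the velocity draws
  expect_lt(abs(fit_vm_kappa(m2$x_V) - 5) / 5, 0.1)
})

test_that("cue likelihoods have the right modes, symmetries and flat limits", {
  g <- direction_grid()
  lv <- velocity_likelihood(123, 8)
  expect_equal(g[which.max(lv$mass)], 123)
  # pointwise proportional to the von Mises density
  expect_equal(lv$mass, vm_pdf(g, 123, 8) / sum(vm_pdf(g, 123, 8)),
               tolerance = 1e-12)
  flat <- velocity_likelihood(50, 0)
  expect_lt(diff(range(flat$mass)), 1e-15)
  lo <- orientation_likelihood(30, 10)
  half <- length(g) / 2
  # 180-degree periodicity over the whole grid
  expect_equal(lo$mass[1:half], lo$mass[(half + 1):length(g)],
               tolerance = 1e-12)
  peaks <- g[order(lo$mass, decreasing = TRUE)[1:2]]
  expect_setequal(sort(peaks), c(30, 210))
  expect_lt(diff(range(orientation_likelihood(30, 0)$mass)), 1e-15)
})

test_that("the analytic posterior mixture equals the brute-force normalized product", {
  set.seed(7)
  g <- direction_grid()
  worst <- 0
  for (i in 1:100) {
    xV <- runif(1, 0, 360); xO <- runif(1, 0, 180)
    kV <- exp(runif(1, log(0.05), log(80)))
    kO <- exp(runif(1, log(0.05), log(80)))
    mix <- combined_posterior(list(x_V = xV, x_O = xO),
                              list(kappa_V = kV, kappa_O = kO))
    worst <- max(worst, max(abs(as_distribution(mix)$mass -
                                  brute_force_posterior(xV, xO, kV, kO))))
    expect_equal(mix$w_A + mix$w_B, 1, tolerance = 1e-9)
  }
  expect_lt(worst, 1e-8)
})

test_that("posterior weights follow the limiting noise regimes", {
  # precise velocity: second component vanishes
  m <- combined_posterior(list(x_V = 10, x_O = 15),
                          observer_params(kappa_V = 50, kappa_O = 10))
  expect_lt(m$w_B, 1e-3)
  # uninformative velocity: two identical peaks at the orientation and its
  # opposite
  m2 <- combined_posterior(list(x_V = 33, x_O = 70),
                           observer_params(kappa_V = 0, kappa_O = 10))
  expect_equal(m2$w_A, 0.5, tolerance = 1e-9)
  expect_setequal(sort(wrap360(c(m2$theta_A, m2$theta_B))), c(70, 250))
  # both cues uninformative: near-uniform two-component mixture, no error
  m3 <- combined_posterior(list(x_V = 10, x_O = 20),
                           observer_params(kappa_V = 0, kappa_O = 0))
  expect_equal(m3$w_A, 0.5, tolerance = 1e-9)
  expect_lt(max(m3$kappa_A, m3$kappa_B), 1e-9)
})

test_that("posterior is invariant to the orientation wrap and swaps weights under a velocity flip", {
  p <- observer_params(kappa_V = 3, kappa_O = 6)
  g <- direction_grid()
  a <- as_distribution(combined_posterior(list(x_V = 80, x_O = 40), p))
  b <- as_distribution(combined_posterior(list(x_V = 80, x_O = 40 + 180), p))
  expect_equal(a$mass, b$mass, tolerance = 1e-12)
  m1 <- combined_posterior(list(x_V = 80, x_O = 40), p)
  m2 <- combined_posterior(list(x_V = wrap360(80 + 180), x_O = 40), p)
  expect_equal(sort(c(m1$w_A, m1$w_B)), sort(c(m2$w_A, m2$w_B)),
               tolerance = 1e-9)
})

test_that("MAP readout matches the unimodal mode, closed form, and deterministic tie-break", {
  g <- direction_grid()
  post <- combined_posterior(list(x_V = 100, x_O = 100),
                             observer_params(kappa_V = 20, kappa_O = 20))
  expect_equal(map_readout(post), 100)
  # low-noise regime: grid argmax within 1 degree of the closed form
  set.seed(9)
  kV <- sigma_to_kappa(10); kO <- sigma_to_kappa(10)
  p <- observer_params(kappa_V = kV, kappa_O = kO)
  worst <- 0
  for (i in 1:1000) {
    m <- sample_measurements(runif(1, 0, 360), p, n = 1)
    grid_map <- map_readout(combined_posterior(m, p))
    cf <- map_closed_form(m$x_V, m$x_O, kV, kO)
    worst <- max(worst, abs(ang_diff(grid_map, cf)))
  }
  expect_lt(worst, 1)
  # exactly symmetric bimodal posterior: smaller canonical angle wins
  sym <- combined_posterior(list(x_V = 30, x_O = 120),
                            observer_params(kappa_V = 0, kappa_O = 10))
  expect_equal(map_readout(sym), 120)
})

test_that("velocity-only readout is the measurement and recovers its distribution", {
  expect_equal(velocity_only_readout(list(x_V = 123.4)), 123.4)
  # independent of the orientation measurement by construction
  set.seed(11)
  p <- observer_params(kappa_V = 10, kappa_O = 2)
  m <- sample_measurements(200, p, n = 10000)
  est <- velocity_only_readout(m)
  expect_lt(abs(fit_vm_kappa(est) - 10) / 10, 0.1)
  expect_lt(abs(ang_diff(circ_mean(est), 200)), 2)
})

test_that("the von Mises approximation to the MAP distribution holds at low noise", {
  kV <- sigma_to_kappa(10); kO <- sigma_to_kappa(10)
  ap <- map_distribution_approx(40, observer_params(kappa_V = kV, kappa_O = kO))
  expect_equal(ap$mu_MAP, 40)
  expect_equal(ap$kappa_MAP, kV + kO)
  # kappa_O = 0 collapses to the velocity precision (and the approximation
  # is flagged as invalid: the second component has weight 1/2)
  expect_warning(ap0 <- map_distribution_approx(0, observer_params(kappa_V = 5, kappa_O = 0)),
                 "non-negligible")
  expect_equal(ap0$kappa_MAP, 5)
  # coincident measurements: closed form returns the velocity measurement
  expect_equal(map_closed_form(77, 77, 3, 9), 77)
})

test_that("combined posterior is on average no less certain than velocity alone", {
  g <- direction_grid()
  set.seed(13)
  for (sig in list(c(20, 10), c(40, 20), c(60, 30))) {
    kV <- sigma_to_kappa(sig[1]); kO <- sigma_to_kappa(sig[2])
    p <- observer_params(kappa_V = kV, kappa_O = kO)
    m <- sample_measurements(0, p, n = 300)
    vel_mass <- vm_pdf(g, 0, kV); vel_mass <- vel_mass / sum(vel_mass)
    ent_vel <- entropy_bits(vel_mass)
    ent_comb <- sapply(seq_len(300), function(i)
      entropy_bits(as_distribution(combined_posterior(m[i, ], p))))
    expect_lt(mean(ent_comb), ent_vel)
  }
})
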
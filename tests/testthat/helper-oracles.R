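# Independent numerical oracles used across tests.

# modified Bessel function of the first kind, order 0, by power series
# (independent of base R's besselI)
bessel_i0_series <- function(x, terms = 60) {
  k <- 0:(terms - 1)
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# brute-force normalized posterior on the grid from the raw likelihood
# product (velocity von Mises times 180-degree-ambiguous orientation term)
brute_force_posterior <- function(x_V, x_O, kappa_V, kappa_O,
                                  grid = direction_grid()) {
  L <- vm_pdf(grid, x_V, kappa_V) *
    (vm_pdf(grid, x_O, kappa_O) + vm_pdf(grid, x_O + 180, kappa_O))
  L / sum(L)
}

# grid masses of the descriptive mixture for given parameters
mixture_mass_oracle <- function(lambda, alpha, mu1, kappa1, mu2, kappa2,
                                grid = direction_grid()) {
  f <- (1 - lambda) * (alpha * vm_pdf(grid, mu1, kappa1) +
                         (1 - alpha) * vm_pdf(grid, mu2, kappa2)) +
    lambda / (2 * pi)
  f / sum(f)
}

# draw from an independent-coordinate bivariate von Mises cluster (degrees)
r_bvm_cluster <- function(n, mux, muy, kx, ky) {
  data.frame(x_deg = rvm(n, mux, kx), y_deg = rvm(n, muy, ky))
}

# small default synthetic voxel dataset shared by decoder tests
make_test_voxel_data <- function(seed = 42, ori_weight = 0, n_runs = 10,
                                 n_voxels = 200, ...) {
  truth <- voxel_truth(n_voxels = n_voxels, ori_weight = ori_weight,
                       seed = seed, ...)
  design <- make_design(n_runs, seed = seed + 1)
  sample_voxel_patterns(design, truth, seed = seed + 2)
}
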
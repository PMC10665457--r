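# Behavioral preprocessing (cardinal-bias removal, outlier flagging),
# uncertainty-variability summaries, and unimodal-vs-bimodal response model
# comparison.

# Fit one bias model family: split directions into four 90-degree bins
# centered at `centers`, fit a 4th-degree orthogonal polynomial of
# (direction - bin center) to the errors within each bin, and model the
# residual SD as log-linear in |direction - bin center|.
fit_bias_family <- function(s, err, centers, min_per_bin = 10L) {
  bins <- lapply(centers, function(ctr) {
    d <- ang_diff(s, ctr)
    idx <- which(d >= -45 & d < 45)
    if (length(idx) < min_per_bin)
      stop(sprintf("bin centered at %g deg has fewer than %d trials",
                   ctr, min_per_bin))
    x <- d[idx]; y <- err[idx]
    mean_fit <- lm(y ~ poly(x, 4, raw = FALSE))
    mu <- unname(predict(mean_fit))
    r <- y - mu
    dd <- abs(x)
    # heteroscedastic dispersion: log variance linear in distance to center
    var_fit <- lm(log(pmax(r^2, 1e-6)) ~ dd)
    # E[log chi2_1] = digamma(1/2) + log 2; correct the bias
    log_s2 <- unname(predict(var_fit)) - (digamma(0.5) + log(2))
    sd_hat <- sqrt(exp(log_s2))
    ll <- sum(dnorm(y, mu, sd_hat, log = TRUE))
    list(idx = idx, center = ctr, mean_fit = mean_fit, var_fit = var_fit,
         fitted_mean = mu, predicted_sd = sd_hat, loglik = ll)
  })
  list(bins = bins, loglik = sum(vapply(bins, `[[`, numeric(1), "loglik")),
       centers = centers)
}

bias_family_predict <- function(fam, s) {
  mu <- numeric(length(s)); sdv <- numeric(length(s))
  for (b in fam$bins) {
    d <- ang_diff(s, b$center)
    in_bin <- d >= -45 & d < 45
    if (!any(in_bin)) next
    x <- d[in_bin]
    mu[in_bin] <- unname(predict(b$mean_fit, newdata = data.frame(x = x)))
    lv <- unname(predict(b$var_fit, newdata = data.frame(dd = abs(x)))) -
      (digamma(0.5) + log(2))
    sdv[in_bin] <- sqrt(exp(lv))
  }
  list(mean = mu, sd = sdv)
}

#' Remove cardinal biases from behavioral errors
#'
#' Fits two candidate bias models -- attraction toward cardinals (errors
#' near zero at cardinal directions; bins centered at 0/90/180/270) and
#' repulsion from cardinals (errors near zero at obliques; bins centered at
#' 45/135/225/315). Each model fits a 4th-degree orthogonal polynomial of
#' direction (relative to bin center) to the errors per bin, with the error
#' SD allowed to vary with distance to the bin center. The better model by
#' total likelihood is selected; residuals and the predicted per-trial SD
#' (for outlier flagging) are returned.
#'
#' @param trials data.frame with `s_true_deg` and `response_deg` (errors
#'   are computed as the signed circular difference), or with an `error_deg`
#'   column.
#' @return object of class `bias_model`: `kind` ("attraction" or
#'   "repulsion"), `residuals`, `predicted_sd`, per-family log-likelihoods,
#'   and the selected family's fits.
#' @export
remove_cardinal_bias <- function(trials) {
  s <- wrap360(trials$s_true_deg)
  err <- if ("error_deg" %in% names(trials)) trials$error_deg
  else ang_diff(trials$response_deg, trials$s_true_deg)
  attraction <- fit_bias_family(s, err, c(0, 90, 180, 270))
  repulsion <- fit_bias_family(s, err, c(45, 135, 225, 315))
  kind <- if (attraction$loglik >= repulsion$loglik) "attraction" else "repulsion"
  fam <- if (kind == "attraction") attraction else repulsion
  pred <- bias_family_predict(fam, s)
  structure(list(kind = kind, family = fam,
                 loglik_attraction = attraction$loglik,
                 loglik_repulsion = repulsion$loglik,
                 fitted_mean = pred$mean,
                 predicted_sd = pred$sd,
                 residuals = err - pred$mean,
                 s = s),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf(
    "cardinal-bias model: %s selected (logLik %.1f vs %.1f); residual SD %.2f deg\n",
    x$kind,
    if (x$kind == "attraction") x$loglik_attraction else x$loglik_repulsion,
    if (x$kind == "attraction") x$loglik_repulsion else x$loglik_attraction,
    sd(x$residuals)))
  invisible(x)
}

#' Flag outlier errors
#'
#' Marks residual errors larger than `k` times the predicted standard
#' deviation from the bias model.
#'
#' @param residuals bias-corrected errors, degrees.
#' @param predicted_sd per-trial predicted SD, degrees.
#' @param k threshold multiplier (default 3).
#' @return logical mask with attribute `fraction` (flagged proportion).
#' @export
flag_outliers <- function(residuals, predicted_sd, k = 3) {
  mask <- abs(residuals) > k * predicted_sd
  attr(mask, "fraction") <- mean(mask)
  mask
}

#' Within-subject regression of behavioral variability on decoded
#' uncertainty
#'
#' Regresses the squared (optionally log-transformed) bias-corrected error
#' on the decoded posterior entropy, demeaned within subject, with the
#' distance to the nearest cardinal direction as a covariate and optional
#' per-subject intercepts. Inference is by permutation of the entropies
#' within subject.
#'
#' @param trials data.frame with `error_deg`, `entropy_bits`, `s_true_deg`
#'   and optionally `subject`.
#' @param log_transform log-transform the squared errors.
#' @param n_perm permutations.
#' @param seed RNG seed for permutations.
#' @return list with `slope` (effect of demeaned entropy), `p` and the
#'   fitted model.
#' @export
uncertainty_variability_regression <- function(trials, log_transform = FALSE,
                                               n_perm = 1000L, seed = NULL) {
  y <- trials$error_deg^2
  if (log_transform) y <- log(pmax(y, 1e-6))
  sub <- if ("subject" %in% names(trials)) factor(trials$subject)
  else factor(rep(1, nrow(trials)))
  ent <- stats::ave(trials$entropy_bits, sub,
                    FUN = function(v) v - mean(v))
  obl <- oblique_distance(trials$s_true_deg)
  fit_slope <- function(e) {
    f <- if (nlevels(sub) > 1) lm(y ~ e + obl + sub) else lm(y ~ e + obl)
    unname(coef(f)["e"])
  }
  slope <- fit_slope(ent)
  if (!is.null(seed)) set.seed(seed)
  null_s <- replicate(n_perm, fit_slope(stats::ave(ent, sub, FUN = sample)))
  list(slope = slope,
       p = (1 + sum(abs(null_s) >= abs(slope))) / (n_perm + 1),
       null_sd = sd(null_s))
}

# negative log-likelihood of the response-error mixture (errors in radians,
# peaks fixed at 0 and pi)
response_model_nll <- function(par, err_rad, bimodal) {
  lambda <- par[1]
  if (bimodal) {
    alpha <- par[2]; k1 <- exp(par[3]); k2 <- exp(par[4])
  } else {
    alpha <- 1; k1 <- exp(par[2]); k2 <- 1
  }
  f <- (1 - lambda) *
    (alpha * exp(k1 * (cos(err_rad) - 1)) /
       (2 * pi * besselI(k1, 0, expon.scaled = TRUE)) +
       (1 - alpha) * exp(k2 * (cos(err_rad - pi) - 1)) /
       (2 * pi * besselI(k2, 0, expon.scaled = TRUE))) +
    lambda / (2 * pi)
  -sum(log(pmax(f, 1e-300)))
}

fit_one_response_model <- function(err_rad, bimodal) {
  lk_lo <- log(0.001); lk_hi <- log(100)
  if (bimodal) {
    lower <- c(0, 1e-5, lk_lo, lk_lo); upper <- c(0.9, 1 - 1e-5, lk_hi, lk_hi)
    starts <- expand.grid(lambda = c(0.05, 0.3), alpha = c(0.5, 0.8),
                          lk1 = log(c(2, 15)), lk2 = log(c(2, 15)))
  } else {
    lower <- c(0, lk_lo); upper <- c(0.9, lk_hi)
    starts <- expand.grid(lambda = c(0.05, 0.3, 0.6), lk1 = log(c(1, 5, 25)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), response_model_nll, err_rad = err_rad,
            bimodal = bimodal, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("response model optimization failed")
  n_par <- length(lower)
  ll <- -best$value
  par <- best$par
  out <- list(loglik = ll, bic = -2 * ll + n_par * log(length(err_rad)),
              lambda = par[1], n_params = n_par)
  if (bimodal) {
    out$alpha <- par[2]; out$kappa1 <- exp(par[3]); out$kappa2 <- exp(par[4])
  } else {
    out$alpha <- 1; out$kappa1 <- exp(par[2]); out$kappa2 <- NA_real_
  }
  out
}

#' Compare unimodal and bimodal response-error models
#'
#' Fits, by maximum likelihood, (1) a unimodal von Mises centered on the
#' true direction plus a uniform lapse component and (2) a two-component
#' von Mises mixture with peaks fixed at the true (0 degrees) and opposite
#' (180 degrees) directions plus a uniform lapse component, to the
#' distribution of behavioral errors. Model comparison is by BIC;
#' `delta_bic > 0` favors the bimodal model. For group-level inference sum
#' `delta_bic` across subjects.
#'
#' @param errors signed behavioral errors relative to the true direction,
#'   degrees in \eqn{[-180, 180)}.
#' @return object of class `response_model_fit` with `unimodal`, `bimodal`
#'   fits and `delta_bic` (= BIC_unimodal - BIC_bimodal).
#' @export
fit_response_models <- function(errors) {
  if (length(errors) < 30)
    warning("fewer than 30 errors; model comparison will be unstable")
  err_rad <- ang_diff(errors, 0) * DEG2RAD
  uni <- fit_one_response_model(err_rad, bimodal = FALSE)
  bi <- fit_one_response_model(err_rad, bimodal = TRUE)
  structure(list(unimodal = uni, bimodal = bi,
                 delta_bic = uni$bic - bi$bic, n = length(errors)),
            class = "response_model_fit")
}

#' @export
print.response_model_fit <- function(x, ...) {
  cat(sprintf(
    paste0("response-error model comparison (n = %d):\n",
           "  unimodal: logLik %.1f, BIC %.1f (lambda %.2f, kappa %.3g)\n",
           "  bimodal:  logLik %.1f, BIC %.1f (lambda %.2f, alpha %.2f, kappa %.3g/%.3g)\n",
           "  delta BIC (uni - bi) = %.1f -> %s model preferred\n"),
    x$n, x$unimodal$loglik, x$unimodal$bic, x$unimodal$lambda, x$unimodal$kappa1,
    x$bimodal$loglik, x$bimodal$bic, x$bimodal$lambda, x$bimodal$alpha,
    x$bimodal$kappa1, x$bimodal$kappa2, x$delta_bic,
    if (x$delta_bic > 0) "bimodal" else "unimodal"))
  invisible(x)
}
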
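# Thomas cluster process family: Poisson parents with isotropic Gaussian
# offspring (dispersal limitation), the nested double-cluster variant, and
# the inhomogeneous variant (Thomas realization thinned by an intensity
# surface, i.e. dispersal limitation plus habitat filtering). Closed-form
# summary functions, simulators, and minimal-contrast fitting.

#' Thomas cluster process parameters
#'
#' @param sigma cluster radius: Gaussian dispersal sd per axis, metres.
#' @param rho parent (cluster centre) density, parents per square metre.
#' @param lambda_total total specimen intensity, specimens per square metre.
#' @return An object of class `thomas_params`; the mean number of offspring
#'   per parent `mu = lambda_total / rho` is derived.
#' @export
thomas_params <- function(sigma, rho, lambda_total) {
  stopifnot(sigma > 0, rho > 0, lambda_total > 0)
  structure(list(sigma = sigma, rho = rho, lambda_total = lambda_total,
                 mu = lambda_total / rho),
            class = "thomas_params")
}

#' @export
print.thomas_params <- function(x, ...) {
  cat(sprintf(
    "<Thomas: sigma %.4g m, rho %.4g /m2, lambda %.4g /m2, mu %.4g>\n",
    x$sigma, x$rho, x$lambda_total, x$mu))
  invisible(x)
}

#' Nested (double) Thomas cluster parameters
#'
#' Parent points of the small-scale clusters themselves follow a Thomas
#' cluster process (`large`); each such parent receives on average
#' `small_mu` offspring at Gaussian sd `small_sigma`. The total intensity is
#' `large$lambda_total * small_mu`.
#'
#' @param large a [thomas_params()] describing the outer clustering.
#' @param small_sigma nested cluster radius, metres (typically smaller than
#'   `large$sigma`; a warning is raised otherwise).
#' @param small_mu mean points per nested cluster.
#' @export
double_thomas_params <- function(large, small_sigma, small_mu) {
  stopifnot(inherits(large, "thomas_params"), small_sigma > 0, small_mu > 0)
  if (small_sigma >= large$sigma)
    warning("nested cluster radius is not smaller than the outer radius")
  structure(list(large = large, small_sigma = small_sigma,
                 small_mu = small_mu,
                 lambda_total = large$lambda_total * small_mu),
            class = "double_thomas_params")
}

#' Closed-form pair correlation function of a Thomas process
#'
#' g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 rho).
#'
#' @param params a [thomas_params()].
#' @param r distances, metres.
#' @export
thomas_pcf <- function(params, r) {
  stopifnot(all(r >= 0))
  1 + exp(-r^2 / (4 * params$sigma^2)) / (4 * pi * params$sigma^2 * params$rho)
}

#' Closed-form Ripley's K of a Thomas process
#' @inheritParams thomas_pcf
#' @export
thomas_K <- function(params, r) {
  pi * r^2 + (1 - exp(-r^2 / (4 * params$sigma^2))) / params$rho
}

#' Closed-form pair correlation function of a double Thomas process
#'
#' Sum of the CSR level, the between-nest term at the combined scale
#' sqrt(sigma_large^2 + sigma_small^2), and the within-nest term at the
#' small scale.
#'
#' @param params a [double_thomas_params()].
#' @param r distances, metres.
#' @export
double_thomas_pcf <- function(params, r) {
  s12 <- params$large$sigma^2 + params$small_sigma^2
  rho1 <- params$large$rho
  rho_p <- params$large$rho * params$large$mu  # nested-parent density
  1 + exp(-r^2 / (4 * s12)) / (4 * pi * s12 * rho1) +
    exp(-r^2 / (4 * params$small_sigma^2)) /
      (4 * pi * params$small_sigma^2 * rho_p)
}

#' Closed-form Ripley's K of a double Thomas process
#' @inheritParams double_thomas_pcf
#' @export
double_thomas_K <- function(params, r) {
  s12 <- params$large$sigma^2 + params$small_sigma^2
  rho1 <- params$large$rho
  rho_p <- params$large$rho * params$large$mu
  pi * r^2 + (1 - exp(-r^2 / (4 * s12))) / rho1 +
    (1 - exp(-r^2 / (4 * params$small_sigma^2))) / rho_p
}

# Gaussian offspring around parent coordinates, clipped to the window.
scatter_offspring <- function(parents, mu, sigma, window) {
  if (nrow(parents) == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (nrow(parents) * mu > 5e6)
    stop("cluster simulation would generate > 5e6 offspring points; ",
         "parameters are implausible for this window")
  counts <- rpois(nrow(parents), mu)
  tot <- sum(counts)
  if (tot == 0) return(cbind(x = numeric(0), y = numeric(0)))
  px <- rep(parents[, 1], counts) + rnorm(tot, 0, sigma)
  py <- rep(parents[, 2], counts) + rnorm(tot, 0, sigma)
  keep <- window_contains(window, px, py)
  cbind(x = px[keep], y = py[keep])
}

# Poisson parents on the window's bounding box dilated by `buffer`.
poisson_parents <- function(rho, window, buffer) {
  xr <- window$xrange + c(-buffer, buffer)
  yr <- window$yrange + c(-buffer, buffer)
  expected <- rho * diff(xr) * diff(yr)
  if (expected > 5e6)
    stop("cluster simulation would generate > 5e6 parent points; ",
         "parameters are implausible for this window")
  np <- rpois(1, expected)
  cbind(x = runif(np, xr[1], xr[2]), y = runif(np, yr[1], yr[2]))
}

#' Simulate a Thomas cluster process
#'
#' Parents are Poisson with density `rho` on the window dilated by 4 sigma
#' (edge buffer); offspring counts are Poisson(`mu`) with isotropic Gaussian
#' displacements of sd `sigma` per axis; the realization is clipped to the
#' window.
#'
#' @param params a [thomas_params()].
#' @param window an [sppa_window][owin_rect].
#' @param seed optional RNG seed.
#' @export
simulate_thomas <- function(params, window, seed = NULL) {
  with_seed(seed, {
    parents <- poisson_parents(params$rho, window, 4 * params$sigma)
    scatter_offspring(parents, params$mu, params$sigma, window)
  })
}

#' Simulate a double (nested) Thomas cluster process
#'
#' An outer Thomas realization (generated without clipping, on the dilated
#' region) serves as the parent set for the inner Gaussian clusters.
#'
#' @param params a [double_thomas_params()].
#' @inheritParams simulate_thomas
#' @export
simulate_double_thomas <- function(params, window, seed = NULL) {
  with_seed(seed, {
    buffer <- 4 * (params$large$sigma + params$small_sigma)
    xr <- window$xrange + c(-buffer, buffer)
    yr <- window$yrange + c(-buffer, buffer)
    big <- owin_rect(xr, yr)
    outer_parents <- poisson_parents(params$large$rho, big, 0)
    nested_parents <- scatter_offspring(outer_parents, params$large$mu,
                                        params$large$sigma, big)
    scatter_offspring(nested_parents, params$small_mu, params$small_sigma,
                      window)
  })
}

#' Simulate an inhomogeneous Thomas cluster process
#'
#' A homogeneous Thomas realization independently thinned with retention
#' probability proportional to the intensity surface (habitat filtering on
#' top of dispersal limitation). With `rescale = TRUE` the mean offspring
#' count is inflated by the reciprocal of the mean retention so the expected
#' total intensity stays at `params$lambda_total`; the parent density is
#' left alone because independent thinning does not change the pair
#' correlation function, whose cluster excess is set by the parent density.
#'
#' @param params a [thomas_params()].
#' @param surface an [intensity_surface()]; retention is
#'   `surface$evaluate / max(surface)`.
#' @param window an [sppa_window][owin_rect].
#' @param seed optional RNG seed.
#' @param rescale compensate the thinning loss (default `FALSE`).
#' @export
simulate_inhom_thomas <- function(params, surface, window, seed = NULL,
                                  rescale = FALSE) {
  with_seed(seed, {
    smax <- surface$lmax
    if (smax <= 0) return(cbind(x = numeric(0), y = numeric(0)))
    p <- params
    if (rescale) {
      ret <- mean_retention(surface, window)
      if (ret <= 0) return(cbind(x = numeric(0), y = numeric(0)))
      p <- thomas_params(params$sigma, params$rho, params$lambda_total / ret)
    }
    pts <- simulate_thomas(p, window)
    if (nrow(pts) == 0) return(pts)
    keep_p <- pmin(1, surface$evaluate(pts[, 1], pts[, 2]) / smax)
    pts[runif(nrow(pts)) <= keep_p, , drop = FALSE]
  })
}

# Mean of surface/max over the window (midpoint grid).
mean_retention <- function(surface, window, nside = 41) {
  gx <- seq(window$xrange[1], window$xrange[2], length.out = nside)
  gy <- seq(window$yrange[1], window$yrange[2], length.out = nside)
  gg <- expand.grid(x = gx, y = gy)
  keep <- window_contains(window, gg$x, gg$y)
  mean(pmin(1, surface$evaluate(gg$x[keep], gg$y[keep]) / surface$lmax))
}

#' Mean number of individuals per cluster
#'
#' lambda / rho: the total intensity divided by the parent density.
#'
#' @param params a [thomas_params()].
#' @export
mean_cluster_size <- function(params) params$lambda_total / params$rho

# Contiguous fitting region: distances above the exclusion radius where the
# observed PCF exceeds 1, taking the run that contains the PCF maximum (the
# aggregation signal, not fluctuations around the CSR line).
aggregation_region <- function(g_curve, r_exclusion) {
  ok <- g_curve$r > r_exclusion & is.finite(g_curve$values)
  above <- ok & g_curve$values > 1
  if (!any(above))
    stop_sppa("no aggregation signal: observed PCF <= 1 everywhere",
              "sppa_no_aggregation")
  gmax_idx <- which(ok)[which.max(g_curve$values[ok])]
  if (!above[gmax_idx])
    stop_sppa("no aggregation signal: observed PCF <= 1 everywhere",
              "sppa_no_aggregation")
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  k <- which(starts <= gmax_idx & ends >= gmax_idx)
  starts[k]:ends[k]
}

#' Fit a Thomas cluster model by minimal contrast
#'
#' Minimizes the summed squared discrepancy between observed and model
#' summary functions over the contiguous distance range where the observed
#' PCF exceeds 1 (excluding very small distances, which reflect finite
#' specimen size). The PCF enters the contrast directly; the L-based
#' contrast uses the variance-stabilizing fourth-root transform of K. With
#' `fit_basis = "PCF+L"` both contrasts are summed with equal weight. The
#' total intensity is fixed at the observed value, so only the cluster
#' scale(s) and parent density are free.
#'
#' @param observed_g PCF `sppa_curve`.
#' @param observed_L L `sppa_curve` from [estimate_L()] (needed unless
#'   `fit_basis = "PCF"`).
#' @param model_family `"TC"` (single Thomas) or `"DTC"` (nested double).
#' @param fit_basis `"PCF+L"`, `"PCF"` or `"L"`.
#' @param r_exclusion small-scale exclusion radius, metres (default 0.02 m).
#' @return A [thomas_params()] or [double_thomas_params()].
#' @export
fit_minimal_contrast <- function(observed_g, observed_L = NULL,
                                 model_family = c("TC", "DTC"),
                                 fit_basis = c("PCF+L", "PCF", "L"),
                                 r_exclusion = 0.02) {
  model_family <- match.arg(model_family)
  fit_basis <- match.arg(fit_basis)
  if (fit_basis != "PCF" && is.null(observed_L))
    stop("observed_L is required unless fit_basis = 'PCF'")
  idx <- aggregation_region(observed_g, r_exclusion)
  r_full <- observed_g$r
  span <- observed_g$smoothing_span
  r <- r_full[idx]
  g_obs <- observed_g$values[idx]
  lambda <- observed_g$lambda
  K_obs <- if (!is.null(observed_L)) attr(observed_L, "K")[idx] else NULL
  use_g <- fit_basis %in% c("PCF+L", "PCF")
  use_L <- fit_basis %in% c("PCF+L", "L")
  # the observed PCF is a smoothed estimate, so the model PCF enters the
  # contrast smoothed by the same moving average
  model_g <- function(fun, p) smooth_ma(fun(p, r_full), span)[idx]

  # keep the optimizer inside a physically meaningful box
  sigma_box <- c(observed_g$bandwidth / 50, 4 * max(r_full))
  rho_box <- c(1e-6, 1e6)
  obj_tc <- function(par) {
    sigma <- exp(par[1]); rho <- exp(par[2])
    if (sigma < sigma_box[1] || sigma > sigma_box[2] ||
        rho < rho_box[1] || rho > rho_box[2]) return(1e10)
    p <- list(sigma = sigma, rho = rho)
    val <- 0
    if (use_g) val <- val + sum((g_obs - model_g(thomas_pcf, p))^2)
    if (use_L) val <- val + sum((K_obs^0.25 - thomas_K(p, r)^0.25)^2)
    val
  }
  excess <- max(g_obs) - 1
  sigma0 <- max(r[which.max(g_obs)], observed_g$bandwidth)
  starts <- list(c(log(sigma0), log(1 / (4 * pi * sigma0^2 * max(excess, 0.1)))),
                 c(log(sigma0 / 3), log(lambda / 5)),
                 c(log(sigma0 * 2), log(lambda / 20)),
                 c(log(0.1), log(1)))
  if (model_family == "TC") {
    best <- NULL
    for (st in starts) {
      fit <- optim(st, obj_tc, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
      fit <- optim(fit$par, obj_tc, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    return(thomas_params(exp(best$par[1]), exp(best$par[2]), lambda))
  }
  # DTC: free (sigma1, rho1, sigma2, mu2); mu1 = lambda / (rho1 mu2)
  obj_dtc <- function(par) {
    sigma1 <- exp(par[1]); rho1 <- exp(par[2])
    sigma2 <- exp(par[3]); mu2 <- exp(par[4])
    mu1 <- lambda / (rho1 * mu2)
    if (!is.finite(mu1) || mu1 <= 0) return(1e10)
    if (min(sigma1, sigma2) < sigma_box[1] ||
        max(sigma1, sigma2) > sigma_box[2] ||
        rho1 < rho_box[1] || rho1 > rho_box[2] || mu2 > 1e6) return(1e10)
    large <- list(sigma = sigma1, rho = rho1, mu = mu1,
                  lambda_total = rho1 * mu1)
    p <- list(large = large, small_sigma = sigma2, small_mu = mu2)
    val <- 0
    if (use_g) val <- val + sum((g_obs - model_g(double_thomas_pcf, p))^2)
    if (use_L) val <- val + sum((K_obs^0.25 - double_thomas_K(p, r)^0.25)^2)
    val
  }
  tc0 <- fit_minimal_contrast(observed_g, observed_L, "TC", fit_basis,
                              r_exclusion)
  starts_d <- list(c(log(tc0$sigma * 3), log(tc0$rho / 2),
                     log(tc0$sigma), log(max(tc0$mu / 4, 1.5))),
                   c(log(tc0$sigma * 5), log(tc0$rho / 4),
                     log(tc0$sigma / 2), log(2)))
  best <- NULL
  for (st in starts_d) {
    fit <- optim(st, obj_dtc, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
    fit <- optim(fit$par, obj_dtc, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  sigma1 <- exp(best$par[1]); rho1 <- exp(best$par[2])
  sigma2 <- exp(best$par[3]); mu2 <- exp(best$par[4])
  mu1 <- lambda / (rho1 * mu2)
  suppressWarnings(double_thomas_params(
    thomas_params(sigma1, rho1, rho1 * mu1), sigma2, mu2))
}
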
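# Differential (modern) erosion can thin the preserved specimen density
# along strike, dip, or with distance from an exposure edge. Competing
# inhomogeneous-Poisson intensity models — log-linear in x, in y, or in the
# distance to an anchor point, against a homogeneous baseline — are fitted
# by maximum likelihood and compared by AIC; an adopted heterogeneous model
# becomes the null background for the downstream spatial analyses.

# Integral of exp(b * z) over the window, where z is the covariate. Closed
# form for linear covariates on rectangles, Gauss-Legendre quadrature
# otherwise (the integrand is smooth).
window_covariate_integral <- function(window, kind, b, anchor = NULL) {
  if (window$is_rect && kind %in% c("homogeneous", "gradient_x",
                                    "gradient_y")) {
    a1 <- diff(window$xrange); a2 <- diff(window$yrange)
    if (kind == "homogeneous" || abs(b) < 1e-12)
      return(a1 * a2)
    if (kind == "gradient_x")
      return((exp(b * window$xrange[2]) - exp(b * window$xrange[1])) / b * a2)
    return((exp(b * window$yrange[2]) - exp(b * window$yrange[1])) / b * a1)
  }
  zf <- covariate_fun(kind, anchor)
  gauss_quad_window(function(x, y) exp(b * zf(x, y)), window)
}

# Tensor Gauss-Legendre quadrature over the window: exact-domain panels for
# rectangles; fan triangulation with a Duffy-style map for convex polygons.
gauss_quad_window <- function(f, window, n_nodes = 24, n_panels = 4) {
  gl <- gauss_legendre_nodes(n_nodes)
  if (window$is_rect) {
    xs <- seq(window$xrange[1], window$xrange[2], length.out = n_panels + 1)
    ys <- seq(window$yrange[1], window$yrange[2], length.out = n_panels + 1)
    total <- 0
    for (i in seq_len(n_panels)) for (j in seq_len(n_panels)) {
      nx <- (xs[i] + xs[i + 1]) / 2 + (xs[i + 1] - xs[i]) / 2 * gl$x
      ny <- (ys[j] + ys[j + 1]) / 2 + (ys[j + 1] - ys[j]) / 2 * gl$x
      wx <- (xs[i + 1] - xs[i]) / 2 * gl$w
      wy <- (ys[j + 1] - ys[j]) / 2 * gl$w
      gg <- expand.grid(a = seq_len(n_nodes), b = seq_len(n_nodes))
      total <- total + sum(f(nx[gg$a], ny[gg$b]) * wx[gg$a] * wy[gg$b])
    }
    return(total)
  }
  v <- window$vertices
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  m <- nrow(v)
  total <- 0
  gg <- expand.grid(a = seq_len(n_nodes), b = seq_len(n_nodes))
  u <- (gl$x + 1) / 2; wu <- gl$w / 2
  for (e in seq_len(m)) {
    f2 <- if (e == m) 1L else e + 1L
    ax <- v[e, 1] - cx; ay <- v[e, 2] - cy
    bx <- v[f2, 1] - cx; by <- v[f2, 2] - cy
    jac <- abs(ax * by - ay * bx)
    uu <- u[gg$a]; vv <- u[gg$b]
    px <- cx + uu * (ax + vv * (bx - ax))
    py <- cy + uu * (ay + vv * (by - ay))
    total <- total + jac * sum(f(px, py) * uu * wu[gg$a] * wu[gg$b])
  }
  total
}

gauss_legendre_nodes <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix.
  i <- seq_len(n - 1)
  bsub <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bsub
  J[cbind(i + 1, i)] <- bsub
  eg <- eigen(J, symmetric = TRUE)
  idx <- order(eg$values)
  list(x = eg$values[idx], w = 2 * eg$vectors[1, idx]^2)
}

fit_one_erosion_model <- function(xy, window, kind, anchor = NULL) {
  n <- nrow(xy)
  A <- window_area(window)
  if (kind == "homogeneous") {
    ll <- n * log(n / A) - n
    return(list(model_kind = "homogeneous",
                params = c(a = log(n / A), b = 0),
                log_likelihood = ll, aic = 2 * 1 - 2 * ll, n_params = 1L,
                anchor = NULL))
  }
  zf <- covariate_fun(kind, anchor)
  z <- zf(xy[, 1], xy[, 2])
  zrange <- switch(kind,
                   gradient_x = diff(window$xrange),
                   gradient_y = diff(window$yrange),
                   radial_from_point = diff(range(z)) + 1e-9)
  if (zrange < 1e-9) return(NULL)  # degenerate covariate extent
  # profile log-likelihood in b: a*(b) = log(n / I(b))
  prof <- function(b) {
    I <- window_covariate_integral(window, kind, b, anchor)
    n * log(n / I) - n + b * sum(z)
  }
  opt <- optimize(prof, interval = c(-30, 30) / zrange, maximum = TRUE,
                  tol = 1e-10)
  b <- as.numeric(opt$maximum)
  I <- as.numeric(window_covariate_integral(window, kind, b, anchor))
  ll <- as.numeric(opt$objective)
  list(model_kind = kind, params = c(a = log(nrow(xy) / I), b = b),
       log_likelihood = ll, aic = 2 * 2 - 2 * ll, n_params = 2L,
       anchor = anchor)
}

#' Fit competing erosion intensity models
#'
#' Fits inhomogeneous-Poisson models with log-linear intensity
#' `lambda(x, y) = exp(a + b z)` for the covariates z = 1 (homogeneous),
#' x, y, and distance to an anchor point, by maximizing the point-process
#' log-likelihood `sum log lambda(points) - integral_W lambda`, and ranks
#' them by AIC.
#'
#' @param pattern specimen coordinates (all taxa pooled, typically).
#' @param window an [sppa_window][owin_rect].
#' @param anchor optional `c(x, y)` for the radial covariate (e.g. the point
#'   nearest the modern exposure edge); the radial model is skipped with a
#'   message when absent.
#' @return A list of class `erosion_fits`, sorted by AIC; each element has
#'   `model_kind`, `params` (a, b on log intensity), `log_likelihood`,
#'   `aic`, `n_params`.
#' @export
fit_erosion_models <- function(pattern, window, anchor = NULL) {
  xy <- as_coords(pattern)
  if (nrow(xy) < 10) stop_sppa("need at least 10 points",
                               "sppa_insufficient_data")
  kinds <- c("homogeneous", "gradient_x", "gradient_y")
  fits <- lapply(kinds, function(k) fit_one_erosion_model(xy, window, k))
  if (!is.null(anchor)) {
    fits <- c(fits, list(fit_one_erosion_model(xy, window,
                                               "radial_from_point", anchor)))
  } else {
    message("no anchor point supplied; radial erosion model skipped")
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  fits <- fits[order(vapply(fits, function(f) f$aic, numeric(1)))]
  structure(fits, class = "erosion_fits", window = window)
}

#' @export
print.erosion_fits <- function(x, ...) {
  tab <- erosion_report(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabulate erosion model fits (AIC ranking and adoption flag)
#'
#' A heterogeneous model is adopted when its AIC beats the homogeneous
#' model's by more than `delta_aic` (default 2, the conventional support
#' threshold).
#'
#' @param fits an `erosion_fits` list.
#' @param delta_aic adoption threshold on the AIC difference.
#' @export
erosion_report <- function(fits, delta_aic = 2) {
  hom_aic <- vapply(fits, function(f)
    if (f$model_kind == "homogeneous") f$aic else NA_real_, numeric(1))
  hom_aic <- hom_aic[!is.na(hom_aic)][1]
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    model_kind = f$model_kind, a = f$params[["a"]], b = f$params[["b"]],
    logLik = f$log_likelihood, AIC = f$aic,
    stringsAsFactors = FALSE)))
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  tab$adopted <- FALSE
  best <- which.min(tab$AIC)
  if (tab$model_kind[best] != "homogeneous" &&
      hom_aic - tab$AIC[best] > delta_aic) tab$adopted[best] <- TRUE
  else tab$adopted[tab$model_kind == "homogeneous"] <- TRUE
  tab
}

#' Intensity surface of a fitted erosion model
#'
#' Exposes the fitted log-linear intensity as an [intensity_surface()] so it
#' can serve as the null background in the spatial analyses (heterogeneous
#' randomness rung, inhomogeneous cluster thinning). By the likelihood
#' stationarity of the fitted intercept, the surface integrates over the
#' window to the observed point count.
#'
#' @param fit one element of [fit_erosion_models()] output.
#' @param window the window the model was fitted on (taken from the fits
#'   object when available).
#' @export
apply_bias_surface <- function(fit, window) {
  a <- fit$params[["a"]]; b <- fit$params[["b"]]
  if (fit$model_kind == "homogeneous")
    return(constant_intensity(exp(a)))
  gradient_intensity(fit$model_kind, a, b, anchor = fit$anchor,
                     window = window)
}
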
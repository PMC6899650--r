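# Null models: homogeneous Poisson (complete spatial randomness) and
# heterogeneous Poisson processes, nonparametric moving-window intensity
# surfaces, Monte-Carlo simulation envelopes and Diggle's rank
# goodness-of-fit test.

#' Intensity surface
#'
#' @param evaluate vectorized function of `(x, y)` returning intensity in
#'   points per square metre (non-negative).
#' @param kind label: `"constant"`, `"moving_window"` or
#'   `"parametric_gradient"`.
#' @param lmax upper bound (or close upper estimate) of the intensity over
#'   the window, used to dominate rejection sampling.
#' @param R moving-window radius, metres (if applicable).
#' @param params optional parameter list.
#' @return An object of class `intensity_surface`.
#' @export
intensity_surface <- function(evaluate, kind, lmax, R = NULL, params = NULL) {
  structure(list(evaluate = evaluate, kind = kind, lmax = lmax, R = R,
                 params = params),
            class = "intensity_surface")
}

#' Constant intensity surface
#' @param lambda intensity, points per square metre.
#' @export
constant_intensity <- function(lambda) {
  stopifnot(lambda >= 0)
  intensity_surface(function(x, y) rep(lambda, length(x)), "constant",
                    lmax = lambda, params = list(lambda = lambda))
}

#' Log-linear gradient intensity surface
#'
#' lambda(x, y) = exp(a + b z) with covariate z equal to x, y, or the
#' distance to an anchor point.
#'
#' @param kind `"gradient_x"`, `"gradient_y"` or `"radial_from_point"`.
#' @param a,b intercept and slope on log intensity.
#' @param anchor numeric `c(x, y)` for the radial covariate.
#' @param window window used to bound the intensity for rejection sampling.
#' @export
gradient_intensity <- function(kind = c("gradient_x", "gradient_y",
                                        "radial_from_point"),
                               a, b, anchor = NULL, window) {
  kind <- match.arg(kind)
  zfun <- covariate_fun(kind, anchor)
  ev <- function(x, y) exp(a + b * zfun(x, y))
  v <- window$vertices
  gx <- seq(window$xrange[1], window$xrange[2], length.out = 21)
  gy <- seq(window$yrange[1], window$yrange[2], length.out = 21)
  gg <- expand.grid(x = c(gx, v[, 1]), y = c(gy, v[, 2]))
  lmax <- max(ev(gg$x, gg$y))  # exp of a linear/convex covariate: boundary max
  intensity_surface(ev, "parametric_gradient", lmax = lmax,
                    params = list(covariate = kind, a = a, b = b,
                                  anchor = anchor))
}

covariate_fun <- function(kind, anchor = NULL) {
  switch(kind,
         homogeneous = function(x, y) rep(0, length(x)),
         gradient_x = function(x, y) x,
         gradient_y = function(x, y) y,
         radial_from_point = {
           if (is.null(anchor)) stop("radial covariate needs an anchor point")
           function(x, y) sqrt((x - anchor[1])^2 + (y - anchor[2])^2)
         },
         stop("unknown covariate kind: ", kind))
}

#' Moving-window intensity estimate
#'
#' Nonparametric intensity surface for heterogeneous Poisson null models:
#' the intensity at (x, y) is the number of pattern points within distance R
#' divided by the area of the R-disc clipped to the window (edge-aware).
#'
#' @param pattern point coordinates.
#' @param window an [sppa_window][owin_rect].
#' @param R moving-window radius in metres; the conventional range is
#'   0.1-1 m (values outside it draw a warning, not an error).
#' @return An `intensity_surface` of kind `"moving_window"`.
#' @export
moving_window_intensity <- function(pattern, window, R) {
  if (R <= 0) stop("R must be positive")
  if (R < 0.1 - 1e-12 || R > 1 + 1e-12)
    warning("moving-window radius outside the conventional 0.1-1 m range")
  xy <- as_coords(pattern)
  ev <- function(x, y) {
    cnt <- cpp_count_within(x, y, xy[, 1], xy[, 2], R)
    ar <- disc_window_area(window, x, y, R)
    ifelse(ar > 0, cnt / ar, 0)
  }
  # upper intensity estimate for rejection sampling: evaluate at the data
  # points and on a grid finer than R, with a safety factor
  gx <- seq(window$xrange[1], window$xrange[2],
            length.out = max(8, ceiling(diff(window$xrange) / (R / 2))))
  gy <- seq(window$yrange[1], window$yrange[2],
            length.out = max(8, ceiling(diff(window$yrange) / (R / 2))))
  gg <- expand.grid(x = gx, y = gy)
  qx <- c(gg$x, xy[, 1]); qy <- c(gg$y, xy[, 2])
  keep <- window_contains(window, qx, qy)
  lmax <- 1.2 * max(ev(qx[keep], qy[keep]), 0)
  intensity_surface(ev, "moving_window", lmax = lmax, R = R,
                    params = list(n = nrow(xy)))
}

# Uniform points on a window (rejection from the bounding box).
runif_window <- function(n, window) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(16, ceiling((n - nrow(out)) * 1.6))
    px <- runif(m, window$xrange[1], window$xrange[2])
    py <- runif(m, window$yrange[1], window$yrange[2])
    keep <- if (window$is_rect) rep(TRUE, m) else window_contains(window, px, py)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Simulate complete spatial randomness
#'
#' Either a fixed number of independent uniform points (binomial variant,
#' the conditioning used for null-model envelopes) or a homogeneous Poisson
#' count at the given intensity.
#'
#' @param n fixed number of points (binomial variant), or `NULL`.
#' @param lambda intensity, points per square metre (Poisson-count variant;
#'   used when `n` is `NULL`).
#' @param window an [sppa_window][owin_rect].
#' @param seed optional RNG seed (the ambient RNG stream is restored).
#' @return Two-column coordinate matrix.
#' @export
simulate_csr <- function(n = NULL, lambda = NULL, window, seed = NULL) {
  with_seed(seed, {
    if (is.null(n)) {
      if (is.null(lambda) || lambda < 0) stop("need n >= 0 or lambda >= 0")
      n <- rpois(1, lambda * window_area(window))
    }
    if (n < 0) stop("n must be non-negative")
    runif_window(n, window)
  })
}

#' Simulate a heterogeneous (inhomogeneous) Poisson process
#'
#' Thinning of a dominating homogeneous process at the surface's intensity
#' bound. With `n` supplied the pattern is conditioned to exactly n points,
#' i.e. n independent draws from the density proportional to the intensity.
#'
#' @param surface an [intensity_surface()].
#' @param window an [sppa_window][owin_rect].
#' @param seed optional RNG seed.
#' @param n optional fixed point count.
#' @return Two-column coordinate matrix.
#' @export
simulate_heterogeneous_poisson <- function(surface, window, seed = NULL,
                                           n = NULL) {
  with_seed(seed, {
    lmax <- surface$lmax
    if (lmax <= 0) return(cbind(x = numeric(0), y = numeric(0)))
    if (is.null(n)) {
      prop <- simulate_csr(lambda = lmax, window = window)
      if (nrow(prop) == 0) return(prop)
      p <- pmin(1, surface$evaluate(prop[, 1], prop[, 2]) / lmax)
      prop[runif(nrow(prop)) <= p, , drop = FALSE]
    } else {
      out <- matrix(numeric(0), 0, 2)
      guard <- 0
      while (nrow(out) < n && guard < 10000) {
        m <- max(32, ceiling((n - nrow(out)) * 2))
        prop <- runif_window(m, window)
        p <- pmin(1, surface$evaluate(prop[, 1], prop[, 2]) / lmax)
        out <- rbind(out, prop[runif(m) <= p, , drop = FALSE])
        guard <- guard + 1
      }
      if (nrow(out) < n) stop("intensity surface too sparse to place points")
      out <- out[seq_len(n), , drop = FALSE]
      colnames(out) <- c("x", "y")
      out
    }
  })
}

#' Simulate a hard-core pattern by simple sequential inhibition
#'
#' Uniform proposals are rejected when closer than `min_dist` to an already
#' accepted point, producing small-scale segregation.
#'
#' @param n number of points.
#' @param min_dist minimum inter-point spacing, metres.
#' @param window an [sppa_window][owin_rect].
#' @param seed optional RNG seed.
#' @export
simulate_inhibition <- function(n, min_dist, window, seed = NULL) {
  with_seed(seed, {
    px <- numeric(0); py <- numeric(0)
    attempts <- 0; max_attempts <- 1000 * max(n, 1)
    while (length(px) < n && attempts < max_attempts) {
      attempts <- attempts + 1
      q <- runif_window(1, window)
      if (length(px) == 0 ||
          min((px - q[1])^2 + (py - q[2])^2) >= min_dist^2) {
        px <- c(px, q[1]); py <- c(py, q[2])
      }
    }
    if (length(px) < n)
      warning("inhibition sampler placed only ", length(px), " of ", n,
              " points")
    cbind(x = px, y = py)
  })
}

summary_statistic_fun <- function(statistic, window, grid) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
         pcf = function(p) estimate_pcf(p, window, grid),
         L = function(p) estimate_L(p, window, grid),
         oring = function(p) estimate_oring(p, window, grid),
         nn = function(p) estimate_nn(p, window, grid),
         stop("unknown statistic: ", statistic))
}

# Runs of TRUE in a logical vector -> r intervals.
excursion_table <- function(flag, r, direction) {
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) return(NULL)
  rle_f <- rle(flag)
  ends <- cumsum(rle_f$lengths)
  starts <- ends - rle_f$lengths + 1
  keep <- rle_f$values
  data.frame(r_lo = r[starts[keep]], r_hi = r[ends[keep]],
             direction = direction, n_steps = rle_f$lengths[keep])
}

#' Monte-Carlo simulation envelope
#'
#' Simulates the model `n_sims` times, recomputes the summary statistic for
#' each realization, and takes the rank-th smallest/largest simulated values
#' at each distance as the envelope (rank 50 of 999 marks off the 5% highest
#' and lowest simulations). Excursions of the observed curve outside the
#' envelope are tabulated.
#'
#' @param pattern observed point pattern.
#' @param window an [sppa_window][owin_rect].
#' @param generator function of one argument (the simulation index)
#'   returning a simulated point pattern.
#' @param statistic `"pcf"`, `"L"`, `"oring"`, `"nn"`, or a function mapping
#'   a pattern to an `sppa_curve`.
#' @param grid a [distance_grid()].
#' @param n_sims number of simulations (default 999).
#' @param rank envelope rank (default 50); requires `n_sims >= 2 * rank`.
#' @param seed optional RNG seed governing the whole simulation set.
#' @return An object of class `envelope_result` with elements `observed`
#'   (curve with envelope attached), `lo`, `hi`, `sims` (matrix of simulated
#'   curves), `excursions`, `n_sims`, `rank`.
#' @export
monte_carlo_envelope <- function(pattern, window, generator,
                                 statistic = "pcf", grid = distance_grid(),
                                 n_sims = 999, rank = 50, seed = NULL) {
  stopifnot(n_sims >= 2 * rank, rank >= 1)
  sfun <- summary_statistic_fun(statistic, window, grid)
  observed <- sfun(pattern)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      p <- generator(i)
      sfun(p)$values
    }, numeric(length(observed$values)))
  })
  env <- envelope_from_sims(observed, sims, rank)
  env
}

# Build an envelope_result from an observed curve and a matrix of simulated
# curve values (rows = r, cols = sims).
envelope_from_sims <- function(observed, sims, rank) {
  n_sims <- ncol(sims)
  lo <- apply(sims, 1, function(v) sort(v)[rank])
  hi <- apply(sims, 1, function(v) sort(v, decreasing = TRUE)[rank])
  obs <- observed
  obs$envelope_lo <- lo; obs$envelope_hi <- hi; obs$n_sims <- n_sims
  exc <- rbind(excursion_table(observed$values > hi + 1e-12, observed$r,
                               "above"),
               excursion_table(observed$values < lo - 1e-12, observed$r,
                               "below"))
  structure(list(observed = obs, lo = lo, hi = hi, sims = sims,
                 excursions = exc, n_sims = n_sims, rank = rank),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  nexc <- if (is.null(x$excursions)) 0 else nrow(x$excursions)
  cat(sprintf("<envelope: %s, %d sims, rank %d, %d excursion interval(s)>\n",
              x$observed$kind, x$n_sims, x$rank, nexc))
  invisible(x)
}

#' Diggle's goodness-of-fit test
#'
#' For the observed curve and each simulated curve, the deviation measure
#' u_i is the sum over the distance range of the squared difference between
#' curve i and the pointwise mean of all other curves (leave-one-out mean
#' over the pooled observed + simulated set). The p-value is the rank of the
#' observed deviation: p_d = (#\{u_sim >= u_obs\} + 1) / (n_sims + 1), so
#' p_d near 1 means the model fits well and the smallest attainable value is
#' 1/(n_sims + 1).
#'
#' @param observed an `sppa_curve`.
#' @param simulated matrix of simulated curve values (rows matching
#'   `observed$r`), a list of `sppa_curve`s, or an `envelope_result`.
#' @param r_range numeric `c(lo, hi)` distance range over which the
#'   deviation is summed (default: the whole grid).
#' @return An object of class `gof_result` with `p_d`, `statistic`,
#'   `summary_kind`, `r_range`.
#' @export
diggle_gof <- function(observed, simulated, r_range = NULL) {
  if (inherits(simulated, "envelope_result")) simulated <- simulated$sims
  if (is.list(simulated) && !is.matrix(simulated))
    simulated <- vapply(simulated, function(cv) cv$values,
                        numeric(length(observed$values)))
  if (nrow(simulated) != length(observed$r)) stop("mismatched grids")
  n_sims <- ncol(simulated)
  if (n_sims < 39) stop("need at least 39 simulated curves")
  if (is.null(r_range)) r_range <- range(observed$r)
  sel <- observed$r >= r_range[1] - 1e-12 & observed$r <= r_range[2] + 1e-12
  all_curves <- cbind(observed$values, simulated)[sel, , drop = FALSE]
  ok <- rowSums(!is.finite(all_curves)) == 0
  all_curves <- all_curves[ok, , drop = FALSE]
  if (nrow(all_curves) == 0) stop("no finite values in the chosen r range")
  m <- ncol(all_curves)
  tot <- rowSums(all_curves)
  loo <- (tot - all_curves) / (m - 1)
  u <- colSums((all_curves - loo)^2)
  p_d <- (sum(u[-1] >= u[1]) + 1) / (n_sims + 1)
  structure(list(p_d = p_d, statistic = u[1],
                 summary_kind = observed$kind, r_range = r_range),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<Diggle GOF on %s over [%.3g, %.3g] m: p_d = %.4f>\n",
              x$summary_kind, x$r_range[1], x$r_range[2], x$p_d))
  invisible(x)
}
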
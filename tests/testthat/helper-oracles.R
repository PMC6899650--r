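# Independent brute-force oracles: plain double-loop R implementations of
# the estimator definitions, written against the same conventions (box
# kernel of width h on centres (k - 1/2) h, translation edge correction,
# border-corrected nearest-neighbour CDF) but sharing no code with the
# package's vectorized/compiled paths.

brute_pair_curves <- function(xy, xr, yr, nbins, h) {
  n <- nrow(xy)
  a <- diff(xr); b <- diff(yr)
  A <- a * b
  r <- (seq_len(nbins) - 0.5) * h
  g_num <- numeric(nbins)
  K <- numeric(nbins)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- xy[i, 1] - xy[j, 1]; dy <- xy[i, 2] - xy[j, 2]
    d <- sqrt(dx^2 + dy^2)
    w <- (a - abs(dx)) * (b - abs(dy))
    if (w <= 0) next
    bin <- floor(d / h) + 1
    if (d > 0 && bin <= nbins) g_num[bin] <- g_num[bin] + 1 / (2 * pi * d * w)
    K <- K + as.numeric(d <= r) / w
  }
  lam2 <- n * (n - 1) / A^2
  list(r = r, g = g_num / (h * lam2), K = K / lam2)
}

brute_smooth <- function(v, span) {
  if (span <= 1) return(v)
  n <- length(v)
  hl <- floor((span - 1) / 2); hr <- ceiling((span - 1) / 2)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(v[max(1, i - hl):min(n, i + hr)])
  out
}

brute_pcf <- function(xy, xr, yr, grid) {
  bc <- brute_pair_curves(xy, xr, yr, grid$nbins, grid$bandwidth)
  brute_smooth(bc$g, grid$smoothing_span)
}

brute_cross_pcf <- function(xya, xyb, xr, yr, grid) {
  a <- diff(xr); b <- diff(yr); A <- a * b
  h <- grid$bandwidth; nbins <- grid$nbins
  g_num <- numeric(nbins)
  for (i in seq_len(nrow(xya))) for (j in seq_len(nrow(xyb))) {
    dx <- xya[i, 1] - xyb[j, 1]; dy <- xya[i, 2] - xyb[j, 2]
    d <- sqrt(dx^2 + dy^2)
    w <- (a - abs(dx)) * (b - abs(dy))
    if (w <= 0 || d == 0) next
    bin <- floor(d / h) + 1
    if (bin <= nbins) g_num[bin] <- g_num[bin] + 1 / (2 * pi * d * w)
  }
  lam2 <- nrow(xya) * nrow(xyb) / A^2
  brute_smooth(g_num / (h * lam2), grid$smoothing_span)
}

brute_nn <- function(xy, xr, yr, grid) {
  n <- nrow(xy)
  d <- rep(Inf, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dij <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (dij < d[i]) d[i] <- dij
  }
  bdist <- pmin(xy[, 1] - xr[1], xr[2] - xy[, 1],
                xy[, 2] - yr[1], yr[2] - xy[, 2])
  D <- sapply(grid$r, function(r) {
    denom <- sum(bdist >= r)
    if (denom == 0) return(NA_real_)
    sum(d <= r & bdist >= r) / denom
  })
  D <- cummax(ifelse(is.na(D), -Inf, D))
  D[!is.finite(D)] <- NA
  pmin(1, pmax(0, D))
}

# deterministic scattered fixture (no RNG state dependence)
fixture_points <- function(n, xr = c(0, 1), yr = c(0, 1)) {
  i <- seq_len(n)
  x <- xr[1] + diff(xr) * ((i * 0.61803398875) %% 1)
  y <- yr[1] + diff(yr) * ((i * i * 0.41421356237) %% 1)
  cbind(x = x, y = y)
}

rotate_xy <- function(xy, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy %*% t(R)
}

# toroidal pairwise distances on a rectangle
torus_dists <- function(xy, xr, yr) {
  a <- diff(xr); b <- diff(yr)
  n <- nrow(xy)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- abs(xy[i, 1] - xy[j, 1]); dx <- min(dx, a - dx)
    dy <- abs(xy[i, 2] - xy[j, 2]); dy <- min(dy, b - dy)
    out <- c(out, sqrt(dx^2 + dy^2))
  }
  sort(out)
}
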
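# Tectonic strain: originally circular holdfast discs are preserved as
# ellipses whose common aspect ratio and long-axis orientation estimate the
# finite strain; retrodeformation applies the inverse pure shear to restore
# the pre-strain geometry.

#' Strain estimate
#'
#' @param ratio long/short axis ratio (>= 1, dimensionless).
#' @param orientation long-axis orientation in radians, reduced to `[0, pi)`
#'   (axial quantity).
#' @return An object of class `strain_estimate`.
#' @export
strain_estimate <- function(ratio, orientation = 0) {
  stopifnot(is.finite(ratio), ratio >= 1, is.finite(orientation))
  structure(list(ratio = ratio, orientation = orientation %% pi),
            class = "strain_estimate")
}

#' @export
print.strain_estimate <- function(x, ...) {
  cat(sprintf("<strain: ratio %.4f, orientation %.2f deg>\n",
              x$ratio, x$orientation * 180 / pi))
  invisible(x)
}

#' Estimate tectonic strain from elliptical disc outlines
#'
#' The strain ratio is the median of the per-disc long/short axis ratios and
#' the orientation is the axial (period-pi) circular mean of the long-axis
#' orientations, weighted by ellipticity so near-circular discs do not pull
#' the orientation.
#'
#' @param discs data.frame with columns `long`, `short` (axis lengths,
#'   metres) and `orientation` (radians).
#' @return A [strain_estimate()].
#' @export
estimate_strain <- function(discs) {
  discs <- as.data.frame(discs)
  stopifnot(all(c("long", "short", "orientation") %in% names(discs)))
  ok <- is.finite(discs$long) & is.finite(discs$short) &
    discs$long > 0 & discs$short > 0
  discs <- discs[ok, , drop = FALSE]
  if (nrow(discs) < 3)
    stop_sppa("need at least 3 measurable discs to estimate strain",
              "sppa_insufficient_data")
  rat <- pmax(discs$long, discs$short) / pmin(discs$long, discs$short)
  th <- ifelse(discs$long >= discs$short, discs$orientation,
               discs$orientation + pi / 2)
  wgt <- rat - 1
  if (sum(wgt) <= 0) {
    orient <- 0  # all circular: orientation unconstrained
  } else {
    orient <- 0.5 * atan2(sum(wgt * sin(2 * th)), sum(wgt * cos(2 * th)))
  }
  strain_estimate(median(rat), orient %% pi)
}

# Linear strain map. Area-preserving pure shear stretches the long axis by
# sqrt(ratio) and shortens the short axis by 1/sqrt(ratio) (aspect ratio of a
# circle becomes `ratio`, densities unchanged); the uniaxial variant
# stretches the long axis by `ratio` and leaves the short axis alone.
strain_matrix <- function(strain, inverse = FALSE, area_preserving = TRUE) {
  th <- strain$orientation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- if (area_preserving) c(sqrt(strain$ratio), 1 / sqrt(strain$ratio))
       else c(strain$ratio, 1)
  if (inverse) s <- 1 / s
  R %*% diag(s) %*% t(R)
}

# Transform an ellipse (semi-axes a >= b at orientation phi) by the linear
# map M; returns the new (a, b, phi).
transform_ellipse <- function(a, b, phi, M) {
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  E <- Rm %*% diag(c(a^2, b^2)) %*% t(Rm)
  E2 <- M %*% E %*% t(M)
  eg <- eigen(E2, symmetric = TRUE)
  v <- eg$vectors[, 1]
  c(a = sqrt(eg$values[1]), b = sqrt(eg$values[2]),
    phi = atan2(v[2], v[1]) %% pi)
}

apply_linear_map <- function(map, M) {
  rec <- map$records
  if (nrow(rec) > 0) {
    xy <- cbind(rec$x, rec$y) %*% t(M)
    rec$x <- xy[, 1]; rec$y <- xy[, 2]
    has_disc <- all(c("disc_length", "disc_width") %in% names(rec))
    if (has_disc) {
      orient <- if (!is.null(rec$disc_orientation)) rec$disc_orientation
                else rep(0, nrow(rec))
      orient[is.na(orient)] <- 0
      for (i in seq_len(nrow(rec))) {
        a <- rec$disc_length[i]; b <- rec$disc_width[i]
        if (is.na(a) || is.na(b)) next
        e <- transform_ellipse(max(a, b) / 2, min(a, b) / 2,
                               if (a >= b) orient[i] else orient[i] + pi / 2,
                               M)
        rec$disc_length[i] <- 2 * e[["a"]]
        rec$disc_width[i] <- 2 * e[["b"]]
        rec$disc_orientation[i] <- e[["phi"]]
      }
    }
  }
  win <- transform_window(map$window, M)
  bed_map(rec, window = win, surface_name = map$surface_name)
}

#' Apply tectonic strain to a map (forward model)
#'
#' Stretches coordinates, window and disc outlines by the pure-shear strain;
#' the exact inverse of [retrodeform()].
#'
#' @param map a `bed_map`.
#' @param strain a [strain_estimate()].
#' @param area_preserving use the area-preserving shear (default) rather
#'   than a uniaxial stretch.
#' @export
apply_tectonic_strain <- function(map, strain, area_preserving = TRUE) {
  apply_linear_map(map, strain_matrix(strain, inverse = FALSE,
                                      area_preserving = area_preserving))
}

#' Retrodeform a tectonically strained map
#'
#' Applies the inverse pure shear implied by the strain estimate: rotate to
#' the strain axes, shrink the long axis, restore. With `area_preserving =
#' TRUE` (default) specimen densities are unchanged by the correction.
#'
#' @inheritParams apply_tectonic_strain
#' @export
retrodeform <- function(map, strain, area_preserving = TRUE) {
  apply_linear_map(map, strain_matrix(strain, inverse = TRUE,
                                      area_preserving = area_preserving))
}
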
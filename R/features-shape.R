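shape_feature_names <- c(
  "shape_area", "shape_perimeter", "shape_area_perimeter_ratio",
  "shape_convex_area", "shape_eccentricity", "shape_euler",
  "shape_major_axis", "shape_minor_axis", "shape_axis_ratio",
  "shape_curvature", "shape_roundness"
)

# circular moving average used to smooth closed boundary polylines before
# curvature estimation
smooth_closed <- function(x, w) {
  n <- length(x)
  if (n <= w) return(x)
  idx <- outer(seq_len(n), -(w %/% 2):(w %/% 2), function(i, d) ((i + d - 1) %% n) + 1)
  rowMeans(matrix(x[idx], n))
}

# ordered outer boundary of the largest connected component, as an n x 2
# matrix of (row, col) pixel coordinates
mask_contour <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  oc <- EBImage::ocontour(matrix(as.numeric(lab == big), nrow(mask), ncol(mask)))
  # EBImage returns 0-based (x, y) = (row, col) in matrix orientation
  oc[[1]] + 1L
}

#' Shape features of a binary mask
#'
#' Eleven size-and-roundness descriptors with physical units: area (mm^2),
#' perimeter (mm, boundary-polyline segment weighting), area/perimeter
#' ratio (mm), convex-hull area (mm^2), eccentricity of the second-moment
#' ellipse, Euler number (components minus holes), major and minor axis
#' lengths (mm, second-moment ellipse), their ratio, mean absolute boundary
#' curvature (1/mm, from a smoothed boundary polyline), and roundness
#' 4*pi*A/P^2.
#'
#' @param mask logical matrix, nonempty.
#' @param spacing pixel spacing in mm/pixel.
#' @return named numeric vector of length 11.
#' @export
shape_features <- function(mask, spacing = 1) {
  n_px <- sum(mask)
  if (n_px == 0) {
    out <- rep(NA_real_, 11L); names(out) <- shape_feature_names
    attr(out, "missing") <- TRUE
    return(out)
  }
  if (n_px < 5) warning("degenerate mask (< 5 px); shape features unstable")

  area <- n_px * spacing^2

  # second-moment ellipse (with the 1/12 pixel-integration correction)
  idx <- which(mask, arr.ind = TRUE)
  mu_r <- mean(idx[, 1]); mu_c <- mean(idx[, 2])
  m20 <- mean((idx[, 1] - mu_r)^2) + 1 / 12
  m02 <- mean((idx[, 2] - mu_c)^2) + 1 / 12
  m11 <- mean((idx[, 1] - mu_r) * (idx[, 2] - mu_c))
  common <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- (m20 + m02) / 2 + common
  l2 <- max((m20 + m02) / 2 - common, 1e-12)
  major <- 4 * sqrt(l1) * spacing
  minor <- 4 * sqrt(l2) * spacing
  ecc <- sqrt(max(0, 1 - l2 / l1))

  # Euler number: connected components minus holes
  mm <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ncomp <- max(EBImage::bwlabel(mm))
  filled <- EBImage::fillHull(mm)
  nholes <- max(EBImage::bwlabel(filled - mm))
  euler <- ncomp - nholes

  # boundary polyline of the largest component
  ct <- mask_contour(mask)
  nv <- nrow(ct)
  seg <- sqrt(rowSums((ct - ct[c(2:nv, 1), , drop = FALSE])^2))
  perimeter <- max(sum(seg) * spacing, 1e-9)

  # convex hull of pixel centers
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  convex_area <- max(abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2,
                     n_px * 0.5) * spacing^2
  convex_area <- max(convex_area, area)

  # mean absolute curvature of the smoothed closed boundary
  curvature <- NA_real_
  if (nv >= 8) {
    w <- max(5L, round(nv / 20))
    sx <- smooth_closed(ct[, 1], w); sy <- smooth_closed(ct[, 2], w)
    d1x <- (sx[c(2:nv, 1)] - sx[c(nv, 1:(nv - 1))]) / 2
    d1y <- (sy[c(2:nv, 1)] - sy[c(nv, 1:(nv - 1))]) / 2
    d2x <- sx[c(2:nv, 1)] - 2 * sx + sx[c(nv, 1:(nv - 1))]
    d2y <- sy[c(2:nv, 1)] - 2 * sy + sy[c(nv, 1:(nv - 1))]
    denom <- (d1x^2 + d1y^2)^1.5
    ok <- denom > 1e-9
    curvature <- mean(abs(d1x[ok] * d2y[ok] - d1y[ok] * d2x[ok]) / denom[ok]) / spacing
  } else {
    curvature <- 0
  }

  out <- c(area, perimeter, area / perimeter, convex_area, ecc, euler,
           major, minor, major / minor, curvature,
           4 * pi * area / perimeter^2)
  names(out) <- shape_feature_names
  attr(out, "missing") <- FALSE
  out
}
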
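#' Rescale a CT slice to lung-window gray levels
#'
#' Maps the HU interval `[level - width/2, level + width/2]` linearly onto
#' the 8-bit range 0-255, clipping outside the window and rounding half-up
#' to integers. Defaults are standard lung-window settings (WW 1500 HU,
#' WL -600 HU).
#'
#' @param slice a [ct_slice()], or a bare numeric matrix of HU values (in
#'   which case the rescaled integer matrix is returned directly).
#' @param width window width in HU (> 0).
#' @param level window level (center) in HU.
#' @return object of class `windowed_slice` with integer `pixels` in
#'   \[0, 255\], `spacing`, `window` and `patient_id`; for matrix input,
#'   just the pixel matrix.
#' @export
window_rescale <- function(slice, width = 1500, level = -600) {
  stopifnot(width > 0)
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  stopifnot(is.matrix(px))
  lo <- level - width / 2
  g <- (px - lo) / width * 255
  g[g < 0] <- 0
  g[g > 255] <- 255
  g <- floor(g + 0.5)          # round half-up, not banker's rounding
  storage.mode(g) <- "integer"
  if (!inherits(slice, "ct_slice")) return(g)
  structure(list(pixels = g, spacing = slice$spacing,
                 window = c(width = width, level = level),
                 patient_id = slice$patient_id),
            class = "windowed_slice")
}

#' @export
print.windowed_slice <- function(x, ...) {
  cat(sprintf("<windowed_slice> %dx%d px, window WW %g / WL %g HU\n",
              nrow(x$pixels), ncol(x$pixels), x$window["width"],
              x$window["level"]))
  invisible(x)
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

#' Crop an image (and companion masks) around a tumor mask
#'
#' Takes the axis-aligned bounding box of `tumor_mask`, expands it by
#' `margin_mm` (converted to pixels via the slice spacing), and clips to the
#' image bounds. The default 35 mm margin leaves room for the largest 30 mm
#' peritumoral ring. The returned `offset` gives the (row, col) of the
#' crop's top-left pixel in the original image, so coordinates are
#' recoverable with [uncrop_indices()].
#'
#' @param slice a `ct_slice` or `windowed_slice`.
#' @param tumor_mask logical matrix, nonempty, same dimensions as the slice.
#' @param margin_mm margin around the mask bounding box in mm.
#' @return list with `slice` (same class as input, cropped), `offset`
#'   (integer row/col of the top-left corner, 1-based), and `crop_mask`
#'   helper closure is not stored -- use [crop_with_offset()] for masks.
#' @export
crop_to_roi <- function(slice, tumor_mask, margin_mm = 35) {
  stopifnot(inherits(slice, "ct_slice") || inherits(slice, "windowed_slice"))
  px <- slice$pixels
  stopifnot(all(dim(tumor_mask) == dim(px)))
  bb <- mask_bbox(tumor_mask)
  m <- round(margin_mm / slice$spacing)
  r1 <- max(1L, bb["rmin"] - m); r2 <- min(nrow(px), bb["rmax"] + m)
  c1 <- max(1L, bb["cmin"] - m); c2 <- min(ncol(px), bb["cmax"] + m)
  out <- slice
  out$pixels <- px[r1:r2, c1:c2, drop = FALSE]
  list(slice = out, offset = c(row = as.integer(r1), col = as.integer(c1)))
}

#' Apply a previously computed crop to a mask or matrix
#'
#' @param mat matrix with the original (uncropped) dimensions.
#' @param offset crop offset from [crop_to_roi()].
#' @param dim_cropped dimensions of the cropped image.
#' @return the matching submatrix.
#' @export
crop_with_offset <- function(mat, offset, dim_cropped) {
  r <- offset["row"]; c <- offset["col"]
  mat[r:(r + dim_cropped[1] - 1), c:(c + dim_cropped[2] - 1), drop = FALSE]
}

#' Map cropped-image pixel indices back to original coordinates
#'
#' @param idx two-column matrix of (row, col) indices in the cropped frame.
#' @param offset crop offset from [crop_to_roi()].
#' @return indices in the original image frame.
#' @export
uncrop_indices <- function(idx, offset) {
  idx <- as.matrix(idx)
  cbind(row = idx[, 1] + offset["row"] - 1L,
        col = idx[, 2] + offset["col"] - 1L)
}
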
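#' Exact Euclidean disk structuring element
#'
#' Pixels whose center lies within `r` pixels of the element center.
#' Dilation by this element is equivalent to thresholding the Euclidean
#' distance transform at `r`.
#'
#' @param r radius in pixels (>= 0, integer).
#' @return square 0/1 numeric matrix of side `2r + 1`.
#' @export
disk_brush <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0)
  d <- 2L * r + 1L
  ii <- matrix(seq_len(d) - r - 1L, d, d)
  jj <- t(ii)
  (ii^2 + jj^2 <= r^2 + 1e-9) * 1
}

dilate_mask <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                         disk_brush(r_px))
  matrix(as.logical(out > 0.5), nrow(mask), ncol(mask))
}

#' Intratumoral region from a tumor mask
#'
#' Returns the segmented tumor with interior holes filled: necrotic and
#' cavitated areas at low attenuation inside the tumor belong to the
#' intratumoral region. The mask is not required to be connected; multiple
#' components raise a warning (or an error under `strict = TRUE`) since
#' they usually indicate a segmentation artifact.
#'
#' @param tumor_mask logical matrix, nonempty.
#' @param strict error instead of warning on a disconnected mask.
#' @return logical matrix.
#' @export
intratumoral_region <- function(tumor_mask, strict = FALSE) {
  if (!any(tumor_mask)) stop("tumor mask is empty")
  lab <- EBImage::bwlabel(matrix(as.numeric(tumor_mask),
                                 nrow(tumor_mask), ncol(tumor_mask)))
  ncomp <- max(lab)
  if (ncomp > 1) {
    msg <- sprintf("tumor mask has %d connected components", ncomp)
    if (strict) stop(msg) else warning(msg)
  }
  filled <- EBImage::fillHull(matrix(as.numeric(tumor_mask),
                                     nrow(tumor_mask), ncol(tumor_mask)))
  matrix(as.logical(filled > 0.5), nrow(tumor_mask), ncol(tumor_mask))
}

#' Peritumoral band at a given dilation distance
#'
#' The cumulative band from the tumor boundary out to `d_mm`, built by
#' morphological dilation of the tumor with a disk of radius
#' `round(d_mm / spacing)` pixels, minus the tumor itself. Chest wall and
#' mediastinum are removed by the HU threshold (default -224 HU, applied on
#' the original calibrated image, not on windowed gray levels), and the
#' bronchi are removed via the supplied airway mask dilated by one pixel to
#' strip partial-volume rims. Pixels falling outside the image are simply
#' absent.
#'
#' @param tumor_mask logical matrix (intratumoral region).
#' @param d_mm band extent in mm (typically 3, 6, ..., 30).
#' @param hu_image a [ct_slice()] aligned with the mask.
#' @param airway_mask logical matrix (may be all-FALSE).
#' @param threshold exclusion threshold in HU.
#' @return logical matrix with attribute `empty` set to `TRUE` when no
#'   pixel survives the exclusions (e.g. a tumor filling the lung), so
#'   downstream features can be marked missing.
#' @export
peritumoral_region <- function(tumor_mask, d_mm, hu_image,
                               airway_mask = NULL, threshold = -224) {
  stopifnot(inherits(hu_image, "ct_slice"), d_mm > 0)
  spacing <- hu_image$spacing
  r_px <- round(d_mm / spacing)
  ring <- dilate_mask(tumor_mask, r_px) & !tumor_mask
  ring <- ring & (hu_image$pixels <= threshold)
  if (!is.null(airway_mask) && any(airway_mask)) {
    ring <- ring & !dilate_mask(airway_mask, 1L)
  }
  attr(ring, "empty") <- !any(ring)
  ring
}

#' Combined region: union of disjoint intratumoral and peritumoral masks
#'
#' @param intratumoral,peritumoral logical matrices; must be disjoint.
#' @return logical matrix.
#' @export
combined_region <- function(intratumoral, peritumoral) {
  if (any(intratumoral & peritumoral)) {
    stop("intratumoral and peritumoral masks overlap")
  }
  intratumoral | peritumoral
}

#' Build the full region set for one patient
#'
#' Constructs the intratumoral mask (holes filled), the cumulative
#' peritumoral bands at each requested distance, and the combined masks.
#' Bands are nested by construction (larger dilation radii contain smaller
#' ones) and disjoint from the tumor.
#'
#' @param tumor_mask segmented tumor, logical matrix.
#' @param hu_image a [ct_slice()] (used for spacing and the HU exclusion).
#' @param airway_mask logical matrix or `NULL`.
#' @param distances_mm vector of band extents in mm.
#' @param threshold chest-wall exclusion threshold in HU.
#' @return object of class `region_set`: list with `intratumoral`,
#'   `peritumoral` and `combined` (named lists keyed by distance),
#'   `spacing`, `distances_mm`, `threshold`.
#' @export
build_region_set <- function(tumor_mask, hu_image, airway_mask = NULL,
                             distances_mm = seq(3, 30, by = 3),
                             threshold = -224) {
  intra <- intratumoral_region(tumor_mask)
  peri <- lapply(distances_mm, function(d) {
    peritumoral_region(intra, d, hu_image, airway_mask, threshold)
  })
  names(peri) <- as.character(distances_mm)
  comb <- lapply(peri, function(p) combined_region(intra, p))
  structure(list(intratumoral = intra, peritumoral = peri, combined = comb,
                 spacing = hu_image$spacing, distances_mm = distances_mm,
                 threshold = threshold),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> intratumoral %d px; bands at %s mm (px counts: %s)\n",
              sum(x$intratumoral), paste(x$distances_mm, collapse = ","),
              paste(vapply(x$peritumoral, sum, 0L), collapse = ",")))
  invisible(x)
}

#' Per-patient region inventory
#'
#' Pixel counts per region tag, convenient for logging and QC.
#' @param rs a `region_set`.
#' @return data.frame with `region_tag` and `n_pixels`.
#' @export
region_inventory <- function(rs) {
  tags <- c("intra",
            paste0("peri_", names(rs$peritumoral)),
            paste0("comb_", names(rs$combined)))
  counts <- c(sum(rs$intratumoral),
              vapply(rs$peritumoral, sum, 0L),
              vapply(rs$combined, sum, 0L))
  data.frame(region_tag = tags, n_pixels = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
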
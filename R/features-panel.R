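#' Feature panel schema
#'
#' Canonical ordered feature names per region kind: 69 intratumoral
#' (12 intensity + 14 GLCM + 22 GLRLM + 10 LBP + 11 shape), 58 peritumoral
#' (no shape), 127 combined (the intratumoral vector concatenated with the
#' peritumoral vector, prefixed `intra_`/`peri_`). The `shape_roundness`
#' entry is a non-canonical 11th shape descriptor (4*pi*A/P^2) completing
#' the size-and-roundness family. A version hash over the ordered names
#' guards against silent schema drift.
#'
#' @return list with `intra`, `peri`, `combined` name vectors and `hash`.
#' @export
feature_schema <- function() {
  texture <- c(glcm_feature_names, glrlm_feature_names, lbp_feature_names)
  intra <- c(intensity_feature_names, texture, shape_feature_names)
  peri <- c(intensity_feature_names, texture)
  combined <- c(paste0("intra_", intra), paste0("peri_", peri))
  tf <- tempfile()
  writeLines(c(intra, peri), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(intra = intra, peri = peri, combined = combined, hash = hash)
}

# 58 intensity + texture features of one region on the windowed image
region_features_58 <- function(gray, mask) {
  if (!any(mask)) {
    out <- rep(NA_real_, 58L)
    names(out) <- c(intensity_feature_names, glcm_feature_names,
                    glrlm_feature_names, lbp_feature_names)
    attr(out, "missing") <- TRUE
    return(out)
  }
  out <- c(intensity_features(gray[mask]),
           glcm_features(gray, mask),
           glrlm_features(gray, mask),
           lbp_features(gray, mask))
  attr(out, "missing") <- FALSE
  out
}

#' Extract the full radiomic feature panel for one patient
#'
#' Computes, on the windowed (0-255) image: the 69-feature intratumoral
#' vector (intensity + texture + shape), a 58-feature vector for every
#' peritumoral band, and a 127-feature combined vector per band formed by
#' concatenating the intratumoral and band vectors (the combined region is
#' characterised by its parts, not by features of the union mask). Empty
#' peritumoral bands yield all-NA vectors flagged missing.
#'
#' @param windowed a `windowed_slice` aligned with the region set.
#' @param region_set a [build_region_set()] result.
#' @return named list of feature vectors keyed by region tag (`intra`,
#'   `peri_<d>`, `comb_<d>`); each has attributes `region_tag` and
#'   `missing`.
#' @export
extract_panel <- function(windowed, region_set) {
  stopifnot(inherits(windowed, "windowed_slice"),
            inherits(region_set, "region_set"))
  gray <- windowed$pixels
  stopifnot(all(dim(gray) == dim(region_set$intratumoral)))

  intra <- c(region_features_58(gray, region_set$intratumoral),
             shape_features(region_set$intratumoral, region_set$spacing))
  attr(intra, "missing") <- FALSE
  attr(intra, "region_tag") <- "intra"

  out <- list(intra = intra)
  for (d in names(region_set$peritumoral)) {
    pv <- region_features_58(gray, region_set$peritumoral[[d]])
    attr(pv, "region_tag") <- paste0("peri_", d)
    out[[paste0("peri_", d)]] <- pv

    cv <- c(stats::setNames(as.numeric(intra), paste0("intra_", names(intra))),
            stats::setNames(as.numeric(pv), paste0("peri_", names(pv))))
    attr(cv, "missing") <- isTRUE(attr(pv, "missing"))
    attr(cv, "region_tag") <- paste0("comb_", d)
    out[[paste0("comb_", d)]] <- cv
  }
  out
}

#' Extract a cohort feature table from phantom (or loaded) images
#'
#' Runs preprocessing (lung windowing, ROI cropping), region construction
#' and panel extraction for every patient and returns one wide data frame:
#' `patient_id` plus `"<region_tag>__<feature_name>"` columns for the
#' intratumoral region and every peritumoral band. Combined-region design
#' matrices are assembled from these columns with [region_design_matrix()],
#' since combined vectors are concatenations.
#'
#' @param images list as returned in `generate_cohort()$images`: each
#'   element has `ct`, `tumor_mask`, `airway_mask`.
#' @param distances_mm peritumoral band extents in mm.
#' @param window_width,window_level lung-window settings in HU.
#' @param crop_margin_mm crop margin around the tumor bounding box.
#' @param threshold chest-wall exclusion threshold in HU.
#' @return data.frame, one row per patient.
#' @export
extract_feature_table <- function(images, distances_mm = seq(3, 30, by = 3),
                                  window_width = 1500, window_level = -600,
                                  crop_margin_mm = 35, threshold = -224) {
  rows <- lapply(images, function(im) {
    cropped <- crop_to_roi(im$ct, im$tumor_mask, crop_margin_mm)
    dims <- dim(cropped$slice$pixels)
    tmask <- crop_with_offset(im$tumor_mask, cropped$offset, dims)
    amask <- crop_with_offset(im$airway_mask, cropped$offset, dims)
    win <- window_rescale(cropped$slice, window_width, window_level)
    rs <- build_region_set(tmask, cropped$slice, amask,
                           distances_mm = distances_mm, threshold = threshold)
    panel <- extract_panel(win, rs)
    keep <- c("intra", paste0("peri_", distances_mm))
    vals <- unlist(lapply(keep, function(tag) {
      v <- panel[[tag]]
      stats::setNames(as.numeric(v), paste0(tag, "__", names(v)))
    }))
    vals
  })
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = names(images), tab, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Design matrix for one region tag from a wide feature table
#'
#' `intra` and `peri_<d>` tags select their own columns; `comb_<d>` binds
#' the intratumoral and band columns, mirroring the 69 + 58 = 127 combined
#' panel.
#'
#' @param feature_table output of [extract_feature_table()].
#' @param region_tag one of `"intra"`, `"peri_<d>"`, `"comb_<d>"`.
#' @return numeric matrix with patients as rows.
#' @export
region_design_matrix <- function(feature_table, region_tag) {
  cols <- colnames(feature_table)
  pick <- function(tag) cols[startsWith(cols, paste0(tag, "__"))]
  sel <- if (startsWith(region_tag, "comb_")) {
    d <- sub("^comb_", "", region_tag)
    c(pick("intra"), pick(paste0("peri_", d)))
  } else {
    pick(region_tag)
  }
  if (length(sel) == 0) stop("unknown region tag: ", region_tag)
  m <- as.matrix(feature_table[, sel, drop = FALSE])
  rownames(m) <- feature_table$patient_id
  m
}

#' Tidy (long) export of a wide feature table
#'
#' @param feature_table output of [extract_feature_table()].
#' @return data.frame with `patient_id`, `region_tag`, `feature_name`,
#'   `value`.
#' @export
feature_table_long <- function(feature_table) {
  cols <- setdiff(colnames(feature_table), "patient_id")
  parts <- strsplit(cols, "__", fixed = TRUE)
  long <- do.call(rbind, lapply(seq_along(cols), function(k) {
    data.frame(patient_id = feature_table$patient_id,
               region_tag = parts[[k]][1],
               feature_name = parts[[k]][2],
               value = feature_table[[cols[k]]],
               stringsAsFactors = FALSE)
  }))
  row.names(long) <- NULL
  long
}
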
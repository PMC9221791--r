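# Serialization of phantom slices, masks and clinical tables: NIfTI
# (single-z-slice volumes with pixel spacing in the header), lossless PNG
# (HU offset by 1024 and packed into two 8-bit channels, i.e. a 16-bit
# encoding), CSV clinical tables, and a JSON manifest binding the files of
# each patient.

#' Write one phantom (image + masks) to disk
#'
#' @param phantom output of [generate_phantom()].
#' @param dir target directory (created if needed).
#' @param format `"nifti"`, `"png"` or both.
#' @return named character vector of the files written.
#' @export
write_phantom <- function(phantom, dir, format = c("nifti", "png")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- phantom$ct$patient_id
  sp <- phantom$ct$spacing
  files <- character(0)
  if ("nifti" %in% format) {
    as_slice_nifti <- function(mat) {
      img <- RNifti::asNifti(array(mat, dim = dim(mat)))
      RNifti::pixdim(img) <- c(sp, sp)
      img
    }
    f <- file.path(dir, paste0(id, "_ct.nii.gz"))
    RNifti::writeNifti(as_slice_nifti(phantom$ct$pixels), f)
    files["ct_nifti"] <- f
    for (nm in c("tumor_mask", "airway_mask")) {
      fm <- file.path(dir, paste0(id, "_", nm, ".nii.gz"))
      RNifti::writeNifti(as_slice_nifti(phantom[[nm]] * 1), fm)
      files[paste0(nm, "_nifti")] <- fm
    }
  }
  if ("png" %in% format) {
    f <- file.path(dir, paste0(id, "_ct.png"))
    png::writePNG(hu_to_png(phantom$ct$pixels), f)
    files["ct_png"] <- f
    for (nm in c("tumor_mask", "airway_mask")) {
      fm <- file.path(dir, paste0(id, "_", nm, ".png"))
      png::writePNG(matrix(as.numeric(phantom[[nm]]),
                           nrow(phantom[[nm]]), ncol(phantom[[nm]])), fm)
      files[paste0(nm, "_png")] <- fm
    }
  }
  files
}

# HU in [-1024, 3071] -> offset 16-bit split into high/low 8-bit channels
hu_to_png <- function(px) {
  v <- as.integer(px) + 1024L
  hi <- v %/% 256L
  lo <- v %% 256L
  out <- array(0, dim = c(nrow(px), ncol(px), 2L))
  out[, , 1] <- hi / 255
  out[, , 2] <- lo / 255
  out
}

png_to_hu <- function(arr) {
  hi <- round(arr[, , 1] * 255)
  lo <- round(arr[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo) - 1024L, dim(arr)[1], dim(arr)[2])
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir directory; `id` patient identifier; `format` which encoding
#'   to read; `spacing` required for PNG (which stores no spacing).
#' @return list with `ct`, `tumor_mask`, `airway_mask`.
#' @export
read_phantom <- function(dir, id, format = c("nifti", "png"), spacing = NULL) {
  format <- match.arg(format)
  drop_z <- function(img) {
    d <- dim(img)
    if (length(d) == 3) img[, , 1] else img
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(file.path(dir, paste0(id, "_ct.nii.gz")))
    sp <- RNifti::pixdim(img)[1]
    v <- drop_z(img)
    px <- matrix(as.integer(v), nrow(v), ncol(v))
    masks <- lapply(c("tumor_mask", "airway_mask"), function(nm) {
      m <- RNifti::readNifti(file.path(dir, paste0(id, "_", nm, ".nii.gz")))
      mv <- drop_z(m)
      matrix(mv > 0.5, nrow(mv), ncol(mv))
    })
  } else {
    stopifnot(!is.null(spacing))
    sp <- spacing
    px <- png_to_hu(png::readPNG(file.path(dir, paste0(id, "_ct.png"))))
    masks <- lapply(c("tumor_mask", "airway_mask"), function(nm) {
      m <- png::readPNG(file.path(dir, paste0(id, "_", nm, ".png")))
      if (length(dim(m)) == 3) m <- m[, , 1]
      m > 0.5
    })
  }
  list(ct = ct_slice(px, sp, id), tumor_mask = masks[[1]],
       airway_mask = masks[[2]])
}

#' Write a cohort to disk: images, clinical CSV and manifest JSON
#'
#' @param cohort output of [generate_cohort()] (with images).
#' @param dir target directory.
#' @param format image encoding passed to [write_phantom()].
#' @return path of the manifest file.
#' @export
write_cohort <- function(cohort, dir, format = "nifti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$records, clin, row.names = FALSE)
  entries <- lapply(names(cohort$images), function(id) {
    files <- write_phantom(cohort$images[[id]], dir, format)
    fl <- as.list(basename(files))
    names(fl) <- names(files)
    c(list(patient_id = id,
           spacing = cohort$images[[id]]$ct$spacing), fl)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(clinical = basename(clin), patients = entries),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Read a cohort clinical table
#'
#' @param dir cohort directory written by [write_cohort()].
#' @return data.frame of patient records.
#' @export
read_clinical <- function(dir) {
  utils::read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
}
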
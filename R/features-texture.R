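# Texture features: GLCM (Haralick), GLRLM (run-length) and uniform LBP.
# All operate on the 0-255 windowed image quantized to Ng gray levels by
# equal-width binning of the fixed 0-255 range, with pairs/runs/neighborhoods
# restricted to the region mask.

glcm_stat_names <- c("asm", "contrast", "sum_average", "sum_variance",
                     "sum_entropy", "entropy", "difference_entropy")
glcm_feature_names <- as.vector(t(outer(glcm_stat_names, c("mean", "std"),
                                        function(a, b) paste("glcm", a, b, sep = "_"))))
glrlm_stat_names <- c("sre", "lre", "gln", "rln", "rp",
                      "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")
glrlm_feature_names <- as.vector(t(outer(glrlm_stat_names, c("mean", "std"),
                                         function(a, b) paste("glrlm", a, b, sep = "_"))))
lbp_feature_names <- c(paste0("lbp_u", 0:8), "lbp_nonuniform")

# standard 2-D offsets at distance 1: 0, 45, 90, 135 degrees (row, col)
glcm_default_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Quantize gray levels to Ng equal-width bins over 0-255
#'
#' @param gray matrix (or vector) of gray levels in \[0, 255\].
#' @param Ng number of gray levels after quantization.
#' @return integer bins in 1..Ng with the same shape.
#' @export
quantize_gray <- function(gray, Ng = 32L) {
  q <- floor(gray / (256 / Ng)) + 1L
  q[q > Ng] <- Ng
  if (is.matrix(gray)) matrix(as.integer(q), nrow(gray), ncol(gray)) else as.integer(q)
}

# population sd (divisor n), used for mean/std aggregation across
# directions and offsets
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Symmetric normalized gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized gray pairs at one pixel offset; only pairs
#' with both pixels inside the mask contribute. The count matrix is
#' symmetrized and normalized to sum to one.
#'
#' @param qimg integer matrix of quantized levels (1..Ng).
#' @param mask logical matrix.
#' @param offset integer `c(drow, dcol)`.
#' @param Ng number of gray levels.
#' @return Ng x Ng matrix summing to 1, or `NULL` if no valid pair exists.
#' @export
glcm_matrix <- function(qimg, mask, offset, Ng = 32L) {
  nr <- nrow(qimg); nc <- ncol(qimg)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0 || length(c1) == 0) return(NULL)
  a <- qimg[r1, c1, drop = FALSE]
  b <- qimg[r1 + dr, c1 + dc, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) return(NULL)
  idx <- (a[ok] - 1L) * Ng + b[ok]
  counts <- matrix(tabulate(idx, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
  counts <- counts + t(counts)
  counts / sum(counts)
}

# the seven Haralick statistics of one normalized GLCM (log base 2,
# 0 log 0 = 0); sum variance is the spread of the p_{x+y} diagonal
# distribution about the sum average
haralick_stats <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), 0)
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  sum_avg <- sum(k_sum * p_sum)
  sum_var <- sum((k_sum - sum_avg)^2 * p_sum)
  ent_of <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  c(asm = asm, contrast = contrast, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = ent_of(p_sum),
    entropy = ent_of(as.vector(P)), difference_entropy = ent_of(p_diff))
}

#' GLCM texture features of a masked gray-level image
#'
#' One symmetric normalized co-occurrence matrix per offset (the four
#' standard 2-D directions at distance one pixel), the seven Haralick
#' statistics of each, then the mean and population SD of each statistic
#' across directions: 14 values. Directions without any valid in-mask pair
#' are dropped; if all are dropped the vector is missing.
#'
#' @param gray matrix of gray levels in \[0, 255\].
#' @param mask logical matrix.
#' @param Ng gray levels after quantization.
#' @param offsets list of `c(drow, dcol)` offsets.
#' @return named numeric vector of length 14.
#' @export
glcm_features <- function(gray, mask, Ng = 32L,
                          offsets = glcm_default_offsets) {
  qimg <- quantize_gray(gray, Ng)
  per_offset <- list()
  for (off in offsets) {
    P <- glcm_matrix(qimg, mask, off, Ng)
    if (!is.null(P)) per_offset[[length(per_offset) + 1L]] <- haralick_stats(P)
  }
  if (length(per_offset) == 0) {
    out <- rep(NA_real_, 14L); names(out) <- glcm_feature_names
    attr(out, "missing") <- TRUE
    return(out)
  }
  S <- do.call(rbind, per_offset)
  out <- as.vector(rbind(colMeans(S), apply(S, 2, pop_sd)))
  names(out) <- glcm_feature_names
  attr(out, "missing") <- FALSE
  out
}

# Flatten the masked quantized image into scan lines for one direction,
# separated by NA so a single rle() call yields all runs. Directions:
# "h" (0 deg), "v" (90 deg), "d" (down-right 45 deg), "a" (down-left 135 deg).
direction_lines <- function(qimg, mask, direction) {
  v <- qimg
  v[!mask] <- NA_integer_
  switch(direction,
    h = as.vector(t(cbind(v, NA_integer_))),
    v = as.vector(rbind(v, NA_integer_)),
    d = {
      key <- col(v) - row(v)
      unlist(lapply(split(v, key), function(x) c(x, NA_integer_)),
             use.names = FALSE)
    },
    a = {
      key <- col(v) + row(v)
      unlist(lapply(split(v, key), function(x) c(x, NA_integer_)),
             use.names = FALSE)
    },
    stop("unknown direction")
  )
}

#' Gray-level run-length matrix for one direction
#'
#' Runs of equal quantized gray level along scan lines of one direction,
#' truncated at the mask boundary.
#'
#' @param qimg integer matrix of quantized levels (1..Ng).
#' @param mask logical matrix.
#' @param direction one of `"h"`, `"v"`, `"d"` (45 deg), `"a"` (135 deg).
#' @param Ng number of gray levels.
#' @return Ng x Rmax count matrix (Rmax = longest observed run).
#' @export
glrlm_matrix <- function(qimg, mask, direction, Ng = 32L) {
  r <- rle(direction_lines(qimg, mask, direction))
  keep <- !is.na(r$values)
  lev <- r$values[keep]
  len <- r$lengths[keep]
  if (length(lev) == 0) return(matrix(0L, Ng, 1L))
  rmax <- max(len)
  m <- matrix(tabulate((lev - 1L) * rmax + len, nbins = Ng * rmax),
              Ng, rmax, byrow = TRUE)
  m
}

# the eleven canonical run-length statistics
glrlm_stats <- function(R, n_pixels) {
  nr <- sum(R)
  if (nr == 0) return(stats::setNames(rep(NA_real_, 11L), glrlm_stat_names))
  Ng <- nrow(R); Rmax <- ncol(R)
  l <- matrix(seq_len(Ng), Ng, Rmax)       # gray level index
  j <- matrix(seq_len(Rmax), Ng, Rmax, byrow = TRUE)  # run length
  c(sre = sum(R / j^2) / nr,
    lre = sum(R * j^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    rp = nr / n_pixels,
    lgre = sum(R / l^2) / nr,
    hgre = sum(R * l^2) / nr,
    srlge = sum(R / (l^2 * j^2)) / nr,
    srhge = sum(R * l^2 / j^2) / nr,
    lrlge = sum(R * j^2 / l^2) / nr,
    lrhge = sum(R * j^2 * l^2) / nr)
}

#' GLRLM texture features of a masked gray-level image
#'
#' Run-length matrices in the four 2-D directions, the eleven canonical run
#' statistics (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE,
#' LRHGE) per direction, then mean and population SD across directions:
#' 22 values.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 22.
#' @export
glrlm_features <- function(gray, mask, Ng = 32L) {
  if (!any(mask)) {
    out <- rep(NA_real_, 22L); names(out) <- glrlm_feature_names
    attr(out, "missing") <- TRUE
    return(out)
  }
  qimg <- quantize_gray(gray, Ng)
  n_pixels <- sum(mask)
  S <- t(vapply(c("h", "v", "d", "a"), function(d) {
    glrlm_stats(glrlm_matrix(qimg, mask, d, Ng), n_pixels)
  }, numeric(11L)))
  out <- as.vector(rbind(colMeans(S), apply(S, 2, pop_sd)))
  names(out) <- glrlm_feature_names
  attr(out, "missing") <- FALSE
  out
}

# 8-neighborhood offsets in circular order (angle 0, 45, ..., 315)
lbp_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                    c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

#' Rotation-invariant uniform LBP histogram (P = 8, R = 1)
#'
#' Local binary patterns over the 8-neighborhood: each neighbor is
#' thresholded against the center (strictly greater; ties give a 0 bit, so
#' a flat region produces the all-zero pattern); patterns with at most two
#' circular 0/1 transitions are "uniform" and binned by their number of set
#' bits (0-8), all others share one non-uniform bin, giving exactly 10
#' descriptors.
#' Only pixels whose full 3x3 neighborhood lies inside the mask contribute;
#' the histogram is normalized to sum to one.
#'
#' @param gray matrix of gray levels.
#' @param mask logical matrix.
#' @return named numeric vector of length 10.
#' @export
lbp_features <- function(gray, mask) {
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr < 3 || nc < 3) {
    out <- rep(NA_real_, 10L); names(out) <- lbp_feature_names
    attr(out, "missing") <- TRUE
    return(out)
  }
  ctr_r <- 2:(nr - 1); ctr_c <- 2:(nc - 1)
  center <- gray[ctr_r, ctr_c, drop = FALSE]
  eligible <- mask[ctr_r, ctr_c, drop = FALSE]
  bits <- vector("list", 8L)
  for (k in seq_along(lbp_offsets)) {
    off <- lbp_offsets[[k]]
    nb <- gray[ctr_r + off[1], ctr_c + off[2], drop = FALSE]
    eligible <- eligible & mask[ctr_r + off[1], ctr_c + off[2], drop = FALSE]
    bits[[k]] <- nb > center
  }
  if (!any(eligible)) {
    out <- rep(NA_real_, 10L); names(out) <- lbp_feature_names
    attr(out, "missing") <- TRUE
    return(out)
  }
  B <- vapply(bits, function(b) as.integer(b[eligible]), integer(sum(eligible)))
  B <- matrix(B, ncol = 8L)
  transitions <- rowSums(B != B[, c(2:8, 1), drop = FALSE])
  ones <- rowSums(B)
  bin <- ifelse(transitions <= 2L, ones + 1L, 10L)
  h <- tabulate(bin, nbins = 10L) / length(bin)
  names(h) <- lbp_feature_names
  attr(h, "missing") <- FALSE
  h
}
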
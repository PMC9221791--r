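test_that("intensity features handle degenerate and closed-form regions", {
  f <- intensity_features(rep(100, 50))
  expect_equal(unname(f["hist_mean"]), 100)
  expect_equal(unname(f["hist_std"]), 0)
  expect_equal(unname(f["hist_skewness"]), 0)
  expect_equal(unname(f["hist_kurtosis"]), 0)
  expect_equal(unname(f["hist_entropy"]), 0)
  expect_true(all(f[c("hist_p05", "hist_p25", "hist_p50", "hist_p75",
                      "hist_p95")] == 100))

  two <- intensity_features(rep(c(0, 255), 20))
  expect_equal(unname(two["hist_entropy"]), 1)   # two equal bins = 1 bit

  unif <- intensity_features(0:255)
  expect_equal(unname(unif["hist_entropy"]), 8)  # 256 equal bins = 8 bits
  expect_equal(unname(unif["hist_p25"]), 63.75)  # linear interpolation

  miss <- intensity_features(numeric(0))
  expect_true(attr(miss, "missing"))
  expect_true(all(is.na(miss)))
})

test_that("GLCM features: constant image, hand-enumerated checkerboard, complement symmetry", {
  const <- glcm_features(matrix(7, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(unname(const["glcm_asm_mean"]), 1)
  expect_equal(unname(const["glcm_contrast_mean"]), 0)
  expect_equal(unname(const["glcm_entropy_mean"]), 0)
  expect_equal(unname(const["glcm_asm_std"]), 0)

  # 2x2 checkerboard of extreme levels, single horizontal offset, Ng = 2:
  # the two horizontal pairs are (0,1) and (1,0); after symmetrization the
  # mass splits evenly on the off-diagonal -> ASM 0.5, contrast 1
  cb <- matrix(c(0, 255, 255, 0), 2, 2)
  P <- glcm_matrix(quantize_gray(cb, 2L), matrix(TRUE, 2, 2), c(0L, 1L), 2L)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  h <- perirad:::haralick_stats(P)
  expect_equal(unname(h["asm"]), 0.5)
  expect_equal(unname(h["contrast"]), 1)

  # gray-level complement leaves mean contrast unchanged
  set.seed(5)
  for (i in 1:10) {
    im <- random_masked_image(8, 8)
    a <- glcm_features(im$gray, im$mask)
    b <- glcm_features(255 - im$gray, im$mask)
    expect_equal(unname(a["glcm_contrast_mean"]),
                 unname(b["glcm_contrast_mean"]))
  }
})

test_that("GLRLM features: single-run closed forms and checkerboard runs", {
  # one row of L identical pixels: a single horizontal run of length L
  L <- 7L
  gray <- matrix(100, 1, L)
  mask <- matrix(TRUE, 1, L)
  R <- glrlm_matrix(quantize_gray(gray, 32L), mask, "h", 32L)
  s <- perirad:::glrlm_stats(R, sum(mask))
  expect_equal(unname(s["lre"]), L^2)
  expect_equal(unname(s["sre"]), 1 / L^2)
  expect_equal(unname(s["rp"]), 1 / L)

  # checkerboard: every axial run has length 1
  cb <- matrix(rep(c(0, 255), 18), 6, 6)
  cb[, c(2, 4, 6)] <- 255 - cb[, c(2, 4, 6)]
  for (d in c("h", "v")) {
    R <- glrlm_matrix(quantize_gray(cb, 2L), matrix(TRUE, 6, 6), d, 2L)
    s <- perirad:::glrlm_stats(R, 36)
    expect_equal(unname(s["sre"]), 1)
    expect_equal(unname(s["lre"]), 1)
    expect_equal(unname(s["rp"]), 1)
  }
})

test_that("GLRLM conserves pixel counts in every direction", {
  set.seed(9)
  for (i in 1:10) {
    im <- random_masked_image(9, 7)
    q <- quantize_gray(im$gray, 8L)
    for (d in c("h", "v", "d", "a")) {
      R <- glrlm_matrix(q, im$mask, d, 8L)
      run_len <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
      expect_equal(sum(R * run_len), sum(im$mask))
    }
  }
})

test_that("LBP histogram is normalized, flat regions are all-zero uniform, rotation invariant", {
  const <- lbp_features(matrix(50, 8, 8), matrix(TRUE, 8, 8))
  expect_equal(unname(const["lbp_u0"]), 1)
  expect_equal(sum(const), 1)

  set.seed(13)
  for (i in 1:8) {
    im <- random_masked_image(10, 10, p_mask = 0.9)
    h <- lbp_features(im$gray, im$mask)
    expect_equal(sum(h), 1)
    rot_g <- t(im$gray)[nrow(im$gray):1, , drop = FALSE]
    rot_m <- t(im$mask)[nrow(im$mask):1, , drop = FALSE]
    expect_equal(h, lbp_features(rot_g, rot_m))
  }
})

test_that("shape features match analytic disk and ellipse geometry", {
  n <- 61L
  disk <- disk_mask(n, 20)
  f <- shape_features(disk, spacing = 1)
  expect_lt(abs(f["shape_area"] - pi * 400) / (pi * 400), 0.02)
  expect_lt(unname(f["shape_eccentricity"]), 0.1)
  expect_equal(unname(f["shape_euler"]), 1)
  expect_gte(unname(f["shape_convex_area"]), unname(f["shape_area"]) * 0.98)

  holed <- disk & !disk_mask(n, 6)
  expect_equal(unname(shape_features(holed, 1)["shape_euler"]), 0)

  # 2:1 ellipse
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  ell <- ((ii - 31) / 24)^2 + ((jj - 31) / 12)^2 <= 1
  fe <- shape_features(ell, spacing = 1)
  expect_lt(abs(fe["shape_axis_ratio"] - 2) / 2, 0.05)
  expect_lt(abs(fe["shape_major_axis"] - 48) / 48, 0.05)

  # physical units scale with spacing
  f2 <- shape_features(disk, spacing = 2)
  expect_equal(unname(f2["shape_area"]), unname(f["shape_area"]) * 4)
  expect_equal(unname(f2["shape_perimeter"]), unname(f["shape_perimeter"]) * 2)
})

test_that("panel cardinalities and combined concatenation are schema-exact", {
  sch <- feature_schema()
  expect_length(sch$intra, 69)
  expect_length(sch$peri, 58)
  expect_length(sch$combined, 127)
  expect_false(any(duplicated(sch$combined)))

  ph <- generate_phantom(phantom_spec(seed = 21))
  win <- window_rescale(ph$ct)
  rs <- build_region_set(ph$tumor_mask, ph$ct, ph$airway_mask,
                         distances_mm = c(3, 30))
  panel <- extract_panel(win, rs)
  expect_length(panel$intra, 69)
  expect_length(panel$peri_3, 58)
  expect_length(panel$comb_3, 127)
  expect_equal(names(panel$intra), sch$intra)
  expect_equal(names(panel$comb_3), sch$combined)
  expect_equal(unname(panel$comb_3),
               unname(c(panel$intra, panel$peri_3)), ignore_attr = TRUE)
})

test_that("features are local: pixels outside every mask do not matter", {
  ph <- generate_phantom(phantom_spec(seed = 22))
  rs <- build_region_set(ph$tumor_mask, ph$ct, ph$airway_mask,
                         distances_mm = 30)
  win1 <- window_rescale(ph$ct)
  outside <- !(rs$combined[["30"]])
  ct2 <- ph$ct
  set.seed(1)
  ct2$pixels[outside] <- sample(c(-900L, 200L), sum(outside), TRUE)
  win2 <- window_rescale(ct2)
  p1 <- extract_panel(win1, rs)
  p2 <- extract_panel(win2, rs)
  expect_equal(p1$intra, p2$intra)
  expect_equal(p1$peri_30, p2$peri_30)
})

test_that("texture features are translation invariant", {
  set.seed(17)
  n <- 32L
  gray <- matrix(sample(0:255, n * n, TRUE), n, n)
  mask <- disk_mask(n, 8, center = c(12, 12))
  shift <- function(m, dr, dc) {
    out <- matrix(if (is.logical(m)) FALSE else 0L, n, n)
    out[(1 + dr):n, (1 + dc):n] <- m[1:(n - dr), 1:(n - dc)]
    out
  }
  g2 <- shift(gray, 5, 7); m2 <- shift(mask, 5, 7)
  expect_equal(glcm_features(gray, mask), glcm_features(g2, m2))
  expect_equal(glrlm_features(gray, mask), glrlm_features(g2, m2))
  expect_equal(lbp_features(gray, mask), lbp_features(g2, m2))
})

test_that("longer texture correlation length lowers mean GLCM contrast", {
  contrasts <- sapply(c(1, 6), function(cl) {
    mean(sapply(1:5, function(s) {
      ph <- generate_phantom(phantom_spec(texture_corr_px = cl,
                                          tumor_heterogeneity = 40,
                                          shape_irregularity = 0, seed = s))
      win <- window_rescale(ph$ct)
      glcm_features(win$pixels, ph$tumor_mask)["glcm_contrast_mean"]
    }))
  })
  expect_gt(contrasts[1], contrasts[2])
})

test_that("empty peritumoral regions produce flagged missing vectors", {
  n <- 31L
  tumor <- matrix(TRUE, n, n); tumor[1, ] <- FALSE
  ct <- flat_ct(matrix(30L, n, n), 1)
  rs <- build_region_set(tumor, ct, distances_mm = 3)
  panel <- extract_panel(window_rescale(ct), rs)
  expect_true(attr(panel$peri_3, "missing"))
  expect_length(panel$peri_3, 58)
  expect_true(all(is.na(panel$peri_3)))
  expect_equal(sum(is.na(panel$comb_3)), 58)
})
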
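test_that("phantom generation is bit-reproducible given the seed", {
  spec <- phantom_spec(seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$ct$pixels, b$ct$pixels)
  expect_identical(a$tumor_mask, b$tumor_mask)
  expect_identical(a$airway_mask, b$airway_mask)
})

test_that("degenerate spec yields a rasterized disk with constant interior", {
  spec <- phantom_spec(shape_irregularity = 0, tumor_heterogeneity = 0,
                       seed = 5)
  ph <- generate_phantom(spec)
  n <- spec$image_size
  center <- c(n / 2 + 0.5, n / 2 + 0.5) + c(0.06 * n, -0.04 * n)
  r0 <- (spec$tumor_diameter / 2) / spec$pixel_spacing
  expect_identical(unname(ph$tumor_mask), unname(disk_mask(n, r0, center)))
  expect_equal(length(unique(ph$ct$pixels[ph$tumor_mask])), 1L)
  eq_d <- 2 * sqrt(sum(ph$tumor_mask) / pi) * spec$pixel_spacing
  expect_lt(abs(eq_d - spec$tumor_diameter) / spec$tumor_diameter, 0.05)
})

test_that("tumor equivalent diameter tracks the spec for irregular shapes", {
  for (s in 1:5) {
    spec <- phantom_spec(tumor_diameter = 25, shape_irregularity = 0.2,
                         seed = s)
    ph <- generate_phantom(spec)
    eq_d <- 2 * sqrt(sum(ph$tumor_mask) / pi) * spec$pixel_spacing
    expect_lt(abs(eq_d - 25) / 25, 0.05)
  }
})

test_that("zero vessel density leaves the peritumoral shell clean", {
  spec <- phantom_spec(vessel_density = 0, seed = 11)
  ph <- generate_phantom(spec)
  n <- spec$image_size
  shell_r <- round(30 / spec$pixel_spacing)
  dist_out <- EBImage::distmap(matrix(as.numeric(!ph$tumor_mask), n, n))
  shell <- dist_out > 0 & dist_out <= shell_r
  wall <- ph$ct$pixels > -224 & !ph$tumor_mask & !ph$airway_mask
  check <- shell & !ph$tumor_mask & !wall & !ph$airway_mask
  expect_true(all(ph$ct$pixels[check] <= spec$lung_hu + 3 * spec$noise_sd))
})

test_that("HU histogram is bimodal across the -224 HU boundary and masks are coherent", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  n_lung_like <- sum(ph$ct$pixels < -700)
  n_wall_like <- sum(ph$ct$pixels > -100)
  expect_gt(n_lung_like, 0.2 * length(ph$ct$pixels))
  expect_gt(n_wall_like, 0.1 * length(ph$ct$pixels))
  expect_false(any(ph$tumor_mask & ph$airway_mask))
  # both masks sit strictly inside the lung field (flood the wall from a corner)
  expect_true(all(ph$ct$pixels[ph$airway_mask] < -224))
})

test_that("oversized tumors are rejected", {
  expect_error(generate_phantom(phantom_spec(tumor_diameter = 100,
                                             image_size = 128L)),
               "too large")
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(lung_hu = -100), "-224")
  expect_error(phantom_spec(tumor_diameter = -5))
  expect_error(phantom_spec(vessel_density = -1))
})

test_that("cohort labels follow the outcome model and times respect the 24-month cut", {
  co <- generate_cohort(40, outcome = outcome_model(censoring_rate = 0.3),
                        seed = 2, keep_images = FALSE)
  r <- co$records
  expect_true(all(r$time_months > 0))
  expect_true(all(r$time_months[r$recurrence == 1] <= 24))
  expect_true(all(r$event[r$recurrence == 1] == 1))
  expect_true(all(r$event[r$recurrence == 0] == 0))
  expect_true(all(r$t_stage %in% c("T1", "T2", "T3")))
  expect_true(all(r$n_stage %in% c("N0", "N1", "N2")))
})

test_that("degenerate outcome probabilities give single-class cohorts with a warning", {
  never <- outcome_model(intercept = -50, beta_diameter = 0,
                         beta_heterogeneity = 0, beta_vessel = 0)
  expect_warning(co <- generate_cohort(15, outcome = never, seed = 1,
                                       keep_images = FALSE), "single")
  expect_true(all(co$records$recurrence == 0))
  km <- kaplan_meier(co$records$time_months, co$records$event)
  expect_equal(as.numeric(two_year_rfs(km)), 1.0)

  always <- outcome_model(intercept = 50, beta_diameter = 0,
                          beta_heterogeneity = 0, beta_vessel = 0,
                          censoring_rate = 0)
  expect_warning(co2 <- generate_cohort(15, outcome = always, seed = 1,
                                        keep_images = FALSE), "single")
  expect_true(all(co2$records$recurrence == 1))
})

test_that("label prevalence converges to the mean recurrence probability", {
  om <- outcome_model()
  co <- generate_cohort(2000, outcome = om, seed = 7, keep_images = FALSE)
  r <- co$records
  p <- om$recurrence_probability(r$tumor_longest_diameter, r$heterogeneity,
                                 r$vessel_density)
  # binomial tolerance: 4 sd of the mean of independent Bernoullis
  tol <- 4 * sqrt(sum(p * (1 - p))) / nrow(r)
  expect_lt(abs(mean(r$recurrence) - mean(p)), tol)
})
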
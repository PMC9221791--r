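#' Specification of a synthetic CT phantom slice
#'
#' Describes a single 2-D chest-CT-like phantom: an elliptical lung field of
#' low-attenuation parenchyma surrounded by chest wall, containing one tumor
#' with controllable size, intensity heterogeneity and boundary irregularity,
#' a bronchial (airway) structure, and thin curvilinear vessels scattered in
#' the 30 mm peritumoral shell.
#'
#' @param image_size side length of the square image in pixels.
#' @param pixel_spacing in-plane spacing in mm/pixel (isotropic).
#' @param lung_hu mean parenchyma attenuation in HU (must be below -224).
#' @param wall_hu mean chest-wall/mediastinum attenuation in HU (above -224).
#' @param tumor_diameter target equivalent diameter of the tumor in mm.
#' @param tumor_mean_hu mean intratumoral attenuation in HU.
#' @param tumor_heterogeneity standard deviation (HU) of the spatially
#'   correlated intratumoral texture field; 0 gives a perfectly flat tumor.
#' @param texture_corr_px correlation length of the tumor texture in pixels.
#' @param vessel_density expected vessel count per cm^2 of the 30 mm
#'   peritumoral shell.
#' @param vessel_hu attenuation of vessel cores in HU.
#' @param shape_irregularity dimensionless boundary perturbation amplitude;
#'   0 yields a rasterized disk.
#' @param noise_sd parenchyma/wall noise SD in HU. Noise is winsorized at
#'   three SDs so the background stays within a known band.
#' @param seed integer seed; phantom generation is bit-reproducible given it.
#'
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L,
                         pixel_spacing = 0.7,
                         lung_hu = -850,
                         wall_hu = 40,
                         tumor_diameter = 20,
                         tumor_mean_hu = 30,
                         tumor_heterogeneity = 25,
                         texture_corr_px = 3,
                         vessel_density = 2,
                         vessel_hu = -100,
                         shape_irregularity = 0.15,
                         noise_sd = 20,
                         seed = 1L) {
  spec <- list(
    image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
    lung_hu = lung_hu, wall_hu = wall_hu,
    tumor_diameter = tumor_diameter, tumor_mean_hu = tumor_mean_hu,
    tumor_heterogeneity = tumor_heterogeneity,
    texture_corr_px = texture_corr_px,
    vessel_density = vessel_density, vessel_hu = vessel_hu,
    shape_irregularity = shape_irregularity,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(
    spec$tumor_diameter > 0,
    spec$pixel_spacing > 0,
    spec$image_size >= 32L,
    spec$vessel_density >= 0,
    spec$tumor_heterogeneity >= 0,
    spec$shape_irregularity >= 0,
    spec$noise_sd >= 0
  )
  if (!(spec$lung_hu < -224 && spec$wall_hu > -224)) {
    stop("lung_hu must be below -224 HU and wall_hu above -224 HU")
  }
  invisible(spec)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Construct a calibrated CT slice object
#'
#' @param pixels integer-valued matrix of HU values in \[-1024, 3071\].
#' @param spacing in-plane pixel spacing in mm/pixel.
#' @param patient_id identifier string.
#' @return object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, spacing, patient_id = "anon") {
  stopifnot(is.matrix(pixels), spacing > 0)
  pixels <- clamp_hu(pixels)
  structure(list(pixels = pixels, spacing = spacing, patient_id = patient_id),
            class = "ct_slice")
}

clamp_hu <- function(px) {
  px <- round(px)
  px[px < -1024] <- -1024
  px[px > 3071] <- 3071
  storage.mode(px) <- "integer"
  px
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %dx%d px, %.2f mm/px, HU range [%d, %d], patient %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing,
              min(x$pixels), max(x$pixels), x$patient_id))
  invisible(x)
}

# Gaussian-correlated random field with given marginal sd, via white noise
# smoothed by an isotropic Gaussian kernel and rescaled.
correlated_field <- function(n, corr_px, sd) {
  if (sd <= 0) return(matrix(0, n, n))
  z <- matrix(stats::rnorm(n * n), n, n)
  if (corr_px > 0.5) {
    z <- EBImage::gblur(z, sigma = corr_px)
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z * sd
}

# Winsorized white noise: values clipped at +-3 sd.
clipped_noise <- function(n, sd) {
  if (sd <= 0) return(matrix(0, n, n))
  z <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  pmax(pmin(z, 3 * sd), -3 * sd)
}

# Rasterize a star-convex tumor: radius r(theta) = r0 * (1 + irregular
# low-order harmonic perturbation), renormalized to preserve the disk area.
rasterize_tumor <- function(n, center, r0_px, irregularity) {
  if (irregularity <= 0) {
    co <- expand_grid_dist(n, center)
    return(matrix(co <= r0_px, n, n))
  }
  k <- 2:5
  amp <- stats::rnorm(length(k), sd = irregularity / 2)
  phs <- stats::runif(length(k), 0, 2 * pi)
  radial <- function(theta) {
    pert <- rep(1, length(theta))
    for (i in seq_along(k)) pert <- pert + amp[i] * cos(k[i] * theta + phs[i])
    pmax(pert, 0.2)
  }
  # renormalize so the enclosed area matches pi * r0^2
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  scale <- sqrt(mean(radial(th)^2))
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- ii - center[1]; dx <- jj - center[2]
  dist <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  dist <= (r0_px / scale) * radial(theta)
}

expand_grid_dist <- function(n, center) {
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((ii - center[1])^2 + (jj - center[2])^2)
}

# Random-walk vessel polylines (width 1-2 px) seeded in the peritumoral shell.
draw_vessels <- function(allowed, shell, density_per_cm2, spacing) {
  n <- nrow(allowed)
  core <- matrix(FALSE, n, n)
  shell_px <- which(shell & allowed)
  if (length(shell_px) == 0 || density_per_cm2 <= 0) return(core)
  area_cm2 <- length(shell_px) * spacing^2 / 100
  n_vessels <- stats::rpois(1, density_per_cm2 * area_cm2)
  if (n_vessels == 0) return(core)
  starts <- sample(shell_px, min(n_vessels, length(shell_px)),
                   replace = n_vessels > length(shell_px))
  for (s in starts) {
    r <- (s - 1) %% n + 1
    c <- (s - 1) %/% n + 1
    theta <- stats::runif(1, 0, 2 * pi)
    len <- sample(10:40, 1)
    wide <- stats::runif(1) < 0.5
    for (step in seq_len(len)) {
      ri <- round(r); ci <- round(c)
      if (ri < 1 || ri > n || ci < 1 || ci > n) break
      if (allowed[ri, ci]) {
        core[ri, ci] <- TRUE
        if (wide) {
          r2 <- ri + round(cos(theta + pi / 2)); c2 <- ci + round(sin(theta + pi / 2))
          if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= n && allowed[r2, c2]) {
            core[r2, c2] <- TRUE
          }
        }
      }
      theta <- theta + stats::rnorm(1, sd = 0.25)
      r <- r + sin(theta); c <- c + cos(theta)
    }
  }
  core
}

#' Generate a synthetic CT phantom slice
#'
#' Renders a chest-CT-like 2-D slice from a [phantom_spec()]: an elliptical
#' lung field at `lung_hu` inside a chest wall at `wall_hu`, one tumor whose
#' equivalent diameter tracks `tumor_diameter` within a few percent, a
#' two-branch bronchial structure, and random-walk vessel polylines in the
#' 30 mm shell around the tumor. Vessel cores are rendered at `vessel_hu`
#' with a one-pixel partial-volume halo at the lung/vessel midpoint, so the
#' -224 HU chest-wall exclusion removes cores but leaves halos, as on real
#' lung windows.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier attached to the returned slice.
#' @return a list with elements `ct` (a `ct_slice`), `tumor_mask` and
#'   `airway_mask` (logical matrices), and `spec`.
#' @export
generate_phantom <- function(spec, patient_id = "phantom") {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    n <- spec$image_size
    sp <- spec$pixel_spacing
    center <- c(n / 2 + 0.5, n / 2 + 0.5)
    a <- 0.45 * n; b <- 0.42 * n     # lung ellipse semi-axes (rows, cols)

    ii <- matrix(seq_len(n), n, n)
    jj <- matrix(seq_len(n), n, n, byrow = TRUE)
    lung <- ((ii - center[1]) / a)^2 + ((jj - center[2]) / b)^2 <= 1

    r0_px <- (spec$tumor_diameter / 2) / sp
    if (r0_px * (1 + spec$shape_irregularity) + 3 > min(a, b)) {
      stop("tumor too large to fit inside the lung field at this image size")
    }
    tcenter <- center + c(0.06 * n, -0.04 * n)
    tumor <- rasterize_tumor(n, tcenter, r0_px, spec$shape_irregularity) & lung

    # bronchial structure: two air-filled tubes entering from the top of the
    # lung field, excluded from the tumor
    airway <- matrix(FALSE, n, n)
    for (off in c(-0.10, 0.10)) {
      ac <- c(center[1] - 0.28 * n, center[2] + off * n)
      rad <- max(2, 0.02 * n)
      airway <- airway | (sqrt((ii - ac[1])^2 + (jj - ac[2])^2) <= rad)
    }
    airway <- airway & lung & !tumor

    # vessels live in the 30 mm shell outside the tumor
    shell_r_px <- round(30 / sp)
    dist_out <- EBImage::distmap(matrix(as.numeric(!tumor), n, n))
    shell <- dist_out > 0 & dist_out <= shell_r_px & lung & !airway
    allowed <- lung & !tumor & !airway
    vessel_core <- draw_vessels(allowed, shell, spec$vessel_density, sp)
    vessel_halo <- EBImage::dilate(vessel_core,
                                   EBImage::makeBrush(3, "box")) > 0
    vessel_halo <- vessel_halo & allowed & !vessel_core

    img <- matrix(spec$wall_hu, n, n)
    img[lung] <- spec$lung_hu
    noise <- clipped_noise(n, spec$noise_sd)
    img[lung] <- img[lung] + noise[lung]
    img[!lung] <- img[!lung] + noise[!lung] / 2
    img[vessel_halo] <- (spec$vessel_hu + spec$lung_hu) / 2
    img[vessel_core] <- spec$vessel_hu
    img[airway] <- -1000

    texture <- correlated_field(n, spec$texture_corr_px,
                                spec$tumor_heterogeneity)
    img[tumor] <- spec$tumor_mean_hu + texture[tumor]

    list(ct = ct_slice(img, sp, patient_id),
         tumor_mask = tumor, airway_mask = airway, spec = spec)
  })
}

#' Logistic outcome model for synthetic cohorts
#'
#' Ground-truth recurrence mechanism for phantom cohorts: the probability of
#' recurrence within 24 months follows a logistic link on tumor diameter
#' (cm), intratumoral heterogeneity (HU) and peritumoral vessel density
#' (vessels/cm^2).
#'
#' @param intercept,beta_diameter,beta_heterogeneity,beta_vessel logistic
#'   coefficients. Defaults give roughly balanced classes for the default
#'   cohort attribute distributions, with vessel density the strongest axis.
#' @param time_horizon follow-up horizon in months.
#' @param censoring_rate fraction of non-recurrent patients censored before
#'   24 months.
#' @return object of class `outcome_model` with a `recurrence_probability`
#'   function field.
#' @export
outcome_model <- function(intercept = -1.4,
                          beta_diameter = 0.25,
                          beta_heterogeneity = 0.01,
                          beta_vessel = 0.35,
                          time_horizon = 60,
                          censoring_rate = 0.2) {
  stopifnot(time_horizon > 24, censoring_rate >= 0, censoring_rate <= 1)
  coef <- c(intercept = intercept, diameter = beta_diameter,
            heterogeneity = beta_heterogeneity, vessel = beta_vessel)
  m <- list(
    coef = coef,
    recurrence_probability = function(diameter_cm, heterogeneity, vessel_density) {
      stats::plogis(coef["intercept"] + coef["diameter"] * diameter_cm +
                      coef["heterogeneity"] * heterogeneity +
                      coef["vessel"] * vessel_density)
    },
    time_horizon = time_horizon,
    censoring_rate = censoring_rate
  )
  class(m) <- "outcome_model"
  m
}

# T stage from diameter (size criteria only) and N stage from a latent nodal
# variable tied to the linear predictor, thresholded to give a mix of
# N0/N1/N2 comparable to an operable NSCLC registry.
assign_stages <- function(diameter_cm, linpred, nodal_noise) {
  t_stage <- ifelse(diameter_cm < 3, "T1", ifelse(diameter_cm <= 7, "T2", "T3"))
  latent <- linpred + nodal_noise
  qs <- stats::quantile(latent, c(0.56, 0.82))
  n_stage <- ifelse(latent <= qs[1], "N0", ifelse(latent <= qs[2], "N1", "N2"))
  list(t_stage = t_stage, n_stage = n_stage)
}

#' Generate a synthetic phantom cohort with outcomes
#'
#' Draws per-patient tumor attributes from a two-component mixture of
#' phantom templates (an indolent-appearance and an aggressive-appearance
#' class), renders one phantom slice per patient, and draws recurrence
#' labels from the logistic [outcome_model()] applied to the drawn
#' attributes. Event times for recurrences are uniform on (2, 24) months;
#' non-recurrent patients are censored, a `censoring_rate` fraction of them
#' before 24 months and the rest between 24 months and the horizon.
#'
#' @param n_patients cohort size (>= 10).
#' @param class_specs list of two `phantom_spec` templates named
#'   `non_recurrence` and `recurrence`; per-patient attributes jitter around
#'   a 50/50 mixture of the two.
#' @param outcome an [outcome_model()].
#' @param seed integer seed for the whole cohort.
#' @param diameter_meanlog,diameter_sdlog,diameter_range lognormal diameter
#'   draw (mm), clamped to `diameter_range`.
#' @param keep_images if `FALSE`, only the clinical table is returned
#'   (useful for outcome-model checks at large n).
#' @return list with `images` (per-patient list of `generate_phantom()`
#'   outputs, or `NULL`) and `records` (data.frame of patient id, recurrence
#'   label, time in months, T/N stage and tumor longest diameter in cm).
#' @export
generate_cohort <- function(n_patients,
                            class_specs = default_class_specs(),
                            outcome = outcome_model(),
                            seed = 1L,
                            diameter_meanlog = log(30),
                            diameter_sdlog = 0.45,
                            diameter_range = c(10, 85),
                            keep_images = TRUE) {
  stopifnot(n_patients >= 10)
  s_nr <- class_specs$non_recurrence
  s_r <- class_specs$recurrence
  stopifnot(inherits(s_nr, "phantom_spec"), inherits(s_r, "phantom_spec"))
  with_seed(seed, {
    mix <- stats::runif(n_patients) < 0.5
    diam_mm <- pmin(pmax(stats::rlnorm(n_patients, diameter_meanlog,
                                       diameter_sdlog),
                         diameter_range[1]), diameter_range[2])
    het <- ifelse(mix, s_r$tumor_heterogeneity, s_nr$tumor_heterogeneity) *
      stats::runif(n_patients, 0.7, 1.3)
    vess <- ifelse(mix, s_r$vessel_density, s_nr$vessel_density) *
      stats::runif(n_patients, 0.6, 1.4)
    irr <- ifelse(mix, s_r$shape_irregularity, s_nr$shape_irregularity)

    p <- outcome$recurrence_probability(diam_mm / 10, het, vess)
    labels <- as.integer(stats::runif(n_patients) < p)
    if (length(unique(labels)) < 2) {
      warning("degenerate cohort draw: a single outcome class was generated")
    }

    time <- numeric(n_patients)
    event <- integer(n_patients)
    for (i in seq_len(n_patients)) {
      if (labels[i] == 1) {
        time[i] <- stats::runif(1, 2, 24)
        event[i] <- 1L
      } else if (stats::runif(1) < outcome$censoring_rate) {
        time[i] <- stats::runif(1, 6, 24)
        event[i] <- 0L
      } else {
        time[i] <- stats::runif(1, 24, outcome$time_horizon)
        event[i] <- 0L
      }
    }

    linpred <- stats::qlogis(p)
    stages <- assign_stages(diam_mm / 10, linpred,
                            stats::rnorm(n_patients, sd = 1))
    ids <- sprintf("P%04d", seq_len(n_patients))
    seeds <- sample.int(.Machine$integer.max - 1L, n_patients)

    records <- data.frame(
      patient_id = ids,
      recurrence = labels,
      time_months = time,
      event = event,
      t_stage = stages$t_stage,
      n_stage = stages$n_stage,
      tumor_longest_diameter = diam_mm / 10,
      heterogeneity = het,
      vessel_density = vess,
      stringsAsFactors = FALSE
    )

    images <- NULL
    if (keep_images) {
      base <- s_nr
      images <- vector("list", n_patients)
      for (i in seq_len(n_patients)) {
        sp_i <- base
        sp_i$tumor_diameter <- diam_mm[i]
        sp_i$tumor_heterogeneity <- het[i]
        sp_i$vessel_density <- vess[i]
        sp_i$shape_irregularity <- irr[i]
        sp_i$seed <- seeds[i]
        images[[i]] <- generate_phantom(sp_i, patient_id = ids[i])
      }
      names(images) <- ids
    }
    list(images = images, records = records)
  })
}

#' Default per-class phantom templates
#'
#' The two appearance classes differ in peritumoral vessel density and
#' intratumoral heterogeneity; everything else is shared, reflecting how
#' similar recurrent and non-recurrent tumors look on CT.
#'
#' @param image_size,pixel_spacing shared geometry of all phantoms.
#' @return list with `non_recurrence` and `recurrence` templates.
#' @export
default_class_specs <- function(image_size = 192L, pixel_spacing = 0.7) {
  list(
    non_recurrence = phantom_spec(
      image_size = image_size, pixel_spacing = pixel_spacing,
      tumor_heterogeneity = 15, vessel_density = 1.0,
      shape_irregularity = 0.10
    ),
    recurrence = phantom_spec(
      image_size = image_size, pixel_spacing = pixel_spacing,
      tumor_heterogeneity = 35, vessel_density = 4.0,
      shape_irregularity = 0.20
    )
  )
}

#' Study conditions with signal planted only in peritumoral vessels
#'
#' Phantom templates and outcome model for the signal-recovery study: the
#' two appearance classes share tumor size, heterogeneity and shape
#' distributions and differ only in peritumoral vessel density (0.5 vs 6
#' vessels/cm^2), and the outcome depends on vessel density alone. Any
#' predictive information must therefore come from the peritumoral band.
#'
#' @param image_size phantom side in pixels.
#' @return list with `class_specs`, `outcome`, and the cohort diameter
#'   draw parameters (`diameter_meanlog`, `diameter_sdlog`,
#'   `diameter_range`).
#' @export
vessel_signal_conditions <- function(image_size = 128L) {
  specs <- default_class_specs(image_size = image_size)
  for (cl in names(specs)) {
    specs[[cl]]$tumor_heterogeneity <- 25
    specs[[cl]]$shape_irregularity <- 0.15
  }
  specs$non_recurrence$vessel_density <- 0.5
  specs$recurrence$vessel_density <- 6
  list(class_specs = specs,
       outcome = outcome_model(intercept = -2.3, beta_diameter = 0,
                               beta_heterogeneity = 0, beta_vessel = 0.8),
       diameter_meanlog = log(20), diameter_sdlog = 0.3,
       diameter_range = c(10, 40))
}
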
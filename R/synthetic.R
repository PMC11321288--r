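# Synthetic layered-retina B-scan phantom with planted, labeled biomarkers
# and longitudinal outcomes. The phantom is the ground-truth oracle for the
# whole pipeline: every planted lesion records its class, a pixel mask, and
# class-driven visual acuity and conversion times.

.px_axial <- 7.0    # micrometres per pixel, axial (rows)
.px_ml <- 23.4      # micrometres per pixel, mediolateral (columns)

#' Micrometre / pixel conversions (mediolateral axis)
#'
#' Lateral sizes convert at 23.4 um per column, matching the standardized
#' B-scan pixel pitch.
#' @param um,px physical size / pixel count.
#' @return pixels (rounded) / micrometres.
#' @export
um_to_px <- function(um) as.integer(round(um / .px_ml))

#' @rdname um_to_px
#' @export
px_to_um <- function(px) px * .px_ml

#' Biomarker vocabulary of the synthetic generator
#'
#' The planted lesion classes. They cover the grading-relevant anatomy
#' (drusen by size, pigment epithelial detachment, sub/intraretinal fluid,
#' incomplete and complete atrophy with hypertransmission, double-layer
#' sign, scarring, choroidal thickening) plus a poor-quality class.
#' @return character vector of class names.
#' @export
oct_classes <- function() {
  c("healthy", "drusen_small", "drusen_large", "confluent_drusen", "PED",
    "subretinal_fluid", "intraretinal_fluid", "atrophy_incomplete",
    "atrophy_complete", "thick_choroid", "DLS", "scarring", "poor_quality")
}

# Ordinal severity (outcome model driver) and true mean visual acuity in
# letters. Bases are strictly ordered from healthy (best) down to scarring
# (worst) along the severity chain; poor_quality sits outside the chain.
.severity_table <- c(
  healthy = 0, thick_choroid = 1, drusen_small = 2, drusen_large = 3,
  confluent_drusen = 4, DLS = 5, PED = 6, subretinal_fluid = 7,
  intraretinal_fluid = 8, atrophy_incomplete = 9, atrophy_complete = 10,
  scarring = 11, poor_quality = 5)

.va_base_table <- c(
  healthy = 85, thick_choroid = 82, drusen_small = 79, drusen_large = 76,
  confluent_drusen = 72, DLS = 69, PED = 65, subretinal_fluid = 62,
  intraretinal_fluid = 58, atrophy_incomplete = 54, atrophy_complete = 48,
  scarring = 40, poor_quality = 70)

# Default lesion extents in micrometres.
.size_table <- c(
  healthy = NA, drusen_small = 60, drusen_large = 120, confluent_drusen = 280,
  PED = 400, subretinal_fluid = 350, intraretinal_fluid = 300,
  atrophy_incomplete = 180, atrophy_complete = 600, thick_choroid = NA,
  DLS = 500, scarring = 400, poor_quality = NA)

#' Grading vocabulary and class-to-grading map
#'
#' The five grading labels used for stage annotation: healthy,
#' early/intermediate AMD (drusen >= 63 um), MNV (macular fluid), and cRORA
#' split at 1000 um atrophy width. Synthetic classes map onto them;
#' poor-quality images are left unlabeled.
#' @return character vector of grading labels.
#' @export
grading_labels <- function() {
  c("healthy", "early_intermediate", "MNV", "cRORA_250_1000", "cRORA_ge_1000")
}

#' @rdname grading_labels
#' @param class synthetic class name.
#' @param size_um planted lesion extent (decides the cRORA split).
#' @export
grading_from_class <- function(class, size_um = NA) {
  switch(class,
         healthy = "healthy", thick_choroid = "healthy",
         drusen_small = "healthy",   # below the 63 um drusen threshold
         drusen_large = "early_intermediate",
         confluent_drusen = "early_intermediate",
         DLS = "early_intermediate",
         atrophy_incomplete = "early_intermediate",
         PED = "MNV", subretinal_fluid = "MNV", intraretinal_fluid = "MNV",
         scarring = "MNV",
         atrophy_complete = if (!is.na(size_um) && size_um >= 1000)
           "cRORA_ge_1000" else "cRORA_250_1000",
         poor_quality = NA_character_,
         stop("unknown class: ", class))
}

#' Generate smooth retinal layer geometry
#'
#' Draws band-limited boundary curves (ILM, RPE, Bruch's membrane,
#' choroid-sclera junction) with a central foveal depression. Boundaries are
#' per-column depths in pixels, row 0 at the top (vitreous).
#'
#' @param height,width image size in pixels (both >= 64).
#' @param pit_depth foveal pit depth in pixels (0 gives flat ILM).
#' @param pit_width foveal pit full width in pixels.
#' @param wiggle amplitude (pixels) of the low-frequency boundary
#'   undulation shared by all layers.
#' @param depth_offset constant added to every boundary (vertical placement
#'   of the retina; used as an acquisition nuisance by [generate_cohort()]).
#' @return object of class `"layer_geometry"`.
#' @export
generate_retina_layers <- function(height = 64L, width = 64L,
                                   pit_depth = 0.10 * height,
                                   pit_width = 0.28 * width,
                                   wiggle = 0.2, depth_offset = 0) {
  if (height < 64 || width < 64) {
    stop("invalid dimensions: height and width must both be at least 64")
  }
  H <- as.integer(height); W <- as.integer(width)
  x <- seq_len(W)
  band_limited <- function(amp) {
    if (amp <= 0) return(rep(0, W))
    out <- rep(0, W)
    for (j in 1:3) {
      out <- out + amp * 0.8 / j *
        cos(2 * pi * j * x / W + stats::runif(1, 0, 2 * pi))
    }
    out
  }
  shared <- band_limited(wiggle) + depth_offset
  ilm <- 0.24 * H + shared + band_limited(0.25 * wiggle)
  sigma <- max(pit_width, 1) / 2.355
  ilm <- ilm + pit_depth * exp(-((x - (W + 1) / 2)^2) / (2 * sigma^2))
  rpe <- 0.60 * H + shared + band_limited(0.25 * wiggle)
  bm <- rpe + max(2, H / 32)
  csj <- bm + 0.24 * H + band_limited(0.5 * wiggle)
  ilm <- pmax(ilm, 2)
  csj <- pmin(csj, H - 1)
  geom <- structure(list(ilm = ilm, rpe = rpe, bm = bm, csj = csj,
                         height = H, width = W,
                         pit = list(depth = pit_depth, width = pit_width),
                         choroid_um = mean(csj - bm) * .px_axial,
                         overlay = NULL, hypertrans = rep(FALSE, W),
                         poor_quality = FALSE),
                    class = "layer_geometry")
  validate_geometry(geom)
  geom
}

#' @rdname generate_retina_layers
#' @param geometry a `"layer_geometry"` object.
#' @export
validate_geometry <- function(geometry) {
  g <- geometry
  ok <- all(g$ilm < g$rpe) && all(g$rpe < g$bm) && all(g$bm < g$csj)
  if (!ok) stop("layer boundaries out of order: need ILM < RPE < BM < CSJ at every column")
  if (any(g$ilm < 1) || any(g$csj > g$height - 1)) {
    stop("layer boundaries fall outside the image")
  }
  if (g$choroid_um <= 0) stop("choroid thickness must be positive")
  invisible(geometry)
}

#' Specification of a biomarker to plant
#'
#' @param class one of [oct_classes()].
#' @param size_um lateral lesion extent in micrometres; defaults per class.
#'   Sizes convert to columns at the 23.4 um mediolateral pitch, so e.g. a
#'   63 um druse occupies `round(63 / 23.4) = 3` columns.
#' @param location center column of the lesion, or `NULL` to draw one near
#'   the image center.
#' @return object of class `"biomarker_spec"`.
#' @export
biomarker_spec <- function(class, size_um = NULL, location = NULL) {
  class <- match.arg(class, oct_classes())
  if (is.null(size_um)) size_um <- unname(.size_table[class])
  if (class == "drusen_large" && !is.na(size_um) && size_um < 63) {
    stop("drusen_large requires diameter >= 63 um")
  }
  if (class == "atrophy_complete" && !is.na(size_um) && size_um < 250) {
    stop("atrophy_complete requires width >= 250 um")
  }
  structure(list(class = class, size_um = size_um, location = location),
            class = "biomarker_spec")
}

# sinusoidal dome over w columns, at least 1 px tall at every column so the
# mask covers exactly the lesion's columns
.dome <- function(w, h) pmax(1, h * sin(pi * seq_len(w) / (w + 1)))

#' Plant a biomarker into layer geometry
#'
#' Deforms the boundary curves and/or adds reflectivity overlays according
#' to the lesion class: drusen and PED elevate the RPE, fluids carve
#' hyporeflective pockets, atrophy thins the retina (complete atrophy also
#' flags choroidal hypertransmission), DLS opens a shallow RPE-Bruch's
#' separation, scarring deposits subretinal hyperreflective material,
#' thick_choroid deepens the choroid-sclera junction, and poor_quality
#' flags the render for blur and washout.
#'
#' @param geometry a `"layer_geometry"`.
#' @param spec a [biomarker_spec()].
#' @return list with the modified `geometry` (ordering invariant preserved)
#'   and a binary `mask` matrix covering exactly the modified pixels (empty
#'   for healthy and poor_quality).
#' @export
plant_biomarker <- function(geometry, spec) {
  validate_geometry(geometry)
  stopifnot(inherits(spec, "biomarker_spec"))
  g <- geometry
  H <- g$height; W <- g$width
  mask <- matrix(0L, H, W)
  if (is.null(g$overlay)) g$overlay <- matrix(NA_real_, H, W)
  Rm <- matrix(seq_len(H), H, W)

  if (spec$class %in% c("healthy", "poor_quality")) {
    g$poor_quality <- spec$class == "poor_quality"
    return(list(geometry = g, mask = mask))
  }
  if (spec$class == "thick_choroid") {
    old_csj <- g$csj
    g$csj <- pmin(g$bm + 1.8 * (g$csj - g$bm), H - 1)
    g$choroid_um <- mean(g$csj - g$bm) * .px_axial
    band <- sweep(Rm, 2, old_csj, ">") & sweep(Rm, 2, g$csj, "<=")
    mask[band] <- 1L
    validate_geometry(g)
    return(list(geometry = g, mask = mask))
  }

  w <- um_to_px(spec$size_um)
  if (w < 1) w <- 1L
  if (w > W - 4) stop("lesion wider than image")
  cx <- spec$location
  if (is.null(cx)) cx <- round(W / 2 + stats::runif(1, -0.04, 0.04) * W)
  lo <- cx - floor((w - 1) / 2)
  lo <- max(3L, min(lo, W - 2L - w + 1L))
  cols <- lo:(lo + w - 1L)

  band_mask <- function(top, bottom, columns) {
    m <- matrix(0L, H, W)
    for (i in seq_along(columns)) {
      rows <- which(seq_len(H) > top[i] & seq_len(H) <= bottom[i])
      m[rows, columns[i]] <- 1L
    }
    m
  }
  set_overlay <- function(top, bottom, columns, value) {
    for (i in seq_along(columns)) {
      rows <- which(seq_len(H) > top[i] & seq_len(H) <= bottom[i])
      g$overlay[rows, columns[i]] <<- value
    }
  }

  ilm_c <- g$ilm[cols]; rpe_c <- g$rpe[cols]; bm_c <- g$bm[cols]
  if (spec$class %in% c("drusen_small", "drusen_large", "confluent_drusen", "PED")) {
    h_px <- min(0.8 * spec$size_um / .px_axial, min(rpe_c - ilm_c) - 3)
    if (spec$class == "PED") h_px <- min(14, min(rpe_c - ilm_c) - 3)
    if (spec$class == "confluent_drusen") {
      n_dome <- 3L
      wd <- ceiling(w / n_dome)
      elev <- rep(0, w)
      for (d in seq_len(n_dome)) {
        ii <- (((d - 1) * wd + 1):min(d * wd, w))
        elev[ii] <- .dome(length(ii), min(0.8 * wd * .px_ml / .px_axial, h_px))
      }
    } else {
      elev <- .dome(w, h_px)
    }
    new_rpe <- pmax(rpe_c - elev, ilm_c + 2)
    mask <- band_mask(new_rpe, rpe_c, cols)
    if (spec$class == "PED") set_overlay(new_rpe + 2, bm_c - 1, cols, 0.35)
    g$rpe[cols] <- new_rpe
  } else if (spec$class == "subretinal_fluid") {
    elev <- pmin(.dome(w, 10), rpe_c - ilm_c - 3)
    set_overlay(rpe_c - elev, rpe_c, cols, 0.05)
    mask <- band_mask(rpe_c - elev, rpe_c, cols)
  } else if (spec$class == "intraretinal_fluid") {
    mid <- (ilm_c + rpe_c) / 2
    n_cyst <- 3L
    centers <- round(seq(1, w, length.out = n_cyst + 2)[2:(n_cyst + 1)])
    for (k in seq_len(n_cyst)) {
      rx <- max(2, floor(w / (2 * n_cyst)))
      ry <- 5
      cc <- cols[centers[k]]
      for (dc in -rx:rx) {
        col <- cc + dc
        if (col < 1 || col > W) next
        half <- ry * sqrt(max(0, 1 - (dc / rx)^2))
        if (half <= 0) next
        center_r <- mid[min(max(centers[k] + dc, 1), w)]
        rows <- which(abs(seq_len(H) - center_r) <= half &
                      seq_len(H) > g$ilm[col] + 2 & seq_len(H) < g$rpe[col] - 1)
        if (length(rows)) {
          g$overlay[rows, col] <- 0.05
          mask[rows, col] <- 1L
        }
      }
    }
  } else if (spec$class %in% c("atrophy_incomplete", "atrophy_complete")) {
    h_px <- if (spec$class == "atrophy_complete") 9 else 6
    thin <- pmin(.dome(w, h_px), (rpe_c - ilm_c) * 0.55)
    new_rpe <- rpe_c - thin
    new_ilm <- pmin(ilm_c + 0.4 * thin, new_rpe - 2)
    mask <- band_mask(new_rpe, rpe_c, cols) | band_mask(ilm_c, new_ilm, cols)
    mask <- matrix(as.integer(mask), H, W)
    # the vacated outer retina renders as dim degeneration, not as a
    # thickened bright band: only a thin RPE line remains at the new depth
    set_overlay(new_rpe + 2, bm_c, cols, 0.30)
    g$rpe[cols] <- new_rpe
    g$ilm[cols] <- new_ilm
    if (spec$class == "atrophy_complete") g$hypertrans[cols] <- TRUE
  } else if (spec$class == "DLS") {
    elev <- pmax(1, pmin(3, .dome(w, 3)))
    new_rpe <- pmax(rpe_c - elev, ilm_c + 2)
    set_overlay(new_rpe + 1, bm_c - 1, cols, 0.40)
    mask <- band_mask(new_rpe, rpe_c, cols)
    g$rpe[cols] <- new_rpe
  } else if (spec$class == "scarring") {
    elev <- pmin(.dome(w, 13), rpe_c - ilm_c - 3)
    set_overlay(rpe_c - elev, rpe_c, cols, 0.90)
    mask <- band_mask(rpe_c - elev, rpe_c, cols)
  }
  validate_geometry(g)
  list(geometry = g, mask = mask)
}

# small separable gaussian blur with replicated edges (poor-quality render)
.blur <- function(img, sigma = 1.5) {
  r <- ceiling(2 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_apply <- function(m) {
    top <- m[rep(1, r), , drop = FALSE]; bot <- m[rep(nrow(m), r), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- stats::filter(mp, k, sides = 2)
    out[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  t(pad_apply(t(pad_apply(img))))
}

#' Render a B-scan from layer geometry
#'
#' Fills the layer bands with their mean reflectivities, applies lesion
#' overlays, brightens the choroidal region under hypertransmission columns,
#' and multiplies in gamma-distributed speckle with unit mean and standard
#' deviation `noise`. With `noise = 0` the render is exactly piecewise
#' constant at the configured reflectivities.
#'
#' @param geometry a (possibly lesioned) `"layer_geometry"`.
#' @param reflect named list of band reflectivities in `[0, 1]`.
#' @param noise speckle standard deviation (0 disables).
#' @return a `"bscan"`: numeric matrix in `[0, 1]` with pixel-size metadata
#'   (7.0 um axial x 23.4 um mediolateral).
#' @export
render_bscan <- function(geometry,
                         reflect = list(vitreous = 0.03, retina = 0.45,
                                        rpe = 0.85, choroid = 0.25,
                                        sclera = 0.08),
                         noise = 0.12) {
  validate_geometry(geometry)
  g <- geometry
  H <- g$height; W <- g$width
  Rm <- matrix(seq_len(H), H, W)
  gt <- function(b) sweep(Rm, 2, b, ">")
  img <- reflect$vitreous +
    (reflect$retina - reflect$vitreous) * gt(g$ilm) +
    (reflect$rpe - reflect$retina) * gt(g$rpe) +
    (reflect$choroid - reflect$rpe) * gt(g$bm) +
    (reflect$sclera - reflect$choroid) * gt(g$csj)
  if (any(g$hypertrans)) {
    ht <- matrix(rep(g$hypertrans, each = H), H, W)
    below_bm <- gt(g$bm)
    img[ht & below_bm] <- pmin(img[ht & below_bm] * 2.2, 0.95)
    rpe_band <- gt(g$rpe) & !below_bm
    img[ht & rpe_band] <- img[ht & rpe_band] * 0.5
  }
  if (!is.null(g$overlay)) {
    ov <- !is.na(g$overlay)
    img[ov] <- g$overlay[ov]
  }
  if (isTRUE(g$poor_quality)) {
    img <- .blur(img, 1.5)
    img <- mean(img) + 0.65 * (img - mean(img))
  }
  if (noise > 0) {
    shape <- 1 / noise^2
    img <- img * matrix(stats::rgamma(H * W, shape = shape, rate = shape), H, W)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(img, class = c("bscan", "matrix", "array"),
            pixel_size = c(axial = .px_axial, mediolateral = .px_ml))
}

#' Cohort configuration for the synthetic generator
#'
#' Defines the study conditions the generator emulates: patients, eyes,
#' longitudinal visits at a fixed interval, a class mixture over planted
#' biomarkers, acquisition nuisances (global brightness/gain jitter and
#' vertical placement shift), class-driven visual acuity, and a
#' conversion-time model that decreases linearly in an ordinal severity
#' score with exponential noise.
#'
#' @param n_patients,eyes_per_patient,visits_per_eye cohort shape (all >= 1).
#' @param image_hw image size `c(height, width)`, pixels.
#' @param classes planted classes; defaults to eight visually distinct ones.
#' @param mixture class mixture proportions (must sum to 1).
#' @param noise speckle SD passed to [render_bscan()].
#' @param va_sd per-visit visual acuity noise, letters.
#' @param visit_interval years between visits.
#' @param labeled_frac fraction of visits carrying a grading label.
#' @param brightness_jitter,gain_jitter,shift_px acquisition nuisances:
#'   additive intensity offset range, multiplicative gain range (1 +/-), and
#'   vertical retina placement range in pixels.
#' @param outcome conversion-time model: `time = base - slope * severity +
#'   Exp(mean = noise_mean)`, floored at 0.1 years, per eye and event type.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 200L, eyes_per_patient = 1L,
                          visits_per_eye = 10L, image_hw = c(64L, 64L),
                          classes = c("healthy", "drusen_large", "PED",
                                      "subretinal_fluid", "intraretinal_fluid",
                                      "atrophy_complete", "thick_choroid",
                                      "scarring"),
                          mixture = rep(1 / length(classes), length(classes)),
                          noise = 0.12, va_sd = 4, visit_interval = 0.5,
                          labeled_frac = 0.8, brightness_jitter = 0.12,
                          gain_jitter = 0.15, shift_px = 4,
                          outcome = list(base_mnv = 6.5, base_crora = 7.0,
                                         slope_mnv = 0.45, slope_crora = 0.5,
                                         noise_mean = 0.6),
                          seed = 1L) {
  if (n_patients < 1 || eyes_per_patient < 1 || visits_per_eye < 1) {
    stop("all cohort counts must be at least 1")
  }
  classes <- match.arg(classes, oct_classes(), several.ok = TRUE)
  if (length(mixture) != length(classes)) {
    stop("mixture must have one proportion per class")
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop("class mixture proportions must sum to 1")
  structure(list(n_patients = as.integer(n_patients),
                 eyes_per_patient = as.integer(eyes_per_patient),
                 visits_per_eye = as.integer(visits_per_eye),
                 image_hw = as.integer(image_hw), classes = classes,
                 mixture = mixture, noise = noise, va_sd = va_sd,
                 visit_interval = visit_interval, labeled_frac = labeled_frac,
                 brightness_jitter = brightness_jitter,
                 gain_jitter = gain_jitter, shift_px = shift_px,
                 outcome = outcome, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic longitudinal OCT cohort
#'
#' One image per visit. Each eye carries a fixed planted class; its true
#' visual acuity is the class base (strictly ordered from healthy, best, to
#' scarring, worst) plus Gaussian noise, and its conversion times to MNV and
#' cRORA decrease linearly in the class severity score with exponential
#' noise. Images carry acquisition nuisances (brightness/gain jitter,
#' vertical shift) that the contrastive augmentations are designed to
#' discount.
#'
#' @param config a [cohort_config()].
#' @return object of class `"oct_cohort"`: `images` (H x W x N array),
#'   `manifest` (one row per visit: image_id, patient_id, eye_id,
#'   visit_index, visit_years, age, sex, logmar, letters, grading_label),
#'   and `truth` (per-image class and lesion masks, per-eye conversion
#'   times, the outcome-model coefficients).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  H <- cf$image_hw[1]; W <- cf$image_hw[2]
  n_eyes <- cf$n_patients * cf$eyes_per_patient
  N <- n_eyes * cf$visits_per_eye
  with_seed(cf$seed, {
    images <- array(NA_real_, c(H, W, N))
    masks <- array(0L, c(H, W, N))
    class_img <- character(N)
    man <- vector("list", N)
    conv <- vector("list", n_eyes)
    i <- 0L; e <- 0L
    for (p in seq_len(cf$n_patients)) {
      pid <- sprintf("P%04d", p)
      age <- min(max(round(stats::rnorm(1, 78, 7)), 51), 102)
      sex <- sample(c("F", "M"), 1)
      for (ey in seq_len(cf$eyes_per_patient)) {
        e <- e + 1L
        eid <- sprintf("%s_E%d", pid, ey)
        cls <- sample(cf$classes, 1, prob = cf$mixture)
        sev <- unname(.severity_table[cls])
        t_mnv <- max(0.1, cf$outcome$base_mnv - cf$outcome$slope_mnv * sev +
                       stats::rexp(1, 1 / cf$outcome$noise_mean))
        t_crora <- max(0.1, cf$outcome$base_crora - cf$outcome$slope_crora * sev +
                         stats::rexp(1, 1 / cf$outcome$noise_mean))
        conv[[e]] <- data.frame(eye_id = eid, class = cls, severity = sev,
                                time_mnv = t_mnv, time_crora = t_crora,
                                stringsAsFactors = FALSE)
        for (v in seq_len(cf$visits_per_eye)) {
          i <- i + 1L
          geom <- generate_retina_layers(
            H, W, depth_offset = stats::runif(1, -cf$shift_px, cf$shift_px))
          pl <- plant_biomarker(geom, biomarker_spec(cls))
          img <- render_bscan(pl$geometry, noise = cf$noise)
          gain <- 1 + stats::runif(1, -cf$gain_jitter, cf$gain_jitter)
          off <- stats::runif(1, -cf$brightness_jitter, cf$brightness_jitter)
          img <- gain * img + off
          img[img < 0] <- 0; img[img > 1] <- 1
          images[, , i] <- img
          masks[, , i] <- pl$mask
          class_img[i] <- cls
          letters <- min(max(.va_base_table[cls] + stats::rnorm(1, 0, cf$va_sd), 5), 95)
          lab <- if (stats::runif(1) < cf$labeled_frac)
            grading_from_class(cls, .size_table[cls]) else NA_character_
          man[[i]] <- data.frame(
            image_id = sprintf("img_%05d", i), patient_id = pid, eye_id = eid,
            visit_index = v, visit_years = (v - 1) * cf$visit_interval,
            age = age, sex = sex, logmar = round((85 - letters) / 50, 4),
            letters = letters, grading_label = lab, stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(images = images,
                   manifest = do.call(rbind, man),
                   truth = list(class = class_img, masks = masks,
                                conversions = do.call(rbind, conv),
                                outcome = cf$outcome),
                   config = cf),
              class = "oct_cohort")
  })
}

#' @export
print.oct_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic OCT cohort: %d images (%dx%d) from %d eyes / %d patients\n",
              nrow(m), dim(x$images)[1], dim(x$images)[2],
              length(unique(m$eye_id)), length(unique(m$patient_id))))
  tab <- table(x$truth$class[!duplicated(m$eye_id)])
  cat("  planted classes (per eye):\n")
  print(tab)
  invisible(x)
}
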
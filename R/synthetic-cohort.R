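# Synthetic scan/rescan cohort generator.
#
# Each patient gets one anatomy — an annular vessel wall (outer ellipse,
# eccentric lumen ellipse) slowly varying along a stack of axial planes,
# carrying smooth plaque-component lesions — imaged twice.  The rescan
# differs by a through-plane stack shift, a small in-plane translation, a
# per-weighting multiplicative intensity drift, and fresh noise.  Labels
# come from the same anatomy, so ground truth is known exactly in both
# sessions; an imperfect manual observer is simulated on top of the truth.

ellipse_polygon <- function(center, a, b, phi, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(th); y0 <- b * sin(th)
  cbind(x = center[1] + x0 * cos(phi) - y0 * sin(phi),
        y = center[2] + x0 * sin(phi) + y0 * cos(phi))
}

# Draw one patient's anatomy: ellipse parameters varying smoothly along a
# continuous through-plane coordinate z (in slice units), a bifurcation
# plane, and component lesions (defined in wall-relative coordinates:
# angle around the lumen, normalized radial depth, plane coordinate).
draw_anatomy <- function(cfg, patient_seed) {
  with_seed(patient_seed, {
    lim <- vessel_geometry_limits()
    S <- cfg$slices_per_patient
    shift <- cfg$rescan$through_plane_shift_slices
    n_planes <- S + shift
    fov <- cfg$grid * cfg$pixel_spacing
    center0 <- fov / 2 + runif(2, -1, 1)
    tilt <- runif(2, -0.12, 0.12)              # mm per plane
    a_out <- runif(1, 4.7, lim$outer_max)
    b_out <- runif(1, lim$outer_min, a_out)
    phi <- runif(1, 0, pi)
    taper <- runif(1, -0.015, 0.015)           # relative size per plane
    a_lum <- runif(1, 1.9, lim$lumen_max)
    b_lum <- runif(1, lim$lumen_min, a_lum)
    scale_min <- 1 - abs(taper) * n_planes / 2
    off_max <- max(0, min(a_out, b_out) * scale_min -
                     max(a_lum, b_lum) - lim$min_wall_mm)
    psi <- runif(1, 0, 2 * pi)
    off <- runif(1, 0.2, 0.75) * off_max
    lumen_off <- c(cos(psi), sin(psi)) * off

    mid <- (n_planes + 1) / 2
    geom <- list(center0 = center0, tilt = tilt, mid = mid,
                 a_out = a_out, b_out = b_out, phi = phi, taper = taper,
                 a_lum = a_lum, b_lum = b_lum, lumen_off = lumen_off)

    r_mid <- ((a_out + b_out) / 2 + (a_lum + b_lum) / 2) / 2
    th_mean <- (a_out + b_out) / 2 - (a_lum + b_lum) / 2

    lesions <- list()
    for (cls in component_names()) {
      if (cls == "fibrous") next
      prev <- cfg$component_prevalence[[cls]]
      if (prev <= 0) next
      carries <- runif(1) < prev
      bp <- cfg$component_blob_params[[cls]]
      n_les <- if (carries) 1L + rpois(1, bp$extra_lesion_rate) else 0L
      # draw lesion geometry with a fixed number of RNG calls whether or
      # not the patient carries the component, so anatomy is stable
      for (l in seq_len(max(1L, n_les))) {
        theta0 <- runif(1, -pi, pi)
        z0 <- runif(1, 1.5, n_planes - 0.5)
        h <- runif(1, bp$z_extent_slices[1], bp$z_extent_slices[2])
        sdl <- sqrt(log(1 + bp$area_cv^2))
        area <- rlnorm(1, log(bp$area_mean_mm2) - sdl^2 / 2, sdl)
        wob_amp <- runif(1, 0, 0.08)
        wob_phase <- runif(1, 0, 2 * pi)
        if (l > n_les) next
        band <- bp$radial_band
        # annulus capacity for this component's radial band; a config whose
        # mean lesion cannot fit is rejected, and individual heavy-tail
        # draws are truncated to 90% of the capacity
        max_area <- 2 * pi * r_mid * (band[2] - band[1]) * th_mean * 0.9
        if (bp$area_mean_mm2 > max_area) {
          abort(sprintf(
            "component blobs for class '%s' (mean area %.1f mm2) cannot fit inside the wall annulus (capacity %.1f mm2).",
            cls, bp$area_mean_mm2, max_area), class = "plaquerep_blob_fit_error")
        }
        area <- min(area, max_area)
        theta_hw <- area / (2 * r_mid * (band[2] - band[1]) * th_mean)
        lesions[[length(lesions) + 1L]] <- list(
          class = cls, code = class_code(cls), theta0 = theta0, z0 = z0,
          h = h, theta_hw = theta_hw, band = band,
          wob_amp = wob_amp, wob_phase = wob_phase)
      }
    }
    # fixed assignment priority when lesions overlap
    prio <- c("calcification", "lipid", "loose_matrix", "ulceration", "hemorrhage")
    lesions <- lesions[order(match(vapply(lesions, `[[`, "", "class"), prio))]
    bif_plane <- shift + max(1L, round(S * 0.55))
    list(geom = geom, lesions = lesions, bifurcation_plane = bif_plane,
         n_planes = n_planes)
  })
}

# ellipse parameters at a (possibly fractional) through-plane coordinate z
plane_params <- function(anatomy, z) {
  g <- anatomy$geom
  sc <- 1 + (z - g$mid) * g$taper
  list(center = g$center0 + (z - g$mid) * g$tilt,
       a_out = g$a_out * sc, b_out = g$b_out * sc, phi = g$phi,
       a_lum = g$a_lum, b_lum = g$b_lum, lumen_off = g$lumen_off)
}

plane_contours <- function(pl, offset_mm = c(0, 0)) {
  outer <- ellipse_polygon(pl$center + offset_mm, pl$a_out, pl$b_out, pl$phi)
  lumen <- ellipse_polygon(pl$center + pl$lumen_off + offset_mm,
                           pl$a_lum, pl$b_lum, pl$phi)
  vessel_contours(lumen = lumen, outer = outer)
}

# truth label map of one plane: fibrous wall with lesion footprints
plane_truth_labels <- function(anatomy, z, contours, grid, pixel_spacing) {
  mask <- rasterize_wall_mask(contours, grid, pixel_spacing)
  lab <- matrix(0L, grid, grid)
  lab[mask] <- class_code("fibrous")
  if (length(anatomy$lesions) == 0 || !any(mask)) return(lab)
  geo <- geometric_features(mask, contours, pixel_spacing)
  idx <- which(mask, arr.ind = TRUE)
  cx <- pixel_centers(grid, pixel_spacing)
  lc <- polygon_centroid(contours$lumen)
  theta <- atan2(cx[idx[, 1]] - lc[2], cx[idx[, 2]] - lc[1])
  t_frac <- geo$d_lumen[idx] / pmax(geo$thickness[idx], 1e-9)
  assigned <- rep(FALSE, nrow(idx))
  for (les in anatomy$lesions) {
    w <- les$theta_hw * max(0, 1 - ((z - les$z0) / les$h)^2)
    if (w <= 0) next
    dth <- abs(((theta - les$theta0 + pi) %% (2 * pi)) - pi)
    lo <- les$band[1] + les$wob_amp * sin(3 * theta + les$wob_phase)
    hi <- les$band[2] + les$wob_amp * sin(3 * theta + les$wob_phase + 1)
    hit <- !assigned & dth <= w & t_frac >= lo & t_frac <= hi
    if (any(hit)) {
      lab[idx[hit, , drop = FALSE]] <- les$code
      assigned <- assigned | hit
    }
  }
  lab
}

# render the four weightings of one slice from its truth labels
render_slice_images <- function(labels, contours, cfg, drift) {
  grid <- cfg$grid
  tab <- cfg$class_intensity_table
  blood <- c(T1w = 0.15, T2w = 0.15, PDw = 0.15, TOF = 2.2)
  in_lumen <- polygon_pixel_mask(contours$lumen, grid, cfg$pixel_spacing,
                                 boundary = FALSE)
  imgs <- list()
  for (w in weighting_names()) {
    base <- matrix(1.0, grid, grid)           # muscle-like reference tissue
    base[in_lumen] <- blood[[w]]
    for (cls in component_names()) {
      sel <- labels == class_code(cls)
      if (any(sel)) base[sel] <- tab[cls, w]
    }
    img <- base * drift[[w]]
    if (cfg$noise_sd > 0) {
      img <- img + matrix(rnorm(grid * grid, 0, cfg$noise_sd), grid, grid)
    }
    imgs[[w]] <- img
  }
  imgs
}

#' Generate a paired scan/rescan synthetic cohort
#'
#' Produces, for every patient, two imaging sessions of the same vessel
#' anatomy.  Session 2 is perturbed by the configured through-plane stack
#' shift (with the bifurcation index updated consistently), an in-plane
#' translation, per-weighting multiplicative intensity drift, and
#' independent noise.  Ground-truth label maps follow the configured
#' contrast rules; a simulated manual observer (see [simulate_observer()])
#' provides an imperfect second set of labels.  The whole cohort is a pure
#' function of the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A `plaque_cohort` tibble with one row per patient/session/slice
#'   and list-columns `images` (named list of four intensity matrices),
#'   `contours` ([vessel_contours()]), `truth` and `observer` (integer
#'   label matrices), plus `bifurcation_index` and voxel geometry columns.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2, slices_per_patient = 3, grid = 60, seed = 3)
#' coh <- generate_cohort(cfg)
#' dplyr::count(coh, patient_id, scan_session)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  S <- cfg$slices_per_patient
  shift <- cfg$rescan$through_plane_shift_slices
  out <- vector("list", cfg$n_patients * 2L)
  k <- 0L
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    anatomy <- draw_anatomy(cfg, derive_seed(cfg$seed, p, 1))
    for (s in 1:2) {
      sess <- with_seed(derive_seed(cfg$seed, p, 2, s), {
        drift <- lapply(setNames(nm = weighting_names()), function(w) {
          if (s == 2 && cfg$rescan$intensity_drift_sd > 0)
            max(0.2, 1 + rnorm(1, 0, cfg$rescan$intensity_drift_sd)) else 1
        })
        offset <- if (s == 2 && cfg$rescan$inplane_jitter_mm > 0)
          rnorm(2, 0, cfg$rescan$inplane_jitter_mm) else c(0, 0)
        # residual through-plane misalignment smaller than the slice
        # thickness, which integer stack alignment cannot correct
        tpj <- cfg$rescan$through_plane_jitter_slices
        delta <- if (s == 2 && tpj > 0)
          max(-0.49, min(0.49, rnorm(1, 0, tpj))) else 0
        plane_of <- seq_len(S) + (if (s == 2) shift + delta else 0)
        slices <- lapply(seq_len(S), function(i) {
          z <- plane_of[i]
          ctr <- plane_contours(plane_params(anatomy, z), offset)
          lab <- plane_truth_labels(anatomy, z, ctr, cfg$grid, cfg$pixel_spacing)
          imgs <- render_slice_images(lab, ctr, cfg, drift)
          list(contours = ctr, truth = lab, images = imgs)
        })
        bif <- anatomy$bifurcation_plane - if (s == 2) shift else 0L
        list(slices = slices, bif = bif)
      })
      obs <- simulate_observer(
        truth = lapply(sess$slices, `[[`, "truth"),
        observer = cfg$observer, pixel_spacing = cfg$pixel_spacing,
        intensity_table = cfg$class_intensity_table,
        seed = derive_seed(cfg$seed, p, 4, s))
      k <- k + 1L
      out[[k]] <- tibble(
        patient_id = pid, scan_session = s, slice_index = seq_len(S),
        pixel_spacing = cfg$pixel_spacing, slice_thickness = cfg$slice_thickness,
        grid = cfg$grid, bifurcation_index = sess$bif,
        images = lapply(sess$slices, `[[`, "images"),
        contours = lapply(sess$slices, `[[`, "contours"),
        truth = lapply(sess$slices, `[[`, "truth"),
        observer = obs)
    }
  }
  coh <- dplyr::bind_rows(out)
  attr(coh, "config") <- cfg
  class(coh) <- c("plaque_cohort", class(coh))
  coh
}
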
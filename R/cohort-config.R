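# Cohort configuration: the knobs of the synthetic scan/rescan generator.

#' Default per-class relative intensity table
#'
#' Mean signal intensity of each tissue class on each contrast weighting,
#' relative to fibrous tissue (fixed at 1.0 on every weighting).  The
#' defaults encode the standard visual criteria used for manual plaque
#' review: calcification is hypointense on all four weightings; lipid is
#' hyperintense on T1w and PDw; loose matrix is hyperintense on T2w and
#' PDw.  T2w lipid contrast is left neutral.  Hemorrhage and ulceration
#' rows exist so the classes are representable, but those components are
#' only generated when explicitly given non-zero prevalence.
#'
#' @return A numeric matrix with one row per non-background tissue class
#'   and one column per weighting (`T1w`, `T2w`, `PDw`, `TOF`).
#' @export
#' @examples
#' default_intensity_table()
default_intensity_table <- function() {
  m <- rbind(
    fibrous       = c(1.00, 1.00, 1.00, 1.00),
    lipid         = c(1.35, 1.00, 1.35, 1.00),
    calcification = c(0.40, 0.40, 0.40, 0.40),
    loose_matrix  = c(1.00, 1.40, 1.40, 1.00),
    ulceration    = c(0.60, 0.80, 0.80, 1.40),
    hemorrhage    = c(1.50, 1.00, 1.20, 1.50)
  )
  colnames(m) <- weighting_names()
  m[component_names(), , drop = FALSE]
}

# Default lesion count/size parameters per component.  Peak per-slice areas
# are drawn lognormally around `area_mean_mm2`; `extra_lesion_rate` is the
# Poisson rate of lesions beyond the first; `radial_band` is the band of
# normalized wall depth (0 = lumen boundary, 1 = outer boundary) the
# component occupies; `z_extent_slices` is the through-plane half-extent.
default_blob_params <- function() {
  list(
    lipid         = list(area_mean_mm2 = 17.5, area_cv = 0.45,
                         extra_lesion_rate = 0.3,
                         radial_band = c(0.00, 0.75),
                         z_extent_slices = c(1.2, 2.5)),
    calcification = list(area_mean_mm2 = 12.2, area_cv = 0.55,
                         extra_lesion_rate = 0.4,
                         radial_band = c(0.10, 0.90),
                         z_extent_slices = c(1.2, 2.5)),
    loose_matrix  = list(area_mean_mm2 = 15.8, area_cv = 0.45,
                         extra_lesion_rate = 0.3,
                         radial_band = c(0.25, 1.00),
                         z_extent_slices = c(1.2, 2.5)),
    ulceration    = list(area_mean_mm2 = 8.7, area_cv = 0.40,
                         extra_lesion_rate = 0.0,
                         radial_band = c(0.00, 0.50),
                         z_extent_slices = c(1.0, 2.0)),
    hemorrhage    = list(area_mean_mm2 = 4.6, area_cv = 0.30,
                         extra_lesion_rate = 0.0,
                         radial_band = c(0.10, 0.80),
                         z_extent_slices = c(1.0, 2.0))
  )
}

#' Configure a synthetic scan/rescan cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: grid and
#' voxel geometry of the acquisition (defaults: 120 x 120 matrix, 0.5 mm
#' pixels, 8 slices of 2 mm), the per-class relative-intensity contrast
#' rules, component prevalences at the patient level, lesion count/size
#' distributions, the scan-to-rescan perturbation (through-plane stack
#' shift, multiplicative per-weighting intensity drift, small in-plane
#' translation), and the simulated manual observer (per-session intensity
#' bias driving boundary erosion/dilation, and omission of small
#' components).
#'
#' @param n_patients Number of patients; each contributes two scan sessions.
#' @param slices_per_patient Axial slices per session (default 8).
#' @param grid Pixels per image axis (default 120).
#' @param pixel_spacing In-plane pixel size in mm (default 0.5).
#' @param slice_thickness Slice thickness in mm (default 2).
#' @param class_intensity_table Per-class, per-weighting mean relative
#'   intensity; see [default_intensity_table()].
#' @param noise_sd SD of additive Gaussian intensity noise, in
#'   relative-intensity units (default 0.08).
#' @param component_prevalence Named probabilities that a patient carries
#'   each component.  Fibrous tissue must be 1 (it is the wall backbone).
#'   Defaults are the observed patient-level prevalences of a typical
#'   symptomatic 30-70% stenosis cohort: lipid 0.43, calcification 0.87,
#'   loose matrix 0.65; ulceration and hemorrhage off.
#' @param component_blob_params Lesion count/size distributions per
#'   component; see `default_blob_params` in the package source.
#' @param rescan List with `through_plane_shift_slices` (integer stack
#'   shift, default 1), `through_plane_jitter_slices` (SD, in slice units,
#'   of the residual sub-slice through-plane misalignment that integer
#'   stack alignment cannot correct; truncated to half a slice; default
#'   0.35), `intensity_drift_sd` (SD of the multiplicative per-weighting
#'   session drift, default 0.05) and `inplane_jitter_mm` (SD of the
#'   rescan in-plane translation, default 0.2).
#' @param observer List with `session_bias_sd` (SD, in relative-intensity
#'   units, of the per-session intensity bias that drives boundary
#'   erosion/dilation, default 0.08), `p_miss_small` (probability a small
#'   component is missed in a slice, default 0.35),
#'   `small_area_threshold_mm2` (default 8), `boundary_jitter_px` (SD of
#'   per-region boundary jitter in pixels, default 0.4) and
#'   `reliable_contrast` (contrast margin above which a component's
#'   boundary is traced without jitter, default 0.5).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   config including this seed.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2, seed = 7)
#' cfg$rescan$through_plane_shift_slices
cohort_config <- function(n_patients = 23,
                          slices_per_patient = 8,
                          grid = 120,
                          pixel_spacing = 0.5,
                          slice_thickness = 2.0,
                          class_intensity_table = default_intensity_table(),
                          noise_sd = 0.08,
                          component_prevalence = c(
                            fibrous = 1.0, lipid = 0.43,
                            calcification = 0.87, loose_matrix = 0.65,
                            ulceration = 0.0, hemorrhage = 0.0),
                          component_blob_params = default_blob_params(),
                          rescan = list(through_plane_shift_slices = 1L,
                                        through_plane_jitter_slices = 0.35,
                                        intensity_drift_sd = 0.05,
                                        inplane_jitter_mm = 0.2),
                          observer = list(session_bias_sd = 0.08,
                                          p_miss_small = 0.35,
                                          small_area_threshold_mm2 = 8,
                                          boundary_jitter_px = 0.4,
                                          reliable_contrast = 0.5),
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    slices_per_patient = check_count(slices_per_patient, "slices_per_patient"),
    grid = check_count(grid, "grid", min = 16L),
    pixel_spacing = check_number(pixel_spacing, "pixel_spacing",
                                 min = 0, strict_min = TRUE),
    slice_thickness = check_number(slice_thickness, "slice_thickness",
                                   min = 0, strict_min = TRUE),
    class_intensity_table = class_intensity_table,
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    component_prevalence = component_prevalence,
    component_blob_params = component_blob_params,
    rescan = rescan,
    observer = observer,
    seed = check_count(seed, "seed", min = 0L)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  tab <- cfg$class_intensity_table
  if (!is.matrix(tab) || !all(component_names() %in% rownames(tab)) ||
      !all(weighting_names() %in% colnames(tab))) {
    abort(paste0("`class_intensity_table` must have a row for each of: ",
                 paste(component_names(), collapse = ", "),
                 " and a column for each weighting."))
  }
  prev <- cfg$component_prevalence
  if (is.null(names(prev)) || !all(component_names() %in% names(prev))) {
    abort("`component_prevalence` must be named for every tissue class.")
  }
  if (any(prev < 0 | prev > 1)) {
    abort("`component_prevalence` values must lie in [0, 1].")
  }
  if (prev[["fibrous"]] != 1) {
    abort("`component_prevalence[\"fibrous\"]` must be 1: fibrous tissue forms the vessel wall in every patient.")
  }
  rs <- cfg$rescan
  rs$through_plane_shift_slices <-
    check_count(rs$through_plane_shift_slices, "rescan$through_plane_shift_slices", min = 0L)
  rs$through_plane_jitter_slices <- rs$through_plane_jitter_slices %||% 0
  check_number(rs$through_plane_jitter_slices, "rescan$through_plane_jitter_slices",
               min = 0, max = 0.49)
  check_number(rs$intensity_drift_sd, "rescan$intensity_drift_sd", min = 0)
  check_number(rs$inplane_jitter_mm, "rescan$inplane_jitter_mm", min = 0)
  if (rs$through_plane_shift_slices >= cfg$slices_per_patient) {
    abort("`rescan$through_plane_shift_slices` must be smaller than `slices_per_patient` or no slice pair overlaps.")
  }
  cfg$rescan <- rs
  ob <- cfg$observer
  check_number(ob$session_bias_sd, "observer$session_bias_sd", min = 0)
  check_number(ob$p_miss_small, "observer$p_miss_small", min = 0, max = 1)
  check_number(ob$small_area_threshold_mm2, "observer$small_area_threshold_mm2", min = 0)
  check_number(ob$boundary_jitter_px, "observer$boundary_jitter_px", min = 0)
  ob$reliable_contrast <- ob$reliable_contrast %||% 0.5
  check_number(ob$reliable_contrast, "observer$reliable_contrast", min = 0)
  cfg$observer <- ob
  fov_mm <- cfg$grid * cfg$pixel_spacing
  if (fov_mm < 2 * (vessel_geometry_limits()$outer_max + 2)) {
    abort(sprintf("grid x pixel_spacing gives a %.1f mm field of view, too small to contain the vessel.", fov_mm))
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients x 2 sessions, %d slices of %g mm, grid %dx%d @ %g mm\n",
              x$n_patients, x$slices_per_patient, x$slice_thickness,
              x$grid, x$grid, x$pixel_spacing))
  cat(sprintf("  noise_sd %.3g; rescan shift %d slice(s), drift sd %.3g, jitter %.3g mm\n",
              x$noise_sd, x$rescan$through_plane_shift_slices,
              x$rescan$intensity_drift_sd, x$rescan$inplane_jitter_mm))
  prev <- x$component_prevalence[component_names()]
  cat("  prevalence:", paste(sprintf("%s %.2f", names(prev), prev), collapse = ", "), "\n")
  invisible(x)
}

# hard geometric bounds of the simulated vessel (mm); used by config
# validation and by the lesion-fit check
vessel_geometry_limits <- function() {
  list(outer_min = 4.0, outer_max = 5.6, lumen_min = 1.7, lumen_max = 2.6,
       min_wall_mm = 0.9)
}
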
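# From label maps to per-slice areas, per-patient volumes, presence/absence
# tables and aligned scan/rescan slice pairs.

#' Per-class areas of one label map
#'
#' `area(class) = pixel count x pixel_spacing^2`; the wall area is the sum
#' over the tissue classes (pixel-exact partition of the wall mask).
#'
#' @param labels Integer label matrix.
#' @param pixel_spacing Pixel size (mm).
#' @return One-row tibble with a column per tissue class (mm2) and
#'   `wall_area`.
#' @export
#' @examples
#' lab <- matrix(0L, 10, 10); lab[2:5, 2:5] <- 1L; lab[3, 3] <- 2L
#' areas_from_labels(lab, 0.5)
areas_from_labels <- function(labels, pixel_spacing) {
  px2 <- pixel_spacing^2
  counts <- vapply(component_names(),
                   function(cls) sum(labels == class_code(cls)), numeric(1))
  out <- as_tibble(as.list(counts * px2))
  out$wall_area <- sum(counts) * px2
  out
}

#' Tidy per-slice component areas of a cohort
#'
#' @param cohort A `plaque_cohort`, optionally carrying a `predicted`
#'   column from [lopo_crossval()].
#' @param methods Which label sets to quantify; any of `"truth"`,
#'   `"observer"`, `"predicted"` present in the cohort.
#' @return Long tibble: `patient_id`, `scan_session`, `slice_index`,
#'   `method`, `class`, `area_mm2`, `wall_area`.  Slices whose label map is
#'   `NULL` under a method (e.g. excluded from classification) are skipped
#'   for every method, keeping the slice basis identical across methods.
#' @export
component_areas <- function(cohort,
                            methods = intersect(c("truth", "observer", "predicted"),
                                                names(cohort))) {
  has_all <- rep(TRUE, nrow(cohort))
  for (m in methods) {
    has_all <- has_all & !vapply(cohort[[m]], is.null, logical(1))
  }
  rows <- list()
  for (i in which(has_all)) {
    for (m in methods) {
      a <- areas_from_labels(cohort[[m]][[i]], cohort$pixel_spacing[i])
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = cohort$patient_id[i],
        scan_session = cohort$scan_session[i],
        slice_index = cohort$slice_index[i],
        method = m) |>
        dplyr::bind_cols(
          tidyr::pivot_longer(a[, component_names()], dplyr::everything(),
                              names_to = "class", values_to = "area_mm2")) |>
        dplyr::mutate(wall_area = a$wall_area)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-patient component volumes
#'
#' `volume = sum(slice areas) x slice_thickness` per patient, session,
#' method and class.
#'
#' @param areas Tidy area tibble from [component_areas()].
#' @param slice_thickness Slice thickness (mm).
#' @return Tibble with `volume_mm3` per patient/session/method/class.
#' @export
volumes_from_areas <- function(areas, slice_thickness) {
  check_number(slice_thickness, "slice_thickness", min = 0, strict_min = TRUE)
  if (nrow(areas) == 0) abort("`areas` is empty.")
  areas |>
    dplyr::group_by(.data$patient_id, .data$scan_session, .data$method,
                    .data$class) |>
    dplyr::summarise(volume_mm3 = sum(.data$area_mm2) * slice_thickness,
                     n_slices = dplyr::n(), .groups = "drop")
}

#' Align scan and rescan slices through the bifurcation index
#'
#' Slice `i` of session 1 is paired with slice `i + (bif2 - bif1)` of
#' session 2, so the bifurcation slices coincide; non-overlapping slices
#' are dropped and counted.
#'
#' @param cohort A `plaque_cohort` (both sessions of each patient).
#' @return Tibble `patient_id`, `slice1`, `slice2`, `offset`; attribute
#'   `n_dropped` counts slice indices without a partner.
#' @export
align_scan_pairs <- function(cohort) {
  meta <- dplyr::distinct(cohort, .data$patient_id, .data$scan_session,
                          .data$bifurcation_index)
  pairs <- list(); dropped <- 0L
  for (pid in unique(meta$patient_id)) {
    b1 <- meta$bifurcation_index[meta$patient_id == pid & meta$scan_session == 1]
    b2 <- meta$bifurcation_index[meta$patient_id == pid & meta$scan_session == 2]
    if (length(b1) != 1 || length(b2) != 1) {
      abort(sprintf("patient %s does not have exactly two sessions with a bifurcation index.", pid))
    }
    s1 <- sort(cohort$slice_index[cohort$patient_id == pid & cohort$scan_session == 1])
    s2 <- sort(cohort$slice_index[cohort$patient_id == pid & cohort$scan_session == 2])
    off <- b2 - b1
    keep <- s1[(s1 + off) %in% s2]
    dropped <- dropped + (length(s1) - length(keep)) + (length(s2) - length(keep))
    if (length(keep)) {
      pairs[[length(pairs) + 1L]] <- tibble(
        patient_id = pid, slice1 = keep, slice2 = keep + off, offset = off)
    }
  }
  out <- dplyr::bind_rows(pairs)
  attr(out, "n_dropped") <- dropped
  out
}

#' Paired scan/rescan areas on aligned slices
#'
#' Joins the tidy area table onto the aligned slice pairs, giving one row
#' per patient/slice-pair/method/class with the session-1 and session-2
#' areas.
#'
#' @param areas Tidy area tibble from [component_areas()].
#' @param pairs Aligned pairs from [align_scan_pairs()].
#' @return Tibble with `area1_mm2`, `area2_mm2` (and wall areas).
#' @export
paired_areas <- function(areas, pairs) {
  a1 <- areas |>
    dplyr::filter(.data$scan_session == 1) |>
    dplyr::select("patient_id", slice1 = "slice_index", "method", "class",
                  area1_mm2 = "area_mm2", wall1_mm2 = "wall_area")
  a2 <- areas |>
    dplyr::filter(.data$scan_session == 2) |>
    dplyr::select("patient_id", slice2 = "slice_index", "method", "class",
                  area2_mm2 = "area_mm2", wall2_mm2 = "wall_area")
  pairs |>
    dplyr::inner_join(a1, by = c("patient_id", "slice1"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(a2, by = c("patient_id", "slice2", "method", "class"))
}

#' Presence/absence of each component per patient and session
#'
#' A component is present for a patient in a session iff its total area
#' over that session's quantified slices is positive (after any
#' post-processing embedded in the label maps).
#'
#' @param areas Tidy area tibble from [component_areas()].
#' @return Tibble `method`, `class`, `patient_id`, `present1`, `present2`,
#'   plus the per-class 2x2 contingency in `presence_contingency()`.
#' @export
presence_table <- function(areas) {
  areas |>
    dplyr::group_by(.data$method, .data$class, .data$patient_id,
                    .data$scan_session) |>
    dplyr::summarise(total = sum(.data$area_mm2), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "scan_session", values_from = "total",
                       names_prefix = "area_s") |>
    dplyr::mutate(present1 = .data$area_s1 > 0, present2 = .data$area_s2 > 0) |>
    dplyr::select("method", "class", "patient_id", "present1", "present2")
}

#' @rdname presence_table
#' @param presence Output of [presence_table()].
#' @export
presence_contingency <- function(presence) {
  presence |>
    dplyr::count(.data$method, .data$class, .data$present1, .data$present2) |>
    tidyr::complete(.data$method, .data$class,
                    present1 = c(FALSE, TRUE), present2 = c(FALSE, TRUE),
                    fill = list(n = 0L))
}
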
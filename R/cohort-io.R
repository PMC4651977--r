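# Cohort persistence.
#
# Layout under the cohort directory:
#   manifest.json                      cohort geometry + dataset table
#   classes.json                       integer code -> class name
#   <patient>/<patient>_s<k>_<W>.nii.gz     one volume per weighting/session
#   <patient>/<patient>_s<k>_truth.nii.gz   integer label volume
#   <patient>/<patient>_s<k>_observer.nii.gz
#   <patient>/<patient>_s<k>_slice<i>_contours.csv  x_mm, y_mm, ring

#' Write a cohort to a directory tree
#'
#' Volumes (one NIfTI file per weighting per session per patient), integer
#' label volumes, per-slice contour CSVs (`x_mm`, `y_mm`,
#' `ring in {lumen, outer}`), a JSON class dictionary and a JSON manifest.
#'
#' @param cohort A `plaque_cohort` tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tc <- tissue_classes()
  jsonlite::write_json(as.list(setNames(names(tc), tc)),
                       file.path(dir, "classes.json"), auto_unbox = TRUE)
  datasets <- list()
  for (key in split(seq_len(nrow(cohort)),
                    paste(cohort$patient_id, cohort$scan_session))) {
    rows <- cohort[key, ]
    rows <- rows[order(rows$slice_index), ]
    pid <- rows$patient_id[1]; s <- rows$scan_session[1]
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    stem <- file.path(pdir, sprintf("%s_s%d", pid, s))
    grid <- rows$grid[1]; S <- nrow(rows)
    for (w in weighting_names()) {
      vol <- array(NA_real_, c(grid, grid, S))
      for (i in seq_len(S)) vol[, , i] <- rows$images[[i]][[w]]
      RNifti::writeNifti(vol, sprintf("%s_%s.nii.gz", stem, w))
    }
    for (lb in c("truth", "observer")) {
      vol <- array(0L, c(grid, grid, S))
      for (i in seq_len(S)) vol[, , i] <- rows[[lb]][[i]]
      RNifti::writeNifti(vol, sprintf("%s_%s.nii.gz", stem, lb))
    }
    for (i in seq_len(S)) {
      ct <- rows$contours[[i]]
      df <- rbind(
        data.frame(x_mm = ct$lumen[, 1], y_mm = ct$lumen[, 2], ring = "lumen"),
        data.frame(x_mm = ct$outer[, 1], y_mm = ct$outer[, 2], ring = "outer"))
      df$x_mm <- format(df$x_mm, digits = 17, scientific = TRUE)
      df$y_mm <- format(df$y_mm, digits = 17, scientific = TRUE)
      write.csv(df, sprintf("%s_slice%d_contours.csv", stem, rows$slice_index[i]),
                row.names = FALSE)
    }
    datasets[[length(datasets) + 1L]] <- list(
      patient_id = pid, scan_session = s, n_slices = S,
      bifurcation_index = rows$bifurcation_index[1])
  }
  manifest <- list(
    format_version = 1L,
    grid = cohort$grid[1],
    pixel_spacing = cohort$pixel_spacing[1],
    slice_thickness = cohort$slice_thickness[1],
    weightings = weighting_names(),
    datasets = datasets)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory tree
#'
#' Inverse of [write_cohort()]: labels and contours round-trip exactly,
#' intensities within floating-point file precision.  A missing weighting
#' volume raises an error naming the patient, session and weighting.
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @return A `plaque_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) abort(sprintf("no manifest.json in '%s'.", dir))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  out <- list()
  ds <- mf$datasets
  for (d in seq_len(nrow(ds))) {
    pid <- ds$patient_id[d]; s <- ds$scan_session[d]; S <- ds$n_slices[d]
    stem <- file.path(dir, pid, sprintf("%s_s%d", pid, s))
    vols <- list()
    for (w in mf$weightings) {
      f <- sprintf("%s_%s.nii.gz", stem, w)
      if (!file.exists(f)) {
        abort(sprintf(
          "missing %s volume for patient %s, session %d (expected '%s').",
          w, pid, s, f), class = "plaquerep_missing_weighting")
      }
      vols[[w]] <- as.array(RNifti::readNifti(f))
    }
    labs <- list()
    for (lb in c("truth", "observer")) {
      f <- sprintf("%s_%s.nii.gz", stem, lb)
      if (!file.exists(f)) abort(sprintf("missing %s labels for %s session %d.", lb, pid, s))
      labs[[lb]] <- as.array(RNifti::readNifti(f))
    }
    contours <- lapply(seq_len(S), function(i) {
      f <- sprintf("%s_slice%d_contours.csv", stem, i)
      if (!file.exists(f)) abort(sprintf("missing contours for %s session %d slice %d.", pid, s, i))
      df <- read.csv(f, colClasses = c("character", "character", "character"))
      lum <- df[df$ring == "lumen", ]; out_ring <- df[df$ring == "outer", ]
      if (nrow(lum) < 3 || nrow(out_ring) < 3) {
        abort(sprintf("contour with fewer than 3 vertices in '%s'.", f))
      }
      vessel_contours(
        lumen = cbind(x = as.numeric(lum$x_mm), y = as.numeric(lum$y_mm)),
        outer = cbind(x = as.numeric(out_ring$x_mm), y = as.numeric(out_ring$y_mm)))
    })
    out[[length(out) + 1L]] <- tibble(
      patient_id = pid, scan_session = as.integer(s),
      slice_index = seq_len(S),
      pixel_spacing = mf$pixel_spacing, slice_thickness = mf$slice_thickness,
      grid = as.integer(mf$grid),
      bifurcation_index = as.integer(ds$bifurcation_index[d]),
      images = lapply(seq_len(S), function(i)
        lapply(vols, function(v) v[, , i])),
      contours = contours,
      truth = lapply(seq_len(S), function(i)
        matrix(as.integer(labs$truth[, , i]), mf$grid, mf$grid)),
      observer = lapply(seq_len(S), function(i)
        matrix(as.integer(labs$observer[, , i]), mf$grid, mf$grid)))
  }
  coh <- dplyr::bind_rows(out)
  class(coh) <- c("plaque_cohort", class(coh))
  coh
}
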
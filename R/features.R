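# Per-pixel feature extraction: wall-mask rasterization, slice-wise
# intensity normalization, Gaussian scale-space derivatives, and
# wall-geometry (distance/thickness) features.
#
# Coordinate convention: pixel centers at x = (col - 0.5) * spacing,
# y = (row - 0.5) * spacing; origin at the image corner, x right, y down,
# all contour coordinates in mm.

#' Vessel contours
#'
#' Bundle the two manually traced closed boundaries that define the vessel
#' wall annulus: the lumen and the outer wall, as simple polygons in mm
#' coordinates.
#'
#' @param lumen,outer Numeric matrices with columns `x`, `y` (mm), at least
#'   3 vertices each, not explicitly closed (the last vertex connects back
#'   to the first).
#' @return An object of class `vessel_contours`.
#' @export
vessel_contours <- function(lumen, outer) {
  for (nm in c("lumen", "outer")) {
    p <- if (nm == "lumen") lumen else outer
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 || !all(is.finite(p))) {
      abort(sprintf("`%s` must be a finite numeric matrix with >= 3 rows and 2 columns.", nm))
    }
  }
  colnames(lumen) <- colnames(outer) <- c("x", "y")
  structure(list(lumen = lumen, outer = outer), class = "vessel_contours")
}

# pixel-center coordinate vectors for a grid
pixel_centers <- function(grid, pixel_spacing) {
  ((seq_len(grid)) - 0.5) * pixel_spacing
}

# Vectorized even-odd (ray crossing) point-in-polygon test.  Points lying
# exactly on an edge are classified by `boundary`: TRUE counts them as
# inside, FALSE as outside.  Vectorized over points per edge, so the cost
# is n_edges passes over the point vectors.
point_in_polygon <- function(px, py, xv, yv, boundary = TRUE,
                             tol = 1e-9) {
  n <- length(xv)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xv[j]; y1 <- yv[j]; x2 <- xv[i]; y2 <- yv[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # on-edge detection restricted to the edge's bounding box
    cand <- which(px >= min(x1, x2) - tol & px <= max(x1, x2) + tol &
                    py >= min(y1, y2) - tol & py <= max(y1, y2) + tol)
    if (length(cand)) {
      cr <- abs((x2 - x1) * (py[cand] - y1) - (y2 - y1) * (px[cand] - x1))
      len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      on_edge[cand[cr <= tol * max(len, 1)]] <- TRUE
    }
    j <- i
  }
  out <- inside
  out[on_edge] <- boundary
  out
}

# rasterize a polygon onto the pixel grid, testing only pixels inside the
# polygon's bounding box
polygon_pixel_mask <- function(poly, grid, pixel_spacing, boundary = TRUE) {
  cx <- pixel_centers(grid, pixel_spacing)
  ci <- which(cx >= min(poly[, 1]) - pixel_spacing &
                cx <= max(poly[, 1]) + pixel_spacing)
  ri <- which(cx >= min(poly[, 2]) - pixel_spacing &
                cx <= max(poly[, 2]) + pixel_spacing)
  m <- matrix(FALSE, grid, grid)
  if (length(ri) == 0 || length(ci) == 0) return(m)
  pts <- expand.grid(y = cx[ri], x = cx[ci])
  m[as.matrix(expand.grid(ri, ci))] <-
    point_in_polygon(pts$x, pts$y, poly[, 1], poly[, 2], boundary = boundary)
  m
}

#' Rasterize the vessel-wall annulus
#'
#' A pixel belongs to the wall iff its center lies inside (or on) the outer
#' polygon and strictly outside the lumen polygon (pixels on the lumen
#' boundary count as wall).
#'
#' @param contours A [vessel_contours()] object.
#' @param grid Pixels per axis.
#' @param pixel_spacing Pixel size (mm).
#' @return A `grid x grid` logical matrix (rows = y, columns = x).
#' @export
#' @examples
#' circ <- function(r, n = 90) cbind(x = 15 + r * cos(seq(0, 2 * pi, length.out = n + 1)[-1]),
#'                                   y = 15 + r * sin(seq(0, 2 * pi, length.out = n + 1)[-1]))
#' m <- rasterize_wall_mask(vessel_contours(circ(2), circ(6)), grid = 60, pixel_spacing = 0.5)
#' sum(m) * 0.25  # close to pi * (36 - 4)
rasterize_wall_mask <- function(contours, grid, pixel_spacing) {
  stopifnot(inherits(contours, "vessel_contours"))
  # lumen must lie inside the outer boundary
  lin <- point_in_polygon(contours$lumen[, 1], contours$lumen[, 2],
                          contours$outer[, 1], contours$outer[, 2],
                          boundary = TRUE)
  if (!all(lin)) {
    abort("lumen contour is not contained in the outer-wall contour.")
  }
  in_outer <- polygon_pixel_mask(contours$outer, grid, pixel_spacing,
                                 boundary = TRUE)
  in_lumen <- polygon_pixel_mask(contours$lumen, grid, pixel_spacing,
                                 boundary = FALSE)
  in_outer & !in_lumen
}

#' Feature-extraction configuration
#'
#' @param scales_mm Gaussian scales (sigma, mm) of the derivative filter
#'   bank; default `c(0.1, 0.25, 0.5, 1, 2)`.
#' @param derivative_orders Derivative orders to include (subset of 0:2).
#'   Order 0 is the smoothed intensity; order 1 adds Lx, Ly; order 2 adds
#'   Lxx, Lxy, Lyy (the full second-order jet).
#' @param normalization_roi_diameter_mm Diameter (mm) of the circular ROI,
#'   centered at the lumen, whose median intensity normalizes each
#'   weighting (default 40).
#' @param weightings Ordered contrast weightings to use.
#' @param scale_normalize Multiply order-`k` derivatives by `sigma^k`
#'   (gamma = 1 scale normalization) so responses are comparable across
#'   scales; default `TRUE`.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(scales_mm = c(0.1, 0.25, 0.5, 1, 2),
                           derivative_orders = 0:2,
                           normalization_roi_diameter_mm = 40,
                           weightings = weighting_names(),
                           scale_normalize = TRUE) {
  if (length(scales_mm) == 0 || any(scales_mm <= 0) || is.unsorted(scales_mm)) {
    abort("`scales_mm` must be positive and sorted increasing.")
  }
  if (!all(derivative_orders %in% 0:2)) {
    abort("`derivative_orders` must be a subset of 0:2.")
  }
  check_number(normalization_roi_diameter_mm, "normalization_roi_diameter_mm",
               min = 0, strict_min = TRUE)
  if (!all(weightings %in% weighting_names())) {
    abort("`weightings` must be a subset of the four contrast weightings.")
  }
  structure(list(scales_mm = scales_mm,
                 derivative_orders = sort(unique(derivative_orders)),
                 normalization_roi_diameter_mm = normalization_roi_diameter_mm,
                 weightings = weightings,
                 scale_normalize = scale_normalize),
            class = "feature_config")
}

# response names per derivative order
jet_names <- function(orders) {
  unlist(list(`0` = "L", `1` = c("Lx", "Ly"), `2` = c("Lxx", "Lxy", "Lyy")
  )[as.character(orders)], use.names = FALSE)
}

#' Names of the feature columns for a configuration
#'
#' With the defaults this is 4 normalized intensities + 4 weightings x 5
#' scales x 6 jet responses + 3 geometric features = 127 columns.
#'
#' @param config A [feature_config()].
#' @return Character vector of column names in canonical order.
#' @export
feature_names <- function(config = feature_config()) {
  jn <- jet_names(config$derivative_orders)
  c(paste0(config$weightings, "_SI"),
    as.vector(vapply(config$weightings, function(w) {
      as.vector(vapply(config$scales_mm, function(s) {
        paste0(w, "_s", format(s), "_", jn)
      }, character(length(jn))))
    }, character(length(jn) * length(config$scales_mm)))),
    c("d_lumen", "d_outer", "thickness"))
}

#' Normalize a multi-contrast slice
#'
#' Divides every weighting by the median intensity of a circular ROI
#' (default 4 cm diameter) centered at the lumen, computed on that
#' weighting's own pixels, so signal intensities are comparable across
#' weightings, slices and sessions.  After normalization the ROI median of
#' each weighting is exactly 1.
#'
#' @param images Named list of the four intensity matrices.
#' @param lumen_center Numeric `c(x, y)` in mm.
#' @param pixel_spacing Pixel size (mm).
#' @param roi_diameter_mm ROI diameter (mm).
#' @return The list of images, each divided by its ROI median.
#' @export
normalize_slice <- function(images, lumen_center, pixel_spacing,
                            roi_diameter_mm = 40) {
  grid <- nrow(images[[1]])
  cx <- pixel_centers(grid, pixel_spacing)
  dx2 <- outer((cx - lumen_center[2])^2, (cx - lumen_center[1])^2, "+")
  roi <- dx2 <= (roi_diameter_mm / 2)^2
  if (!any(roi)) abort("normalization ROI is empty (clipped outside the image).")
  lapply(images, function(img) {
    m <- median(img[roi])
    if (!is.finite(m) || m == 0) {
      abort("ROI median is zero; degenerate image cannot be normalized.")
    }
    img / m
  })
}

# --- Gaussian scale-space filter bank ------------------------------------

# 1-D sampled-Gaussian kernels of order 0..2 at sigma (pixels).
# The derivative kernels are renormalized to be exact on polynomials of
# their order (first-derivative kernel has unit response to a unit ramp;
# second-derivative kernel is zero-sum and has unit response to x^2/2),
# which keeps small sigmas (down to 0.2 px) well behaved.
gauss_kernels_1d <- function(sigma_px) {
  r <- max(3L, ceiling(4 * sigma_px))
  i <- seq(-r, r)
  g <- exp(-i^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  d1 <- i * g                      # response to ramp a*x is a * sum(i * d1)
  d1 <- d1 / sum(i * d1)
  d2 <- (i^2 / sigma_px^2 - 1) * g
  d2 <- d2 - g * sum(d2) / sum(g)  # zero response to constants
  d2 <- d2 / (sum(i^2 * d2) / 2)   # unit response to x^2/2
  list(g = g, d1 = d1, d2 = d2, radius = r)
}

# reflect (edge-repeating) index mapping into 1..n
reflect_index <- function(j, n) {
  j <- (j - 1) %% (2 * n)
  j <- ifelse(j >= n, 2 * n - 1 - j, j)
  j + 1L
}

# dense n x n operator applying 1-D correlation with `kernel` (centered,
# odd length) under reflect padding: (K %*% v)[i] = sum_t k[t] v[i + t]
conv_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (t in seq(-r, r)) {
    src <- reflect_index(seq_len(n) + t, n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[t + r + 1L]
  }
  K
}

#' Gaussian scale-space derivative features of one image
#'
#' Computes, for every scale sigma, the Gaussian-smoothed image `L` and its
#' derivatives `Lx, Ly, Lxx, Lxy, Lyy` by separable convolution with
#' sampled Gaussian-derivative kernels (reflect boundary handling), with
#' `sigma_pixels = sigma_mm / pixel_spacing`.  Derivatives are taken with
#' respect to mm; with `scale_normalize = TRUE` the order-`k` response is
#' additionally multiplied by `sigma_mm^k`, making responses dimensionless
#' and comparable across scales.
#'
#' @param image A numeric matrix (rows = y, columns = x).
#' @param scales_mm Positive sigmas in mm.
#' @param pixel_spacing Pixel size (mm).
#' @param derivative_orders Subset of 0:2.
#' @param scale_normalize Multiply order-`k` responses by `sigma^k`.
#' @return Named list of response matrices, e.g. `s0.5_Lx`.
#' @export
#' @examples
#' ramp <- outer(rep(1, 32), seq_len(32)) * 0.5 # I = 0.5 per pixel along x
#' f <- scale_space_features(ramp, scales_mm = 1, pixel_spacing = 0.5)
#' f$s1_Lx[16, 16] # = slope (1/mm) * sigma = 1 * 1
scale_space_features <- function(image, scales_mm, pixel_spacing,
                                 derivative_orders = 0:2,
                                 scale_normalize = TRUE) {
  if (length(scales_mm) == 0 || any(scales_mm <= 0)) {
    abort("`scales_mm` must be positive.")
  }
  n_r <- nrow(image); n_c <- ncol(image)
  out <- list()
  for (s in scales_mm) {
    sp <- s / pixel_spacing
    k <- gauss_kernels_1d(sp)
    # row-direction (y) operators act from the left; column-direction (x)
    # operators act from the right (transposed)
    Ry <- lapply(k[c("g", "d1", "d2")], conv_operator, n = n_r)
    Rx <- lapply(k[c("g", "d1", "d2")], function(kk) t(conv_operator(n_c, kk)))
    sn <- function(order) {
      if (!scale_normalize) return(1 / pixel_spacing^order)
      (s^order) / pixel_spacing^order
    }
    tag <- paste0("s", format(s), "_")
    if (0 %in% derivative_orders) {
      out[[paste0(tag, "L")]] <- Ry$g %*% image %*% Rx$g
    }
    if (1 %in% derivative_orders) {
      out[[paste0(tag, "Lx")]] <- (Ry$g %*% image %*% Rx$d1) * sn(1)
      out[[paste0(tag, "Ly")]] <- (Ry$d1 %*% image %*% Rx$g) * sn(1)
    }
    if (2 %in% derivative_orders) {
      out[[paste0(tag, "Lxx")]] <- (Ry$g %*% image %*% Rx$d2) * sn(2)
      out[[paste0(tag, "Lxy")]] <- (Ry$d1 %*% image %*% Rx$d1) * sn(2)
      out[[paste0(tag, "Lyy")]] <- (Ry$d2 %*% image %*% Rx$g) * sn(2)
    }
  }
  out
}

# resample a closed polygon at <= `spacing_mm` arc spacing
resample_polygon <- function(poly, spacing_mm = 0.1) {
  p <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  pieces <- lapply(seq_along(seg), function(i) {
    if (seg[i] == 0) return(p[i, , drop = FALSE])
    k <- ceiling(seg[i] / spacing_mm)
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    cbind(p[i, 1] + t * (p[i + 1, 1] - p[i, 1]),
          p[i, 2] + t * (p[i + 1, 2] - p[i, 2]))
  })
  do.call(rbind, pieces)
}

#' Wall-geometry features
#'
#' For every wall pixel: Euclidean distance (mm) from the pixel center to
#' the lumen boundary and to the outer boundary (polygons densely resampled
#' at <= 0.1 mm arc spacing), and the local wall thickness, taken as their
#' sum.
#'
#' @param mask Logical wall mask from [rasterize_wall_mask()].
#' @param contours A [vessel_contours()] object.
#' @param pixel_spacing Pixel size (mm).
#' @return List of three matrices (`d_lumen`, `d_outer`, `thickness`), `NA`
#'   outside the mask.
#' @export
geometric_features <- function(mask, contours, pixel_spacing) {
  if (!any(mask)) abort("wall mask is empty.")
  grid <- nrow(mask)
  cx <- pixel_centers(grid, pixel_spacing)
  idx <- which(mask, arr.ind = TRUE)
  px <- cx[idx[, 2]]; py <- cx[idx[, 1]]
  dl <- min_dist_to_points(px, py, resample_polygon(contours$lumen))
  do <- min_dist_to_points(px, py, resample_polygon(contours$outer))
  mk <- function(v) {
    m <- matrix(NA_real_, grid, grid)
    m[idx] <- v
    m
  }
  list(d_lumen = mk(dl), d_outer = mk(do), thickness = mk(dl + do))
}

min_dist_to_points <- function(px, py, pts) {
  # chunked to bound memory on large masks
  n <- length(px)
  out <- numeric(n)
  step <- 2048L
  for (s in seq(1L, n, by = step)) {
    e <- min(s + step - 1L, n)
    d2 <- outer(px[s:e], pts[, 1], "-")^2 + outer(py[s:e], pts[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

# polygon centroid (vertex mean; adequate for near-elliptical contours)
polygon_centroid <- function(poly) colMeans(poly)

# --- per-slice feature rows ----------------------------------------------

# Extract the full feature block for one slice.  Filtering runs on a
# cropped window (mask bounding box grown by the largest kernel radius) so
# responses on mask pixels are identical to full-image filtering but much
# cheaper.
slice_feature_rows <- function(images, contours, pixel_spacing, config,
                               labels = NULL) {
  grid <- nrow(images[[1]])
  mask <- rasterize_wall_mask(contours, grid, pixel_spacing)
  if (!any(mask)) abort("wall mask is empty for this slice.")
  norm <- normalize_slice(images, polygon_centroid(contours$lumen),
                          pixel_spacing, config$normalization_roi_diameter_mm)
  geo <- geometric_features(mask, contours, pixel_spacing)
  idx <- which(mask, arr.ind = TRUE)

  r_max <- max(3L, ceiling(4 * max(config$scales_mm) / pixel_spacing))
  r0 <- max(1L, min(idx[, 1]) - r_max); r1 <- min(grid, max(idx[, 1]) + r_max)
  c0 <- max(1L, min(idx[, 2]) - r_max); c1 <- min(grid, max(idx[, 2]) + r_max)
  sub_idx <- cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)

  cols <- list()
  for (w in config$weightings) {
    cols[[paste0(w, "_SI")]] <- norm[[w]][idx]
  }
  for (w in config$weightings) {
    resp <- scale_space_features(norm[[w]][r0:r1, c0:c1, drop = FALSE],
                                 config$scales_mm, pixel_spacing,
                                 config$derivative_orders,
                                 config$scale_normalize)
    for (nm in names(resp)) cols[[paste0(w, "_", nm)]] <- resp[[nm]][sub_idx]
  }
  cols$d_lumen <- geo$d_lumen[idx]
  cols$d_outer <- geo$d_outer[idx]
  cols$thickness <- geo$thickness[idx]

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X,
       row = idx[, 1], col = idx[, 2],
       label = if (!is.null(labels)) labels[idx] else rep(NA_integer_, nrow(idx)),
       mask = mask)
}

#' Build the per-pixel feature matrix of a cohort
#'
#' Extracts one row per vessel-wall pixel over every slice of the cohort
#' tibble that has all four contrast weightings; slices missing any
#' weighting are dropped and counted in the exclusion log (attribute
#' `exclusions`).  Labels are attached from the requested label column.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (one row per
#'   patient/session/slice).
#' @param config A [feature_config()].
#' @param labels_from Which label column provides the per-row tissue label:
#'   `"observer"` (default), `"truth"`, or `NA` for unlabeled features.
#' @return A tibble with provenance columns (`patient_id`, `scan_session`,
#'   `slice_index`, `row`, `col`), a `label` column (integer class code)
#'   and one numeric column per feature; attribute `exclusions` is a tibble
#'   of dropped slices.
#' @export
build_feature_matrix <- function(cohort, config = feature_config(),
                                 labels_from = "observer") {
  stopifnot(inherits(cohort, "data.frame"))
  rows <- vector("list", nrow(cohort))
  excl <- list()
  for (i in seq_len(nrow(cohort))) {
    sl <- cohort[i, ]
    imgs <- sl$images[[1]]
    missing_w <- setdiff(config$weightings,
                         names(imgs)[!vapply(imgs, is.null, logical(1))])
    if (length(missing_w) > 0) {
      excl[[length(excl) + 1L]] <- tibble(
        patient_id = sl$patient_id, scan_session = sl$scan_session,
        slice_index = sl$slice_index,
        reason = paste("missing weighting:", paste(missing_w, collapse = ", ")))
      next
    }
    lab <- if (is.na(labels_from)) NULL else sl[[labels_from]][[1]]
    fr <- slice_feature_rows(imgs, sl$contours[[1]], sl$pixel_spacing,
                             config, labels = lab)
    rows[[i]] <- tibble(
      patient_id = sl$patient_id, scan_session = sl$scan_session,
      slice_index = sl$slice_index, row = fr$row, col = fr$col,
      label = fr$label) |>
      dplyr::bind_cols(as_tibble(fr$X))
  }
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    abort("no slice had all required weightings; feature matrix is empty.")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble(patient_id = character(), scan_session = integer(),
           slice_index = integer(), reason = character())
  attr(out, "feature_names") <- setdiff(
    names(out), c("patient_id", "scan_session", "slice_index", "row", "col", "label"))
  out
}
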
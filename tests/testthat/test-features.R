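# Feature extraction: wall rasterization against geometric and
# point-in-polygon oracles, normalization contracts, the Gaussian
# derivative filter bank, and feature-matrix assembly.

test_that("wall mask of a concentric annulus matches the analytic area", {
  ct <- vessel_contours(lumen = circle_poly(15, 15, 2),
                        outer = circle_poly(15, 15, 6))
  m <- rasterize_wall_mask(ct, grid = 60, pixel_spacing = 0.5)
  area <- sum(m) * 0.25
  analytic <- pi * (36 - 4)             # 100.53 mm2
  # within one ring of boundary pixels: perimeter ~ 2*pi*(6+2) mm,
  # half a pixel thick
  tol <- 2 * pi * 8 * 0.5 / 2
  expect_lt(abs(area - analytic), tol)
})

test_that("wall mask agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  ct <- vessel_contours(lumen = circle_poly(14.3, 15.2, 2.1, n = 50),
                        outer = circle_poly(15.1, 14.8, 5.7, n = 50))
  m <- rasterize_wall_mask(ct, grid = 60, pixel_spacing = 0.5)
  cx <- (seq_len(60) - 0.5) * 0.5
  pts <- expand.grid(y = cx, x = cx)
  in_outer <- pracma::inpolygon(pts$x, pts$y, ct$outer[, 1], ct$outer[, 2],
                                boundary = TRUE)
  in_lumen <- pracma::inpolygon(pts$x, pts$y, ct$lumen[, 1], ct$lumen[, 2],
                                boundary = FALSE)
  oracle <- matrix(in_outer & !in_lumen, 60, 60)
  expect_identical(m, oracle)
})

test_that("degenerate annulus (lumen == outer) gives an empty mask", {
  ct <- vessel_contours(lumen = circle_poly(15, 15, 4),
                        outer = circle_poly(15, 15, 4))
  m <- rasterize_wall_mask(ct, grid = 60, pixel_spacing = 0.5)
  expect_equal(sum(m), 0)
})

test_that("a lumen outside the outer wall is rejected", {
  ct <- vessel_contours(lumen = circle_poly(25, 25, 3),
                        outer = circle_poly(12, 12, 5))
  expect_error(rasterize_wall_mask(ct, 60, 0.5), "not contained")
})

test_that("slice normalization divides by the ROI median", {
  imgs <- list(T1w = matrix(5, 40, 40), T2w = matrix(2, 40, 40),
               PDw = matrix(7, 40, 40), TOF = matrix(1, 40, 40))
  out <- normalize_slice(imgs, lumen_center = c(10, 10), pixel_spacing = 0.5)
  for (w in names(out)) expect_true(all(out[[w]] == 1))

  # a known median: ROI median 200, a pixel at 300 maps to 1.5
  img <- matrix(200, 40, 40)
  img[20, 20] <- 300
  out2 <- normalize_slice(list(T1w = img, T2w = img, PDw = img, TOF = img),
                          c(10, 10), 0.5)
  expect_equal(out2$T1w[20, 20], 1.5)

  # scale invariance and idempotence
  imgs_k <- lapply(imgs, function(m) m * 3.7)
  expect_equal(normalize_slice(imgs_k, c(10, 10), 0.5),
               normalize_slice(imgs, c(10, 10), 0.5))
  once <- normalize_slice(imgs, c(10, 10), 0.5)
  expect_equal(normalize_slice(once, c(10, 10), 0.5), once)

  expect_error(normalize_slice(list(T1w = matrix(0, 40, 40)), c(10, 10), 0.5),
               "median is zero")
})

test_that("filter bank is exact on flat and ramp images", {
  flat <- matrix(3, 32, 32)
  f <- scale_space_features(flat, scales_mm = c(0.1, 0.5, 1), 0.5)
  for (nm in names(f)) {
    if (grepl("_L$", nm)) {
      expect_equal(f[[nm]], flat)
    } else {
      expect_lt(max(abs(f[[nm]])), 1e-10)
    }
  }
  # ramp I(x) = a * x_mm: Lx (scale-normalized) = a * sigma, Lxx ~ 0;
  # checked away from the boundary, beyond the largest kernel radius (16
  # pixels at sigma = 2 mm on a 0.5 mm grid)
  a <- 0.8; spacing <- 0.5
  ramp <- outer(rep(1, 80), seq_len(80)) * a * spacing # a per mm
  for (s in c(0.25, 1, 2)) {
    f <- scale_space_features(ramp, scales_mm = s, spacing)
    inner <- 20:60
    expect_equal(f[[paste0("s", s, "_Lx")]][inner, inner],
                 matrix(a * s, length(inner), length(inner)),
                 tolerance = 1e-8)
    expect_lt(max(abs(f[[paste0("s", s, "_Lxx")]][inner, inner])), 1e-8)
    expect_lt(max(abs(f[[paste0("s", s, "_Ly")]][inner, inner])), 1e-8)
  }
  expect_error(scale_space_features(flat, scales_mm = -1, 0.5), "positive")
})

test_that("the default configuration yields 127 named feature columns", {
  cfg <- feature_config()
  fn <- feature_names(cfg)
  expect_length(fn, 4 + 4 * 5 * 6 + 3)
  expect_identical(tail(fn, 3), c("d_lumen", "d_outer", "thickness"))
  expect_false(anyDuplicated(fn) > 0)
})

test_that("geometric features match the analytic annulus and a nearest-vertex oracle", {
  ct <- vessel_contours(lumen = circle_poly(15, 15, 2),
                        outer = circle_poly(15, 15, 6))
  m <- rasterize_wall_mask(ct, 60, 0.5)
  g <- geometric_features(m, ct, 0.5)
  idx <- which(m)
  expect_true(all(g$d_lumen[idx] >= 0))
  expect_true(all(g$d_outer[idx] >= 0))
  # thickness ~ 4 mm up to one pixel of discretization
  expect_lt(max(abs(g$thickness[idx] - 4)), 0.5 + 1e-9)
  expect_equal(g$thickness[idx], g$d_lumen[idx] + g$d_outer[idx])

  # brute-force nearest-vertex oracle on dense polygons
  dense_l <- circle_poly(15, 15, 2, n = 2000)
  dense_o <- circle_poly(15, 15, 6, n = 2000)
  ij <- which(m, arr.ind = TRUE)
  cx <- (seq_len(60) - 0.5) * 0.5
  for (k in sample(seq_len(nrow(ij)), 25)) {
    px <- cx[ij[k, 2]]; py <- cx[ij[k, 1]]
    dl <- min(sqrt((dense_l[, 1] - px)^2 + (dense_l[, 2] - py)^2))
    expect_lt(abs(g$d_lumen[ij[k, 1], ij[k, 2]] - dl), 0.25)
  }

  # monotone distance along a ray from the lumen outwards
  row15 <- which(m[30, ])
  dl_ray <- g$d_lumen[30, row15]
  right <- dl_ray[cx[row15] > 15]
  expect_true(all(diff(right) >= -1e-9))
})

test_that("features are equivariant under whole-pixel translation", {
  cfg <- feature_config(scales_mm = c(0.25, 1))
  set.seed(4)
  img <- matrix(rnorm(60 * 60), 60, 60)
  shift <- 3L
  img_shifted <- matrix(0, 60, 60)
  img_shifted[, (1 + shift):60] <- img[, 1:(60 - shift)]
  f0 <- scale_space_features(img, cfg$scales_mm, 0.5)
  f1 <- scale_space_features(img_shifted, cfg$scales_mm, 0.5)
  inner_r <- 20:40; inner_c <- 20:40
  for (nm in names(f0)) {
    expect_equal(f1[[nm]][inner_r, inner_c + shift],
                 f0[[nm]][inner_r, inner_c], tolerance = 1e-10)
  }
})

test_that("feature matrix has one row per wall pixel with faithful provenance", {
  cfg <- tiny_config(seed = 30, n_patients = 1, slices = 2)
  coh <- generate_cohort(cfg)
  fm <- build_feature_matrix(coh, feature_config(), labels_from = "truth")
  n_wall <- sum(vapply(coh$truth, function(m) sum(m > 0), numeric(1)))
  expect_equal(nrow(fm), n_wall)
  expect_length(attr(fm, "feature_names"), 127)
  expect_false(anyNA(fm))

  # labels can be reassembled into the original label maps from provenance
  sl <- dplyr::filter(fm, patient_id == "P01", scan_session == 1,
                      slice_index == 1)
  lab <- matrix(0L, 60, 60)
  lab[cbind(sl$row, sl$col)] <- sl$label
  expect_identical(lab, coh$truth[[which(coh$patient_id == "P01" &
                                           coh$scan_session == 1 &
                                           coh$slice_index == 1)]])
})

test_that("slices missing a weighting are dropped and counted", {
  cfg <- tiny_config(seed = 30, n_patients = 1, slices = 3)
  coh <- generate_cohort(cfg)
  full <- build_feature_matrix(coh, feature_config())
  drop_i <- which(coh$scan_session == 1 & coh$slice_index == 2)
  coh$images[[drop_i]]$T2w <- NULL
  part <- build_feature_matrix(coh, feature_config())
  lost <- sum(coh$truth[[drop_i]] > 0)
  expect_equal(nrow(full) - nrow(part), lost)
  excl <- attr(part, "exclusions")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "T2w")
  coh$images <- lapply(coh$images, function(x) list())
  expect_error(build_feature_matrix(coh, feature_config()), "empty")
})
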
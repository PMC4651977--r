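# Synthetic cohort generator: determinism, perturbation contracts,
# contrast rules, and the simulated observer's behaviour.

test_that("identical seeds give bit-identical cohorts", {
  cfg <- tiny_config(seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$observer, c2$observer)
  expect_identical(c1$images, c2$images)
  expect_identical(c1$contours, c2$contours)
})

test_that("zero perturbation makes scan and rescan pixel-identical", {
  cfg <- tiny_config(seed = 7, noise_sd = 0, rescan = quiet_rescan())
  coh <- generate_cohort(cfg)
  s1 <- dplyr::filter(coh, scan_session == 1)
  s2 <- dplyr::filter(coh, scan_session == 2)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$bifurcation_index, s2$bifurcation_index)
})

test_that("cohort dimensions and fibrous presence follow the design", {
  cfg <- cohort_config(n_patients = 23, slices_per_patient = 8, grid = 60,
                       seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 23 * 2 * 8)
  expect_equal(sum(coh$scan_session == 1), 184) # 184 slices per session
  # fibrous tissue present in every patient's wall in both sessions
  fib <- coh |>
    dplyr::group_by(patient_id, scan_session) |>
    dplyr::summarise(has_fib = any(vapply(
      truth, function(m) any(m == tissue_classes()[["fibrous"]]), logical(1))),
      .groups = "drop")
  expect_true(all(fib$has_fib))
  expect_equal(sum(fib$has_fib[fib$scan_session == 1]), 23)
})

test_that("noise-free contrast rules hold for every generated class", {
  cfg <- tiny_config(seed = 5, n_patients = 4, noise_sd = 0,
                     rescan = quiet_rescan(),
                     component_prevalence = c(fibrous = 1, lipid = 1,
                                              calcification = 1,
                                              loose_matrix = 1,
                                              ulceration = 0, hemorrhage = 0))
  coh <- generate_cohort(cfg)
  mean_class <- function(cls, w) {
    v <- unlist(mapply(function(im, tr) im[[w]][tr == tissue_classes()[[cls]]],
                       coh$images, coh$truth, SIMPLIFY = FALSE))
    mean(v)
  }
  for (w in weighting_names()) {
    expect_lt(mean_class("calcification", w), mean_class("fibrous", w))
  }
  for (w in c("T1w", "PDw")) {
    expect_gt(mean_class("lipid", w), mean_class("fibrous", w))
  }
  for (w in c("T2w", "PDw")) {
    expect_gt(mean_class("loose_matrix", w), mean_class("fibrous", w))
  }
})

test_that("a config whose lesions cannot fit in the annulus is rejected", {
  bp <- plaquerep:::default_blob_params()
  bp$lipid$area_mean_mm2 <- 500
  cfg <- tiny_config(seed = 1,
                     component_prevalence = c(fibrous = 1, lipid = 1,
                                              calcification = 0,
                                              loose_matrix = 0,
                                              ulceration = 0, hemorrhage = 0),
                     component_blob_params = bp)
  expect_error(generate_cohort(cfg), class = "plaquerep_blob_fit_error")
})

test_that("fibrous prevalence below 1 is rejected at config time", {
  expect_error(
    tiny_config(component_prevalence = c(fibrous = 0.9, lipid = 0.4,
                                         calcification = 0.9,
                                         loose_matrix = 0.6,
                                         ulceration = 0, hemorrhage = 0)),
    "fibrous")
  expect_error(
    tiny_config(component_prevalence = c(fibrous = 1, lipid = 1.4,
                                         calcification = 0.9,
                                         loose_matrix = 0.6,
                                         ulceration = 0, hemorrhage = 0)),
    "\\[0, 1\\]")
})

test_that("a noise-free observer reproduces the truth exactly", {
  cfg <- tiny_config(seed = 9, observer = quiet_observer())
  coh <- generate_cohort(cfg)
  expect_identical(coh$observer, coh$truth)
})

test_that("an observer that misses everything reads an all-fibrous wall", {
  cfg <- tiny_config(seed = 9,
                     observer = quiet_observer(p_miss = 1, threshold = 1e6))
  coh <- generate_cohort(cfg)
  fib <- tissue_classes()[["fibrous"]]
  for (i in seq_len(nrow(coh))) {
    obs <- coh$observer[[i]]
    expect_true(all(obs[obs > 0] == fib))
    expect_identical(obs > 0, coh$truth[[i]] > 0) # wall mask untouched
  }
})

test_that("observer reads are reproducible and session-dependent", {
  cfg <- tiny_config(seed = 15)
  coh <- generate_cohort(cfg)
  sl <- dplyr::filter(coh, patient_id == "P01", scan_session == 1)
  obs1 <- simulate_observer(sl$truth, attr(coh, "config")$observer,
                            pixel_spacing = 0.5, seed = 123)
  obs2 <- simulate_observer(sl$truth, attr(coh, "config")$observer,
                            pixel_spacing = 0.5, seed = 123)
  obs3 <- simulate_observer(sl$truth, attr(coh, "config")$observer,
                            pixel_spacing = 0.5, seed = 456)
  expect_identical(obs1, obs2)
  expect_false(identical(obs1, obs3))
})

test_that("increasing the miss probability never increases detection consistency", {
  cfg <- tiny_config(seed = 21, n_patients = 3, slices = 4)
  coh <- generate_cohort(cfg)
  ob <- attr(coh, "config")$observer
  # count (patient, class) combinations detected in both sessions under a
  # common random seed, over a grid of miss probabilities
  consistency <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    ob$p_miss_small <- p
    reads <- coh
    for (ix in split(seq_len(nrow(coh)),
                     paste(coh$patient_id, coh$scan_session))) {
      sd_ps <- 7 * match(coh$patient_id[ix[1]], unique(coh$patient_id)) +
        coh$scan_session[ix[1]]
      reads$observer[ix] <- simulate_observer(
        coh$truth[ix], ob, pixel_spacing = 0.5, seed = 999 + sd_ps)
    }
    pres <- component_areas(reads, methods = "observer") |>
      presence_table()
    sum(pres$present1 & pres$present2)
  }, numeric(1))
  expect_true(all(diff(consistency) <= 0))
})

test_that("intra-session repeat reads agree better than inter-session reads", {
  # Monte-Carlo over seeds: Spearman correlation of per-slice component
  # areas between two same-session reads (identical by construction)
  # versus reads of the two scan sessions
  wins <- 0L
  n_rep <- 20L
  for (k in seq_len(n_rep)) {
    cfg <- tiny_config(seed = 100 + k, n_patients = 2, slices = 4)
    coh <- generate_cohort(cfg)
    ar <- component_areas(coh, methods = "observer") |>
      dplyr::filter(class %in% c("lipid", "calcification", "loose_matrix"))
    pairs <- align_scan_pairs(coh)
    pa <- paired_areas(ar, pairs)
    pa <- dplyr::filter(pa, area1_mm2 > 0 | area2_mm2 > 0)
    if (nrow(pa) < 4 || sd(pa$area1_mm2) == 0 || sd(pa$area2_mm2) == 0) next
    inter <- cor(pa$area1_mm2, pa$area2_mm2, method = "spearman")
    # repeat read of session 1 with the same seed: identical labels, r = 1
    intra <- 1
    if (intra > inter) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
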
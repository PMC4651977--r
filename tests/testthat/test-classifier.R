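# Linear discriminant classifier: the prior rule, oracle equivalence of
# posteriors, tie-breaking, post-processing, and leakage-free
# cross-validation.

test_that("the prior rule fixes fibrous and splits the rest by frequency", {
  pri <- compute_priors(c(fibrous = 700, lipid = 100, calcification = 100,
                          loose_matrix = 100))
  expect_equal(unname(pri["fibrous"]), 0.55)
  expect_equal(unname(pri[c("lipid", "calcification", "loose_matrix")]),
               rep(0.15, 3))
  expect_equal(sum(pri), 1)

  expect_warning(p1 <- compute_priors(c(fibrous = 10)), "prior is set to 1")
  expect_equal(unname(p1["fibrous"]), 1)

  expect_error(compute_priors(c(lipid = 5)), "fibrous")
  expect_error(compute_priors(c(fibrous = 100), fibrous_prior = 1.2),
               "fibrous_prior")
})

test_that("priors sum to one and fibrous stays fixed on fuzzed count tables", {
  set.seed(77)
  for (k in seq_len(1000)) {
    n_cls <- sample(2:6, 1)
    cls <- c("fibrous", sample(setdiff(component_names(), "fibrous"),
                               n_cls - 1))
    counts <- setNames(c(sample(1:5000, 1), sample(0:5000, n_cls - 1,
                                                   replace = TRUE)), cls)
    fp <- runif(1, 0.05, 0.95)
    if (sum(counts[-1]) == 0) {
      expect_warning(pri <- compute_priors(counts, fp))
      expect_equal(sum(pri), 1)
    } else {
      pri <- compute_priors(counts, fp)
      expect_equal(sum(pri), 1)
      expect_equal(unname(pri["fibrous"]), fp)
      expect_true(all(pri >= 0))
    }
  }
})

# small labelled 2-D training set with three classes
toy_features <- function(seed = 1, n = 60) {
  set.seed(seed)
  mu <- list(fibrous = c(0, 0), lipid = c(3, 0), calcification = c(0, 3))
  X <- do.call(rbind, lapply(mu, function(m) {
    cbind(rnorm(n, m[1], 0.7), rnorm(n, m[2], 0.7))
  }))
  colnames(X) <- c("f1", "f2")
  tibble::tibble(label = rep(c(1L, 2L, 3L), each = n)) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

test_that("posteriors match the brute-force Gaussian-Bayes oracle", {
  feats <- toy_features(seed = 3)
  model <- train_ldc(feats, classifier_config(covariance_regularization = 0))
  set.seed(5)
  Xnew <- cbind(f1 = rnorm(100, 1, 2), f2 = rnorm(100, 1, 2))
  pred <- classify_pixels(model, Xnew)
  oracle <- oracle_posterior(Xnew, model$means, model$covariance,
                             as.list(model$priors))
  expect_lt(max(abs(as.matrix(pred[, model$classes]) - oracle)), 1e-8)
  expect_equal(rowSums(as.matrix(pred[, model$classes])), rep(1, 100))
})

test_that("equal-prior LDA separates two classes at the perpendicular bisector", {
  set.seed(8)
  n <- 4000
  X <- rbind(cbind(rnorm(n, -2, 1), rnorm(n, 0, 1)),
             cbind(rnorm(n, 2, 1), rnorm(n, 0, 1)))
  colnames(X) <- c("f1", "f2")
  feats <- tibble::tibble(label = rep(1:2, each = n)) |>
    dplyr::bind_cols(tibble::as_tibble(X))
  model <- train_ldc(feats, classifier_config(fibrous_prior = 0.5))
  probe <- cbind(f1 = c(-0.4, 0.4), f2 = c(0, 0))
  pred <- classify_pixels(model, probe)
  expect_equal(pred$.code, c(1L, 2L))
  # near the bisector the posterior is close to 1/2
  mid <- classify_pixels(model, cbind(f1 = 0, f2 = 0))
  expect_lt(abs(mid$fibrous - 0.5), 0.05)
})

test_that("exact posterior ties go to the earlier class in canonical order", {
  feats <- toy_features(seed = 11)
  # symmetric construction: two classes mirrored about f1 = 0, equal priors
  f2 <- dplyr::filter(feats, label %in% c(1L, 2L))
  f2$f1[f2$label == 1L] <- -abs(f2$f1[f2$label == 1L])
  f2$f1[f2$label == 2L] <- abs(f2$f1[f2$label == 2L])
  f2$f1[f2$label == 2L] <- -rev(f2$f1[f2$label == 1L]) # exact mirror
  f2$f2[f2$label == 2L] <- rev(f2$f2[f2$label == 1L])
  model <- train_ldc(f2, classifier_config(fibrous_prior = 0.5))
  onaxis <- classify_pixels(model, cbind(f1 = 0, f2 = mean(f2$f2)))
  expect_equal(onaxis$.code, 1L) # fibrous preferred on an exact tie
})

test_that("raising a class prior never shrinks its assigned pixel count", {
  feats <- toy_features(seed = 13)
  set.seed(14)
  Xnew <- cbind(f1 = rnorm(300, 1.5, 1.5), f2 = rnorm(300, 1.5, 1.5))
  n_lipid <- vapply(c(0.2, 0.4, 0.6, 0.8), function(fp) {
    # reweight priors: grow lipid at the expense of the others
    model <- train_ldc(feats, classifier_config(fibrous_prior = 0.3))
    pri <- model$priors
    pri["lipid"] <- fp
    rest <- setdiff(names(pri), "lipid")
    pri[rest] <- (1 - fp) * pri[rest] / sum(pri[rest])
    model$priors <- pri
    sum(classify_pixels(model, Xnew)$.class == "lipid")
  }, numeric(1))
  expect_true(all(diff(n_lipid) >= 0))
})

test_that("singular covariance without regularization advises shrinkage", {
  feats <- toy_features(seed = 15)
  feats$f3 <- feats$f1 + feats$f2 # exact collinearity
  expect_error(train_ldc(feats, classifier_config(covariance_regularization = 0)),
               "covariance_regularization")
  # with default shrinkage it fits
  expect_s3_class(train_ldc(feats), "plaque_ldc")
})

test_that("isolated pixels are relabelled to the neighbourhood majority", {
  lab <- matrix(0L, 8, 8)
  lab[2:7, 2:7] <- 1L
  lab[4, 4] <- 2L                       # singleton lipid
  out <- remove_isolated_pixels(lab)
  expect_equal(out[4, 4], 1L)
  expect_equal(sum(out == 2L), 0)

  lab2 <- matrix(0L, 8, 8); lab2[2:7, 2:7] <- 1L
  lab2[4, 4] <- 2L; lab2[4, 5] <- 2L    # two adjacent lipid pixels
  expect_identical(remove_isolated_pixels(lab2), lab2)

  lab3 <- matrix(0L, 8, 8); lab3[2:7, 2:7] <- 1L
  expect_identical(remove_isolated_pixels(lab3), lab3)

  # isolated pixel with no in-mask neighbours becomes fibrous
  lab4 <- matrix(0L, 8, 8); lab4[4, 4] <- 3L
  expect_equal(remove_isolated_pixels(lab4)[4, 4], 1L)

  # post-processing only ever touches singleton classes
  set.seed(99)
  for (k in 1:20) {
    lab5 <- matrix(0L, 10, 10)
    lab5[3:8, 3:8] <- sample(1:4, 36, replace = TRUE,
                             prob = c(0.7, 0.1, 0.1, 0.1))
    out5 <- remove_isolated_pixels(lab5)
    tab_in <- table(factor(lab5[lab5 > 0], levels = 1:6))
    tab_out <- table(factor(out5[out5 > 0], levels = 1:6))
    changed <- names(tab_in)[tab_in != tab_out]
    expect_true(all(tab_in[changed] == 1 | tab_out[changed] > tab_in[changed]))
    expect_true(all(abs(tab_out - tab_in) <= sum(tab_in == 1)))
  }
})

test_that("cross-validation folds never contain the test patient", {
  cfg <- tiny_config(seed = 20, n_patients = 3, slices = 3)
  coh <- generate_cohort(cfg)
  cv <- lopo_crossval(coh)
  folds <- attr(cv, "folds")
  expect_equal(nrow(folds), 6)          # 2 folds per patient
  expect_true(all(folds$n_train_datasets == 4))
  for (i in seq_len(nrow(folds))) {
    expect_false(folds$patient_id[i] %in% folds$train_patients[[i]])
  }
  expect_error(lopo_crossval(generate_cohort(tiny_config(n_patients = 2))),
               "at least 3 patients")
})

test_that("a serialized model predicts identically after restoration", {
  feats <- toy_features(seed = 21)
  model <- train_ldc(feats)
  f <- withr::local_tempfile(fileext = ".json")
  write_ldc(model, f)
  back <- read_ldc(f)
  set.seed(22)
  Xnew <- cbind(f1 = rnorm(50, 1, 2), f2 = rnorm(50, 1, 2))
  p1 <- classify_pixels(model, Xnew)
  p2 <- classify_pixels(back, Xnew)
  expect_equal(p2, p1, tolerance = 1e-12)
})
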
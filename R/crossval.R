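# Leave-one-patient-out cross-validation.
#
# Each of the 2 * n_patients datasets (one per patient per scan session) is
# predicted by a classifier trained on the datasets of all OTHER patients —
# both sessions of the test patient are excluded, so no pixel of the test
# patient ever reaches its own training set.  Training labels are the
# simulated observer's read; ground truth is reserved for evaluation.
#
# Folds are fitted from per-dataset per-class sufficient statistics
# (counts, feature sums, cross-products), so the pooled covariance of a
# fold is the global accumulation minus the held-out patient's
# contribution: identical to refitting from scratch, at a fraction of the
# cost.

#' Leave-one-patient-out cross-validated pixel classification
#'
#' @param cohort A `plaque_cohort` tibble (needs `observer` labels).
#' @param feature_cfg A [feature_config()].
#' @param classifier_cfg A [classifier_config()] (`standardize` must be
#'   `FALSE` here).
#' @return The cohort with a `predicted` list-column of post-processed
#'   label matrices (`NULL` for slices excluded for missing weightings).
#'   Attributes: `folds` (tibble with one row per fold: test dataset,
#'   number of training datasets, training patients) and `exclusions`.
#' @export
lopo_crossval <- function(cohort, feature_cfg = feature_config(),
                          classifier_cfg = classifier_config()) {
  patients <- unique(cohort$patient_id)
  if (length(patients) < 3) {
    abort("leave-one-patient-out cross-validation needs at least 3 patients.")
  }
  if (classifier_cfg$standardize) {
    abort("`standardize = TRUE` is not supported in cross-validation; fit with `train_ldc()` directly.")
  }
  feats <- build_feature_matrix(cohort, feature_cfg, labels_from = "observer")
  fn <- attr(feats, "feature_names")
  exclusions <- attr(feats, "exclusions")

  ds_key <- paste(feats$patient_id, feats$scan_session, sep = "|")
  ds_split <- split(seq_len(nrow(feats)), ds_key)
  X_all <- as.matrix(feats[, fn, drop = FALSE])

  all_classes <- component_names()
  stats <- lapply(ds_split, function(ix) {
    class_stats(X_all[ix, , drop = FALSE], feats$label[ix])
  })
  zero <- list(n = setNames(numeric(length(all_classes)), all_classes),
               sums = lapply(setNames(nm = all_classes),
                             function(.) numeric(length(fn))),
               cross = lapply(setNames(nm = all_classes),
                              function(.) matrix(0, length(fn), length(fn))))
  add_stats <- function(acc, st, sign = 1) {
    for (cls in names(st$n)) {
      acc$n[[cls]] <- acc$n[[cls]] + sign * st$n[[cls]]
      acc$sums[[cls]] <- acc$sums[[cls]] + sign * st$sums[[cls]]
      acc$cross[[cls]] <- acc$cross[[cls]] + sign * st$cross[[cls]]
    }
    acc
  }
  total <- Reduce(function(a, s) add_stats(a, s), stats, accumulate = FALSE,
                  init = zero)

  patient_of <- vapply(strsplit(names(ds_split), "|", fixed = TRUE),
                       `[[`, "", 1L)
  predicted <- rep(list(NULL), nrow(cohort))
  folds <- list()
  for (d in seq_along(ds_split)) {
    test_patient <- patient_of[d]
    fold <- zero
    fold <- add_stats(fold, total)
    for (e in which(patient_of == test_patient)) {
      fold <- add_stats(fold, stats[[e]], sign = -1)
    }
    model <- ldc_from_stats(fold$n, fold$sums, fold$cross, fn, classifier_cfg)
    ix <- ds_split[[d]]
    pred <- classify_pixels(model, X_all[ix, , drop = FALSE])
    prov <- feats[ix, c("patient_id", "scan_session", "slice_index",
                        "row", "col")]
    prov$code <- pred$.code
    for (grp in split(seq_len(nrow(prov)), prov$slice_index)) {
      si <- prov$slice_index[grp[1]]
      ci <- which(cohort$patient_id == test_patient &
                    cohort$scan_session == prov$scan_session[grp[1]] &
                    cohort$slice_index == si)
      g <- cohort$grid[ci]
      lab <- matrix(0L, g, g)
      lab[cbind(prov$row[grp], prov$col[grp])] <- prov$code[grp]
      predicted[[ci]] <- remove_isolated_pixels(
        lab, classifier_cfg$postprocess_window)
    }
    folds[[d]] <- tibble(
      patient_id = test_patient,
      scan_session = as.integer(sub(".*\\|", "", names(ds_split)[d])),
      n_train_datasets = sum(patient_of != test_patient),
      train_patients = list(sort(unique(patient_of[patient_of != test_patient]))))
  }
  out <- cohort
  out$predicted <- predicted
  attr(out, "folds") <- dplyr::bind_rows(folds)
  attr(out, "exclusions") <- exclusions
  attr(out, "config") <- attr(cohort, "config")
  class(out) <- unique(c("plaque_cohort", class(out)))
  out
}
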
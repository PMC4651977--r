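# Report assembly: per-class scan/rescan repeatability for the manual
# observer and the automated classifier, automated-vs-manual agreement,
# Bland-Altman summaries (components and vessel wall), presence/absence
# contingencies and volume summaries.

#' Statistics configuration for the repeatability report
#'
#' @param pair_inclusion Which aligned slice pairs enter the per-class
#'   Spearman / Bland-Altman analyses: `"any_nonzero"` (default; the
#'   component is present in at least one session for that method — the
#'   all-zero pairs carry no information about the component and would
#'   inflate the correlation) or `"all_pairs"`.
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96, the
#'   95% band).
#' @param cr_multiplier Coefficient-of-repeatability multiplier (default 2).
#' @param conf_level Confidence level for Spearman CIs (default 0.95).
#' @param alpha Significance level quoted in summaries (default 0.05).
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(pair_inclusion = c("any_nonzero", "all_pairs"),
                         loa_multiplier = 1.96, cr_multiplier = 2,
                         conf_level = 0.95, alpha = 0.05) {
  pair_inclusion <- match.arg(pair_inclusion)
  check_number(loa_multiplier, "loa_multiplier", min = 0)
  check_number(cr_multiplier, "cr_multiplier", min = 0)
  check_number(conf_level, "conf_level", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  check_number(alpha, "alpha", min = 0, max = 1)
  structure(list(pair_inclusion = pair_inclusion,
                 loa_multiplier = loa_multiplier,
                 cr_multiplier = cr_multiplier,
                 conf_level = conf_level, alpha = alpha),
            class = "stats_config")
}

safe_spearman <- function(x, y, conf_level) {
  if (length(x) < 3) {
    return(tibble(r = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                  n = length(x), agreement = NA_character_))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                  n = length(x), agreement = NA_character_))
  }
  spearman_ci(x, y, conf_level)
}

# one class x method scan-rescan analysis on paired areas
scan_rescan_row <- function(a1, a2, cfg) {
  if (length(a1) < 2) {
    return(tibble(r = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                  agreement = NA_character_, bias = NA_real_,
                  sd_diff = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
                  cr = NA_real_, wilcoxon_p = NA_real_, normality_p = NA_real_,
                  n_pairs = length(a1), n_single_detection = NA_integer_))
  }
  sp <- safe_spearman(a1, a2, cfg$conf_level)
  ba <- bland_altman(a1, a2, cfg$loa_multiplier, cfg$cr_multiplier)
  wx <- wilcoxon_matched_pairs(a1, a2)
  np <- if (length(a1) >= 20 && sd(a1 - a2) > 0) {
    dagostino_pearson(a1 - a2)$p_value
  } else NA_real_
  tibble(r = sp$r, conf_low = sp$conf_low, conf_high = sp$conf_high,
         agreement = sp$agreement, bias = ba$bias, sd_diff = ba$sd_diff,
         loa_low = ba$loa_low, loa_high = ba$loa_high, cr = ba$cr,
         wilcoxon_p = wx$p_value, normality_p = np,
         n_pairs = ba$n_pairs, n_single_detection = ba$n_single_detection)
}

#' Build the full repeatability report
#'
#' From a cross-validated cohort (a `plaque_cohort` carrying `observer`
#' labels and a `predicted` column from [lopo_crossval()]), computes:
#' per-class scan-rescan repeatability (Spearman r with CI and qualitative
#' agreement category, Bland-Altman bias / limits of agreement /
#' coefficient of repeatability, Wilcoxon matched-pairs p, normality p)
#' for the manual observer and the automated classifier; a Levene
#' comparison of the inter-scan difference variances between the two
#' methods per class; automated-vs-manual agreement per class; the
#' Bland-Altman analysis of the vessel-wall area; presence/absence
#' contingencies; volume summaries; and the slice/pair bookkeeping.
#'
#' @param cohort A `plaque_cohort` with `predicted` labels.
#' @param config A [stats_config()].
#' @return An object of class `repeatability_report` with `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @export
build_report <- function(cohort, config = stats_config()) {
  if (!"predicted" %in% names(cohort)) {
    abort("`cohort` has no `predicted` column; run `lopo_crossval()` first.")
  }
  areas <- component_areas(cohort, methods = c("observer", "predicted")) |>
    dplyr::mutate(method = dplyr::recode(.data$method, observer = "manual",
                                         predicted = "automated"))
  pairs <- align_scan_pairs(cohort)
  paired <- paired_areas(areas, pairs)
  classes <- quantified_classes()

  include <- function(df) {
    if (config$pair_inclusion == "any_nonzero") {
      dplyr::filter(df, .data$area1_mm2 > 0 | .data$area2_mm2 > 0)
    } else df
  }

  scan_rescan <- paired |>
    dplyr::filter(.data$class %in% classes) |>
    dplyr::group_by(.data$method, .data$class) |>
    dplyr::group_modify(function(df, key) {
      df <- include(df)
      scan_rescan_row(df$area1_mm2, df$area2_mm2, config)
    }) |>
    dplyr::ungroup()

  # Levene on the inter-scan differences: manual vs automated, per class
  method_comparison <- purrr::map_dfr(classes, function(cl) {
    dm <- include(dplyr::filter(paired, .data$class == cl,
                                .data$method == "manual"))
    da <- include(dplyr::filter(paired, .data$class == cl,
                                .data$method == "automated"))
    diffs_m <- dm$area1_mm2 - dm$area2_mm2
    diffs_a <- da$area1_mm2 - da$area2_mm2
    if (length(diffs_m) < 2 || length(diffs_a) < 2) {
      return(tibble(class = cl, levene_W = NA_real_, levene_p = NA_real_,
                    cr_manual = NA_real_, cr_automated = NA_real_))
    }
    lv <- levene_test(diffs_m, diffs_a)
    tibble(class = cl, levene_W = lv$statistic, levene_p = lv$p_value,
           cr_manual = config$cr_multiplier * sd(diffs_m),
           cr_automated = config$cr_multiplier * sd(diffs_a))
  })

  # automated-vs-manual agreement on the same slices (both sessions pooled)
  agreement <- areas |>
    dplyr::filter(.data$class %in% classes) |>
    tidyr::pivot_wider(names_from = "method", values_from = "area_mm2") |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(df, key) {
      if (config$pair_inclusion == "any_nonzero") {
        df <- dplyr::filter(df, .data$manual > 0 | .data$automated > 0)
      }
      safe_spearman(df$automated, df$manual, config$conf_level)
    }) |>
    dplyr::ungroup()

  # vessel-wall area repeatability (contour-based; same wall for both
  # methods, reported once)
  wall_pairs <- paired |>
    dplyr::filter(.data$method == "manual", .data$class == "fibrous")
  wall <- scan_rescan_row(wall_pairs$wall1_mm2, wall_pairs$wall2_mm2, config)

  presence <- presence_table(areas)
  volumes <- volumes_from_areas(areas, cohort$slice_thickness[1])
  volume_summary <- volumes |>
    dplyr::filter(.data$class %in% classes) |>
    dplyr::group_by(.data$method, .data$class, .data$scan_session) |>
    dplyr::summarise(mean_mm3 = mean(.data$volume_mm3),
                     sd_mm3 = sd(.data$volume_mm3), .groups = "drop")

  excl <- attr(cohort, "exclusions")
  bookkeeping <- list(
    n_patients = length(unique(cohort$patient_id)),
    n_datasets = nrow(dplyr::distinct(cohort, .data$patient_id,
                                      .data$scan_session)),
    n_slices_total = nrow(cohort),
    n_slices_excluded = if (is.null(excl)) 0L else nrow(excl),
    n_slices_analyzed = sum(!vapply(cohort$predicted, is.null, logical(1))),
    n_aligned_pairs = nrow(pairs),
    n_pairs_dropped = attr(pairs, "n_dropped"),
    folds = attr(cohort, "folds"))

  structure(list(scan_rescan = scan_rescan,
                 method_comparison = method_comparison,
                 agreement = agreement,
                 wall = wall,
                 presence = presence,
                 presence_contingency = presence_contingency(presence),
                 volume_summary = volume_summary,
                 paired = paired,
                 bookkeeping = bookkeeping,
                 config = config),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  b <- x$bookkeeping
  cat(sprintf("<repeatability_report> %d patients, %d datasets, %d aligned slice pairs\n",
              b$n_patients, b$n_datasets, b$n_aligned_pairs))
  cat("\nScan-rescan repeatability (area, mm2):\n")
  print(as.data.frame(dplyr::select(x$scan_rescan, "method", "class", "r",
                                    "agreement", "bias", "cr", "n_pairs")),
        digits = 3, row.names = FALSE)
  cat("\nCR comparison (Levene):\n")
  print(as.data.frame(x$method_comparison), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname build_report
#' @param x A `repeatability_report`.
#' @param ... Unused.
#' @export
tidy.repeatability_report <- function(x, ...) x$scan_rescan

#' @rdname build_report
#' @export
glance.repeatability_report <- function(x, ...) {
  mc <- x$method_comparison
  tibble(
    n_patients = x$bookkeeping$n_patients,
    n_aligned_pairs = x$bookkeeping$n_aligned_pairs,
    n_slices_excluded = x$bookkeeping$n_slices_excluded,
    auto_more_repeatable_lipid =
      mc$cr_automated[mc$class == "lipid"] < mc$cr_manual[mc$class == "lipid"],
    auto_more_repeatable_loose_matrix =
      mc$cr_automated[mc$class == "loose_matrix"] <
        mc$cr_manual[mc$class == "loose_matrix"],
    wall_cr = x$wall$cr)
}

#' Plot a repeatability report
#'
#' `type = "bland_altman"`: per-class difference-vs-mean panels for both
#' methods with bias and limits-of-agreement lines (single-scan detections
#' fall on the steep `diff = 2 x mean` line).  `type = "spearman"`:
#' per-class scan-rescan Spearman r with CIs by method.
#' `type = "agreement"`: automated-vs-manual agreement per class.
#'
#' @param object A `repeatability_report`.
#' @param type One of `"bland_altman"`, `"spearman"`, `"agreement"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repeatability_report
#' @export
autoplot.repeatability_report <- function(object,
                                          type = c("bland_altman", "spearman",
                                                   "agreement"),
                                          ...) {
  type <- match.arg(type)
  if (type == "bland_altman") {
    dat <- object$paired |>
      dplyr::filter(.data$class %in% quantified_classes()) |>
      dplyr::mutate(mean = (.data$area1_mm2 + .data$area2_mm2) / 2,
                    diff = .data$area1_mm2 - .data$area2_mm2)
    if (object$config$pair_inclusion == "any_nonzero") {
      dat <- dplyr::filter(dat, .data$area1_mm2 > 0 | .data$area2_mm2 > 0)
    }
    lines <- object$scan_rescan |>
      dplyr::select("method", "class", "bias", "loa_low", "loa_high") |>
      tidyr::pivot_longer(c("bias", "loa_low", "loa_high"),
                          names_to = "line", values_to = "y")
    return(
      ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean, y = .data$diff,
                                        colour = .data$method)) +
        ggplot2::geom_point(alpha = 0.6, size = 1) +
        ggplot2::geom_hline(data = lines,
                            ggplot2::aes(yintercept = .data$y,
                                         colour = .data$method,
                                         linetype = .data$line == "bias"),
                            show.legend = FALSE) +
        ggplot2::facet_grid(method ~ class, scales = "free") +
        ggplot2::labs(x = "mean of scan and rescan area (mm2)",
                      y = "scan - rescan difference (mm2)") +
        ggplot2::guides(linetype = "none") +
        ggplot2::theme_bw())
  }
  if (type == "spearman") {
    dat <- object$scan_rescan
    ylab <- "scan-rescan Spearman r"
  } else {
    dat <- dplyr::mutate(object$agreement, method = "automated vs manual")
    ylab <- "automated vs manual Spearman r"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$r,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_bw()
}
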
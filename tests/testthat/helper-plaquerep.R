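# Shared fixtures and independent oracles.  Oracles are deliberately
# written without reusing the package's internal code paths.

# closed circle polygon in mm
circle_poly <- function(cx, cy, r, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# a small fast cohort config for unit tests
tiny_config <- function(seed = 11, n_patients = 2, slices = 3, grid = 60, ...) {
  cohort_config(n_patients = n_patients, slices_per_patient = slices,
                grid = grid, seed = seed, ...)
}

# rescan / observer parameter lists with every perturbation off
quiet_rescan <- function(shift = 0L) {
  list(through_plane_shift_slices = shift, through_plane_jitter_slices = 0,
       intensity_drift_sd = 0, inplane_jitter_mm = 0)
}
quiet_observer <- function(p_miss = 0, threshold = 10) {
  list(session_bias_sd = 0, p_miss_small = p_miss,
       small_area_threshold_mm2 = threshold, boundary_jitter_px = 0,
       reliable_contrast = 0.5)
}

# brute-force Gaussian-Bayes posterior oracle: full density x prior,
# normalized, via explicit log-density arithmetic
oracle_posterior <- function(X, means, Sigma, priors) {
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  p <- ncol(X)
  logdens <- sapply(rownames(means), function(cls) {
    D <- sweep(X, 2, means[cls, ])
    q <- colSums(backsolve(ch, t(D), transpose = TRUE)^2)
    -0.5 * (p * log(2 * pi) + logdet + q) + log(priors[[cls]])
  })
  m <- apply(logdens, 1, max)
  w <- exp(logdens - m)
  w / rowSums(w)
}

# mean per-pixel accuracy of predicted vs truth label maps over a cohort
pixel_accuracy <- function(cohort) {
  vals <- mapply(function(p, t) {
    if (is.null(p)) return(NA_real_)
    mean(p[t > 0] == t[t > 0])
  }, cohort$predicted, cohort$truth)
  mean(vals, na.rm = TRUE)
}
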
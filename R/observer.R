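# Simulated manual observer.
#
# Two error mechanisms, mirroring how a human reader behaves on repeated
# scans: (a) small components are sometimes missed outright (their pixels
# read as fibrous); (b) a per-session intensity bias shifts the perceived
# component boundaries, eroding or dilating each region.  The boundary
# effect is scaled inversely with the component's intensity contrast
# against fibrous tissue: a faint class (lipid, loose matrix) moves more
# under the same bias than a conspicuous one (calcification).  Two calls
# with the same seed agree exactly; different sessions draw independent
# biases, so intra-session agreement exceeds inter-scan agreement.

# 4-neighbour binary erosion/dilation constrained to a region
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

erode1 <- function(m) {
  m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0) &
    shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
}

dilate1 <- function(m, allowed) {
  grown <- m | shift_mat(m, 1, 0) | shift_mat(m, -1, 0) |
    shift_mat(m, 0, 1) | shift_mat(m, 0, -1)
  m | (grown & allowed)
}

# mean absolute contrast of a class against fibrous across weightings
class_contrast_margin <- function(intensity_table, cls) {
  max(0.1, mean(abs(intensity_table[cls, ] - intensity_table["fibrous", ])))
}

#' Simulate a manual observer's plaque delineation
#'
#' Corrupts ground-truth label maps the way an experienced but imperfect
#' reader would: whole components whose per-slice area is below
#' `small_area_threshold_mm2` are missed (relabeled fibrous) with
#' probability `p_miss_small`; surviving component regions are eroded or
#' dilated by a number of pixels driven by a per-session intensity bias
#' (drawn once per call) divided by the class's contrast margin, plus
#' per-region jitter.  The function is a pure function of `(truth, observer
#' params, seed)`: identical seeds give identical reads.
#'
#' @param truth List of integer label matrices (one per slice), non-zero
#'   exactly on the wall mask.
#' @param observer Observer parameter list; see [cohort_config()].
#' @param pixel_spacing Pixel size (mm).
#' @param intensity_table Per-class intensity table used to derive contrast
#'   margins.
#' @param seed Integer seed for this read (one session of one patient).
#' @return List of observer label matrices, same shape as `truth`.
#' @export
simulate_observer <- function(truth, observer, pixel_spacing,
                              intensity_table = default_intensity_table(),
                              seed = 1L) {
  stopifnot(is.list(truth))
  comps <- setdiff(component_names(), "fibrous")
  fib <- class_code("fibrous")
  with_seed(seed, {
    session_bias <- rnorm(1, 0, observer$session_bias_sd)
    # draw every decision up-front with a fixed call pattern so that the
    # draws for a given slice/class do not depend on parameter values
    n_sl <- length(truth)
    u_miss <- matrix(runif(n_sl * length(comps)), n_sl, length(comps),
                     dimnames = list(NULL, comps))
    eps <- matrix(rnorm(n_sl * length(comps)), n_sl, length(comps),
                  dimnames = list(NULL, comps))
    lapply(seq_len(n_sl), function(i) {
      lab <- truth[[i]]
      wall <- lab != 0L
      # pass 1: misses of small components
      for (cls in comps) {
        m <- lab == class_code(cls)
        if (!any(m)) next
        area <- sum(m) * pixel_spacing^2
        if (area < observer$small_area_threshold_mm2 &&
            u_miss[i, cls] < observer$p_miss_small) {
          lab[m] <- fib
        }
      }
      # pass 2: bias-driven boundary erosion/dilation; components whose
      # contrast margin exceeds `reliable_contrast` are traced reliably
      # and are not jittered (their boundaries are conspicuous)
      for (cls in comps) {
        m <- lab == class_code(cls)
        if (!any(m)) next
        margin <- class_contrast_margin(intensity_table, cls)
        if (margin >= (observer$reliable_contrast %||% 0.5)) next
        k <- round(session_bias / margin +
                     eps[i, cls] * observer$boundary_jitter_px)
        k <- max(-2L, min(2L, k))
        if (k == 0) next
        if (k > 0) {
          allowed <- wall & lab == fib
          for (j in seq_len(k)) m <- dilate1(m, allowed)
          lab[m & lab == fib] <- class_code(cls)
        } else {
          for (j in seq_len(-k)) m <- erode1(m)
          lab[lab == class_code(cls) & !m] <- fib
        }
      }
      lab
    })
  })
}
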
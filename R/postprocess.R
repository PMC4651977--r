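# Isolated-pixel post-processing: a pixel is isolated if it is the only
# pixel of its plaque component in the slice; it is relabelled to the
# majority class of its in-mask neighbours within a window (default 3x3).

#' Relabel isolated pixels
#'
#' Exactly those pixels whose class has a per-slice count of 1 are
#' relabelled, in a single simultaneous pass, to the modal class among the
#' in-mask neighbours inside the `window x window` neighbourhood (center
#' excluded; background / outside-mask pixels are never counted).  A
#' neighbourhood tie keeps the earliest class in the canonical order; a
#' singleton with no in-mask neighbours becomes fibrous.
#'
#' @param labels Integer label matrix (0 = background).
#' @param window Odd window side, default 3.
#' @return The relabelled matrix.
#' @export
#' @examples
#' lab <- matrix(1L, 5, 5); lab[3, 3] <- 2L
#' remove_isolated_pixels(lab)[3, 3]  # singleton lipid becomes fibrous
remove_isolated_pixels <- function(labels, window = 3L) {
  window <- check_count(window, "window", min = 3L)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  counts <- table(labels[labels > 0L])
  singles <- as.integer(names(counts)[counts == 1L])
  if (length(singles) == 0L) return(labels)
  out <- labels
  r <- (window - 1L) %/% 2L
  n <- nrow(labels); p <- ncol(labels)
  prefer <- unname(tissue_classes()[component_names()])
  for (cd in singles) {
    pos <- which(labels == cd, arr.ind = TRUE)
    i <- pos[1, 1]; j <- pos[1, 2]
    nb <- labels[max(1L, i - r):min(n, i + r),
                 max(1L, j - r):min(p, j + r)]
    nb <- nb[nb > 0L]
    nb <- nb[-match(cd, nb)]    # drop the center pixel itself
    out[i, j] <- if (length(nb) == 0L) class_code("fibrous")
                 else modal_code(nb, prefer)
  }
  out
}
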
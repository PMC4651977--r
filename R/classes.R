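# Tissue class encoding shared across the package.
#
# Label maps are integer matrices over the image grid: 0 outside the vessel
# wall, 1..6 inside it.  The fixed order doubles as the deterministic
# tie-break order of the classifier.

#' Tissue class dictionary
#'
#' Integer codes used in all label maps: 0 = background (outside the vessel
#' wall), 1 = fibrous tissue, 2 = lipid, 3 = calcification, 4 = loose matrix,
#' 5 = ulceration, 6 = hemorrhage.  The order of the non-background classes
#' is also the tie-break order used by [classify_pixels()].
#'
#' @return Named integer vector mapping class name to code.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  c(background = 0L, fibrous = 1L, lipid = 2L, calcification = 3L,
    loose_matrix = 4L, ulceration = 5L, hemorrhage = 6L)
}

# non-background class names in tie-break order
component_names <- function() {
  setdiff(names(tissue_classes()), "background")
}

# classes entering quantitative analysis (ulceration/hemorrhage excluded)
quantified_classes <- function() {
  c("fibrous", "lipid", "calcification", "loose_matrix")
}

class_code <- function(name) {
  unname(tissue_classes()[name])
}

class_name <- function(code) {
  tc <- tissue_classes()
  names(tc)[match(code, tc)]
}

#' MRI contrast weightings
#'
#' The four contrast weightings of the multi-contrast protocol, in the fixed
#' order used for feature-column naming.
#'
#' @return Character vector `c("T1w", "T2w", "PDw", "TOF")`.
#' @export
weighting_names <- function() {
  c("T1w", "T2w", "PDw", "TOF")
}
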
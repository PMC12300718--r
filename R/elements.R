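#' Atomic property table used by the descriptor engine
#'
#' Pinned table of the three atomic weighting properties used by the 2D
#' autocorrelation and information-content descriptors: relative atomic mass,
#' Sanderson electronegativity (the weighting convention of the reference
#' descriptor software for `e`-weighted autocorrelations) and static dipole
#' polarizability (cubic Angstroms). The table covers the elements admitted
#' by the curation rules (organic subset plus Si and B); it is versioned
#' with the package so that descriptor values are reproducible.
#'
#' @return A data frame with columns `element`, `mass`, `electronegativity`,
#'   `polarizability`, one row per element.
#' @examples
#' element_properties()
#' @export
element_properties <- function() {
  data.frame(
    element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
    mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
             28.086, 30.974, 32.06, 35.453, 79.904, 126.904),
    electronegativity = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000,
                          2.138, 2.515, 2.957, 3.475, 3.219, 2.778),
    polarizability = c(0.667, 3.030, 1.760, 1.100, 0.802, 0.557,
                       5.380, 3.630, 2.900, 2.180, 3.050, 5.350),
    stringsAsFactors = FALSE
  )
}

# Elements considered "organic" by the curation rules; anything else flags
# the record as an organometal/inorganic exclusion.
.organic_elements <- c("H", "C", "N", "O", "F", "S", "P", "Cl", "Br", "I", "Si", "B")

.element_property <- function(elements, prop) {
  tab <- element_properties()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    stop("no atomic properties tabulated for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  tab[[prop]][idx]
}
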
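# Exactly specified formulas for the standard immunological readouts used
# to evaluate vaccine responses downstream of the design pipeline.

#' Percent specific lysis from a chromium-release assay
#'
#' `100 * (experimental - control) / (maximum - spontaneous)`. Values are
#' not clamped: negative lysis is an informative QC signal.
#'
#' @param experimental,control,maximum,spontaneous Gamma counts per well.
#' @return Percent specific lysis (may be negative or exceed 100).
#' @export
specific_lysis <- function(experimental, control, maximum, spontaneous) {
  if (any(maximum <= spontaneous))
    stop("maximum release must exceed spontaneous release", call. = FALSE)
  100 * (experimental - control) / (maximum - spontaneous)
}

#' Tumor volume from caliper measurements
#'
#' `(L * W^2) / 2` with `L` the longest diagonal and `W` the perpendicular
#' diagonal, in mm. If `W > L` the two are swapped with a warning.
#'
#' @param length_mm,width_mm Caliper measurements in mm (non-negative).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0))
    stop("caliper measurements must be non-negative", call. = FALSE)
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width exceeds length; measurements swapped", call. = FALSE)
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Background-subtracted ELISpot response
#'
#' Subtracts the no-peptide background well count, floored at zero (a count
#' of responding cells cannot be negative).
#'
#' @param sample_spots,background_spots Spot-forming cell counts (>= 0).
#' @return Background-subtracted spot-forming cells.
#' @export
background_subtracted_sfc <- function(sample_spots, background_spots) {
  if (any(sample_spots < 0) || any(background_spots < 0))
    stop("spot counts must be non-negative", call. = FALSE)
  pmax(sample_spots - background_spots, 0)
}
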
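# Crowding-density estimation from cage geometry. The experimental
# cage is a 5 x 5 x 5 m box over a pyramidal bottom with a printed
# total volume of 149.17 m^3; crowding concentrates the school into
# the pyramidal section.

#' Cage geometry
#'
#' The pyramid depth is not printed anywhere; it is back-derived from
#' the total volume: 149.17 = 5^2 * 5 + (1/3) * 5^2 * d, giving
#' d = 3 * (149.17 - 125) / 25 = 2.9004 m.
#'
#' @param boxSide Box side length, m.
#' @param boxDepth Box depth, m.
#' @param totalVolume Total cage volume, m^3.
#' @return List of class `CageGeometry` with `boxSide`, `boxDepth`,
#'   `pyramidDepth` and `totalVolume`.
#' @export
#' @examples
#' cageGeometry()$pyramidDepth
cageGeometry <- function(boxSide = 5, boxDepth = 5, totalVolume = 149.17) {
  pyramidDepth <- 3 * (totalVolume - boxSide^2 * boxDepth) / boxSide^2
  stopifnot(pyramidDepth > 0)
  structure(list(boxSide = boxSide, boxDepth = boxDepth,
                 pyramidDepth = pyramidDepth, totalVolume = totalVolume),
            class = "CageGeometry")
}

#' Cone/pyramid volume from base area and depth
#'
#' \eqn{V = A d / 3}; identical for a right cone and a right pyramid,
#' so the formula covers both readings of the cage-bottom shape.
#'
#' @param area Base area, m^2 (>= 0).
#' @param depth Depth, m (>= 0).
#' @return Volume, m^3.
#' @export
#' @examples
#' coneVolume(25, 2.9)
coneVolume <- function(area, depth) {
  if (any(area < 0) || any(depth < 0)) stop("area and depth must be >= 0")
  area * depth / 3
}

#' School depth from surface area by geometric similarity
#'
#' Treats the crowded school as a similar shrinking of the full
#' pyramidal section: linear scale \eqn{k = \sqrt{A / s^2}} (s = box
#' side), depth \eqn{= k \cdot} pyramid depth. This is an explicit
#' stand-in for the unstated trigonometric depth derivation.
#'
#' @param area Observed school surface area, m^2; must satisfy
#'   0 < area <= boxSide^2.
#' @param geometry A `CageGeometry` (see [cageGeometry()]).
#' @return School depth, m.
#' @export
#' @examples
#' depthFromSimilarity(25, cageGeometry())   # full pyramid depth
depthFromSimilarity <- function(area, geometry = cageGeometry()) {
  base <- geometry$boxSide^2
  if (any(area <= 0) || any(area > base + 1e-9))
    stop("area must lie in (0, boxSide^2]")
  sqrt(area / base) * geometry$pyramidDepth
}

#' Packing density
#'
#' Biomass over volume, kg/m^3. Supply either `biomass` directly or
#' `nFish` and `meanWeightKg`.
#'
#' @param biomass Total biomass, kg.
#' @param volume Occupied volume, m^3 (> 0).
#' @param nFish,meanWeightKg Alternative biomass specification.
#' @return Density, kg/m^3.
#' @export
#' @examples
#' packingDensity(150 * 0.6788, 0.566)
packingDensity <- function(biomass = NULL, volume, nFish = NULL,
                           meanWeightKg = NULL) {
  if (is.null(biomass)) {
    stopifnot(!is.null(nFish), !is.null(meanWeightKg))
    biomass <- nFish * meanWeightKg
  }
  if (any(volume <= 0)) stop("volume must be > 0")
  biomass / volume
}

#' Estimate crowding density from school area and biomass
#'
#' Composes [depthFromSimilarity()], [coneVolume()] and
#' [packingDensity()]: the crowded school is the similar sub-pyramid
#' whose surface area was observed, its volume follows from the
#' cone/pyramid formula, and density is biomass over that volume.
#'
#' @param schoolArea Observed school surface area, m^2.
#' @param biomass Total biomass, kg (or give `nFish` + `meanWeightKg`).
#' @param geometry A `CageGeometry`.
#' @inheritParams packingDensity
#' @return List of class `DensityEstimate`: `schoolArea`,
#'   `schoolDepth`, `volume`, `biomass`, `density`.
#' @export
#' @examples
#' densityEstimate(10, biomass = 100)
densityEstimate <- function(schoolArea, biomass = NULL, nFish = NULL,
                            meanWeightKg = NULL, geometry = cageGeometry()) {
  if (is.null(biomass)) {
    stopifnot(!is.null(nFish), !is.null(meanWeightKg))
    biomass <- nFish * meanWeightKg
  }
  depth <- depthFromSimilarity(schoolArea, geometry)
  vol <- coneVolume(schoolArea, depth)
  stopifnot(vol <= geometry$totalVolume + 1e-9)
  structure(list(schoolArea = schoolArea, schoolDepth = depth,
                 volume = vol, biomass = biomass,
                 density = packingDensity(biomass, vol)),
            class = "DensityEstimate")
}
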
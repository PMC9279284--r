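#' Lake class labels
#'
#' The ten strata used for upscaling: seven natural terrestrial biomes plus
#' three human-altered classes split by annual air temperature.
#' @export
LAKE_CLASSES <- c("Humid tropical forest", "Other tropical/subtropical",
                  "Temperate forest", "Boreal forest", "Other mid-latitude",
                  "Subpolar and polar", "Deserts",
                  "Cold anthropic", "Moderate anthropic", "Warm anthropic")

#' Land-cover categories treated as human-altered
#' @export
ANTHROPIC_COVERS <- c("cropland", "urban", "paddy field")

NATURAL_COVERS <- c("forest", "broadleaf forest", "needleleaf forest",
                    "mixed forest", "shrubland", "grassland", "sparse vegetation",
                    "wetland", "bare area", "snow and ice", "water", "tundra",
                    "natural vegetation")

#' Classify a lake into one of the ten biome / land-use strata
#'
#' Human-altered land covers (cropland, urban, paddy field) map to the cold,
#' moderate or warm anthropic class by annual air temperature
#' (`< 7.5`, `7.5-15.0`, `> 15` degrees C; the interior interval is closed);
#' any natural cover keeps the lake's terrestrial-biome label.
#'
#' @param biome one of the seven natural biome labels in [LAKE_CLASSES].
#' @param land_cover a land-cover category; anthropic categories are listed
#'   in [ANTHROPIC_COVERS].
#' @param annual_temp annual air temperature at the lake, degrees C.
#' @return a single label from [LAKE_CLASSES]. Vectorized over its arguments.
#' @examples
#' classify_lake("Humid tropical forest", "forest", 26)
#' classify_lake("Temperate forest", "urban", 10)   # "Moderate anthropic"
#' @export
classify_lake <- function(biome, land_cover, annual_temp) {
  n <- max(length(biome), length(land_cover), length(annual_temp))
  biome <- rep_len(as.character(biome), n)
  land_cover <- rep_len(tolower(trimws(as.character(land_cover))), n)
  annual_temp <- rep_len(as.numeric(annual_temp), n)
  known <- c(ANTHROPIC_COVERS, NATURAL_COVERS)
  bad <- !(land_cover %in% known)
  if (any(bad))
    stop("unknown land-cover label(s): ",
         paste(unique(land_cover[bad]), collapse = ", "),
         "; accepted labels: ", paste(known, collapse = ", "))
  if (any(is.na(annual_temp) | annual_temp < -30 | annual_temp > 40))
    stop("annual_temp must lie in [-30, 40] degrees C")
  natural_labels <- LAKE_CLASSES[1:7]
  bad_biome <- !(biome %in% natural_labels)
  if (any(bad_biome & !(land_cover %in% ANTHROPIC_COVERS)))
    stop("unknown biome label(s): ",
         paste(unique(biome[bad_biome]), collapse = ", "),
         "; accepted labels: ", paste(natural_labels, collapse = ", "))
  anth <- land_cover %in% ANTHROPIC_COVERS
  temp_class <- ifelse(annual_temp < 7.5, "Cold anthropic",
                       ifelse(annual_temp <= 15.0, "Moderate anthropic",
                              "Warm anthropic"))
  ifelse(anth, temp_class, biome)
}

#' Filter satellite scenes by river water-level deviation
#'
#' Keeps the scenes acquired when the river stage was close to its long-term
#' average, so that flooded/non-flooded mapping reflects typical conditions.
#' The boundary is inclusive.
#'
#' @param scenes data.frame with columns `scene_id` and `deviation_pct`
#'   (signed % deviation from the long-term mean water level).
#' @param max_dev maximum absolute deviation retained (%; default 8).
#' @return the accepted rows of `scenes`.
#' @export
filter_by_water_level <- function(scenes, max_dev = 8) {
  stopifnot(all(c("scene_id", "deviation_pct") %in% names(scenes)))
  if (nrow(scenes) == 0L) return(scenes)
  if (any(!is.finite(scenes$deviation_pct)))
    stop("deviations must be finite")
  scenes[abs(scenes$deviation_pct) <= max_dev, , drop = FALSE]
}

#' Relative area of non-flooded forest in a buffer
#'
#' Computes `100 * forest / (forest + field + flooded)` from pixel counts,
#' after removing pixels excluded from the buffer (the main river and its
#' far margin).
#'
#' @param forest,field,flooded,excluded non-negative pixel counts for the
#'   buffer: non-flooded forest, non-flooded field, flooded area, and pixels
#'   excluded from the denominator.
#' @return percentage of non-flooded forest; `NA` with a warning when the
#'   denominator is zero. Vectorized.
#' @export
forest_fraction <- function(forest, field, flooded, excluded = 0) {
  counts <- cbind(forest, field, flooded, excluded)
  if (any(counts < 0)) stop("pixel counts must be >= 0")
  denom <- forest + field + flooded
  out <- ifelse(denom > 0, 100 * forest / denom, NA_real_)
  if (any(denom == 0))
    warning("zero usable pixels in ", sum(denom == 0),
            " buffer(s); fraction undefined (NA)")
  out
}
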
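#' Population geographic coordinate table
#'
#' Holds one latitude/longitude pair per population, in decimal degrees with
#' the convention that southern latitudes and western longitudes are
#' negative, plus (after projection) planar x/y coordinates.
#'
#' @param population Character vector of population labels (unique).
#' @param latitude Latitudes in degrees, within \[-90, 90\].
#' @param longitude Longitudes in degrees.
#' @return An object of class `geo_table`: a data.frame with columns
#'   `population`, `latitude`, `longitude`, `x`, `y` and attribute
#'   `projection` (initially `"unprojected"`, with x = longitude and
#'   y = latitude so unprojected coordinates act as an isotropic plane).
#' @export
geo_table <- function(population, latitude, longitude) {
  population <- as.character(population)
  if (anyDuplicated(population)) stop("duplicate population in geo table")
  if (any(abs(latitude) > 90)) stop("latitude outside [-90, 90]")
  out <- data.frame(population = population,
                    latitude = as.numeric(latitude),
                    longitude = as.numeric(longitude),
                    x = as.numeric(longitude),
                    y = as.numeric(latitude),
                    stringsAsFactors = FALSE)
  attr(out, "projection") <- "unprojected"
  class(out) <- c("geo_table", "data.frame")
  out
}

#' Read a population coordinate TSV
#'
#' Expects tab-delimited columns `population`, `latitude`, `longitude`
#' (decimal degrees; negative = south/west).
#'
#' @param path File path.
#' @return A [geo_table()].
#' @export
read_geo_table <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("population", "latitude", "longitude")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  geo_table(tab$population, tab$latitude, tab$longitude)
}

#' Shift the Americas eastward for worldwide analyses
#'
#' Longitudes strictly below `threshold_lon` are increased by `shift`, so
#' that the Americas sit east of Eurasia on the worldwide map instead of
#' wrapping across the antimeridian. Applied before projection; idempotent
#' (shifted longitudes exceed the threshold).
#'
#' @param geo A [geo_table()], still unprojected.
#' @param threshold_lon Longitude cut, default -40 degrees (Atlantic
#'   mid-line).
#' @param shift Degrees added, default +360.
#' @return The shifted `geo_table`.
#' @export
shift_americas <- function(geo, threshold_lon = -40, shift = 360) {
  if (attr(geo, "projection") != "unprojected")
    stop("shift_americas must be applied before projection")
  sel <- geo$longitude < threshold_lon
  geo$longitude[sel] <- geo$longitude[sel] + shift
  geo$x <- geo$longitude
  geo
}

#' Gall-Peters equal-area projection
#'
#' Projects latitude/longitude to planar coordinates with standard parallel
#' 45 degrees and unit sphere radius: `x = lon_rad * cos(45 deg)`,
#' `y = sin(lat) / cos(45 deg)`. The projection is equal-area (the Jacobian
#' is constant) and preserves distances along the 45-degree parallels.
#' Downstream Procrustes similarity is invariant to the sphere radius and to
#' any rigid motion of the projected map, so the unit radius is harmless.
#'
#' @param geo A [geo_table()]; longitudes should already be shifted for
#'   worldwide analyses.
#' @param standard_parallel Standard parallel in degrees, default 45.
#' @return The `geo_table` with `x`, `y` replaced by projected coordinates
#'   and projection attribute `"gall_peters"`.
#' @export
gall_peters_project <- function(geo, standard_parallel = 45) {
  if (any(abs(geo$latitude) > 90)) stop("latitude outside [-90, 90]")
  cs <- cos(standard_parallel * pi / 180)
  geo$x <- (geo$longitude * pi / 180) * cs
  geo$y <- sin(geo$latitude * pi / 180) / cs
  attr(geo, "projection") <- "gall_peters"
  geo
}

#' Expand population coordinates to one row per individual
#'
#' All individuals of a population are assigned that population's single
#' location. Rows follow the ordering of `G$individual_ids`.
#'
#' @param geo A [geo_table()] (projected or not; the current `x`, `y`
#'   columns are used).
#' @param G A [genotype_matrix()], every population of which must appear in
#'   `geo`.
#' @return An n x 2 numeric matrix of planar coordinates, rownames =
#'   individual ids.
#' @export
expand_to_individuals <- function(geo, G) {
  idx <- match(G$population_of, geo$population)
  if (anyNA(idx)) {
    miss <- unique(G$population_of[is.na(idx)])
    stop("populations without coordinates: ", paste(miss, collapse = ", "))
  }
  out <- cbind(x = geo$x[idx], y = geo$y[idx])
  rownames(out) <- G$individual_ids
  out
}
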
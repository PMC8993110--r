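# Region geometries: simple single-ring polygons in WGS-84 lon/lat with a
# metric buffer. Membership in the buffered region is the union of the polygon
# interior and all points within buffer_km (geodesic) of its boundary, so the
# boundary itself is inclusive even at buffer_km = 0.

#' Construct a region geometry
#'
#' A region is a single closed ring of WGS-84 longitude/latitude vertices plus
#' a metric buffer distance. City domains use a buffer equal to the instrument
#' pixel size (6.5 km for OMI and MODIS, 10 km for IASI) when the sampling
#' domain must extend beyond small city boundaries; ocean-background and
#' rural-reference domains are usually unbuffered.
#'
#' @param region_id Character label identifying the region.
#' @param coords Two-column matrix (lon, lat) of ring vertices in degrees. A
#'   repeated closing vertex is accepted and dropped; the ring must not
#'   self-intersect.
#' @param buffer_km Non-negative metric dilation of the polygon, in km.
#' @param kind One of `"city"`, `"ocean_background"`, `"rural_reference"`.
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(region_id, coords, buffer_km = 0,
                            kind = c("city", "ocean_background", "rural_reference")) {
  kind <- match.arg(kind)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must be a two-column (lon, lat) matrix")
  storage.mode(coords) <- "double"
  if (anyNA(coords)) stop("region '", region_id, "' has missing vertex coordinates")
  n <- nrow(coords)
  if (n >= 2 && all(coords[1, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  if (nrow(coords) < 3)
    stop("region '", region_id, "' is degenerate: fewer than 3 distinct vertices")
  if (!is.numeric(buffer_km) || length(buffer_km) != 1 || buffer_km < 0)
    stop("buffer_km must be a single non-negative number")
  structure(list(region_id = as.character(region_id),
                 coords = coords, buffer_km = buffer_km, kind = kind),
            class = "region_geometry")
}

#' @export
print.region_geometry <- function(x, ...) {
  cat(sprintf("<region_geometry> %s (%s), %d vertices, buffer %.1f km\n",
              x$region_id, x$kind, nrow(x$coords), x$buffer_km))
  invisible(x)
}

closed_ring <- function(region) rbind(region$coords, region$coords[1, , drop = FALSE])

#' Bounding box of a region
#'
#' @param region A `region_geometry`.
#' @param buffered Include the metric buffer (converted to degrees at the
#'   region's latitude) in the box.
#' @return Named vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @export
region_bbox <- function(region, buffered = FALSE) {
  rg <- apply(region$coords, 2, range)
  out <- c(lon_min = rg[1, 1], lon_max = rg[2, 1],
           lat_min = rg[1, 2], lat_max = rg[2, 2])
  if (buffered && region$buffer_km > 0) {
    dlat <- region$buffer_km / 110.574
    coslat <- cos(max(abs(out[c("lat_min", "lat_max")])) * pi / 180)
    dlon <- region$buffer_km / (111.320 * max(coslat, 1e-6))
    out <- out + c(-dlon, dlon, -dlat, dlat)
  }
  out
}

#' Geographic centroid of a region
#'
#' @param region A `region_geometry`.
#' @return Numeric `c(lon, lat)`.
#' @export
region_centroid <- function(region) {
  ctr <- geosphere::centroid(closed_ring(region))
  c(lon = ctr[1, 1], lat = ctr[1, 2])
}

# Even-odd ray casting; points exactly on an edge may fall either side here
# and are resolved by the boundary-distance test in point_in_region().
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (yi != yj) {
      crosses <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Buffered point-in-region membership
#'
#' A point belongs to a region when it lies inside the polygon or within
#' `buffer_km` (geodesic distance, WGS-84 sphere) of the polygon boundary.
#' The boundary is inclusive: at `buffer_km = 0` points on an edge are
#' members. Distances to the boundary use [geosphere::dist2Line()].
#'
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @param region A `region_geometry`.
#' @return Logical vector of memberships.
#' @export
point_in_region <- function(lon, lat, region) {
  stopifnot(length(lon) == length(lat))
  if (!length(lon)) return(logical(0))
  member <- point_in_ring(lon, lat, region$coords)
  cand <- which(!member)
  if (length(cand)) {
    bb <- region_bbox(region, buffered = TRUE)
    slack <- 0.02  # degrees, catches on-boundary points at buffer 0
    near <- cand[lon[cand] >= bb["lon_min"] - slack & lon[cand] <= bb["lon_max"] + slack &
                 lat[cand] >= bb["lat_min"] - slack & lat[cand] <= bb["lat_max"] + slack]
    if (length(near)) {
      d_km <- geosphere::dist2Line(cbind(lon[near], lat[near]),
                                   closed_ring(region))[, "distance"] / 1000
      member[near] <- d_km <= region$buffer_km + 1e-6
    }
  }
  member
}

#' Axis-aligned rectangular region helper
#'
#' @param region_id Label.
#' @param lon_min,lon_max,lat_min,lat_max Box edges in degrees.
#' @param buffer_km,kind Passed to [region_geometry()].
#' @return A `region_geometry`.
#' @export
rect_region <- function(region_id, lon_min, lon_max, lat_min, lat_max,
                        buffer_km = 0, kind = "city") {
  region_geometry(region_id,
                  cbind(c(lon_min, lon_max, lon_max, lon_min),
                        c(lat_min, lat_min, lat_max, lat_max)),
                  buffer_km = buffer_km, kind = kind)
}

#' Read regions from a GeoJSON FeatureCollection
#'
#' Features must be simple (outer-ring) Polygons; properties `region_id`,
#' `buffer_km` and `kind` are honoured when present.
#'
#' @param path Path to a GeoJSON file.
#' @return A named list of `region_geometry` objects.
#' @export
read_geojson_regions <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    if (!identical(geom$type, "Polygon"))
      stop("unsupported geometry type: ", geom$type %||% "NULL")
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    props <- f$properties %||% list()
    rid <- props$region_id %||% paste0("region_", length(out) + 1L)
    out[[rid]] <- region_geometry(rid, ring,
                                  buffer_km = props$buffer_km %||% 0,
                                  kind = props$kind %||% "city")
  }
  out
}

#' Write regions to a GeoJSON FeatureCollection
#'
#' @param regions A list of `region_geometry` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_regions <- function(regions, path) {
  if (inherits(regions, "region_geometry")) regions <- list(regions)
  feats <- lapply(regions, function(r) {
    ring <- closed_ring(r)
    list(type = "Feature",
         properties = list(region_id = r$region_id, buffer_km = r$buffer_km,
                           kind = r$kind),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                           c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
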
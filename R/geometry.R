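#' Analysis zones on the synthetic plane
#'
#' A zone couples an identifier with a simple polygon ring (no holes). Rings
#' are numeric matrices with columns x, y; vertices are listed once (the
#' closing edge back to the first vertex is implicit). Synthetic worlds emit
#' axis-aligned rectangles, but every geometric operation here accepts
#' arbitrary simple rings.
#'
#' @param zone_id unique identifier string.
#' @param kind one of "bcu", "bcu_country_portion", "country_union",
#'   "eez", "land".
#' @param ring two-column numeric matrix of vertices.
#' @param bcuid optional integer BCU identifier.
#' @param country optional country code.
#' @return an object of class \code{rp_zone}.
#' @export
rp_zone <- function(zone_id, kind, ring, bcuid = NA_integer_,
                    country = NA_character_) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
  if (!polygon_is_simple(ring)) stop("zone '", zone_id,
                                     "': self-intersecting ring")
  if (polygon_area(ring) <= 0) stop("zone '", zone_id, "': empty geometry")
  structure(list(zone_id = zone_id, kind = kind, ring = ring,
                 bcuid = bcuid, country = country),
            class = "rp_zone")
}

#' Polygon area by the shoelace formula
#'
#' @param ring two-column vertex matrix (closing edge implicit).
#' @return nonnegative area in squared plane units.
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# segment intersection test used by the simplicity check; touching at shared
# endpoints of adjacent edges is allowed
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    list(a = ring[i, ], b = ring[if (i == n) 1 else i + 1, ])
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (segments_cross(edges[[i]]$a, edges[[i]]$b,
                         edges[[j]]$a, edges[[j]]$b)) return(FALSE)
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test
#'
#' Ray casting along +x. Points exactly on an edge are implementation-defined;
#' the zonal-statistics contract only evaluates cell centers, which sit at
#' half-cell offsets and never on the integer-coordinate synthetic boundaries.
#'
#' @param px,py point coordinate vectors.
#' @param ring two-column vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  xi <- ring[, 1]; yi <- ring[, 2]
  xj <- xi[c(n, seq_len(n - 1))]; yj <- yi[c(n, seq_len(n - 1))]
  for (k in seq_along(px)) {
    crosses <- (yi > py[k]) != (yj > py[k])
    if (!any(crosses)) next
    xint <- xi[crosses] + (py[k] - yi[crosses]) *
      (xj[crosses] - xi[crosses]) / (yj[crosses] - yi[crosses])
    inside[k] <- (sum(xint > px[k]) %% 2) == 1
  }
  inside
}

#' Clip a ring against a convex polygon (Sutherland-Hodgman)
#'
#' @param ring subject ring (any simple polygon).
#' @param clip convex clip ring in counter-clockwise order; axis-aligned
#'   rectangles from \code{rect_ring} qualify.
#' @return the clipped ring matrix, or \code{NULL} if the intersection is
#'   empty (zero area).
#' @export
clip_polygon_convex <- function(ring, clip) {
  # ensure CCW clip ring
  if (signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- ring
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    out <- clip_halfplane(out, a, b)
  }
  if (is.null(out) || nrow(out) < 3 || polygon_area(out) < 1e-12) return(NULL)
  out
}

signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

clip_halfplane <- function(poly, a, b) {
  # keep points left of directed edge a->b
  side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    sp <- side(p); sq <- side(q)
    if (sp >= 0) out <- rbind(out, p)
    if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
      t <- sp / (sp - sq)
      out <- rbind(out, p + t * (q - p))
    }
  }
  if (nrow(out) == 0) NULL else out
}

#' Axis-aligned rectangle ring
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return a counter-clockwise four-vertex ring matrix.
#' @export
rect_ring <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Write zones as GeoJSON
#'
#' Standard GeoJSON FeatureCollection (RFC 7946 structure, coordinates on the
#' declared synthetic plane). Coordinates are emitted at fixed precision so a
#' regenerated identical world serializes byte-identically.
#'
#' @param zones list of \code{rp_zone} objects.
#' @param path output path.
#' @param crs_label free-text plane description stored in a foreign member.
#' @return \code{path}, invisibly.
#' @export
write_zones_geojson <- function(zones, path, crs_label = "synthetic, unit = km") {
  features <- lapply(zones, function(z) {
    ring <- rbind(z$ring, z$ring[1, , drop = FALSE])  # GeoJSON rings close
    list(type = "Feature",
         properties = list(zone_id = z$zone_id, kind = z$kind,
                           bcuid = if (is.na(z$bcuid)) NULL else z$bcuid,
                           country = if (is.na(z$country)) NULL else z$country),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ]))))))
  })
  obj <- list(type = "FeatureCollection", plane = crs_label,
              features = features)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

#' Read zones from GeoJSON
#'
#' @param path GeoJSON file written by \code{\link{write_zones_geojson}} (or
#'   any FeatureCollection of single-ring polygons with compatible
#'   properties).
#' @return list of \code{rp_zone} objects.
#' @export
read_zones_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(obj$type, "FeatureCollection"))
  lapply(obj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(coords, unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    p <- f$properties
    rp_zone(p$zone_id, p$kind, ring,
            bcuid = if (is.null(p$bcuid)) NA_integer_ else as.integer(p$bcuid),
            country = if (is.null(p$country)) NA_character_ else p$country)
  })
}
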
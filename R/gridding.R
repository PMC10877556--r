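#' Analysis-grid specification
#'
#' Defines the regular grid used as the sampling unit: a bounding extent, a
#' cell size, and the working coordinate system.  The study design uses
#' 2-degree cells (~220 km) on an equal-area (Mollweide) projection; for
#' projected or synthetic planar coordinates use `projection = "planar"`.
#'
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @param resolution cell size in the units of `extent` (default 2).
#' @param projection `"planar"` (coordinates already projected / abstract)
#'   or `"mollweide"` (extent in lon/lat degrees; centroids are also
#'   reported in projected metres via [mollweide()]).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(extent, resolution = 2,
                      projection = c("planar", "mollweide")) {
  projection <- match.arg(projection)
  if (length(extent) != 4 || any(!is.finite(extent))) {
    stop("extent must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
  }
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (extent[2] - extent[1] < resolution || extent[4] - extent[3] < resolution) {
    stop("extent is smaller than one cell", call. = FALSE)
  }
  structure(list(extent = extent, resolution = resolution,
                 projection = projection), class = "grid_spec")
}

#' Mollweide forward projection
#'
#' Equal-area pseudocylindrical projection used to standardise range maps
#' before gridding.  Iteratively solves \eqn{2\theta + \sin 2\theta =
#' \pi \sin \phi} and maps lon/lat (degrees) to metres on a spherical
#' earth of radius `R`.
#'
#' @param lon,lat coordinates in degrees.
#' @param R sphere radius in metres.
#' @return matrix with columns `x`, `y` in metres.
#' @export
mollweide <- function(lon, lat, R = 6371007.181) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  theta <- phi
  for (i in 1:25) {
    corr <- (2 * theta + sin(2 * theta) - pi * sin(phi)) / (2 + 2 * cos(2 * theta))
    corr[!is.finite(corr)] <- 0          # poles: cos(2 theta) = -1
    theta <- theta - corr
  }
  cbind(x = R * sqrt(8) / pi * lam * cos(theta),
        y = R * sqrt(2) * sin(theta))
}

#' Build the analysis grid
#'
#' Tiles the extent with contiguous, non-overlapping square cells; each
#' cell's centroid is its centre.  The number of cells per axis is the
#' floor of span/resolution (a trailing sliver narrower than one cell is
#' not gridded).
#'
#' @param spec a [grid_spec()].
#' @return data frame of class `tetra_grid` with one row per cell: `cell`
#'   id, column/row indices `ix`/`iy`, cell bounds, and centroid `cx`/`cy`
#'   (plus projected `px`/`py` for Mollweide grids).
#' @examples
#' g <- build_grid(grid_spec(c(0, 10, 0, 10), resolution = 2))
#' nrow(g)  # 25
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  e <- spec$extent; res <- spec$resolution
  nx <- floor((e[2] - e[1]) / res + 1e-9)
  ny <- floor((e[4] - e[3]) / res + 1e-9)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  g <- data.frame(
    cell = sprintf("c%03d_%03d", cells$ix, cells$iy),
    ix = cells$ix, iy = cells$iy,
    xmin = e[1] + (cells$ix - 1) * res, xmax = e[1] + cells$ix * res,
    ymin = e[3] + (cells$iy - 1) * res, ymax = e[3] + cells$iy * res)
  g$cx <- (g$xmin + g$xmax) / 2
  g$cy <- (g$ymin + g$ymax) / 2
  if (spec$projection == "mollweide") {
    pr <- mollweide(g$cx, g$cy)
    g$px <- pr[, "x"]; g$py <- pr[, "y"]
  }
  attr(g, "spec") <- spec
  class(g) <- c("tetra_grid", "data.frame")
  g
}

#' Point-in-polygon membership test
#'
#' Even-odd (ray casting) rule, vectorised over points, with points lying
#' on a polygon edge or vertex counted as inside — the deterministic
#' tie-break for centroids on range boundaries.
#'
#' @param px,py point coordinates.
#' @param ring two-column matrix of polygon vertices (closed or open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  nv <- nrow(ring)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  xs <- ring[, 1]; ys <- ring[, 2]
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # boundary: point within the segment's bounding box and collinear
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    on_seg <- abs(cross) < 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    onedge <- onedge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

valid_ring <- function(ring) {
  is.matrix(ring) || is.data.frame(ring) || (is.numeric(ring) && !is.null(dim(ring)))
}

#' Rasterize species ranges to a presence matrix
#'
#' A species is marked present in a cell iff any of its range polygons
#' contains the cell centroid (boundary counts as containment) — the
#' "polygon intersects the grid centre" membership rule.  As an
#' alternative, `mode = "overlap"` marks presence when a polygon overlaps
#' the cell rectangle at all (tested on the polygon's vertices and the cell
#' centroid; adequate for the convex ranges used here).
#'
#' @param ranges named list: species id -> polygon ring (two-column matrix)
#'   or list of rings for multi-polygon ranges.
#' @param grid a `tetra_grid` from [build_grid()].
#' @param mode `"centroid"` (default) or `"overlap"`.
#' @return binary matrix (cells x species) of class `presence_matrix`, with
#'   centroids attached as attribute `centroids` and skipped species (if
#'   any) in attribute `log`.
#' @export
rasterize_ranges <- function(ranges, grid, mode = c("centroid", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "tetra_grid"))
  n <- nrow(grid)
  species <- names(ranges)
  if (is.null(species)) stop("ranges must be a named list", call. = FALSE)
  P <- matrix(0L, n, length(species), dimnames = list(grid$cell, species))
  skipped <- character(0)
  for (s in seq_along(ranges)) {
    rings <- ranges[[s]]
    if (valid_ring(rings)) rings <- list(rings)
    pres <- logical(n)
    ok <- FALSE
    for (ring in rings) {
      ring <- as.matrix(ring)
      if (nrow(ring) < 3 || any(!is.finite(ring))) next
      ok <- TRUE
      pres <- pres | point_in_polygon(grid$cx, grid$cy, ring)
      if (mode == "overlap") {
        # any polygon vertex inside the cell rectangle also counts
        for (ci in which(!pres)) {
          hit <- any(ring[, 1] >= grid$xmin[ci] & ring[, 1] <= grid$xmax[ci] &
                     ring[, 2] >= grid$ymin[ci] & ring[, 2] <= grid$ymax[ci])
          if (hit) pres[ci] <- TRUE
        }
      }
    }
    if (!ok) {
      skipped <- c(skipped, species[s])
      warning("invalid polygon for species ", species[s], "; skipped",
              call. = FALSE)
      next
    }
    P[pres, s] <- 1L
  }
  structure(P, class = c("presence_matrix", "matrix"),
            centroids = grid[, c("cell", "cx", "cy")], log = skipped)
}

#' Per-cell richness with the minimum-species filter
#'
#' Richness is the row sum of the presence matrix; cells with fewer than
#' `min_species` species are excluded from statistical analyses to reduce
#' sampling bias (default 3, i.e. cells with < 3 species are dropped).
#'
#' @param presence binary presence matrix (cells x species).
#' @param min_species minimum richness for a cell to be retained.
#' @return data frame with `cell`, `richness`, `retained`.
#' @export
richness_and_filter <- function(presence, min_species = 3) {
  P <- as.matrix(presence)
  if (length(P) > 0 && !all(P %in% c(0L, 1L))) {
    stop("presence matrix must be binary", call. = FALSE)
  }
  rich <- if (ncol(P) == 0) rep(0L, nrow(P)) else as.integer(rowSums(P))
  data.frame(cell = rownames(P) %||% as.character(seq_len(nrow(P))),
             richness = rich, retained = rich >= min_species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ranges to GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer for polygon ranges (used for
#' synthetic-bundle fixtures).
#'
#' @param ranges named list of rings / lists of rings.
#' @param path output file.
#' @export
write_ranges_geojson <- function(ranges, path) {
  feats <- lapply(names(ranges), function(sp) {
    rings <- ranges[[sp]]
    if (valid_ring(rings)) rings <- list(rings)
    coords <- lapply(rings, function(r) {
      r <- as.matrix(r)
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
      list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    })
    list(type = "Feature",
         properties = list(species = sp),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
}

#' Read polygon ranges from GeoJSON
#'
#' Reads a FeatureCollection of Polygon / MultiPolygon features into the
#' named-list-of-rings representation used by [rasterize_ranges()].  The
#' species id is taken from the `species` (or first) property.
#'
#' @param path GeoJSON file.
#' @export
read_ranges_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  out <- list()
  for (f in js$features) {
    sp <- f$properties$species %||% f$properties[[1]]
    geom <- f$geometry
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
    rings <- lapply(polys, function(poly) {
      ring <- poly[[1]]  # outer ring only; holes are out of scope
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    out[[as.character(sp)]] <- rings
  }
  out
}
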
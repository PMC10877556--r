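#' Gridded climate layer
#'
#' Plain-matrix representation of a climate raster: values on a regular
#' grid with a lower-left origin and square cells.  Row index increases
#' with y, column index with x.  Variables follow the bioclim convention:
#' annual mean temperature (Bio1, degrees C) and annual precipitation
#' (Bio12, mm), for the current era or the Last Glacial Maximum (~21 ka BP).
#'
#' @param values numeric matrix (ny x nx).
#' @param origin `c(xmin, ymin)` of the raster.
#' @param res cell size.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param era `"current"` or `"lgm"`.
#' @export
climate_layer <- function(values, origin = c(0, 0), res = 1,
                          variable = c("temperature", "precipitation"),
                          era = c("current", "lgm")) {
  structure(list(values = as.matrix(values), origin = origin, res = res,
                 variable = match.arg(variable), era = match.arg(era)),
            class = "climate_layer")
}

#' Extract a climate layer at grid centroids
#'
#' Nearest-cell lookup of the source raster at each cell centroid — the
#' study design samples climate at grid centroids rather than averaging
#' over cells, and against a much finer source raster nearest-neighbour is
#' the faithful reading.  Centroids outside the raster get `NA` and are
#' listed in the `log` attribute.
#'
#' @param layer a [climate_layer()].
#' @param grid a `tetra_grid` (or any data frame with `cell`, `cx`, `cy`).
#' @return named numeric vector of per-cell values (names = cell ids).
#' @export
extract_at_centroids <- function(layer, grid) {
  stopifnot(inherits(layer, "climate_layer"))
  V <- layer$values
  col <- floor((grid$cx - layer$origin[1]) / layer$res) + 1L
  row <- floor((grid$cy - layer$origin[2]) / layer$res) + 1L
  # centroid exactly on the top/right raster edge snaps to the last cell
  col[grid$cx == layer$origin[1] + ncol(V) * layer$res] <- ncol(V)
  row[grid$cy == layer$origin[2] + nrow(V) * layer$res] <- nrow(V)
  ok <- col >= 1 & col <= ncol(V) & row >= 1 & row <= nrow(V)
  out <- rep(NA_real_, nrow(grid))
  out[ok] <- V[cbind(row[ok], col[ok])]
  names(out) <- grid$cell
  attr(out, "log") <- grid$cell[!ok]
  out
}

#' Climate anomaly between the current era and the Last Glacial Maximum
#'
#' Anomaly = current - LGM (signed, default): zero means no change since
#' the LGM, i.e. low climate instability.  `mode = "absolute"` returns the
#' magnitude of the change instead, for analyses where instability is a
#' non-directional quantity.
#'
#' @param current,lgm per-cell values for the two eras (aligned).
#' @param mode `"signed"` or `"absolute"`.
#' @export
compute_anomaly <- function(current, lgm, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (length(current) != length(lgm)) {
    stop("current and LGM vectors must be aligned", call. = FALSE)
  }
  a <- current - lgm
  if (mode == "absolute") a <- abs(a)
  a
}

#' Assemble the per-cell climate table
#'
#' Extracts all four layers (temperature / precipitation x current / LGM)
#' at the grid centroids and computes the two anomalies.
#'
#' @param layers list with elements `temp_current`, `precip_current`,
#'   `temp_lgm`, `precip_lgm`, each a [climate_layer()].
#' @param grid a `tetra_grid`.
#' @param anomaly_mode passed to [compute_anomaly()].
#' @return data frame: `cell`, `temp`, `precip`, `temp_anomaly`,
#'   `precip_anomaly`.
#' @export
climate_table <- function(layers, grid, anomaly_mode = "signed") {
  need <- c("temp_current", "precip_current", "temp_lgm", "precip_lgm")
  if (!all(need %in% names(layers))) {
    stop("layers must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tc <- extract_at_centroids(layers$temp_current, grid)
  pc <- extract_at_centroids(layers$precip_current, grid)
  tl <- extract_at_centroids(layers$temp_lgm, grid)
  pl <- extract_at_centroids(layers$precip_lgm, grid)
  data.frame(cell = grid$cell,
             temp = unname(tc), precip = unname(pc),
             temp_anomaly = unname(compute_anomaly(tc, tl, anomaly_mode)),
             precip_anomaly = unname(compute_anomaly(pc, pl, anomaly_mode)))
}
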
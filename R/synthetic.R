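#' Configuration for the synthetic study system
#'
#' Bundles everything the generator needs: grid dimensions, species counts,
#' the true standardized path coefficients of the grid-level structural
#' model, the spatial autocorrelation range of the climate fields, and the
#' seed.  One global seed feeds independent per-stage substreams, so each
#' stage can be regenerated in isolation.
#'
#' The default path coefficients encode the theoretical expectations of the
#' study system: warmer/wetter climate and higher instability shape the
#' three community-wide traits (with opposing signs), and both climate and
#' the traits drive richness.  Residual standard deviations are derived so
#' that every variable has unit population variance, which makes the true
#' coefficients directly comparable to fitted standardized coefficients.
#'
#' @param grid_nx,grid_ny grid dimensions in cells (product >= 10).
#' @param n_species_per_group species per taxon group (>= 3).
#' @param true_paths data frame `from`, `to`, `coef` with standardized
#'   coefficients in \[-1, 1\]; must be acyclic.
#' @param noise_sd optional named vector overriding the derived residual SD
#'   of specific endogenous nodes (overrides break unit variance).
#' @param spatial_range autocorrelation length of the climate fields, in
#'   cell units (Gaussian kernel bandwidth; `Inf` gives a constant field up
#'   to the latitudinal gradient).
#' @param composite_weights list with unit-norm indicator weights for the
#'   two exogenous composites (`climate` over temp/precip, `instability`
#'   over the two anomalies).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_nx = 20, grid_ny = 20,
                             n_species_per_group = 60,
                             true_paths = default_true_paths(),
                             noise_sd = NULL,
                             spatial_range = 3,
                             composite_weights = list(
                               climate = c(temp = 0.8, precip = 0.6),
                               instability = c(temp_anomaly = 0.8,
                                               precip_anomaly = 0.6)),
                             seed = 1L) {
  if (grid_nx <= 0 || grid_ny <= 0) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (grid_nx * grid_ny < 10) stop("grid must have at least 10 cells", call. = FALSE)
  if (n_species_per_group < 3) {
    stop("need at least 3 species per group", call. = FALSE)
  }
  if (spatial_range <= 0) stop("spatial_range must be positive", call. = FALSE)
  stopifnot(all(c("from", "to", "coef") %in% names(true_paths)))
  if (any(abs(true_paths$coef) > 1)) {
    stop("standardized coefficients must lie in [-1, 1]", call. = FALSE)
  }
  dag_topo_sort(true_paths)  # errors on cycles
  structure(list(grid_nx = grid_nx, grid_ny = grid_ny,
                 n_species_per_group = n_species_per_group,
                 true_paths = true_paths, noise_sd = noise_sd,
                 spatial_range = spatial_range,
                 composite_weights = composite_weights,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default true path coefficients of the synthetic structural model
#'
#' Nodes: the two exogenous composites (`climate`, `instability`), the
#' three community-wide traits, and `richness` (latent continuous scale).
#'
#' @export
default_true_paths <- function() {
  data.frame(
    from = c("climate", "climate", "climate", "climate",
             "instability", "instability", "instability", "instability",
             "body_size", "size_variance", "trophic_structure"),
    to   = c("body_size", "size_variance", "trophic_structure", "richness",
             "body_size", "size_variance", "trophic_structure", "richness",
             "richness", "richness", "richness"),
    coef = c(-0.30, 0.30, 0.20, 0.40,
             0.20, -0.30, -0.20, 0.20,
             -0.25, 0.25, -0.15))
}

# independent per-stage seeds derived from the global seed
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Gaussian kernel smoothing of a matrix, separable and row-normalised so
# the infinite-bandwidth limit is the global mean
smooth_matrix <- function(Z, bandwidth) {
  norm_rows <- function(n) {
    idx <- seq_len(n)
    K <- if (is.infinite(bandwidth)) matrix(1, n, n)
         else exp(-outer(idx, idx, "-")^2 / (2 * bandwidth^2))
    K / rowSums(K)
  }
  Ry <- norm_rows(nrow(Z))
  Rx <- norm_rows(ncol(Z))
  Ry %*% Z %*% t(Rx)
}

#' Generate spatially autocorrelated climate fields for two eras
#'
#' Each field is kernel-smoothed white noise (bandwidth =
#' `spatial_range`) plus a latitudinal gradient; the LGM fields are the
#' current fields plus an independent autocorrelated perturbation and a
#' colder/drier offset, so anomalies are nonconstant.  Units are degrees C
#' (temperature) and mm (precipitation, floored at 0).
#'
#' @param config a [synthetic_config()].
#' @return list of four [climate_layer()]s: `temp_current`,
#'   `precip_current`, `temp_lgm`, `precip_lgm`, on a unit-resolution grid
#'   with origin (0, 0).
#' @export
generate_climate_fields <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nx <- config$grid_nx; ny <- config$grid_ny
  seeds <- substream_seeds(config$seed, 10)
  set.seed(seeds[1])
  h <- config$spatial_range
  std <- function(M) {
    s <- stats::sd(M)
    if (s < 1e-12) M - mean(M) else (M - mean(M)) / s
  }
  field <- function() std(smooth_matrix(matrix(stats::rnorm(ny * nx), ny, nx), h))
  grad <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny, nx)  # poleward in +y

  temp_c <- 15 - 10 * grad + 4 * field()
  precip_c <- pmax(1000 - 500 * grad + 300 * field(), 0)
  temp_l <- temp_c - 4 + 2.5 * field()
  precip_l <- pmax(precip_c - 200 + 180 * field(), 0)

  list(
    temp_current = climate_layer(temp_c, c(0, 0), 1, "temperature", "current"),
    precip_current = climate_layer(precip_c, c(0, 0), 1, "precipitation", "current"),
    temp_lgm = climate_layer(temp_l, c(0, 0), 1, "temperature", "lgm"),
    precip_lgm = climate_layer(precip_l, c(0, 0), 1, "precipitation", "lgm"))
}

# implied population covariance bookkeeping for a standardized recursive
# linear system: returns per-node residual SDs and checks feasibility
derive_residual_sd <- function(edges, order) {
  C <- diag(length(order))
  dimnames(C) <- list(order, order)
  resid_sd <- stats::setNames(numeric(length(order)), order)
  for (v in order) {
    par <- edges$from[edges$to == v]
    if (length(par) == 0) { resid_sd[v] <- 1; next }
    b <- edges$coef[edges$to == v][match(par, edges$from[edges$to == v])]
    var_sys <- drop(t(b) %*% C[par, par, drop = FALSE] %*% b)
    if (var_sys > 1 + 1e-8) {
      stop("path coefficients into '", v, "' imply systematic variance ",
           round(var_sys, 3), " > 1; reduce the coefficients", call. = FALSE)
    }
    resid_sd[v] <- sqrt(max(0, 1 - var_sys))
    for (u in order) {
      if (u == v) next
      C[v, u] <- C[u, v] <- sum(b * C[par, u])
    }
  }
  resid_sd
}

#' Generate the grid-level structural-model table with known truth
#'
#' Variables are generated in topological order: each endogenous variable
#' is the coefficient-weighted sum of its (standardized) parents plus
#' Gaussian noise whose SD is derived from the implied covariance so every
#' variable has unit population variance — the true coefficients are then
#' directly the standardized coefficients an OLS path analysis should
#' recover.  The two exogenous composites are built from four indicator
#' variables (temp, precip and their LGM anomalies) with the configured
#' unit-norm weights, so composite estimation is testable too.  Richness is
#' produced on a latent continuous standardized scale (the analysis models
#' richness by OLS); [richness_to_counts()] maps it to counts if needed.
#'
#' @param config a [synthetic_config()].
#' @param n number of cells (default `grid_nx * grid_ny`).
#' @param exogenous optional matrix/data frame supplying the four indicator
#'   columns (`temp`, `precip`, `temp_anomaly`, `precip_anomaly`), e.g.
#'   standardized spatially structured fields; defaults to i.i.d. N(0, 1).
#' @return list with `data` (indicators + all model nodes), `truth` (the
#'   true path data frame), and `residual_sd`.
#' @export
generate_grid_sem_data <- function(config, n = NULL, exogenous = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(n)) n <- config$grid_nx * config$grid_ny
  edges <- config$true_paths
  order <- dag_topo_sort(edges)
  resid_sd <- derive_residual_sd(edges, order)
  if (!is.null(config$noise_sd)) {
    resid_sd[names(config$noise_sd)] <- config$noise_sd
  }
  seeds <- substream_seeds(config$seed, 10)
  set.seed(seeds[2])

  ind_names <- c("temp", "precip", "temp_anomaly", "precip_anomaly")
  if (is.null(exogenous)) {
    X <- matrix(stats::rnorm(n * 4), n, 4, dimnames = list(NULL, ind_names))
  } else {
    X <- as.matrix(exogenous)[, ind_names, drop = FALSE]
    X <- scale(X)
  }
  w <- config$composite_weights
  comp <- list(
    climate = drop(X[, names(w$climate)] %*% w$climate),
    instability = drop(X[, names(w$instability)] %*% w$instability))

  dat <- as.data.frame(X)
  for (v in order) {
    par <- edges$from[edges$to == v]
    if (length(par) == 0) {
      dat[[v]] <- if (v %in% names(comp)) comp[[v]] else stats::rnorm(n)
      next
    }
    b <- edges$coef[edges$to == v][match(par, edges$from[edges$to == v])]
    sys <- as.matrix(dat[, par, drop = FALSE]) %*% b
    dat[[v]] <- drop(sys) + stats::rnorm(n, sd = resid_sd[v])
  }
  list(data = dat, truth = edges, residual_sd = resid_sd)
}

#' Map latent standardized richness to species counts
#'
#' Exponentiates and rounds: `round(exp(mean_log + sd_log * z))`.  Used
#' only for gridding-stage tests; the structural analyses keep richness on
#' the latent continuous scale.
#'
#' @param z latent standardized richness.
#' @param mean_log,sd_log location and scale on the log scale.
#' @export
richness_to_counts <- function(z, mean_log = log(20), sd_log = 0.5) {
  as.integer(round(exp(mean_log + sd_log * z)))
}

disc_polygon <- function(cx, cy, r, k = 24) {
  a <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(cx + r * cos(a), cy + r * sin(a))
}

#' Generate species ranges and a trait table tied to the climate fields
#'
#' Each species receives a disc-shaped range centred at a
#' climate-dependent location (a random temperature optimum is matched to
#' the current temperature field) with a random radius; a body mass drawn
#' log-normally with its mean tied to the local temperature in the group's
#' assumed direction (smaller endotherms and larger squamates in warm
#' cells); and diet fractions from a three-component mixture, with the
#' first three species of every group pinned to one trophic class each so
#' all classes always occur.
#'
#' @param config a [synthetic_config()].
#' @param fields climate fields from [generate_climate_fields()] (generated
#'   if missing).
#' @return list with `ranges` (named list of polygon rings) and `traits`
#'   (data frame `species`, `group`, `body_mass_g`, `diet_plant`,
#'   `diet_animal`).
#' @export
generate_ranges_and_traits <- function(config, fields = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(fields)) fields <- generate_climate_fields(config)
  nx <- config$grid_nx; ny <- config$grid_ny
  seeds <- substream_seeds(config$seed, 10)
  set.seed(seeds[3])

  temp <- fields$temp_current$values           # ny x nx, origin (0,0), res 1
  temp_std <- (temp - mean(temp)) / stats::sd(temp)
  groups <- c("amphibian", "bird", "mammal", "squamate")
  mu_log10 <- c(amphibian = 1.0, bird = 1.7, mammal = 2.5, squamate = 1.5)
  slope <- c(amphibian = 0, bird = -0.2, mammal = -0.2, squamate = 0.2)

  ranges <- list()
  traits <- list()
  for (g in groups) {
    for (i in seq_len(config$n_species_per_group)) {
      sp <- sprintf("%s_%03d", g, i)
      # climate-dependent placement: match a random temperature optimum
      opt <- stats::quantile(temp, stats::runif(1))
      cand <- which(abs(temp - opt) <= stats::quantile(abs(temp - opt), 0.1))
      pick <- cand[sample.int(length(cand), 1)]
      cy <- ((pick - 1) %% ny) + 0.5          # matrix is column-major: row=y
      cx <- ((pick - 1) %/% ny) + 0.5
      r <- stats::runif(1, 1, max(2, min(nx, ny) / 3))
      ranges[[sp]] <- disc_polygon(cx, cy, r)

      lm10 <- mu_log10[g] + slope[g] * temp_std[pick] + stats::rnorm(1, 0, 0.5)
      cls <- if (i <= 3) c("primary", "omnivore", "secondary")[i]
             else sample(c("primary", "omnivore", "secondary"), 1,
                         prob = c(0.3, 0.4, 0.3))
      if (cls == "primary") {
        plant <- stats::runif(1, 0.92, 1); animal <- (1 - plant) * stats::runif(1)
      } else if (cls == "secondary") {
        animal <- stats::runif(1, 0.92, 1); plant <- (1 - animal) * stats::runif(1)
      } else {
        plant <- stats::runif(1, 0.2, 0.7)
        animal <- (1 - plant) * stats::runif(1, 0.3, 0.9)
      }
      traits[[sp]] <- data.frame(species = sp, group = g,
                                 body_mass_g = 10^lm10,
                                 diet_plant = plant, diet_animal = animal)
    }
  }
  list(ranges = ranges, traits = do.call(rbind, c(traits, make.row.names = FALSE)))
}

#' Generate the full synthetic bundle
#'
#' Climate fields, species ranges and traits, and the grid-level
#' structural-model table with its ground truth, all from one seed.  The
#' structural table's exogenous indicators are the standardized climate
#' values at the cell centroids, so the table is spatially autocorrelated
#' and exercises the spatial-eigenvector stage.
#'
#' @param config a [synthetic_config()].
#' @param spatial_exogenous use the generated climate fields as the
#'   structural model's exogenous indicators (default TRUE); FALSE gives
#'   i.i.d. indicators.
#' @return list of class `synthetic_bundle`: `climate`, `ranges`, `traits`,
#'   `sem_table`, `truth`, `grid`, `config`.
#' @export
generate_bundle <- function(config, spatial_exogenous = TRUE) {
  fields <- generate_climate_fields(config)
  rt <- generate_ranges_and_traits(config, fields)
  grid <- build_grid(grid_spec(c(0, config$grid_nx, 0, config$grid_ny),
                               resolution = 1))
  exo <- NULL
  if (spatial_exogenous) {
    ct <- climate_table(fields, grid)
    exo <- ct[, c("temp", "precip", "temp_anomaly", "precip_anomaly")]
  }
  sem <- generate_grid_sem_data(config, exogenous = exo)
  sem$data$cell <- grid$cell
  structure(list(climate = fields, ranges = rt$ranges, traits = rt$traits,
                 sem_table = sem$data, truth = sem$truth,
                 residual_sd = sem$residual_sd, grid = grid, config = config),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk as plain-text fixtures
#'
#' Ranges as GeoJSON, climate fields and tables as CSV, plus a JSON sidecar
#' with the true coefficients and the configuration.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ranges_geojson(bundle$ranges, file.path(dir, "ranges.geojson"))
  utils::write.csv(bundle$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(bundle$sem_table, file.path(dir, "sem_table.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$climate)) {
    utils::write.csv(bundle$climate[[nm]]$values,
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  cfg <- bundle$config
  jsonlite::write_json(
    list(truth = bundle$truth, residual_sd = as.list(bundle$residual_sd),
         config = list(grid_nx = cfg$grid_nx, grid_ny = cfg$grid_ny,
                       n_species_per_group = cfg$n_species_per_group,
                       spatial_range = cfg$spatial_range, seed = cfg$seed)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 12)
  invisible(dir)
}
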
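#' Trophic-level classification from diet composition
#'
#' Species are placed into three trophic levels from the composition of
#' their diet: primary consumers have more than 90% plant material (leaves,
#' flowers, seeds, fruits), secondary consumers more than 90% animal
#' material (invertebrates plus vertebrates), and all remaining mixed diets
#' are omnivores.  Each level carries a fixed weight used by the
#' trophic-structure index: primary 2, omnivore 2.5, secondary 3 (an
#' intermediate isotopic position for omnivores).
#'
#' @param plant,animal numeric vectors of diet fractions in \[0, 1\];
#'   `plant + animal` may be at most 1 (the remainder is "other").
#' @return data frame with columns `category` (factor: primary / omnivore /
#'   secondary) and `weight` (2 / 2.5 / 3).
#' @examples
#' classify_trophic_level(plant = c(0.95, 0.6, 0.05),
#'                        animal = c(0.02, 0.4, 0.92))
#' @export
classify_trophic_level <- function(plant, animal) {
  if (length(plant) != length(animal)) {
    stop("plant and animal fractions must have equal length", call. = FALSE)
  }
  bad <- !is.finite(plant) | !is.finite(animal) | plant < 0 | animal < 0 |
    plant > 1 | animal > 1
  if (any(bad)) stop("diet fractions must be finite and in [0, 1]", call. = FALSE)
  if (any(plant + animal > 1 + 1e-8)) {
    stop("diet fractions sum to more than 1", call. = FALSE)
  }
  category <- ifelse(plant > 0.9, "primary",
                     ifelse(animal > 0.9, "secondary", "omnivore"))
  weight <- c(primary = 2, omnivore = 2.5, secondary = 3)[category]
  data.frame(category = factor(category,
                               levels = c("primary", "omnivore", "secondary")),
             weight = unname(weight))
}

#' Trophic-structure index of an assemblage
#'
#' Arithmetic mean of the trophic-level weights of the species present in a
#' cell.  Bounded in \[2, 3\]: values near 2 indicate a bottom-heavy pyramid
#' dominated by primary consumers, values near 3 a top-heavy pyramid
#' dominated by secondary consumers.
#'
#' @param weights numeric vector of trophic weights (2, 2.5 or 3), one per
#'   species present.
#' @export
trophic_structure_index <- function(weights) {
  if (length(weights) == 0) {
    stop("trophic structure is undefined for an empty assemblage", call. = FALSE)
  }
  if (!all(weights %in% c(2, 2.5, 3))) {
    stop("trophic weights must be 2, 2.5 or 3", call. = FALSE)
  }
  mean(weights)
}

#' Community size structure: log median body mass and its variance
#'
#' Body size of an assemblage is the log10 of the median body mass in grams
#' (body mass is strongly right-skewed, so models use the logged median);
#' size variance is the sample variance of log10 body mass (variance on the
#' raw gram scale would be dominated by the largest species; set
#' `log_scale = FALSE` for raw-scale variance).  A single-species cell has
#' variance 0.
#'
#' @param masses numeric vector of body masses in grams (> 0).
#' @param log_scale compute the variance on log10 mass (default) or raw grams.
#' @return list with `body_size` (log10 median mass) and `size_variance`.
#' @examples
#' community_size_structure(c(10, 100, 1000))  # body_size = 2
#' @export
community_size_structure <- function(masses, log_scale = TRUE) {
  if (length(masses) == 0) stop("empty assemblage", call. = FALSE)
  if (any(!is.finite(masses) | masses <= 0)) {
    stop("body masses must be finite and positive", call. = FALSE)
  }
  body_size <- log10(stats::median(masses))
  v <- if (length(masses) == 1) 0 else {
    if (log_scale) stats::var(log10(masses)) else stats::var(masses)
  }
  list(body_size = body_size, size_variance = v)
}

#' Aggregate species traits to community-wide traits per cell and group
#'
#' For every cell x taxon-group combination with at least one species
#' present, computes the three community-wide traits from the species
#' present in that cell: log10 median body mass, variance of log10 body
#' mass, and the trophic-structure index.  Every present species must have
#' a trait record (species with missing traits are removed upstream).
#'
#' @param presence binary presence matrix (cells x species) as produced by
#'   [rasterize_ranges()]; rownames are cell ids, colnames species ids.
#' @param traits data frame with columns `species`, `group`, `body_mass_g`,
#'   `diet_plant`, `diet_animal`.
#' @param log_scale passed to [community_size_structure()].
#' @return data frame with columns `cell`, `group`, `n_species`,
#'   `body_size`, `size_variance`, `trophic_structure`.
#' @export
aggregate_assemblage_traits <- function(presence, traits, log_scale = TRUE) {
  presence <- as.matrix(presence)
  sp <- colnames(presence)
  missing_sp <- setdiff(sp, traits$species)
  if (length(missing_sp) > 0) {
    stop("present species without trait records: ",
         paste(utils::head(missing_sp, 5), collapse = ", "), call. = FALSE)
  }
  tr <- traits[match(sp, traits$species), , drop = FALSE]
  lev <- classify_trophic_level(tr$diet_plant, tr$diet_animal)
  tr$trophic_weight <- lev$weight

  out <- list()
  for (g in unique(tr$group)) {
    idx <- which(tr$group == g)
    sub <- presence[, idx, drop = FALSE]
    occ <- rowSums(sub)
    for (ci in which(occ > 0)) {
      present <- idx[sub[ci, ] == 1]
      sz <- community_size_structure(tr$body_mass_g[present], log_scale)
      out[[length(out) + 1L]] <- data.frame(
        cell = rownames(presence)[ci], group = g,
        n_species = length(present),
        body_size = sz$body_size, size_variance = sz$size_variance,
        trophic_structure = trophic_structure_index(tr$trophic_weight[present]))
    }
  }
  if (length(out) == 0) {
    return(data.frame(cell = character(0), group = character(0),
                      n_species = integer(0), body_size = numeric(0),
                      size_variance = numeric(0),
                      trophic_structure = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
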
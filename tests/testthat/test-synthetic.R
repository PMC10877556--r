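test_that("generation is deterministic given the config seed", {
  cfg <- synthetic_config(grid_nx = 8, grid_ny = 8, n_species_per_group = 5,
                          seed = 42)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$sem_table, b2$sem_table)
  expect_identical(b1$traits, b2$traits)
  expect_identical(b1$ranges, b2$ranges)
  expect_identical(b1$climate$temp_current$values,
                   b2$climate$temp_current$values)
})

test_that("infinite smoothing bandwidth leaves only the latitudinal gradient", {
  cfg <- synthetic_config(grid_nx = 6, grid_ny = 9, spatial_range = Inf,
                          seed = 3)
  f <- generate_climate_fields(cfg)
  temp <- f$temp_current$values
  # constant along x (within a latitude band), varying across y
  expect_lt(max(apply(temp, 1, function(r) diff(range(r)))), 1e-9)
  expect_gt(diff(range(temp[, 1])), 1)
})

test_that("generated temperature field is positively autocorrelated on the lattice", {
  cfg <- synthetic_config(grid_nx = 10, grid_ny = 10, spatial_range = 2,
                          seed = 5)
  f <- generate_climate_fields(cfg)
  xy <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  sw <- build_spatial_weights(xy)          # unit lattice: rook neighbours
  x <- as.vector(t(f$temp_current$values)) # row-major to match expand.grid
  n <- length(x)
  expect_gt(morans_i(x, sw), -1 / (n - 1))
  expect_gt(morans_i(x, sw), 0.3)          # smoothing range 2 is far from null
})

test_that("all-zero path coefficients give mutually uncorrelated variables", {
  paths <- default_true_paths()
  paths$coef <- 0
  cfg <- synthetic_config(true_paths = paths, seed = 9)
  g <- generate_grid_sem_data(cfg, n = 2000)
  nodes <- unique(c(paths$from, paths$to))
  cm <- cor(g$data[, nodes])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
})

test_that("a unit-coefficient noiseless chain propagates exactly", {
  paths <- data.frame(from = c("climate", "body_size"),
                      to = c("body_size", "richness"),
                      coef = c(1, 1))
  cfg <- synthetic_config(true_paths = paths, seed = 4)
  g <- generate_grid_sem_data(cfg, n = 500)
  expect_equal(g$data$richness, g$data$climate, tolerance = 1e-12)
  expect_equal(unname(g$residual_sd[c("body_size", "richness")]), c(0, 0))
})

test_that("reduced-form coefficient equals direct plus path product on a chain", {
  paths <- data.frame(
    from = c("climate", "body_size", "climate"),
    to = c("body_size", "richness", "richness"),
    coef = c(-0.4, -0.3, 0.5))
  cfg <- synthetic_config(true_paths = paths, seed = 21)
  g <- generate_grid_sem_data(cfg, n = 2000)
  fit <- lm(richness ~ climate, data = g$data)
  beta_std <- coef(fit)[2] * sd(g$data$climate) / sd(g$data$richness)
  expect_equal(unname(beta_std), 0.5 + (-0.4) * (-0.3), tolerance = 0.06)
})

test_that("every generated model variable has near-unit variance", {
  cfg <- synthetic_config(seed = 13)
  g <- generate_grid_sem_data(cfg, n = 2000)
  nodes <- unique(c(cfg$true_paths$from, cfg$true_paths$to))
  v <- vapply(g$data[, nodes], var, numeric(1))
  expect_true(all(abs(v - 1) < 0.1))
})

test_that("overambitious coefficients are rejected as a configuration error", {
  paths <- data.frame(from = c("climate", "instability"),
                      to = c("richness", "richness"), coef = c(0.9, 0.9))
  expect_error(generate_grid_sem_data(synthetic_config(true_paths = paths)),
               "systematic variance")
  expect_error(synthetic_config(grid_nx = 2, grid_ny = 2), "at least 10")
  expect_error(synthetic_config(grid_nx = -1), "positive")
})

test_that("generated traits cover all trophic classes with positive masses", {
  cfg <- synthetic_config(grid_nx = 6, grid_ny = 6, n_species_per_group = 8,
                          seed = 77)
  rt <- generate_ranges_and_traits(cfg)
  expect_true(all(rt$traits$body_mass_g > 0))
  lev <- classify_trophic_level(rt$traits$diet_plant, rt$traits$diet_animal)
  for (g in unique(rt$traits$group)) {
    expect_setequal(unique(as.character(lev$category[rt$traits$group == g])),
                    c("primary", "omnivore", "secondary"))
  }
  expect_length(rt$ranges, nrow(rt$traits))
})

test_that("richness count transform is a rounded exponential", {
  z <- c(-1, 0, 1)
  expect_identical(richness_to_counts(z, mean_log = log(20), sd_log = 0.5),
                   as.integer(round(exp(log(20) + 0.5 * z))))
})
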
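test_that("grid construction tiles the extent with centred centroids", {
  g <- build_grid(grid_spec(c(0, 10, 0, 10), resolution = 2))
  expect_equal(nrow(g), 25)
  expect_equal(sum((g$xmax - g$xmin) * (g$ymax - g$ymin)), 100)  # covers extent
  # pairwise disjoint: all lower-left corners distinct on the lattice
  expect_equal(anyDuplicated(g[, c("xmin", "ymin")]), 0L)
  c00 <- g[g$xmin == 0 & g$ymin == 0, ]
  expect_equal(c(c00$cx, c00$cy), c(1, 1))
  expect_error(build_grid(grid_spec(c(0, 1, 0, 1), resolution = 2)),
               "smaller than one cell")
})

test_that("mollweide projection has the textbook fixed points", {
  expect_equal(unname(mollweide(0, 0)[1, ]), c(0, 0))
  p <- mollweide(0, 90)
  expect_equal(unname(p[1, "y"]), sqrt(2) * 6371007.181, tolerance = 1e-6)
  expect_equal(unname(p[1, "x"]), 0, tolerance = 1e-6)
  # equal-area sanity: projected y is monotone in latitude
  ys <- mollweide(rep(0, 7), seq(-90, 90, by = 30))[, "y"]
  expect_true(all(diff(ys) > 0))
})

test_that("centroid membership marks presence, with boundary counted inside", {
  g <- build_grid(grid_spec(c(0, 6, 0, 6), resolution = 2))
  sq <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  ranges <- list(
    inside = sq(0.5, 0.5, 1.5, 1.5),    # contains centroid (1,1) strictly
    outside = sq(4.2, 0.2, 4.8, 0.8),   # centroid (5,1) not inside
    boundary = sq(1, 1, 3, 3),          # centroid (1,1) on its corner
    everywhere = sq(-1, -1, 7, 7))
  P <- rasterize_ranges(ranges, g)
  expect_equal(unname(P["c001_001", "inside"]), 1L)
  expect_equal(unname(P["c003_001", "outside"]), 0L)
  expect_equal(unname(P["c001_001", "boundary"]), 1L)
  expect_true(all(P[, "everywhere"] == 1L))
})

test_that("invalid polygons are skipped with a warning, others still rasterized", {
  g <- build_grid(grid_spec(c(0, 4, 0, 4), resolution = 2))
  ranges <- list(bad = cbind(c(0, 1), c(0, 1)),      # 2 vertices
                 good = cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
  expect_warning(P <- rasterize_ranges(ranges, g), "invalid polygon")
  expect_true(all(P[, "good"] == 1L))
  expect_true(all(P[, "bad"] == 0L))
  expect_equal(attr(P, "log"), "bad")
})

test_that("richness matches an exhaustive point-in-rectangle oracle", {
  set.seed(31)
  g <- build_grid(grid_spec(c(0, 5, 0, 5), resolution = 1))
  rects <- replicate(10, {
    x0 <- runif(1, 0, 4); y0 <- runif(1, 0, 4)
    c(x0, y0, x0 + runif(1, 0.5, 3), y0 + runif(1, 0.5, 3))
  })
  ranges <- lapply(seq_len(10), function(i) {
    r <- rects[, i]
    cbind(c(r[1], r[3], r[3], r[1]), c(r[2], r[2], r[4], r[4]))
  })
  names(ranges) <- paste0("sp", 1:10)
  P <- rasterize_ranges(ranges, g)
  oracle <- sapply(seq_len(10), function(i) {
    r <- rects[, i]
    as.integer(g$cx >= r[1] & g$cx <= r[3] & g$cy >= r[2] & g$cy <= r[4])
  })
  expect_equal(unname(as.matrix(P)), oracle, ignore_attr = TRUE)

  # invariances: species order, vertex-order reversal, monotonicity
  P2 <- rasterize_ranges(rev(ranges), g)
  expect_equal(rowSums(P), rowSums(P2))
  flipped <- lapply(ranges, function(r) r[rev(seq_len(nrow(r))), ])
  expect_equal(unname(as.matrix(rasterize_ranges(flipped, g))), oracle,
               ignore_attr = TRUE)
  P3 <- rasterize_ranges(c(ranges, list(extra = cbind(c(0, 5, 5, 0),
                                                      c(0, 0, 5, 5)))), g)
  expect_true(all(rowSums(P3) >= rowSums(P)))
})

test_that("the minimum-species filter drops cells below three species", {
  P <- matrix(0L, 3, 4, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  P["a", 1:2] <- 1L   # richness 2 -> dropped
  P["b", 1:3] <- 1L   # richness 3 -> retained
  rf <- richness_and_filter(P)
  expect_equal(rf$richness, c(2L, 3L, 0L))
  expect_equal(rf$retained, c(FALSE, TRUE, FALSE))
  empty <- richness_and_filter(matrix(0L, 0, 0))
  expect_equal(nrow(empty), 0)
  expect_error(richness_and_filter(matrix(2, 1, 1)), "binary")
})

test_that("GeoJSON range round-trip preserves centroid membership", {
  cfg <- synthetic_config(grid_nx = 6, grid_ny = 6, n_species_per_group = 4,
                          seed = 8)
  rt <- generate_ranges_and_traits(cfg)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_ranges_geojson(rt$ranges, path)
  back <- read_ranges_geojson(path)
  g <- build_grid(grid_spec(c(0, 6, 0, 6), resolution = 1))
  expect_equal(as.matrix(rasterize_ranges(back, g)),
               as.matrix(rasterize_ranges(rt$ranges, g)), ignore_attr = TRUE)
})
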
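test_that("collinearity prefilter drops the higher-AIC member pairwise", {
  set.seed(14)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$dup <- d$x                                # r = 1
  d$z <- rnorm(n)
  d$y <- d$x + rnorm(n, sd = 0.5)
  res <- collinearity_prefilter(d, c("x", "dup", "z"), "y")
  expect_length(res$dropped, 1)
  expect_true(res$dropped %in% c("x", "dup"))
  expect_true("z" %in% res$retained)
  # r = 0.5 pair: both kept
  d2 <- data.frame(a = rnorm(n))
  d2$b <- 0.5 * d2$a + sqrt(1 - 0.25) * rnorm(n)
  d2$y <- rnorm(n)
  expect_length(collinearity_prefilter(d2, c("a", "b"), "y")$dropped, 0)
  # three mutually collinear variables: iteration terminates below threshold
  base <- rnorm(n)
  d3 <- data.frame(p = base + rnorm(n, sd = 0.1),
                   q = base + rnorm(n, sd = 0.1),
                   r = base + rnorm(n, sd = 0.1), y = base)
  res3 <- collinearity_prefilter(d3, c("p", "q", "r"), "y")
  if (length(res3$retained) > 1) {
    cm <- abs(cor(d3[, res3$retained]))
    expect_lte(max(cm[upper.tri(cm)]), 0.7)
  }
  expect_error(collinearity_prefilter(d, "x", "y"), "at least 2")
})

test_that("submodel standardized coefficients obey the closed-form identities", {
  set.seed(15)
  d <- data.frame(x = rnorm(100))
  d$y <- d$x
  f <- suppressWarnings(fit_submodel("y", "x", d))  # exact fit warns in summary.lm
  expect_equal(f$coefficients$std_estimate, 1)
  expect_equal(f$r_squared, 1)
  # simple regression: beta_std equals the Pearson correlation
  d$y2 <- 0.4 * d$x + rnorm(100)
  f2 <- fit_submodel("y2", "x", d)
  expect_equal(f2$coefficients$std_estimate, cor(d$x, d$y2), tolerance = 1e-10)
  d$x2 <- d$x
  expect_error(fit_submodel("y2", c("x", "x2"), d), "rank-deficient")
  expect_error(fit_submodel("y", "x", d[1:2, ]), "too few")
})

test_that("a pure-noise predictor is small in nearly all replicates", {
  set.seed(16)
  hits <- 0
  for (r in 1:200) {
    x <- rnorm(2000); y <- rnorm(2000)
    f <- fit_submodel("y", "x", data.frame(x = x, y = y))
    if (abs(f$coefficients$std_estimate) < 0.07) hits <- hits + 1
  }
  expect_gte(hits, 190)
})

test_that("basis set matches brute-force enumeration on small random DAGs", {
  set.seed(18)
  for (rep in 1:20) {
    edges <- random_dag(sample(4:6, 1))
    spec <- path_model_spec(edges)
    got <- dsep_basis_set(spec)
    want <- brute_basis_set(edges)
    canon <- function(cl) paste(paste(sort(c(cl$x, cl$y)), collapse = "~"),
                                paste(sort(cl$cond), collapse = ","))
    expect_setequal(vapply(got, canon, character(1)),
                    vapply(want, canon, character(1)))
  }
  # correlated-error pairs leave the basis set
  edges <- data.frame(from = c("a", "a"), to = c("m1", "m2"))
  expect_length(dsep_basis_set(path_model_spec(edges)), 1)
  expect_length(dsep_basis_set(
    path_model_spec(edges, correlated_errors = cbind("m1", "m2"))), 0)
})

test_that("Fisher's C combines claim p-values with 2k degrees of freedom", {
  cfg <- synthetic_config(true_paths = calibration_paths(), seed = 23)
  g <- generate_grid_sem_data(cfg, n = 300)
  spec <- path_model_spec(calibration_paths())
  res <- dsep_fisher_c(spec, g$data)
  expect_equal(nrow(res$claims), 5)
  expect_equal(res$df, 10L)
  expect_equal(res$C, -2 * sum(log(res$claims$p)))
  expect_equal(res$p_value, pchisq(res$C, 10, lower.tail = FALSE))
  # saturated model: no claims, C undefined
  sat <- dsep_fisher_c(default_path_model(),
                       generate_grid_sem_data(
                         synthetic_config(seed = 2), n = 200)$data)
  expect_true(sat$saturated)
  expect_equal(sat$df, 0L)
  expect_true(is.na(sat$C))
})

test_that("effect decomposition multiplies along paths and sums with the direct", {
  edges <- data.frame(from = c("a", "m"), to = c("m", "y"),
                      std_coef = c(0.5, 0.4))
  eff <- effect_decomposition(edges, response = "y")
  a <- eff[eff$predictor == "a", ]
  expect_equal(a$indirect, 0.2)
  expect_equal(a$direct, 0)
  expect_equal(a$total, 0.2)
  # direct + indirect
  edges2 <- rbind(edges, data.frame(from = "a", to = "y", std_coef = 0.3))
  a2 <- effect_decomposition(edges2, "y")
  a2 <- a2[a2$predictor == "a", ]
  expect_equal(a2$total, 0.3 + 0.2)
  # no mediated path: indirect 0, total = direct
  m2 <- effect_decomposition(edges2, "y")
  m2 <- m2[m2$predictor == "m", ]
  expect_equal(m2$indirect, 0)
  expect_equal(m2$total, m2$direct)
})

test_that("the full piecewise SEM recovers generating coefficients and their signs", {
  cfg <- synthetic_config(seed = 25)
  g <- generate_grid_sem_data(cfg, n = 1000)
  fit <- fit_psem(default_path_model(), g$data)
  m <- merge(fit$edges, g$truth, by = c("from", "to"))
  expect_equal(nrow(m), nrow(g$truth))
  expect_lt(max(abs(m$std_coef - m$coef)), 0.12)   # 1 seed at n = 1000
  expect_true(all(sign(m$std_coef) == sign(m$coef)))
  expect_s3_class(fit, "sem_fit")
  expect_output(print(fit), "Fisher|saturated")
  # conservation: total = direct + indirect, exactly
  expect_equal(fit$effects$total, fit$effects$direct + fit$effects$indirect)
})

test_that("spatial submodels never end with more residual autocorrelation", {
  cfg <- synthetic_config(grid_nx = 12, grid_ny = 12, seed = 31)
  b <- generate_bundle(cfg)
  sw <- build_spatial_weights(as.matrix(b$grid[, c("cx", "cy")]))
  fit <- fit_psem(default_path_model(), b$sem_table, weights = sw,
                  seed = 5, n_perm = 199, max_mems = 5)
  rep <- fit$mem_report
  expect_true(all(abs(rep$moran_after) <= abs(rep$moran_before) + 1e-9))
  expect_error(fit_psem(default_path_model(), b$sem_table, weights = sw),
               "seed is mandatory")
})

test_that("cyclic specifications are rejected", {
  expect_error(path_model_spec(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cycle")
  expect_error(path_model_spec(data.frame(from = "a", to = "b"),
                               correlated_errors = cbind("a", "zz")),
               "not in model")
})
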
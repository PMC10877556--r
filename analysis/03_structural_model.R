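#!/usr/bin/env Rscript
# Structural analysis: composite climate and instability variables weighted
# by richness, distance-based Moran's eigenvector maps selected to minimise
# residual autocorrelation, and the piecewise SEM with Fisher's C and the
# standardized direct/indirect/total effect decomposition.  Fitted on the
# generated grid table whose true coefficients are known, so estimates can
# be read against truth.

suppressPackageStartupMessages(library(tetrasem))

seed <- 1L
cfg <- synthetic_config(grid_nx = 20, grid_ny = 20, n_species_per_group = 40,
                        seed = seed)
res <- run_pipeline(pipeline_config(synthetic = cfg, seed = seed,
                                    n_perm = 199,
                                    output_dir = "results/sem"))
fit <- res$fits$synthetic

cat("Piecewise SEM on the synthetic grid table (seed", seed, ")\n\n")
print(fit)
cat("\nEstimated vs true standardized coefficients:\n")
m <- merge(fit$edges, res$truth, by = c("from", "to"))
m$error <- m$std_coef - m$coef
print(m[order(m$to, m$from),
        c("from", "to", "coef", "std_coef", "error", "p")],
      row.names = FALSE, digits = 3)
cat("\nSpatial filtering per submodel (residual Moran's I before/after MEMs):\n")
print(fit$mem_report, row.names = FALSE, digits = 3)
cat("\nfull report written to results/sem/\n")
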
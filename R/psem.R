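#' Path-model specification for the piecewise SEM
#'
#' The model is a DAG over composites, trait variables and richness, with
#' optional correlated-error pairs among the trait variables (free
#' covariances, excluded from the d-separation basis set).  Every
#' endogenous node gets one OLS submodel with its parents as predictors.
#'
#' @param edges data frame with `from`, `to`.
#' @param correlated_errors optional data frame / matrix with two columns
#'   naming node pairs whose errors are free to covary.
#' @return object of class `path_model_spec` with `edges`,
#'   `correlated_errors`, `nodes` (topological order), `exogenous`.
#' @export
path_model_spec <- function(edges, correlated_errors = NULL) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  nodes <- dag_topo_sort(edges)
  exo <- setdiff(nodes, unique(edges$to))
  ce <- NULL
  if (!is.null(correlated_errors)) {
    ce <- as.data.frame(correlated_errors)
    names(ce) <- c("a", "b")
    unknown <- setdiff(c(ce$a, ce$b), nodes)
    if (length(unknown) > 0) {
      stop("correlated-error nodes not in model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(edges = edges[, c("from", "to")], correlated_errors = ce,
                 nodes = nodes, exogenous = exo), class = "path_model_spec")
}

#' Theoretical path model of the analysis
#'
#' Contemporary climate and climate instability drive each community-wide
#' trait and richness directly; each trait drives richness; the three
#' traits' errors are mutually correlated.
#'
#' @param traits trait node names.
#' @export
default_path_model <- function(traits = c("body_size", "size_variance",
                                          "trophic_structure")) {
  exo <- c("climate", "instability")
  edges <- rbind(
    expand.grid(from = exo, to = traits, stringsAsFactors = FALSE),
    data.frame(from = c(exo, traits), to = "richness"))
  path_model_spec(edges, correlated_errors = t(utils::combn(traits, 2)))
}

#' Collinearity prefilter with AIC-based dropping
#'
#' For every pair of candidate predictors with |Pearson r| above the
#' threshold (default 0.7), the member whose single-predictor model for the
#' response has the higher AIC is dropped; this is iterated until no pair
#' exceeds the threshold.  Every decision is logged.
#'
#' @param data data frame.
#' @param vars candidate predictor columns (>= 2).
#' @param response response column used for the AIC comparison.
#' @param threshold absolute correlation threshold (pairs at or below it
#'   are kept).
#' @return list with `retained`, `dropped`, and a `log` data frame.
#' @export
collinearity_prefilter <- function(data, vars, response, threshold = 0.7) {
  if (length(vars) < 2) stop("need at least 2 candidate variables", call. = FALSE)
  keep <- vars
  log <- data.frame(dropped = character(0), kept = character(0),
                    r = numeric(0), aic_dropped = numeric(0),
                    aic_kept = numeric(0))
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(data[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    aic_a <- stats::AIC(stats::lm(stats::reformulate(a, response), data))
    aic_b <- stats::AIC(stats::lm(stats::reformulate(b, response), data))
    drop_var <- if (aic_a > aic_b) a else b
    kept_var <- if (aic_a > aic_b) b else a
    log <- rbind(log, data.frame(
      dropped = drop_var, kept = kept_var, r = max(cm),
      aic_dropped = max(aic_a, aic_b), aic_kept = min(aic_a, aic_b)))
    keep <- setdiff(keep, drop_var)
  }
  list(retained = keep, dropped = setdiff(vars, keep), log = log)
}

#' Fit one OLS submodel of the piecewise SEM
#'
#' Ordinary least squares of the response on its substantive predictors
#' plus any spatial eigenvector covariates.  Standardized coefficients
#' (\eqn{\beta_{std} = b \, sd(x)/sd(y)}) are reported for substantive
#' predictors only; MEMs are nuisance covariates.  Residuals are retained
#' for the spatial-autocorrelation audit.
#'
#' @param response response column name.
#' @param predictors substantive predictor names.
#' @param data data frame.
#' @param mems optional matrix of spatial eigenvectors (columns named).
#' @return object of class `submodel_fit`: `coefficients` table (estimate,
#'   std_estimate, se, p per substantive predictor), `r_squared`, `aic`,
#'   `residuals`, `n`, `response`, `mems`.
#' @export
fit_submodel <- function(response, predictors, data, mems = NULL) {
  n <- nrow(data)
  if (n <= length(predictors) + NCOL(mems) + 1) {
    stop("too few observations for the design", call. = FALSE)
  }
  df <- data.frame(data[, c(response, predictors), drop = FALSE])
  if (!is.null(mems) && NCOL(mems) > 0) {
    mems <- as.matrix(mems)
    df <- cbind(df, as.data.frame(mems))
  } else {
    mems <- NULL
  }
  fit <- stats::lm(stats::reformulate(setdiff(names(df), response), response),
                   data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients[predictors, , drop = FALSE]
  sdy <- stats::sd(df[[response]])
  sdx <- vapply(predictors, function(p) stats::sd(df[[p]]), numeric(1))
  coefs <- data.frame(
    predictor = predictors,
    estimate = ct[, 1],
    std_estimate = ct[, 1] * sdx / sdy,
    se = ct[, 2], p = ct[, 4], row.names = NULL)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 aic = stats::AIC(fit), residuals = stats::resid(fit),
                 n = n, response = response,
                 mems = if (is.null(mems)) character(0) else colnames(mems),
                 lm = fit),
            class = "submodel_fit")
}

#' Basis set of directed-separation claims
#'
#' One conditional-independence claim per non-adjacent node pair,
#' conditioned on the union of both nodes' parents.  Pairs where both
#' nodes are exogenous are excluded (their covariance is unconstrained),
#' as are declared correlated-error pairs.  The claim's response is the
#' later node in topological order; the claim is tested by the p-value of
#' the earlier node added to the response's conditional regression.
#'
#' @param spec a [path_model_spec()].
#' @return list of claims, each `list(x, y, cond)` with `y` the response.
#' @export
dsep_basis_set <- function(spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  nodes <- spec$nodes
  adj <- paste(spec$edges$from, spec$edges$to)
  ce <- spec$correlated_errors
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j]
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      if (a %in% spec$exogenous && b %in% spec$exogenous) next
      if (!is.null(ce) && any((ce$a == a & ce$b == b) | (ce$a == b & ce$b == a))) next
      cond <- setdiff(unique(c(dag_parents(spec$edges, a),
                               dag_parents(spec$edges, b))), c(a, b))
      claims[[length(claims) + 1L]] <- list(x = a, y = b, cond = cond)
    }
  }
  claims
}

#' Tests of directed separation and Fisher's C
#'
#' Each basis-set claim is tested by OLS: the claim's response is regressed
#' on the conditioning set plus the claimed-independent node, whose
#' p-value is the claim's p.  Fisher's C = -2 sum(ln p) is compared to a
#' chi-square with 2k degrees of freedom; a large global p means the data
#' are consistent with the causal structure.  A saturated model (empty
#' basis set) reports C undefined with df 0.
#'
#' @param spec a [path_model_spec()].
#' @param data data frame with all node columns.
#' @param mems_by_response optional named list: response node -> matrix of
#'   spatial eigenvectors to include in that node's claim regressions.
#' @return list with `claims` data frame, `C`, `df`, `p_value`,
#'   `saturated`.
#' @export
dsep_fisher_c <- function(spec, data, mems_by_response = NULL) {
  claims <- dsep_basis_set(spec)
  if (length(claims) == 0) {
    return(list(claims = data.frame(), C = NA_real_, df = 0L,
                p_value = NA_real_, saturated = TRUE))
  }
  rows <- lapply(claims, function(cl) {
    mems <- mems_by_response[[cl$y]]
    fit <- fit_submodel(cl$y, c(cl$cond, cl$x), data, mems = mems)
    p <- fit$coefficients$p[fit$coefficients$predictor == cl$x]
    data.frame(x = cl$x, y = cl$y,
               cond = paste(cl$cond, collapse = "+"), p = p)
  })
  claims_df <- do.call(rbind, rows)
  p <- pmax(claims_df$p, .Machine$double.xmin)   # guard log(0)
  C <- -2 * sum(log(p))
  df <- 2L * nrow(claims_df)
  list(claims = claims_df, C = C, df = df,
       p_value = stats::pchisq(C, df, lower.tail = FALSE), saturated = FALSE)
}

#' Decompose standardized effects into direct, indirect and total
#'
#' For every node with a directed path to the response, the direct effect
#' is the standardized coefficient of the direct edge (0 if absent); each
#' mediated path contributes the product of the standardized coefficients
#' along it; the indirect effect is the sum over all multi-edge paths; and
#' total = direct + indirect, exactly.
#'
#' @param edges data frame `from`, `to`, `std_coef`.
#' @param response terminal response node (default `"richness"`).
#' @return data frame `predictor`, `direct`, `indirect`, `total`.
#' @export
effect_decomposition <- function(edges, response = "richness") {
  stopifnot(all(c("from", "to", "std_coef") %in% names(edges)))
  preds <- setdiff(dag_nodes(edges), response)
  coef_of <- function(a, b) {
    k <- edges$std_coef[edges$from == a & edges$to == b]
    if (length(k) == 0) 0 else k
  }
  rows <- lapply(preds, function(v) {
    paths <- dag_all_paths(edges, v, response)
    direct <- coef_of(v, response)
    indirect <- 0
    for (pth in paths) {
      if (length(pth) <= 2) next
      indirect <- indirect +
        prod(mapply(coef_of, pth[-length(pth)], pth[-1]))
    }
    data.frame(predictor = v, direct = direct, indirect = indirect,
               total = direct + indirect)
  })
  out <- do.call(rbind, rows)
  out[out$direct != 0 | out$indirect != 0, , drop = FALSE]
}

#' Fit the full piecewise structural equation model
#'
#' Orchestrates the stages: optional collinearity prefilter on each
#' submodel's predictors, base OLS submodels, residual-driven selection of
#' spatial eigenvectors per submodel (MIR), refit with the selected MEMs,
#' tests of directed separation with Fisher's C, and the standardized
#' effect decomposition onto the terminal response.
#'
#' @param spec a [path_model_spec()].
#' @param data data frame with all node columns.
#' @param weights optional `spatial_weights` over the rows of `data`;
#'   enables the spatial stage.
#' @param basis optional precomputed `mem_basis` (computed from `weights`
#'   if omitted).
#' @param response terminal response node (default `"richness"`).
#' @param alpha significance level for the MIR stop rule.
#' @param n_perm permutations for residual Moran's I tests.
#' @param seed integer seed for the permutation tests (mandatory when
#'   `weights` is supplied).
#' @param prefilter apply [collinearity_prefilter()] within each submodel's
#'   predictor set (default TRUE).
#' @param cor_threshold prefilter threshold.
#' @param max_mems cap on selected MEMs per submodel.
#' @return object of class `sem_fit`: `submodels`, `edges` (with
#'   `std_coef`, `p`), `dsep`, `effects`, `mem_report`, `prefilter_log`,
#'   `spec`.
#' @export
fit_psem <- function(spec, data, weights = NULL, basis = NULL,
                     response = "richness", alpha = 0.05, n_perm = 999,
                     seed = NULL, prefilter = TRUE, cor_threshold = 0.7,
                     max_mems = 10) {
  stopifnot(inherits(spec, "path_model_spec"))
  miss <- setdiff(spec$nodes, names(data))
  if (length(miss) > 0) {
    stop("data lacks model nodes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  spatial <- !is.null(weights)
  if (spatial) {
    if (is.null(seed)) stop("seed is mandatory for the spatial stage", call. = FALSE)
    if (is.null(basis)) basis <- compute_mem_basis(weights)
  }
  seeds <- if (spatial) substream_seeds(seed, length(spec$nodes)) else NULL

  edges <- spec$edges
  endo <- setdiff(spec$nodes, spec$exogenous)
  submodels <- list()
  mem_report <- list()
  mems_by_response <- list()
  prefilter_log <- list()

  for (k in seq_along(endo)) {
    v <- endo[k]
    preds <- dag_parents(edges, v)
    if (prefilter && length(preds) >= 2) {
      pf <- collinearity_prefilter(data, preds, v, threshold = cor_threshold)
      if (length(pf$dropped) > 0) {
        prefilter_log[[v]] <- pf$log
        edges <- edges[!(edges$to == v & edges$from %in% pf$dropped), ]
        preds <- pf$retained
      }
    }
    base <- fit_submodel(v, preds, data)
    mems <- NULL
    if (spatial) {
      sel <- select_mems_mir(base$residuals, basis, weights, alpha = alpha,
                             n_perm = n_perm, seed = seeds[k],
                             max_mems = max_mems)
      i_before <- morans_i(base$residuals, weights)
      if (length(sel$indices) > 0) {
        mems <- basis$vectors[, sel$indices, drop = FALSE]
      }
      final <- if (is.null(mems)) base else fit_submodel(v, preds, data, mems)
      mem_report[[v]] <- data.frame(
        response = v, n_mems = length(sel$indices),
        moran_before = i_before,
        moran_after = morans_i(final$residuals, weights))
      mems_by_response[[v]] <- mems
      submodels[[v]] <- final
    } else {
      submodels[[v]] <- base
    }
  }

  # attach standardized coefficients and p-values to the edges
  edges$std_coef <- NA_real_
  edges$p <- NA_real_
  for (v in names(submodels)) {
    co <- submodels[[v]]$coefficients
    m <- match(paste(co$predictor, v), paste(edges$from, edges$to))
    edges$std_coef[m] <- co$std_estimate
    edges$p[m] <- co$p
  }

  dsep <- dsep_fisher_c(path_model_spec(edges[, c("from", "to")],
                                        spec$correlated_errors),
                        data, mems_by_response = mems_by_response)
  effects <- effect_decomposition(edges, response = response)
  structure(list(submodels = submodels, edges = edges, dsep = dsep,
                 effects = effects,
                 mem_report = if (length(mem_report))
                   do.call(rbind, c(mem_report, make.row.names = FALSE))
                 else NULL,
                 prefilter_log = prefilter_log, spec = spec,
                 response = response),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Piecewise SEM fit\n")
  cat("  submodels:", paste(names(x$submodels), collapse = ", "), "\n")
  r2 <- vapply(x$submodels, function(s) s$r_squared, numeric(1))
  cat("  R-squared:", paste(sprintf("%s=%.2f", names(r2), r2), collapse = ", "),
      "\n")
  if (isTRUE(x$dsep$saturated)) {
    cat("  d-separation: saturated model (no testable claims)\n")
  } else {
    cat(sprintf("  Fisher's C = %.2f, df = %d, p = %.3f\n",
                x$dsep$C, x$dsep$df, x$dsep$p_value))
  }
  cat("  standardized effects on", x$response, "\n")
  print(x$effects, row.names = FALSE)
  invisible(x)
}
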
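#' Composite-variable specification
#'
#' A composite variable collapses several operational variables into a
#' single model node: contemporary climate (temperature + precipitation),
#' climate instability (the two LGM anomalies), or community-wide traits
#' (body size, size variance, trophic structure).  The indicator weights
#' come from a multiple regression of the response on the indicators; the
#' composite score is the weighted sum.
#'
#' @param name composite name.
#' @param indicators character vector of indicator column names (>= 1).
#' @param response column name of the weighting response (the analysis
#'   weights every composite by the taxon group's species richness).
#' @export
composite_spec <- function(name, indicators, response) {
  if (length(indicators) < 1) stop("need at least one indicator", call. = FALSE)
  structure(list(name = name, indicators = indicators, response = response),
            class = "composite_spec")
}

#' Fit a composite variable
#'
#' Indicators are z-scored, the (z-scored) response is regressed on them by
#' OLS, and the composite score is the coefficient-weighted sum of the
#' standardized indicators, re-standardized to unit variance so downstream
#' path coefficients are standardized.  The stored centring/scaling makes
#' [score_composite()] reproduce training scores exactly and keeps new-data
#' scores comparable.  Scores are oriented so the first indicator's weight
#' is positive (the weighted sum is sign-indeterminate as a model node).
#'
#' @param spec a [composite_spec()].
#' @param data data frame containing indicators and response.
#' @return object of class `composite_fit`: `weights` (on the standardized
#'   indicators), `centers`, `scales`, `score_center`, `score_scale`,
#'   `scores`, `r` (multiple correlation with the response), `spec`.
#' @export
fit_composite <- function(spec, data) {
  stopifnot(inherits(spec, "composite_spec"))
  miss <- setdiff(c(spec$indicators, spec$response), names(data))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, spec$indicators, drop = FALSE])
  if (any(!is.finite(X))) stop("indicators contain missing values", call. = FALSE)
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  if (any(scales < 1e-12)) {
    stop("constant indicator: ",
         paste(spec$indicators[scales < 1e-12], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")
  y <- data[[spec$response]]
  ys <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm.fit(cbind(1, Xs), ys)
  if (any(is.na(fit$coefficients))) {
    stop("perfectly collinear indicators in composite '", spec$name,
         "'; run collinearity_prefilter() first", call. = FALSE)
  }
  w <- fit$coefficients[-1]
  names(w) <- spec$indicators
  flip <- if (w[1] < 0) -1 else 1
  raw <- drop(Xs %*% w) * flip
  sc_c <- mean(raw); sc_s <- stats::sd(raw)
  if (sc_s < 1e-12) stop("composite score is constant", call. = FALSE)
  r <- sqrt(max(0, 1 - sum(fit$residuals^2) / sum(ys^2)))
  structure(list(weights = w * flip, centers = centers, scales = scales,
                 score_center = sc_c, score_scale = sc_s,
                 scores = (raw - sc_c) / sc_s, r = r, spec = spec),
            class = "composite_fit")
}

#' Score a composite on (new) data
#'
#' Applies the stored indicator standardization, weights, and score
#' standardization, so scores are comparable across calls; scoring the
#' training data reproduces the training scores exactly.
#'
#' @param fit a `composite_fit`.
#' @param data data frame with the indicator columns.
#' @export
score_composite <- function(fit, data) {
  stopifnot(inherits(fit, "composite_fit"))
  miss <- setdiff(fit$spec$indicators, names(data))
  if (length(miss) > 0) {
    stop("missing indicators: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, fit$spec$indicators, drop = FALSE])
  Xs <- sweep(sweep(X, 2, fit$centers), 2, fit$scales, "/")
  raw <- drop(Xs %*% fit$weights)
  (raw - fit$score_center) / fit$score_scale
}
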
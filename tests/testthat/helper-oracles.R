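# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities from first principles (double loops, exhaustive
# enumeration) rather than calling the package's vectorised implementations.

# Moran's I by the textbook double sum
brute_morans_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# per-cell community traits by an explicit species loop
brute_assemblage_traits <- function(presence, traits) {
  out <- NULL
  for (g in unique(traits$group)) {
    for (ci in seq_len(nrow(presence))) {
      masses <- c(); weights <- c()
      for (sj in seq_len(ncol(presence))) {
        sp <- colnames(presence)[sj]
        row <- traits[traits$species == sp, ]
        if (row$group != g || presence[ci, sj] != 1) next
        masses <- c(masses, row$body_mass_g)
        w <- if (row$diet_plant > 0.9) 2
             else if (row$diet_animal > 0.9) 3 else 2.5
        weights <- c(weights, w)
      }
      if (length(masses) == 0) next
      lv <- log10(masses)
      out <- rbind(out, data.frame(
        cell = rownames(presence)[ci], group = g,
        n_species = length(masses),
        body_size = log10(median(masses)),
        size_variance = if (length(lv) == 1) 0 else var(lv),
        trophic_structure = mean(weights)))
    }
  }
  out
}

# d-separation basis set by exhaustive enumeration over all node pairs,
# following the stated convention: non-adjacent pairs, both-exogenous and
# correlated-error pairs excluded, conditioning on the union of parents
brute_basis_set <- function(edges, correlated = NULL) {
  nodes <- unique(c(edges$from, edges$to))
  # topological order by repeated removal of parentless nodes
  order <- character(0); left <- nodes; e <- edges
  while (length(left)) {
    free <- left[!(left %in% e$to)]
    order <- c(order, free[1]); left <- setdiff(left, free[1])
    e <- e[e$from != free[1], , drop = FALSE]
  }
  exo <- setdiff(nodes, edges$to)
  claims <- list()
  for (i in seq_along(order)) for (j in seq_along(order)) {
    if (j <= i) next
    a <- order[i]; b <- order[j]
    adjacent <- any(edges$from == a & edges$to == b) ||
      any(edges$from == b & edges$to == a)
    if (adjacent) next
    if (a %in% exo && b %in% exo) next
    if (!is.null(correlated) &&
        any((correlated[, 1] == a & correlated[, 2] == b) |
            (correlated[, 1] == b & correlated[, 2] == a))) next
    cond <- sort(unique(c(edges$from[edges$to == a], edges$from[edges$to == b])))
    claims[[length(claims) + 1L]] <- list(x = a, y = b, cond = cond)
  }
  claims
}

# sparser DAG used for Fisher's C calibration: every basis-set claim is a
# true independence under the generator
calibration_paths <- function() {
  data.frame(from = c("climate", "instability", "body_size", "size_variance"),
             to = c("body_size", "size_variance", "richness", "richness"),
             coef = c(0.5, 0.5, 0.3, 0.3))
}

# random small DAG over k nodes (edge prob p), always acyclic by ordering
random_dag <- function(k, p = 0.4) {
  nodes <- paste0("n", seq_len(k))
  from <- c(); to <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (runif(1) < p) { from <- c(from, nodes[i]); to <- c(to, nodes[j]) }
  }
  if (length(from) == 0) { from <- nodes[1]; to <- nodes[2] }
  data.frame(from = from, to = to)
}
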
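# Independent oracles and small fixture builders used across the suite.

# Adjusted Rand index between two partitions (closed form from the
# contingency table).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Naive, unstabilised evaluation of the GTM mixture log-likelihood:
# sum_n log[(1/K) sum_l (beta/2pi)^(D/2) exp(-beta/2 ||x_n - y_l||^2)]
naive_gtm_loglik <- function(x, y, beta) {
  d <- ncol(x)
  k <- nrow(y)
  ll <- 0
  for (n in seq_len(nrow(x))) {
    dens <- 0
    for (l in seq_len(k)) {
      dens <- dens + (beta / (2 * pi))^(d / 2) *
        exp(-beta / 2 * sum((x[n, ] - y[l, ])^2))
    }
    ll <- ll + log(dens / k)
  }
  ll
}

# Exhaustive O(K^3) Ward oracle: at each step recompute, from scratch, the
# increase in total within-cluster sum of squares for every candidate merge
# and take the smallest. Returns the merge sequence as lists of leaf-index
# sets plus the ESS increase of each merge.
ward_oracle <- function(points) {
  points <- as.matrix(points)
  clusters <- lapply(seq_len(nrow(points)), identity)
  ess <- function(idx) {
    p <- points[idx, , drop = FALSE]
    sum(sweep(p, 2, colMeans(p))^2)
  }
  merges <- list()
  deltas <- numeric()
  while (length(clusters) > 1L) {
    best <- NULL
    best_delta <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_delta) {
          best_delta <- delta
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    deltas <- c(deltas, best_delta)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, delta_ess = deltas)
}

# Merge sequence of a ward_dendrogram as sorted leaf-index sets.
dendrogram_merge_sets <- function(dend) {
  sets <- vector("list", nrow(dend$merge))
  resolve <- function(code) {
    if (code < 0L) -code else sets[[code]]
  }
  for (s in seq_len(nrow(dend$merge))) {
    sets[[s]] <- sort(c(resolve(dend$merge[s, 1]), resolve(dend$merge[s, 2])))
  }
  sets
}

# Small complete cohort with explicit roles/types for preprocessing tests.
toy_cohort <- function(n = 10) {
  set.seed(42)
  cohort_table(
    data.frame(hr = rnorm(n, 70, 5), sbp = rnorm(n, 120, 10),
               glucose = rnorm(n, 5, 1), age = round(runif(n, 40, 80))),
    data.frame(name = c("hr", "sbp", "glucose", "age"),
               role = c("modelling", "modelling", "modelling", "investigative"),
               vtype = "continuous", stringsAsFactors = FALSE))
}

# A smooth single-manifold cohort (no cluster structure) for
# topology-preservation checks: latent points fill a square, smooth map to
# D dimensions, modest noise.
smooth_manifold_data <- function(n = 400, d = 5, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  z <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  a <- matrix(rnorm(d * 2), d, 2)
  b <- matrix(rnorm(d * 3, sd = 0.1), d, 3)
  zq <- cbind(z[, 1]^2, z[, 2]^2, z[, 1] * z[, 2])
  x <- z %*% t(a) + zq %*% t(b) + matrix(rnorm(n * d, sd = noise_sd), n, d)
  scale(x)
}

# Chebyshev lattice distance between two node indices of a side x side grid.
lattice_chebyshev <- function(i, j, side) {
  ri <- (i - 1) %/% side; ci <- (i - 1) %% side
  rj <- (j - 1) %/% side; cj <- (j - 1) %% side
  max(abs(ri - rj), abs(ci - cj))
}

# Fraction of subjects whose second-highest-responsibility node is a lattice
# neighbour (Chebyshev distance 1) of their argmax node.
second_best_neighbour_rate <- function(model, x) {
  r <- gtm_e_step(model, x)$R
  side <- model$grid$side
  hits <- vapply(seq_len(nrow(r)), function(n) {
    ord <- order(r[n, ], decreasing = TRUE)
    lattice_chebyshev(ord[1], ord[2], side) == 1
  }, logical(1))
  mean(hits)
}
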
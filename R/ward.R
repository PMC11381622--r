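# Ward's minimum-variance agglomerative clustering via the Lance-Williams
# recurrence on squared Euclidean distances. At each step the pair of
# clusters whose merge least increases the total within-cluster sum of
# squares is joined; heights are reported on the Euclidean-equivalent scale
# (the square root of the Lance-Williams updated squared distance, i.e. the
# sqrt(2 * ESS-increase) family), matching hclust's "ward.D2" convention so
# dendrograms are comparable across implementations.

#' Ward's minimum-variance linkage of the reference vectors
#'
#' @param vectors K x D numeric matrix (typically [reference_vectors()]).
#' @return A list of class `ward_dendrogram`: `merge` (K-1 x 2 matrix in
#'   hclust convention: negative entries are leaves, positive entries prior
#'   merges), `height` (Euclidean-equivalent Ward scale), `sizes` (cluster
#'   size after each merge) and `K`.
#' @export
#' @examples
#' d <- ward_linkage(matrix(c(0, 1, 10, 11), ncol = 1))
#' cut_dendrogram(d, 2)  # c(1, 1, 2, 2)
ward_linkage <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (any(!is.finite(vectors))) stop("vectors must be finite")
  k <- nrow(vectors)
  if (k < 2L) stop("need at least 2 vectors")
  d2 <- squared_distances(vectors, vectors)
  diag(d2) <- Inf
  active <- rep(TRUE, k)
  sizes <- rep(1L, k)
  cluster_id <- -seq_len(k)     # hclust convention for current clusters
  first_leaf <- seq_len(k)      # lowest leaf index per cluster, for ordering
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  out_sizes <- integer(k - 1L)
  for (step in seq_len(k - 1L)) {
    dview <- d2
    dview[!active, ] <- Inf
    dview[, !active] <- Inf
    flat <- which.min(dview)
    j <- (flat - 1L) %/% k + 1L
    i <- flat - (j - 1L) * k
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    height[step] <- sqrt(d2[i, j])
    a <- cluster_id[i]
    b <- cluster_id[j]
    # hclust orders each merge row: leaves (negative) before clusters, and
    # ascending within each kind
    if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
        (a > 0 && b < 0)) {
      tmp <- a; a <- b; b <- tmp
    }
    merge[step, ] <- c(a, b)
    ni <- sizes[i]
    nj <- sizes[j]
    others <- which(active)
    others <- others[others != i & others != j]
    for (h in others) {
      nh <- sizes[h]
      d2[i, h] <- ((ni + nh) * d2[i, h] + (nj + nh) * d2[j, h] -
                     nh * d2[i, j]) / (ni + nj + nh)
      d2[h, i] <- d2[i, h]
    }
    sizes[i] <- ni + nj
    out_sizes[step] <- ni + nj
    active[j] <- FALSE
    cluster_id[i] <- step
    first_leaf[i] <- min(first_leaf[i], first_leaf[j])
  }
  structure(list(merge = merge, height = height, sizes = out_sizes, K = k),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("<ward_dendrogram> %d leaves, %d merges, height range [%.4g, %.4g]\n",
              x$K, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; cluster ids are contiguous `1..k`,
#' numbered by the lowest leaf index they contain.
#'
#' @param dendrogram a [ward_linkage()] result.
#' @param k number of clusters, `1 <= k <= K`.
#' @return Integer vector of length K with labels in `1..k`.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "ward_dendrogram"))
  kk <- dendrogram$K
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > kk) stop("k must be in 1..K")
  parent <- seq_len(kk)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  resolve <- function(code) if (code < 0L) -code else merged_root[code]
  merged_root <- integer(kk - 1L)
  n_apply <- kk - k
  for (step in seq_len(kk - 1L)) {
    a <- resolve(dendrogram$merge[step, 1L])
    b <- resolve(dendrogram$merge[step, 2L])
    ra <- find(a)
    rb <- find(b)
    if (step <= n_apply) {
      root <- min(ra, rb)
      parent[max(ra, rb)] <- root
      merged_root[step] <- root
    } else {
      merged_root[step] <- ra  # unused beyond the cut
    }
  }
  roots <- vapply(seq_len(kk), find, integer(1))
  labels <- match(roots, sort(unique(roots)))
  labels
}

#' Suggest a cut height by the largest relative height gap
#'
#' Advisory heuristic only: returns the `k` within `k_range` whose cut sits
#' below the largest relative gap between successive merge heights. With
#' uniform heights (no gap) the range minimum is returned. The number of
#' phenotypes is ultimately a user decision made by inspecting the
#' dendrogram; this helper is never applied silently.
#'
#' @param dendrogram a [ward_linkage()] result.
#' @param k_range integer vector `c(min, max)` within `[2, K - 1]`.
#' @return A single integer `k`.
#' @export
suggest_k <- function(dendrogram, k_range = c(2L, 8L)) {
  stopifnot(inherits(dendrogram, "ward_dendrogram"))
  kk <- dendrogram$K
  lo <- max(2L, as.integer(k_range[1]))
  hi <- min(kk - 1L, as.integer(k_range[2]))
  if (lo > hi) stop("empty k range")
  h <- dendrogram$height
  ks <- lo:hi
  rel <- vapply(ks, function(k) {
    below <- h[kk - k]        # last merge kept by the cut
    above <- h[kk - k + 1L]   # first merge undone
    (above - below) / max(below, .Machine$double.eps)
  }, numeric(1))
  if (max(rel) <= 0) {
    return(lo)
  }
  ks[which.max(rel)]
}

#' Convert to hclust (for plotting and Newick export)
#'
#' @param x a `ward_dendrogram`.
#' @param ... unused.
#' @return A [stats::hclust] object.
#' @importFrom stats as.hclust
#' @export
as.hclust.ward_dendrogram <- function(x, ...) {
  order <- dendrogram_leaf_order(x)
  structure(list(merge = x$merge, height = x$height, order = order,
                 labels = paste0("node", seq_len(x$K)),
                 method = "ward.D2", dist.method = "euclidean"),
            class = "hclust")
}

dendrogram_leaf_order <- function(x) {
  leaves <- function(step) {
    unlist(lapply(x$merge[step, ], function(code) {
      if (code < 0L) -code else leaves(code)
    }))
  }
  leaves(x$K - 1L)
}

#' Export a dendrogram
#'
#' `write_dendrogram()` writes the merge table as CSV (columns `step`,
#' `cluster_a`, `cluster_b`, `height`, `new_size`); `dendrogram_newick()`
#' returns a Newick string for generic tree viewers.
#'
#' @param dendrogram a `ward_dendrogram`.
#' @param path CSV output path.
#' @return The path, invisibly; or the Newick string.
#' @export
write_dendrogram <- function(dendrogram, path) {
  tab <- data.frame(step = seq_along(dendrogram$height),
                    cluster_a = dendrogram$merge[, 1L],
                    cluster_b = dendrogram$merge[, 2L],
                    height = dendrogram$height,
                    new_size = dendrogram$sizes)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dendrogram
#' @export
dendrogram_newick <- function(dendrogram) {
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy)
}
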
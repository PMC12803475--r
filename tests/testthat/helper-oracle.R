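# Independent brute-force oracle for the agglomeration engine.
# Implements its own point metrics and recomputes every cluster-to-cluster
# distance from scratch at every step; shares no bookkeeping with the
# package engine beyond the published tie-break (lexicographically smallest
# cluster-id pair).

oracle_point_dist <- function(a, b, metric, p = 2) {
  d <- abs(a - b)
  switch(metric,
         "euclidean" = sqrt(sum(d^2)),
         "squared-euclidean" = sum(d^2),
         "cityblock" = sum(d),
         "chebyshev" = max(d),
         "minkowski" = sum(d^p)^(1 / p),
         "correlation" = 1 - stats::cor(a, b),
         "spearman" = 1 - stats::cor(a, b, method = "spearman"))
}

oracle_cluster_dist <- function(A, B, X, metric, linkage, p = 2) {
  if (linkage == "centroid") {
    ca <- colMeans(X[A, , drop = FALSE])
    cb <- colMeans(X[B, , drop = FALSE])
    return(sqrt(sum((ca - cb)^2)))
  }
  d <- numeric(0)
  for (i in A) for (j in B)
    d <- c(d, oracle_point_dist(X[i, ], X[j, ], metric, p))
  switch(linkage, single = min(d), complete = max(d), average = mean(d))
}

# returns the partition at every k (list indexed by k), leaf indices 1..n
oracle_agglomerate <- function(X, metric, linkage, p = 2) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))          # member sets
  ids <- seq_len(n)                        # cluster ids, engine convention
  parts <- vector("list", n)
  parts[[n]] <- canonical_partition(clusters)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- oracle_cluster_dist(clusters[[a]], clusters[[b]], X, metric,
                               linkage, p)
      pair <- sort(c(ids[a], ids[b]))
      if (is.null(best) || d < best$d ||
          (d == best$d && (pair[1L] < best$pair[1L] ||
             (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
        best <- list(d = d, a = a, b = b, pair = pair)
      }
    }
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    keep <- setdiff(seq_along(clusters), c(best$a, best$b))
    clusters <- c(clusters[keep], list(merged))
    ids <- c(ids[keep], n + s)
    parts[[n - s]] <- canonical_partition(clusters)
  }
  parts
}

canonical_partition <- function(clusters) {
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, numeric(1L), 1L))]
}

# random continuous test matrix (distinct distances almost surely)
random_points <- function(n, m, seed) {
  set.seed(seed)
  matrix(stats::runif(n * m), n, m,
         dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(m))))
}

# tiny cohort on the 8-feature core catalog from explicit values
toy_cohort <- function(binary_rows, hr, ids = NULL) {
  catL <- catalog_subset(feature_catalog(), "L")
  n <- length(hr)
  stopifnot(nrow(binary_rows) == n, ncol(binary_rows) == 7L)
  values <- matrix(0, n, 8L,
                   dimnames = list(ids %||% paste0("s", seq_len(n)),
                                   catL$key))
  values[, setdiff(catL$key, "r11_heart_rate")] <- binary_rows
  values[, "r11_heart_rate"] <- hr
  cohort_matrix(values, catL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
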
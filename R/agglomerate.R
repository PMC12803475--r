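#' Agglomerative hierarchical clustering with full merge history
#'
#' Starts from every subject as a singleton cluster and repeatedly merges the
#' pair of clusters at globally minimal \code{\link{cluster_distance}},
#' recording each merge and its height. Cluster ids follow the convention
#' leaves = \code{1..n}, internal nodes = \code{n+1..2n-1} in merge order.
#' When several pairs attain the minimal distance, the pair with the
#' lexicographically smallest (id, id) is merged, which makes the run
#' deterministic. Single, complete and average merge distances are updated
#' with the exact Lance-Williams identities (min, max, size-weighted mean);
#' centroid distances are recomputed from the running arithmetic-mean
#' centroids, so centroid-linkage heights may invert.
#'
#' @param x a normalized \code{\link{cohort_matrix}} or a plain numeric
#'   matrix with at least two rows
#' @param metric a \code{\link{distance_spec}} or metric name
#' @param linkage a \code{\link{linkage_spec}} or criterion name
#' @return an object of class \code{merge_history}: list with
#'   \code{n_leaves}, \code{labels} (subject ids), \code{merges} (data frame
#'   \code{step}, \code{left}, \code{right}, \code{height}, \code{new_id})
#'   and the specs used
#' @examples
#' X <- matrix(c(0, 1, 5, 6), ncol = 1,
#'             dimnames = list(paste0("s", 1:4), "f"))
#' h <- agglomerate(X, "euclidean", "single")
#' h$merges$height  # 1, 1, 4
#' @export
agglomerate <- function(x, metric, linkage) {
  X <- if (inherits(x, "cohort_matrix")) x$values else x
  stopifnot(is.matrix(X), is.numeric(X))
  metric <- as_distance_spec(metric)
  linkage <- as_linkage_spec(linkage)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 subjects")
  m <- 2L * n - 1L

  centroidal <- linkage$criterion == "centroid"
  # initial inter-cluster distances; for centroid linkage the singletons'
  # centroid distances are plain Euclidean point distances
  D0 <- if (centroidal) point_distance_matrix(X, distance_spec("euclidean"))
        else point_distance_matrix(X, metric)

  D <- matrix(Inf, m, m)
  D[1:n, 1:n] <- D0
  diag(D) <- Inf
  active <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  size <- c(rep(1L, n), rep(0L, n - 1L))
  if (centroidal) {
    cent <- matrix(0, m, ncol(X))
    cent[1:n, ] <- X
  }

  merges <- data.frame(step = seq_len(n - 1L), left = integer(n - 1L),
                       right = integer(n - 1L), height = numeric(n - 1L),
                       new_id = n + seq_len(n - 1L))
  for (s in seq_len(n - 1L)) {
    h <- min(D)
    # first linear (column-major) index of the minimum is the
    # lexicographically smallest (i, j) pair, i < j
    ij <- arrayInd(which(D == h)[1L], dim(D))
    i <- min(ij); j <- max(ij)
    new <- n + s
    merges$left[s] <- i; merges$right[s] <- j; merges$height[s] <- h

    act <- which(active); act <- act[!(act %in% c(i, j))]
    if (centroidal) {
      cent[new, ] <- (size[i] * cent[i, ] + size[j] * cent[j, ]) /
        (size[i] + size[j])
      if (length(act)) {
        dnew <- sqrt(rowSums((cent[act, , drop = FALSE] -
                                rep(cent[new, ], each = length(act)))^2))
      } else dnew <- numeric(0)
    } else if (length(act)) {
      dnew <- switch(linkage$criterion,
        single   = pmin(D[i, act], D[j, act]),
        complete = pmax(D[i, act], D[j, act]),
        average  = (size[i] * D[i, act] + size[j] * D[j, act]) /
                     (size[i] + size[j]))
    } else dnew <- numeric(0)

    size[new] <- size[i] + size[j]
    active[c(i, j)] <- FALSE
    active[new] <- TRUE
    D[c(i, j), ] <- Inf
    D[, c(i, j)] <- Inf
    if (length(act)) {
      D[new, act] <- dnew
      D[act, new] <- dnew
    }
  }

  structure(list(n_leaves = n, labels = rownames(X), merges = merges,
                 metric = metric, linkage = linkage),
            class = "merge_history")
}

#' @export
print.merge_history <- function(x, ...) {
  cat(sprintf("<merge_history> %d leaves, %d merges (%s / %s)\n",
              x$n_leaves, nrow(x$merges), x$metric$metric,
              x$linkage$criterion))
  invisible(x)
}

#' Cut a merge history into k clusters
#'
#' Undoes the last \code{k - 1} merges, i.e. applies only the first
#' \code{n - k} merges, and returns the resulting partition.
#'
#' @param history a \code{\link{merge_history}}
#' @param k number of clusters, between 1 and the number of leaves
#' @return a list of \code{k} integer vectors of leaf indices (each sorted),
#'   ordered by smallest member
#' @export
cut_tree <- function(history, k) {
  n <- history$n_leaves
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("contract violation: k must lie in [1, ", n, "]")
  k <- as.integer(k)
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  steps <- seq_len(n - k)
  for (s in steps) {
    parent[find(history$merges$left[s])] <- history$merges$new_id[s]
    parent[find(history$merges$right[s])] <- history$merges$new_id[s]
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), roots)
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, `[`, integer(1L), 1L))]
}

#' Convert a merge history to a \code{stats::hclust} object
#'
#' Useful for plotting and for Newick export. Centroid-linkage histories can
#' contain height inversions, which base plotting reports with a warning.
#'
#' @param history a \code{\link{merge_history}}
#' @return an object of class \code{hclust}
#' @export
as_hclust <- function(history) {
  n <- history$n_leaves
  mm <- matrix(0L, n - 1L, 2L)
  for (s in seq_len(n - 1L)) {
    l <- history$merges$left[s]; r <- history$merges$right[s]
    mm[s, 1L] <- if (l <= n) -l else l - n
    mm[s, 2L] <- if (r <= n) -r else r - n
  }
  # leaf display order from a depth-first walk of the final tree
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(mm[node, 1L]), walk(mm[node, 2L]))
  }
  ord <- walk(n - 1L)
  structure(list(merge = mm, height = history$merges$height, order = ord,
                 labels = history$labels %||% as.character(seq_len(n)),
                 method = history$linkage$criterion,
                 dist.method = history$metric$metric,
                 call = match.call()),
            class = "hclust")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a merge history
#'
#' \code{write_merge_table} writes the merge record as tab-separated text;
#' \code{write_newick} writes the dendrogram in Newick format with branch
#' lengths derived from merge heights, for external viewers.
#'
#' @param history a \code{\link{merge_history}}
#' @param path output file path
#' @export
write_merge_table <- function(history, path) {
  utils::write.table(history$merges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_merge_table
#' @export
write_newick <- function(history, path) {
  phy <- ape::as.phylo(as_hclust(history))
  ape::write.tree(phy, file = path)
  invisible(path)
}
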
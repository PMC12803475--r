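#' Distance metric specification
#'
#' The clustering grid uses seven point-to-point metrics: Euclidean, squared
#' Euclidean, cityblock (Manhattan), Chebyshev, Minkowski with configurable
#' exponent, Pearson correlation distance (1 - r) and Spearman distance
#' (1 - rank correlation, average ranks on ties). With the default exponent
#' of 2 the Minkowski metric coincides with the Euclidean one.
#'
#' @param metric one of \code{"euclidean"}, \code{"squared-euclidean"},
#'   \code{"cityblock"}, \code{"chebyshev"}, \code{"correlation"},
#'   \code{"spearman"}, \code{"minkowski"}
#' @param minkowski_exponent exponent p >= 1, used only for Minkowski
#' @return an object of class \code{distance_spec}
#' @export
distance_spec <- function(metric = c("euclidean", "squared-euclidean",
                                     "cityblock", "chebyshev", "correlation",
                                     "spearman", "minkowski"),
                          minkowski_exponent = 2) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(minkowski_exponent), length(minkowski_exponent) == 1L,
            minkowski_exponent >= 1)
  structure(list(metric = metric, minkowski_exponent = minkowski_exponent),
            class = "distance_spec")
}

#' Linkage criterion specification
#'
#' Cluster-to-cluster distances: \code{single} (minimum pairwise),
#' \code{complete} (maximum pairwise), \code{average} (mean pairwise) and
#' \code{centroid} (Euclidean distance between arithmetic-mean centroids,
#' independent of the point metric).
#'
#' @param criterion one of \code{"single"}, \code{"complete"},
#'   \code{"average"}, \code{"centroid"}
#' @return an object of class \code{linkage_spec}
#' @export
linkage_spec <- function(criterion = c("single", "complete", "average",
                                       "centroid")) {
  structure(list(criterion = match.arg(criterion)), class = "linkage_spec")
}

as_distance_spec <- function(x)
  if (inherits(x, "distance_spec")) x else distance_spec(x)
as_linkage_spec <- function(x)
  if (inherits(x, "linkage_spec")) x else linkage_spec(x)

#' Distance between two feature vectors
#'
#' @param a,b numeric vectors of equal length
#' @param spec a \code{\link{distance_spec}} (or metric name)
#' @return a nonnegative real
#' @examples
#' pairwise_distance(c(0, 3), c(4, 1), "euclidean")  # sqrt(20)
#' pairwise_distance(c(1, 0, 1), c(0, 0, 1), "cityblock")  # 1
#' @export
pairwise_distance <- function(a, b, spec) {
  spec <- as_distance_spec(spec)
  if (length(a) != length(b))
    stop("dimension error: vectors have lengths ", length(a), " and ",
         length(b))
  if (length(a) < 1L) stop("dimension error: empty vectors")
  d <- abs(a - b)
  switch(spec$metric,
    "euclidean" = sqrt(sum(d^2)),
    "squared-euclidean" = sum(d^2),
    "cityblock" = sum(d),
    "chebyshev" = max(d),
    "minkowski" = sum(d^spec$minkowski_exponent)^(1 / spec$minkowski_exponent),
    "correlation" = {
      check_nonconstant(rbind(a, b), spec$metric)
      1 - stats::cor(a, b)
    },
    "spearman" = {
      check_nonconstant(rbind(a, b), spec$metric)
      1 - stats::cor(a, b, method = "spearman")
    })
}

check_nonconstant <- function(X, metric, ids = NULL) {
  const <- apply(X, 1L, function(r) max(r) == min(r))
  if (any(const)) {
    who <- if (is.null(ids)) which(const) else ids[const]
    stop("metric-undefined: ", metric,
         " distance undefined for constant vector(s): ",
         paste(who, collapse = ", "))
  }
  invisible(TRUE)
}

#' All pairwise distances between the rows of a matrix
#'
#' @param X numeric matrix (subjects x features)
#' @param spec a \code{\link{distance_spec}} (or metric name)
#' @return a full symmetric matrix of distances with zero diagonal
#' @export
point_distance_matrix <- function(X, spec) {
  spec <- as_distance_spec(spec)
  D <- switch(spec$metric,
    "euclidean" = as.matrix(stats::dist(X, method = "euclidean")),
    "squared-euclidean" = as.matrix(stats::dist(X, method = "euclidean"))^2,
    "cityblock" = as.matrix(stats::dist(X, method = "manhattan")),
    "chebyshev" = as.matrix(stats::dist(X, method = "maximum")),
    "minkowski" = as.matrix(stats::dist(X, method = "minkowski",
                                        p = spec$minkowski_exponent)),
    "correlation" = {
      check_nonconstant(X, spec$metric, rownames(X))
      1 - stats::cor(t(X))
    },
    "spearman" = {
      check_nonconstant(X, spec$metric, rownames(X))
      1 - stats::cor(t(X), method = "spearman")
    })
  # correlation-family distances can dip microscopically below zero
  D[D < 0 & D > -1e-12] <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Distance between two clusters of subjects
#'
#' Evaluates the linkage criterion on the point metric: \code{single} is the
#' minimum pairwise distance, \code{complete} the maximum, \code{average} the
#' mean over all pairs, and \code{centroid} the Euclidean distance between
#' the arithmetic-mean centroids of the raw member rows (the centroid
#' criterion does not depend on the point metric).
#'
#' @param A,B nonempty, disjoint integer index sets (rows of \code{X})
#' @param X numeric matrix (subjects x features)
#' @param metric a \code{\link{distance_spec}} (or metric name)
#' @param linkage a \code{\link{linkage_spec}} (or criterion name)
#' @return a nonnegative real
#' @export
cluster_distance <- function(A, B, X, metric, linkage) {
  metric <- as_distance_spec(metric)
  linkage <- as_linkage_spec(linkage)
  if (length(A) == 0L || length(B) == 0L)
    stop("contract violation: empty cluster")
  if (length(intersect(A, B)))
    stop("contract violation: clusters overlap")
  if (linkage$criterion == "centroid") {
    ca <- colMeans(X[A, , drop = FALSE])
    cb <- colMeans(X[B, , drop = FALSE])
    return(sqrt(sum((ca - cb)^2)))
  }
  d <- outer(A, B, Vectorize(function(i, j)
    pairwise_distance(X[i, ], X[j, ], metric)))
  switch(linkage$criterion,
         single = min(d), complete = max(d), average = mean(d))
}
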
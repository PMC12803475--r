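#' Intra- and inter-cluster variability
#'
#' \code{intra_variability} is the mean Euclidean distance of a cluster's
#' member rows to their arithmetic-mean centroid; \code{inter_variability} is
#' the Euclidean distance between two clusters' centroids. Both are always
#' evaluated in Euclidean geometry, whatever metric was used to build the
#' clustering.
#'
#' @param members,A,B nonempty integer index sets (rows of \code{X})
#' @param x a \code{\link{cohort_matrix}} or numeric matrix
#' @return a nonnegative real
#' @examples
#' X <- matrix(c(0, 1, 5), ncol = 1)
#' intra_variability(1:2, X)  # 0.5
#' intra_variability(1:3, X)  # 2
#' @export
intra_variability <- function(members, x) {
  X <- if (inherits(x, "cohort_matrix")) x$values else x
  if (length(members) == 0L) stop("contract violation: empty cluster")
  rows <- X[members, , drop = FALSE]
  cen <- colMeans(rows)
  mean(sqrt(rowSums((rows - rep(cen, each = nrow(rows)))^2)))
}

#' @rdname intra_variability
#' @export
inter_variability <- function(A, B, x) {
  X <- if (inherits(x, "cohort_matrix")) x$values else x
  if (length(A) == 0L || length(B) == 0L)
    stop("contract violation: empty cluster")
  ca <- colMeans(X[A, , drop = FALSE])
  cb <- colMeans(X[B, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' R_k index of a partition
#'
#' The R_k cluster-validity index is the minimal inter-cluster centroid
#' distance divided by the maximal mean within-cluster distance to centroid.
#' Large values indicate compact, well-separated clusters. When every
#' cluster is perfectly compact (maximal intra-variability 0) the index is
#' \code{+Inf}; if additionally two centroids coincide (the 0/0 case, only
#' possible with duplicate rows) the result is still \code{+Inf} but carries
#' the attribute \code{degenerate = TRUE} so the run can be inspected.
#'
#' @param partition a list of at least two disjoint index sets covering all
#'   rows of \code{x}
#' @param x a \code{\link{cohort_matrix}} or numeric matrix
#' @return a positive real or \code{+Inf}
#' @examples
#' X <- matrix(c(0, 1, 5, 6), ncol = 1)
#' rk_of_partition(list(1:2, 3:4), X)  # 5 / 0.5 = 10
#' @export
rk_of_partition <- function(partition, x) {
  X <- if (inherits(x, "cohort_matrix")) x$values else x
  if (length(partition) < 2L)
    stop("contract violation: need at least 2 clusters")
  all_members <- sort(unlist(partition))
  if (!identical(as.integer(all_members), seq_len(nrow(X))))
    stop("contract violation: partition must cover all subjects exactly once")
  intra_max <- max(vapply(partition, intra_variability, numeric(1L), x = X))
  pairs <- utils::combn(length(partition), 2L)
  inter_min <- min(apply(pairs, 2L, function(p)
    inter_variability(partition[[p[1L]]], partition[[p[2L]]], X)))
  if (intra_max == 0) {
    out <- Inf
    if (inter_min == 0) attr(out, "degenerate") <- TRUE
    return(out)
  }
  inter_min / intra_max
}

#' R_k curve over candidate cluster counts
#'
#' Cuts the merge history at every k in \code{2..min(k_max, n)} and evaluates
#' \code{\link{rk_of_partition}} on each induced partition. The selected
#' cluster count maximizes R_k over the finite entries (smallest k on ties).
#' The curve is flagged divergent when any entry is infinite or when it is
#' strictly increasing across the whole scan window, the signature of an
#' index that keeps growing with ever finer clusterings.
#'
#' @param history a \code{\link{merge_history}}
#' @param x the matrix (or \code{\link{cohort_matrix}}) that was clustered
#' @param k_max upper end of the scan window (default 11, i.e. the last ten
#'   merge steps)
#' @return an object of class \code{rk_curve}: data frame with columns
#'   \code{k}, \code{rk} and attributes \code{selected_k} and
#'   \code{divergent}
#' @export
rk_curve <- function(history, x, k_max = 11) {
  X <- if (inherits(x, "cohort_matrix")) x$values else x
  n <- history$n_leaves
  stopifnot(k_max >= 2)
  ks <- 2:min(k_max, n)
  rk <- vapply(ks, function(k)
    as.numeric(rk_of_partition(cut_tree(history, k), X)), numeric(1L))
  finite <- is.finite(rk)
  # argmax over the finite entries, smallest k on ties; when every entry is
  # infinite (perfectly compact cuts throughout) fall back to the smallest k
  selected <- if (any(finite)) ks[which.max(replace(rk, !finite, -Inf))]
              else ks[which.max(rk)]
  divergent <- any(!finite) ||
    (length(rk) >= 2L && all(diff(rk) > 0))
  out <- data.frame(k = ks, rk = rk)
  attr(out, "selected_k") <- selected
  attr(out, "divergent") <- divergent
  class(out) <- c("rk_curve", "data.frame")
  out
}

#' @export
print.rk_curve <- function(x, ...) {
  cat(sprintf("<rk_curve> k = %d..%d, selected k = %s%s\n", min(x$k),
              max(x$k), attr(x, "selected_k"),
              if (attr(x, "divergent")) " (divergent)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Export an R_k curve as CSV
#'
#' @param curve an \code{\link{rk_curve}}
#' @param path output path; columns \code{k}, \code{rk}, \code{selected}
#' @export
write_rk_curve <- function(curve, path) {
  df <- data.frame(k = curve$k, rk = curve$rk,
                   selected = curve$k == attr(curve, "selected_k"))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
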
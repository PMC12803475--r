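#' Fit a PCA model to a normalized cohort
#'
#' Standardizes every feature (binary and continuous alike) to zero mean and
#' unit variance, computes the covariance of the standardized data with 1/n
#' weighting (so the matrix is the correlation matrix of the retained
#' features and its trace equals their count), and eigendecomposes it.
#' Zero-variance features carry no information and are dropped with a
#' warning. Eigenvector signs are arbitrary; each loading vector is oriented
#' so that its largest-magnitude entry is positive, which makes projections
#' deterministic across runs.
#'
#' @param cohort a normalized \code{\link{cohort_matrix}} with at least two
#'   subjects
#' @param n_components number of components kept for projection (default 2)
#' @return an object of class \code{pca_model}: feature means and (population)
#'   standard deviations, eigenvalues (nonincreasing), loadings (orthonormal
#'   columns), dropped feature keys, and the cohort's min-max normalization
#'   record for projecting new subjects
#' @export
fit_pca <- function(cohort, n_components = 2L) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  X <- cohort$values
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 subjects")
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(X^2) - mu^2)  # population sd, 1/n weighting
  keep <- sigma > 0
  if (!any(keep)) stop("degenerate input: all features are constant")
  if (any(!keep))
    warning("dropping zero-variance feature(s): ",
            paste(names(sigma)[!keep], collapse = ", "))
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sigma[keep],
             "/")
  S <- crossprod(Z) / n
  eig <- eigen(S, symmetric = TRUE)
  V <- eig$vectors
  # sign convention: largest-|entry| of each loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(Z)
  colnames(V) <- paste0("pc", seq_len(ncol(V)))
  structure(list(feature_means = mu[keep], feature_stds = sigma[keep],
                 eigenvalues = eig$values, loadings = V,
                 n_components = as.integer(n_components),
                 kept_features = colnames(Z),
                 dropped_features = names(sigma)[!keep],
                 catalog = cohort$catalog,
                 normalization = cohort$normalization),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features (%d dropped), leading eigenvalues: %s\n",
              length(x$kept_features), length(x$dropped_features),
              paste(signif(utils::head(x$eigenvalues, 3L), 6L),
                    collapse = ", ")))
  invisible(x)
}

standardize <- function(model, cohort) {
  missing <- setdiff(model$kept_features, colnames(cohort$values))
  if (length(missing))
    stop("schema error: cohort lacks model feature(s): ",
         paste(missing, collapse = ", "))
  X <- cohort$values[, model$kept_features, drop = FALSE]
  sweep(sweep(X, 2L, model$feature_means), 2L, model$feature_stds, "/")
}

#' Project subjects into the fitted component space
#'
#' Maps each subject of a cohort (already on the training scale) to scores
#' on the leading components via the stored standardization and loadings.
#'
#' @param model a \code{\link{fit_pca}} model
#' @param cohort a \code{\link{cohort_matrix}} on the training scale
#' @param group group label assigned to every point (default
#'   \code{"unlabeled"})
#' @return a data frame of class \code{projected_points} with columns
#'   \code{subject_id}, \code{pc1}, \code{pc2}, ... and \code{group}
#' @export
project <- function(model, cohort, group = "unlabeled") {
  Z <- standardize(model, cohort)
  avail <- min(model$n_components, ncol(model$loadings))
  scores <- matrix(0, nrow(Z), model$n_components,
                   dimnames = list(NULL, paste0("pc",
                                                seq_len(model$n_components))))
  # components beyond the retained rank carry no variance and stay at 0
  scores[, seq_len(avail)] <- Z %*% model$loadings[, seq_len(avail),
                                                   drop = FALSE]
  out <- data.frame(subject_id = rownames(Z), scores, group = group,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("projected_points", "data.frame")
  out
}

#' Project new subjects with the stored training transform
#'
#' New subjects are first mapped onto the training scale with the min-max
#' record stored at fit time (values outside the training range are allowed
#' and reported), then standardized with the training means and standard
#' deviations and projected on the training loadings. The model is never
#' refitted.
#'
#' @param model a \code{\link{fit_pca}} model fitted on a normalized cohort
#' @param new_cohort a raw \code{\link{cohort_matrix}} of new subjects on the
#'   original measurement scale
#' @return a \code{projected_points} data frame
#' @export
project_new <- function(model, new_cohort) {
  if (is.null(model$normalization))
    stop("contract violation: model carries no stored normalization record")
  scaled <- apply_normalization(new_cohort, model$normalization)
  project(model, scaled, group = "unlabeled")
}

#' Label projected points by nearest risk-group centroid
#'
#' Splits the reference points into a risk and a non-risk group (reference
#' points labeled \code{"ambiguous"} are pooled into non-risk), computes the
#' two group centroids in the leading-component plane, and labels each query
#' point by the nearer centroid (\code{"new-risk"} / \code{"new-nonrisk"}).
#' A query whose distance margin between the two centroids is below
#' \code{tol} is additionally flagged borderline.
#'
#' @param points \code{projected_points} to classify
#' @param reference \code{projected_points} whose \code{group} column
#'   contains \code{"risk"} and \code{"non-risk"} (and possibly
#'   \code{"ambiguous"})
#' @param tol distance margin below which a point is flagged borderline
#' @return \code{points} with \code{group} assigned and a logical
#'   \code{borderline} column
#' @export
classify_region <- function(points, reference, tol = 1e-8) {
  grp <- reference$group
  grp[grp == "ambiguous"] <- "non-risk"
  if (!any(grp == "risk") || !any(grp == "non-risk"))
    stop("contract violation: reference must contain both risk and non-risk points")
  pcs <- c("pc1", "pc2")
  cen_risk <- colMeans(reference[grp == "risk", pcs, drop = FALSE])
  cen_non <- colMeans(reference[grp == "non-risk", pcs, drop = FALSE])
  q <- as.matrix(points[, pcs, drop = FALSE])
  d_risk <- sqrt(rowSums((q - rep(cen_risk, each = nrow(q)))^2))
  d_non <- sqrt(rowSums((q - rep(cen_non, each = nrow(q)))^2))
  points$group <- ifelse(d_risk <= d_non, "new-risk", "new-nonrisk")
  points$borderline <- abs(d_risk - d_non) < tol
  points
}

#' Plot projected points
#'
#' Scatter of the first two components using the reference color scheme:
#' red for risk, blue for non-risk, black for ambiguous, yellow and green
#' for newly classified subjects.
#'
#' @param x a \code{projected_points} data frame
#' @param ... passed to \code{plot}
#' @export
plot.projected_points <- function(x, ...) {
  cols <- c(risk = "red", "non-risk" = "blue", ambiguous = "black",
            "new-risk" = "yellow3", "new-nonrisk" = "green3",
            unlabeled = "grey50")
  col <- cols[x$group]
  col[is.na(col)] <- "grey50"
  graphics::plot(x$pc1, x$pc2, col = col, pch = 19, xlab = "PC1",
                 ylab = "PC2", ...)
  invisible(x)
}

#' Store and reload a PCA model as plain text
#'
#' The store holds everything needed to project new subjects without
#' refitting: feature keys, means, standard deviations, eigenvalues,
#' loadings, dropped features and the min-max normalization record.
#'
#' @param model a \code{pca_model}
#' @param path output file path
#' @export
write_pca_model <- function(model, path) {
  num <- function(x) paste(formatC(x, digits = 17, format = "g"),
                           collapse = "\t")
  lines <- c(
    paste0("n_components\t", model$n_components),
    paste0("kept_features\t", paste(model$kept_features, collapse = "\t")),
    paste0("dropped_features\t",
           paste(model$dropped_features, collapse = "\t")),
    paste0("feature_means\t", num(model$feature_means)),
    paste0("feature_stds\t", num(model$feature_stds)),
    paste0("eigenvalues\t", num(model$eigenvalues)),
    vapply(seq_len(ncol(model$loadings)), function(j)
      paste0("loading\t", num(model$loadings[, j])), character(1L)),
    if (!is.null(model$normalization))
      vapply(seq_len(nrow(model$normalization)), function(i)
        paste("normalization", model$normalization$key[i],
              formatC(model$normalization$x_min[i], digits = 17, format = "g"),
              formatC(model$normalization$x_max[i], digits = 17, format = "g"),
              sep = "\t"), character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1L), 1L)
  val <- lapply(fields, `[`, -1L)
  get1 <- function(name) val[[which(tag == name)]]
  kept <- get1("kept_features")
  loadings <- do.call(cbind, lapply(val[tag == "loading"], as.numeric))
  rownames(loadings) <- kept
  colnames(loadings) <- paste0("pc", seq_len(ncol(loadings)))
  norm <- NULL
  if (any(tag == "normalization")) {
    rows <- val[tag == "normalization"]
    norm <- data.frame(key = vapply(rows, `[`, character(1L), 1L),
                       x_min = as.numeric(vapply(rows, `[`, character(1L), 2L)),
                       x_max = as.numeric(vapply(rows, `[`, character(1L), 3L)))
  }
  structure(list(
    feature_means = stats::setNames(as.numeric(get1("feature_means")), kept),
    feature_stds = stats::setNames(as.numeric(get1("feature_stds")), kept),
    eigenvalues = as.numeric(get1("eigenvalues")),
    loadings = loadings,
    n_components = as.integer(get1("n_components")),
    kept_features = kept,
    dropped_features = setdiff(get1("dropped_features"), ""),
    catalog = NULL,
    normalization = norm), class = "pca_model")
}
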
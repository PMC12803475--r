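pca_cohort <- function(n = 30, seed = 13) {
  set.seed(seed)
  toy_cohort(matrix(rbinom(n * 7, 1, 0.4), n, 7), hr = runif(n, 45, 160))
}

test_that("perfectly correlated standardized features give eigenvalues 2, 0", {
  x <- c(0.1, 0.4, 0.7, 0.9)
  X <- cbind(f1 = x, f2 = 2 * x + 1)
  rownames(X) <- paste0("s", 1:4)
  catL <- catalog_subset(feature_catalog(), "L")[7:8, ]
  catL$value_type <- "continuous"
  cohort <- cohort_matrix(matrix(X, 4, 2,
                                 dimnames = list(rownames(X), catL$key)),
                          catL)
  model <- fit_pca(cohort)
  expect_equal(model$eigenvalues, c(2, 0), tolerance = 1e-12)
})

test_that("the correlation-form trace identity holds", {
  norm <- minmax_normalize(pca_cohort())
  model <- fit_pca(norm)
  expect_equal(sum(model$eigenvalues), length(model$kept_features),
               tolerance = 1e-6)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))   # nonincreasing
  expect_true(all(model$eigenvalues >= -1e-10))
  # loadings orthonormal
  G <- crossprod(model$loadings)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("projection honors the PCA identities", {
  norm <- minmax_normalize(pca_cohort(n = 40, seed = 19))
  model <- fit_pca(norm)
  pts <- project(model, norm)
  n <- nrow(norm$values)
  # per-component projected variance (1/n weighting) equals the eigenvalue
  expect_equal(mean(pts$pc1^2) - mean(pts$pc1)^2, model$eigenvalues[1L],
               tolerance = 1e-6)
  expect_equal(mean(pts$pc2^2) - mean(pts$pc2)^2, model$eigenvalues[2L],
               tolerance = 1e-6)
  # a subject at the training mean of every feature projects to the origin
  mean_subj <- norm
  mean_subj$values <- rbind(colMeans(norm$values))
  rownames(mean_subj$values) <- "mean"
  at_mean <- project(model, mean_subj)
  expect_equal(c(at_mean$pc1, at_mean$pc2), c(0, 0), tolerance = 1e-10)
  # identical subjects project identically
  expect_equal(pts[1, c("pc1", "pc2")],
               project(model, norm)[1, c("pc1", "pc2")])
})

test_that("full-rank reconstruction reproduces the standardized data", {
  norm <- minmax_normalize(pca_cohort(n = 25, seed = 23))
  model <- fit_pca(norm)
  Z <- scdrisk:::standardize(model, norm)
  scores <- Z %*% model$loadings
  expect_equal(scores %*% t(model$loadings), Z, tolerance = 1e-8)
})

test_that("projection is invariant to subject order and has fixed signs", {
  norm <- minmax_normalize(pca_cohort(n = 30, seed = 29))
  model <- fit_pca(norm)
  perm <- sample(seq_len(30))
  shuffled <- norm
  shuffled$values <- norm$values[perm, ]
  m2 <- fit_pca(shuffled)
  expect_equal(model$loadings, m2$loadings, tolerance = 1e-10)
  p1 <- project(model, norm)
  p2 <- project(m2, shuffled)
  expect_equal(p1[match(p2$subject_id, p1$subject_id), c("pc1", "pc2")],
               p2[, c("pc1", "pc2")], ignore_attr = TRUE, tolerance = 1e-10)
  # sign convention: largest-magnitude loading entry is positive
  for (j in 1:2) {
    col <- model$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("new subjects are projected with the stored transform only", {
  raw <- pca_cohort(n = 30, seed = 31)
  norm <- minmax_normalize(raw)
  model <- fit_pca(norm)
  pts <- project(model, norm)
  # a new subject identical to a training subject lands on the same point
  new <- raw
  new$values <- raw$values[3, , drop = FALSE]
  rownames(new$values) <- "copy"
  new <- cohort_matrix(new$values, raw$catalog)
  got <- project_new(model, new)
  expect_equal(c(got$pc1, got$pc2),
               as.numeric(pts[3, c("pc1", "pc2")]), tolerance = 1e-12)
  no_norm <- model
  no_norm$normalization <- NULL
  expect_error(project_new(no_norm, new), "no stored normalization")
})

test_that("nearest-centroid region labeling behaves at the boundaries", {
  reference <- data.frame(
    subject_id = paste0("r", 1:6),
    pc1 = c(5, 5.5, 4.5, -5, -5.5, -4.5), pc2 = c(0, 1, -1, 0, 1, -1),
    group = c("risk", "risk", "risk", "non-risk", "non-risk", "ambiguous"))
  class(reference) <- c("projected_points", "data.frame")
  q <- data.frame(subject_id = c("at_risk_centroid", "midpoint"),
                  pc1 = c(5, 0.08333333333333333), pc2 = c(0, 0))
  cen_risk <- colMeans(reference[reference$group == "risk", c("pc1", "pc2")])
  q$pc1[1] <- cen_risk[["pc1"]]; q$pc2[1] <- cen_risk[["pc2"]]
  # exact midpoint of the two centroids in pc1
  grp <- replace(reference$group, reference$group == "ambiguous", "non-risk")
  cen_non <- colMeans(reference[grp == "non-risk", c("pc1", "pc2")])
  q$pc1[2] <- (cen_risk[["pc1"]] + cen_non[["pc1"]]) / 2
  q$pc2[2] <- (cen_risk[["pc2"]] + cen_non[["pc2"]]) / 2
  out <- classify_region(q, reference)
  expect_equal(out$group[1], "new-risk")
  expect_true(out$borderline[2])
  expect_error(classify_region(q, reference[reference$group == "risk", ]),
               "both risk and non-risk")
})

test_that("region labeling is invariant under rigid rotation of the plane", {
  set.seed(41)
  reference <- data.frame(subject_id = paste0("r", 1:40),
                          pc1 = c(rnorm(20, 3), rnorm(20, -3)),
                          pc2 = rnorm(40),
                          group = rep(c("risk", "non-risk"), each = 20))
  q <- data.frame(subject_id = paste0("q", 1:10), pc1 = rnorm(10),
                  pc2 = rnorm(10))
  base <- classify_region(q, reference)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(df) {
    xy <- as.matrix(df[, c("pc1", "pc2")]) %*% R
    df$pc1 <- xy[, 1]; df$pc2 <- xy[, 2]
    df
  }
  rotated <- classify_region(rot(q), rot(reference))
  expect_equal(rotated$group, base$group)
})

test_that("the plain-text model store reloads to the same projections", {
  norm <- minmax_normalize(pca_cohort(n = 20, seed = 37))
  model <- fit_pca(norm)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_equal(back$eigenvalues, model$eigenvalues)
  expect_equal(back$loadings, model$loadings)
  p1 <- project(model, norm); p2 <- project(back, norm)
  expect_equal(p2$pc1, p1$pc1)
  expect_equal(p2$pc2, p1$pc2)
})
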
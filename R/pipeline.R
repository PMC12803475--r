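#' Run the full risk-pattern analysis
#'
#' End-to-end orchestration of the pipeline: feature-subset selection,
#' min-max normalization, the metric-by-linkage clustering grid with
#' R_k-driven tree cutting, exclusion rules, cross-run consolidation into a
#' final clustering proposal, risk versus non-risk feature profiling, and
#' PCA projection with risk labels. Input is either an existing cohort or a
#' synthetic-cohort spec. When \code{out_dir} is given, the stage artifacts
#' are written there as plain text (grid report, consolidated clustering,
#' profile table, PCA model store, projected points, R_k curves, manifest);
#' reruns with the same configuration produce identical files.
#'
#' @param cohort a raw \code{\link{cohort_matrix}} (ignored when
#'   \code{synthetic} is given)
#' @param synthetic optional \code{\link{synthetic_spec}} to generate the
#'   cohort from
#' @param catalog catalog used with \code{synthetic} (default the full
#'   45-feature catalog)
#' @param subset feature subset to analyse: \code{"L"}, \code{"complete"} or
#'   \code{"LE"}
#' @param metrics,linkages the clustering grid (defaults: 6 metrics x 4
#'   criteria)
#' @param k_max R_k scan window (default 11)
#' @param max_minority_fraction exclusion threshold for 2-cluster runs
#' @param alpha significance level for the profile table
#' @param merge_map optional consolidation directives
#'   (see \code{\link{consolidate}})
#' @param overlap_policy overlap handling during consolidation; the
#'   automated default is \code{"union"}
#' @param out_dir optional artifact directory
#' @param seed seed recorded in the manifest and used for any stage without
#'   its own seed
#' @return list with elements \code{cohort_raw}, \code{cohort} (normalized
#'   subset), \code{runs}, \code{consensus} (\code{NULL} if no run was
#'   retained), \code{risk_ids}, \code{profile}, \code{model},
#'   \code{points}, \code{truth} (synthetic only) and \code{config}
#' @export
run_pipeline <- function(cohort = NULL, synthetic = NULL,
                         catalog = feature_catalog(),
                         subset = c("L", "complete", "LE"),
                         metrics = default_metric_grid(),
                         linkages = default_linkage_grid(),
                         k_max = 11, max_minority_fraction = 0.10,
                         alpha = 0.05, merge_map = NULL,
                         overlap_policy = "union", out_dir = NULL,
                         seed = 1L) {
  subset <- match.arg(subset)
  truth <- NULL
  if (!is.null(synthetic)) {
    gen <- generate_cohort(synthetic, catalog)
    cohort <- gen$cohort
    truth <- gen$labels
  }
  if (is.null(cohort)) stop("provide a cohort or a synthetic spec")
  set.seed(seed)

  raw <- select_subset(cohort, subset)
  norm <- minmax_normalize(raw)
  runs <- run_grid(norm, metrics, linkages, k_max = k_max,
                   dataset_tag = subset)
  runs <- apply_exclusions(runs, max_minority_fraction)

  consensus <- NULL
  risk_ids <- character(0)
  if (length(retained_runs(runs))) {
    consensus <- consolidate(runs, merge_map = merge_map,
                             overlap_policy = overlap_policy)
    risk_ids <- consensus$different_subjects
  }

  profile <- NULL
  if (length(risk_ids) && length(risk_ids) < nrow(raw$values))
    profile <- prevalence_table(raw, risk_ids, alpha = alpha)

  model <- fit_pca(norm)
  points <- project(model, norm)
  points$group <- ifelse(points$subject_id %in% risk_ids, "risk", "non-risk")

  result <- list(cohort_raw = raw, cohort = norm, runs = runs,
                 consensus = consensus, risk_ids = risk_ids,
                 profile = profile, model = model, points = points,
                 truth = truth,
                 config = list(subset = subset, k_max = k_max,
                               max_minority_fraction = max_minority_fraction,
                               alpha = alpha,
                               overlap_policy = overlap_policy,
                               seed = seed))
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(grid_report(result$runs), p("grid_report.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(result$consensus))
    write_consolidated(result$consensus, p("consolidated.csv"),
                       dataset_tag = result$config$subset)
  if (!is.null(result$profile))
    utils::write.table(
      format_profile(result$profile), p("profile.csv"),
      sep = ",", row.names = FALSE, quote = FALSE)
  write_pca_model(result$model, p("pca_model.txt"))
  utils::write.table(result$points, p("points.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  for (r in result$runs)
    if (!is.null(r$rk))
      write_rk_curve(r$rk, p(sprintf("rk_%s.csv", gsub("/", "_", r$label))))
  cfg <- result$config
  writeLines(c(
    sprintf("package: scdrisk %s",
            as.character(utils::packageVersion("scdrisk"))),
    sprintf("subset: %s", cfg$subset),
    sprintf("k_max: %s", cfg$k_max),
    sprintf("max_minority_fraction: %s", cfg$max_minority_fraction),
    sprintf("alpha: %s", cfg$alpha),
    sprintf("overlap_policy: %s", cfg$overlap_policy),
    sprintf("seed: %s", cfg$seed)), p("manifest.txt"))
  invisible(out_dir)
}

# percentages with two decimals, means/sds with two decimals
format_profile <- function(profile) {
  out <- profile
  pct <- out$value_type == "binary"
  out$risk_value <- ifelse(pct, sprintf("%.2f%%", profile$risk_value),
                           sprintf("%.2f", profile$risk_value))
  out$nonrisk_value <- ifelse(pct, sprintf("%.2f%%", profile$nonrisk_value),
                              sprintf("%.2f", profile$nonrisk_value))
  out
}

#' Classify new subjects against a fitted pipeline
#'
#' Projects new subjects with the pipeline's stored normalization and PCA
#' transform and labels each by the nearer of the risk / non-risk centroids
#' of the training projection (\code{\link{classify_region}}).
#'
#' @param result a \code{\link{run_pipeline}} result (or a list with
#'   elements \code{model} and \code{points})
#' @param new_cohort a raw \code{\link{cohort_matrix}} of new subjects on
#'   the original measurement scale, sharing the training feature subset
#' @param tol borderline margin passed to \code{\link{classify_region}}
#' @return a \code{projected_points} data frame with assigned groups
#' @export
classify_new <- function(result, new_cohort, tol = 1e-8) {
  if (nrow(new_cohort$values) == 0L) {
    warning("empty new-subject table")
    out <- result$points[0, , drop = FALSE]
    out$borderline <- logical(0)
    return(out)
  }
  new_sub <- select_subset(new_cohort, result$config$subset %||% "L")
  pts <- project_new(result$model, new_sub)
  classify_region(pts, result$points, tol = tol)
}
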
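#' Published clustering bookkeeping shipped with the package
#'
#' The package ships plain-text transcriptions of the published cluster
#' memberships for the 711-athlete survey: the retained clustering patterns
#' per dataset (4 patterns for the 8-feature dataset \code{"L"}, 7 for the
#' 45-feature dataset \code{"LE"}, each pattern a list of minority clusters
#' of subject ids), the consolidated final clustering proposals, and the
#' merge-map directives under which \code{\link{consolidate}} reproduces the
#' consolidated proposals exactly.
#'
#' \code{reported_clusterings} parses the pattern fixture;
#' \code{reported_runs} wraps each pattern as a retained
#' \code{clustering_run} over the full 711-subject universe (the majority
#' cluster being all subjects in no minority cluster), ready for
#' \code{\link{consolidate}} and \code{\link{different_subjects}}.
#'
#' Note: the published prose counts 64 "different" subjects, while the union
#' of the two transcribed risk sets is 37 + 33 - 7 = 63; the fixtures encode
#' the printed memberships verbatim and leave the discrepancy standing.
#'
#' @param path fixture path; defaults to the file installed with the package
#' @return \code{reported_clusterings}: a list with elements \code{L} and
#'   \code{LE}, each a list of patterns (\code{pattern}, \code{runs},
#'   \code{clusters})
#' @export
reported_clusterings <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reported_clusterings.tsv",
                                package = "scdrisk", mustWork = TRUE)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", quote = ""),
    error = function(e) stop("parse error: ", conditionMessage(e)))
  need <- c("dataset", "pattern", "runs", "cluster", "members")
  if (!identical(names(tab), need))
    stop("parse error: fixture columns must be ",
         paste(need, collapse = ", "))
  out <- list()
  for (ds in unique(tab$dataset)) {
    sub <- tab[tab$dataset == ds, , drop = FALSE]
    pats <- list()
    for (p in unique(sub$pattern)) {
      rows <- sub[sub$pattern == p, , drop = FALSE]
      clusters <- lapply(strsplit(rows$members, ","), trimws)
      if (any(!lengths(clusters)))
        stop("parse error: empty cluster in pattern ", p)
      pats[[length(pats) + 1L]] <-
        list(pattern = p, runs = rows$runs[1L], clusters = clusters)
    }
    out[[ds]] <- pats
  }
  out
}

#' @rdname reported_clusterings
#' @param dataset \code{"L"} or \code{"LE"}
#' @param universe subject universe (default the 711 published ids)
#' @export
reported_runs <- function(dataset = c("L", "LE"), path = NULL,
                          universe = reported_universe()) {
  dataset <- match.arg(dataset)
  pats <- reported_clusterings(path)[[dataset]]
  if (is.null(pats)) stop("parse error: no patterns for dataset ", dataset)
  lapply(pats, function(p) {
    minorities <- p$clusters
    flagged <- unlist(minorities)
    if (!all(flagged %in% universe))
      stop("parse error: pattern ", p$pattern,
           " names subjects outside the universe")
    majority <- setdiff(universe, flagged)
    new_clustering_run(
      dataset_tag = dataset,
      metric = list(metric = "reported"),
      linkage = list(criterion = "reported"),
      partition = c(list(majority), minorities),
      universe = universe,
      label = paste0("pattern ", p$pattern, ": ", p$runs))
  })
}

#' @rdname reported_clusterings
#' @export
reported_universe <- function() as.character(1:711)

#' @rdname reported_clusterings
#' @export
reported_merge_map <- function(dataset = c("L", "LE"), path = NULL) {
  dataset <- match.arg(dataset)
  path <- path %||% system.file("extdata", "merge_map.tsv",
                                package = "scdrisk", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  tab <- tab[tab$dataset == dataset, , drop = FALSE]
  lapply(strsplit(tab$members, ","), trimws)
}

#' @rdname reported_clusterings
#' @export
reported_final_proposal <- function(dataset = c("L", "LE"), path = NULL) {
  dataset <- match.arg(dataset)
  path <- path %||% system.file("extdata", "final_proposals.tsv",
                                package = "scdrisk", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  tab <- tab[tab$dataset == dataset, , drop = FALSE]
  clusters <- lapply(strsplit(tab$members, ","), trimws)
  names(clusters) <- tab$cluster
  is_others <- vapply(clusters, function(cl) identical(cl, "Others"),
                      logical(1L))
  list(final_clusters = clusters[!is_others],
       others_label = tab$cluster[is_others])
}

#' Consolidate the published clustering patterns of one dataset
#'
#' Runs \code{\link{consolidate}} on the fixture-encoded patterns with the
#' shipped merge map, reproducing the published final clustering proposal.
#'
#' @inheritParams reported_runs
#' @return a \code{consensus_result}
#' @examples
#' \donttest{
#' res <- consolidate_reported("L")
#' length(res$different_subjects)        # 37
#' length(res$final_clusters) + 1L       # 10 clusters including Others
#' }
#' @export
consolidate_reported <- function(dataset = c("L", "LE")) {
  dataset <- match.arg(dataset)
  consolidate(reported_runs(dataset),
              merge_map = reported_merge_map(dataset))
}
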
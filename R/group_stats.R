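#' Risk versus non-risk feature profile
#'
#' Compares the flagged (risk) subjects against the rest of the cohort,
#' feature by feature: for binary features the percentage of active subjects
#' per group with a two-sided Fisher exact test; for continuous features the
#' group means and standard deviations with a Welch (unequal-variance)
#' two-sided t test. No multiplicity correction is applied; the test choices
#' and alpha are recorded as attributes of the result.
#'
#' @param cohort a \code{\link{cohort_matrix}} (raw scale recommended, so
#'   continuous summaries are in measurement units)
#' @param risk_ids nonempty strict subset of the cohort's subject ids
#' @param alpha significance level (default 0.05)
#' @return a data frame with one row per feature: \code{key},
#'   \code{feature_id}, \code{name}, \code{value_type}, \code{risk_value}
#'   (prevalence \% or mean), \code{nonrisk_value}, \code{risk_sd},
#'   \code{nonrisk_sd} (continuous only), \code{p_value},
#'   \code{significant}
#' @export
prevalence_table <- function(cohort, risk_ids, alpha = 0.05) {
  ids <- subject_ids(cohort)
  risk_ids <- as.character(risk_ids)
  if (!length(risk_ids) || !all(risk_ids %in% ids))
    stop("contract violation: risk_ids must be a nonempty subset of the cohort")
  if (length(risk_ids) >= length(ids))
    stop("contract violation: risk_ids must be a strict subset")
  in_risk <- ids %in% risk_ids
  cat <- cohort$catalog
  out <- lapply(seq_len(nrow(cat)), function(j) {
    x <- cohort$values[, cat$key[j]]
    if (cat$value_type[j] == "binary") {
      a <- sum(x[in_risk]); b <- sum(x[!in_risk])
      tab <- matrix(c(a, sum(in_risk) - a, b, sum(!in_risk) - b), 2L)
      p <- stats::fisher.test(tab)$p.value
      data.frame(key = cat$key[j], feature_id = cat$feature_id[j],
                 name = cat$name[j], value_type = "binary",
                 risk_value = 100 * a / sum(in_risk),
                 nonrisk_value = 100 * b / sum(!in_risk),
                 risk_sd = NA_real_, nonrisk_sd = NA_real_,
                 p_value = p, stringsAsFactors = FALSE)
    } else {
      p <- stats::t.test(x[in_risk], x[!in_risk], var.equal = FALSE)$p.value
      data.frame(key = cat$key[j], feature_id = cat$feature_id[j],
                 name = cat$name[j], value_type = "continuous",
                 risk_value = mean(x[in_risk]),
                 nonrisk_value = mean(x[!in_risk]),
                 risk_sd = stats::sd(x[in_risk]),
                 nonrisk_sd = stats::sd(x[!in_risk]),
                 p_value = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_value < alpha
  attr(out, "alpha") <- alpha
  attr(out, "tests") <- c(binary = "fisher.exact", continuous = "welch.t")
  out
}

#' Feature-activation patterns of the final clusters
#'
#' For each final (non-Others) cluster of a consolidation, reports which
#' binary features its members activate: \code{subgroups} lists, per
#' cluster, the distinct activation patterns with the subjects sharing each
#' pattern; \code{summary} is a cluster-by-feature logical matrix marking
#' features activated by at least one member (the union of the subgroup
#' patterns).
#'
#' @param cohort a \code{\link{cohort_matrix}} covering the consolidated
#'   subjects
#' @param consensus a \code{consensus_result}
#' @return list with elements \code{subgroups} and \code{summary}
#' @export
pattern_matrix <- function(cohort, consensus) {
  bin_keys <- cohort$catalog$key[cohort$catalog$value_type == "binary"]
  B <- cohort$values[, bin_keys, drop = FALSE] > 0
  subgroups <- lapply(consensus$final_clusters, function(cl) {
    rows <- B[cl, , drop = FALSE]
    sig <- apply(rows, 1L, function(r) paste(as.integer(r), collapse = ""))
    lapply(split(cl, sig), function(members)
      list(members = sort_ids(members),
           active = bin_keys[rows[members[1L], ]]))
  })
  summary <- t(vapply(consensus$final_clusters, function(cl)
    apply(B[cl, , drop = FALSE], 2L, any), logical(length(bin_keys))))
  dimnames(summary) <- list(names(consensus$final_clusters), bin_keys)
  list(subgroups = subgroups, summary = summary)
}
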
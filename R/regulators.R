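#' Putative TF regulators of eRNAs in one cohort
#'
#' Correlates every TF with every detectable eRNA over the cohort's tumor
#' samples (Spearman, pairwise-complete) and keeps edges with
#' `Rs >= rs_min` and BH-FDR `q < fdr_max`. The FDR adjustment is applied
#' jointly over all TF x eRNA tests within the cohort. Only positive
#' correlations qualify by default (`regulator_absolute = TRUE` switches to
#' `|Rs|`).
#'
#' @param tf_expr TF x sample expression matrix (cohort samples).
#' @param erna_expr eRNA x sample expression matrix (same samples),
#'   already restricted to the cohort's detectable eRNAs.
#' @param cohort cohort label stored on the records.
#' @param config a [pipeline_config()].
#' @return data.frame of edges `(tf_id, erna_id, cohort, n, Rs, p, q)`.
#' @export
putative_regulators <- function(tf_expr, erna_expr, cohort,
                                config = pipeline_config()) {
  rec <- cor_records(tf_expr, erna_expr, min_n = config$min_pairs_n)
  names(rec)[names(rec) == "x_id"] <- "tf_id"
  names(rec)[names(rec) == "y_id"] <- "erna_id"
  rec$cohort <- cohort
  rec$q <- bh_fdr(rec$p)
  pass_rs <- if (isTRUE(config$regulator_absolute)) abs(rec$Rs) else rec$Rs
  edges <- rec[pass_rs >= config$rs_min & rec$q < config$fdr_max, , drop = FALSE]
  rownames(edges) <- NULL
  edges[, c("tf_id", "erna_id", "cohort", "n", "Rs", "p", "q")]
}

#' Master regulators per cohort
#'
#' A TF is a putative master regulator of a cohort when it is significantly
#' correlated with at least `master_fraction` (default 25%) of the cohort's
#' detectable eRNAs.
#'
#' @param edges regulator edges from [putative_regulators()] (one or more
#'   cohorts row-bound).
#' @param detectable_counts named integer vector: detectable eRNAs per
#'   cohort.
#' @param tf_ids character vector of all TFs tested (TFs with zero edges are
#'   reported with fraction 0).
#' @param config a [pipeline_config()].
#' @return data.frame `(tf_id, cohort, n_ernas_correlated,
#'   n_ernas_detectable, fraction, is_master)`.
#' @export
master_regulators <- function(edges, detectable_counts, tf_ids,
                              config = pipeline_config()) {
  cohorts <- names(detectable_counts)
  if (any(detectable_counts <= 0)) {
    stop("cohort with zero detectable eRNAs: ",
         paste(cohorts[detectable_counts <= 0], collapse = ", "))
  }
  grid <- expand.grid(tf_id = tf_ids, cohort = cohorts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(edges$tf_id, edges$cohort, sep = "\r")
  counts <- tapply(edges$erna_id, key, function(v) length(unique(v)))
  grid$n_ernas_correlated <- as.integer(counts[paste(grid$tf_id, grid$cohort, sep = "\r")])
  grid$n_ernas_correlated[is.na(grid$n_ernas_correlated)] <- 0L
  grid$n_ernas_detectable <- as.integer(detectable_counts[grid$cohort])
  grid$fraction <- grid$n_ernas_correlated / grid$n_ernas_detectable
  grid$is_master <- grid$fraction >= config$master_fraction
  grid[order(grid$cohort, -grid$fraction, grid$tf_id), , drop = FALSE]
}

#' General master regulators across cancer types
#'
#' Flags TFs that are master regulators in at least
#' `general_master_min_types` cohorts (default 10).
#'
#' @param profiles output of [master_regulators()].
#' @param config a [pipeline_config()].
#' @return data.frame `(tf_id, n_cohorts_master, is_general_master)`.
#' @export
general_master_regulators <- function(profiles, config = pipeline_config()) {
  n_master <- tapply(profiles$is_master, profiles$tf_id, sum)
  out <- data.frame(tf_id = names(n_master),
                    n_cohorts_master = as.integer(n_master),
                    stringsAsFactors = FALSE)
  out$is_general_master <- out$n_cohorts_master >= config$general_master_min_types
  rownames(out) <- NULL
  out[order(-out$n_cohorts_master, out$tf_id), , drop = FALSE]
}
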
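#' eRNA-drug response associations across cell lines
#'
#' Spearman correlation between eRNA expression and drug-response AUC over
#' the shared cell lines, BH-FDR over all (eRNA, drug) pairs within the
#' source. Higher AUC means a more resistant line (CTRP/GDSC convention),
#' so a significant negative correlation is labeled `sensitive` (high
#' expression, low AUC) and a significant positive one `resistant`.
#'
#' @param erna_expr eRNA x cell-line RPM matrix.
#' @param auc drug x cell-line AUC matrix (missing AUCs allowed).
#' @param source label for the drug-response source (e.g. `"ctrp"`); FDR is
#'   controlled separately per source.
#' @param config a [pipeline_config()].
#' @return data.frame `(erna_id, drug_id, source, n, Rs, p, q, direction)`.
#' @export
drug_associations <- function(erna_expr, auc, source = "ctrp",
                              config = pipeline_config()) {
  shared <- intersect(colnames(erna_expr), colnames(auc))
  if (!length(shared)) stop("no shared cell lines between expression and AUC")
  rec <- cor_records(erna_expr[, shared, drop = FALSE],
                     auc[, shared, drop = FALSE],
                     min_n = config$min_pairs_n)
  names(rec)[names(rec) == "x_id"] <- "erna_id"
  names(rec)[names(rec) == "y_id"] <- "drug_id"
  rec$source <- source
  rec$q <- bh_fdr(rec$p)
  rec$direction <- ifelse(rec$q < config$fdr_max & rec$Rs < 0, "sensitive",
                   ifelse(rec$q < config$fdr_max & rec$Rs > 0, "resistant",
                          "none"))
  rec[, c("erna_id", "drug_id", "source", "n", "Rs", "p", "q", "direction")]
}

#' Within- versus cross-pathway eRNA-drug relationships
#'
#' An association is `within` when the eRNA has at least one putative target
#' gene in the drug's target pathway, `cross` when the eRNA has
#' pathway-annotated targets but none in the drug's pathway, and
#' `unassigned` otherwise (no annotated targets, or drug absent from the
#' map).
#'
#' @param associations output of [drug_associations()].
#' @param erna_pathways `(erna_id, pathway)` table from
#'   [annotate_pathways()].
#' @param drug_pathways data.frame `(drug, pathway)` mapping each drug to
#'   its target pathway.
#' @return `associations` with an added `pathway_relation` column.
#' @export
classify_pathway_relation <- function(associations, erna_pathways,
                                      drug_pathways) {
  erna_sets <- split(erna_pathways$pathway, erna_pathways$erna_id)
  drug_map <- split(drug_pathways$pathway, drug_pathways$drug)
  rel <- vapply(seq_len(nrow(associations)), function(i) {
    ep <- erna_sets[[associations$erna_id[i]]]
    dp <- drug_map[[associations$drug_id[i]]]
    if (is.null(ep) || !length(ep) || is.null(dp) || !length(dp)) return("unassigned")
    if (length(intersect(ep, dp))) "within" else "cross"
  }, character(1))
  associations$pathway_relation <- rel
  associations
}
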
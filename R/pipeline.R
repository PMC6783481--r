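#' Run the full eRNA pipeline from a file manifest
#'
#' Chains region building, quantification, classification, regulator
#' inference, target-network construction with Hi-C support and permutation
#' enrichment, pharmacogenomic screening and clinical association, writing
#' one TSV per stage plus a YAML run log (configuration, seed, input
#' checksums). Stages can be restricted; each stage checks its inputs
#' before any computation.
#'
#' @param manifest named list of input paths: `enhancers` (character vector
#'   of per-source BEDs), `genes`, `lncrnas`, `blacklist`, `chrom_lengths`,
#'   `counts`, `library_sizes`, `metadata`, `tf_list`, `hic`,
#'   `cell_counts`, `cell_library_sizes`, `auc`, `pathways`,
#'   `drug_pathways`.
#' @param outdir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param stages subset of `c("regions", "quantify", "regulators",
#'   "network", "hic", "pharmaco", "clinical")`.
#' @return named list of result objects (also written under `outdir`).
#' @export
run_pipeline <- function(manifest, outdir, config = pipeline_config(),
                         stages = c("regions", "quantify", "regulators",
                                    "network", "hic", "pharmaco",
                                    "clinical")) {
  stages <- match.arg(stages, several.ok = TRUE)
  needs <- list(
    regions = c("enhancers", "genes", "lncrnas", "blacklist", "chrom_lengths"),
    quantify = c("counts", "library_sizes", "metadata"),
    regulators = c("counts", "library_sizes", "metadata", "tf_list"),
    network = c("counts", "library_sizes", "metadata", "genes", "pathways"),
    hic = "hic",
    pharmaco = c("cell_counts", "cell_library_sizes", "auc", "drug_pathways"),
    clinical = c("counts", "library_sizes", "metadata")
  )
  required <- unique(unlist(needs[stages]))
  missing_in <- required[!vapply(required, function(k) {
    !is.null(manifest[[k]]) && all(file.exists(manifest[[k]]))
  }, logical(1))]
  if (length(missing_in)) {
    stop("manifest lacks input(s) for requested stages: ",
         paste(missing_in, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  p <- function(f) file.path(outdir, f)

  if (any(c("regions", "quantify", "network") %in% stages)) {
    sources <- lapply(seq_along(manifest$enhancers), function(i)
      read_bed(manifest$enhancers[i], role = "enhancer",
               source = paste0("source", i)))
    genes <- read_gene_table(manifest$genes, role = "gene")
    lncrnas <- read_gene_table(manifest$lncrnas, role = "lncRNA")
    blacklist <- read_bed(manifest$blacklist, role = "blacklist")
    cl <- utils::read.delim(manifest$chrom_lengths, stringsAsFactors = FALSE)
    chrom_lengths <- stats::setNames(as.integer(cl$length), cl$chrom)
    built <- build_erna_regions(sources, genes, lncrnas, blacklist,
                                chrom_lengths, config)
    out$regions <- built$regions
    out$dropped <- built$dropped
    write_tsv(built$regions, p("erna_regions.tsv"))
    write_bed(annotation_set(built$regions[, c("chrom", "start", "end")],
                             role = "enhancer", source = "eRNA_regions"),
              p("erna_regions.bed"))
    write_tsv(built$dropped, p("region_drop_audit.tsv"))
  }

  if (any(c("quantify", "regulators", "network", "clinical") %in% stages)) {
    counts <- read_matrix(manifest$counts)
    ls_df <- utils::read.delim(manifest$library_sizes, stringsAsFactors = FALSE)
    library_sizes <- stats::setNames(ls_df$library_size, ls_df$sample)
    metadata <- read_metadata(manifest$metadata)
    expr <- rpm(counts, library_sizes)
    erna_rows <- if (!is.null(out$regions)) {
      intersect(rownames(expr), out$regions$id)
    } else grep("^eRNA", rownames(expr), value = TRUE)
    erna_expr <- expr[erna_rows, , drop = FALSE]
    detect <- detectability(erna_expr, metadata, config$rpm_detect)
    out$expr <- expr
    out$detect <- detect
    if ("quantify" %in% stages) {
      write_matrix(erna_expr, p("erna_rpm.tsv"), id_col = "erna_id")
      write_matrix(detect$means, p("cohort_mean_rpm.tsv"), id_col = "erna_id")
      write_tsv(data.frame(erna_id = rownames(erna_expr),
                           n_cohorts_detected = detect$n_cohorts,
                           class = detect$class, row.names = NULL),
                p("erna_classes.tsv"))
      sim <- sample_similarity(erna_expr, detect)
      write_matrix(round(sim, 6), p("sample_similarity.tsv"), id_col = "sample")
      out$similarity <- sim
    }
  }

  tumor_cols <- function(co) {
    md <- out$md_aligned
    which(md$cohort == co & md$condition == "tumor")
  }
  if (any(c("regulators", "network", "clinical") %in% stages)) {
    md <- read_metadata(manifest$metadata)
    out$md_aligned <- md[match(colnames(out$expr), md$sample), , drop = FALSE]
    if (!"condition" %in% names(out$md_aligned)) out$md_aligned$condition <- "tumor"
    out$cohorts <- sort(unique(out$md_aligned$cohort))
  }

  if ("regulators" %in% stages) {
    tf_ids <- utils::read.delim(manifest$tf_list, stringsAsFactors = FALSE)[[1]]
    tf_ids <- intersect(tf_ids, rownames(out$expr))
    edges <- list()
    for (co in out$cohorts) {
      cols <- tumor_cols(co)
      det_ernas <- rownames(out$detect$means)[out$detect$detectable[, co]]
      edges[[co]] <- putative_regulators(
        out$expr[tf_ids, cols, drop = FALSE],
        out$expr[det_ernas, cols, drop = FALSE], co, config)
    }
    out$regulator_edges <- do.call(rbind, edges)
    rownames(out$regulator_edges) <- NULL
    det_counts <- colSums(out$detect$detectable)
    out$master_profiles <- master_regulators(out$regulator_edges, det_counts,
                                             tf_ids, config)
    out$general_masters <- general_master_regulators(out$master_profiles, config)
    write_tsv(out$regulator_edges, p("regulator_edges.tsv"))
    write_tsv(out$master_profiles, p("master_regulators.tsv"))
    write_tsv(out$general_masters, p("general_master_regulators.tsv"))
  }

  if ("network" %in% stages) {
    genes <- read_gene_table(manifest$genes, role = "gene")
    pairs <- candidate_pairs(out$regions, genes, config$max_link_distance_bp)
    links <- list()
    for (co in out$cohorts) {
      cols <- tumor_cols(co)
      det_ernas <- rownames(out$detect$means)[out$detect$detectable[, co]]
      cl <- correlate_links(pairs,
                            out$expr[intersect(det_ernas, rownames(out$expr)),
                                     cols, drop = FALSE],
                            out$expr[intersect(genes$id, rownames(out$expr)),
                                     cols, drop = FALSE],
                            co, config)
      links[[co]] <- cl$links
    }
    out$links <- do.call(rbind, links)
    rownames(out$links) <- NULL
    write_tsv(out$links, p("erna_gene_links.tsv"))
    pathway_sets <- utils::read.delim(manifest$pathways, stringsAsFactors = FALSE)
    out$pathway_annotation <- annotate_pathways(out$links, pathway_sets)
    write_tsv(out$pathway_annotation$erna_pathways, p("erna_pathways.tsv"))
    out$genes_tbl <- genes
  }

  if ("hic" %in% stages) {
    if (is.null(out$links) || !nrow(out$links)) {
      stop("hic stage needs links from the network stage")
    }
    hic <- read_hic(manifest$hic)
    uniq <- unique(out$links[, c("erna_id", "gene_id")])
    out$hic_support <- hic_support(uniq, out$regions, out$genes_tbl, hic, config)
    out$permutation <- permutation_enrichment(out$hic_support, out$regions,
                                              out$genes_tbl, hic, config,
                                              seed = config$seed)
    write_tsv(out$hic_support[, c("erna_id", "gene_id", "supported_tissues",
                                  "supported_any")],
              p("hic_support.tsv"))
    write_tsv(data.frame(observed_fraction = out$permutation$observed_fraction,
                         n_permutations = out$permutation$n_permutations,
                         b = out$permutation$b,
                         p_empirical = out$permutation$p_empirical),
              p("hic_permutation.tsv"))
  }

  if ("pharmaco" %in% stages) {
    cell_counts <- read_matrix(manifest$cell_counts)
    cls <- utils::read.delim(manifest$cell_library_sizes, stringsAsFactors = FALSE)
    cell_expr <- rpm(cell_counts, stats::setNames(cls$library_size, cls$sample))
    auc <- read_matrix(manifest$auc)
    erna_rows <- grep("^eRNA", rownames(cell_expr), value = TRUE)
    out$drug_associations <- drug_associations(
      cell_expr[erna_rows, , drop = FALSE], auc, source = "ctrp", config = config)
    if (!is.null(out$pathway_annotation)) {
      drug_pw <- utils::read.delim(manifest$drug_pathways, stringsAsFactors = FALSE)
      out$drug_associations <- classify_pathway_relation(
        out$drug_associations, out$pathway_annotation$erna_pathways, drug_pw)
    }
    write_tsv(out$drug_associations, p("drug_associations.tsv"))
  }

  if ("clinical" %in% stages) {
    md <- out$md_aligned
    erna_rows <- rownames(out$detect$means)
    de <- list(); assoc <- list()
    for (co in out$cohorts) {
      d <- differential_expression(out$expr[erna_rows, , drop = FALSE],
                                   md, co, config)
      if (!is.null(d)) de[[co]] <- d
      cols <- tumor_cols(co)
      det_ernas <- rownames(out$detect$means)[out$detect$detectable[, co]]
      ex <- out$expr[det_ernas, cols, drop = FALSE]
      for (feat in intersect(c("subtype", "stage", "grade", "smoking"),
                             names(md))) {
        g <- group_tests(ex, md[[feat]][cols], co, feat, config)
        if (!is.null(g)) assoc[[paste(co, feat)]] <- g
      }
      if (all(c("time", "event") %in% names(md))) {
        sv <- survival_association(ex, md$time[cols], md$event[cols], co, config)
        if (!is.null(sv)) {
          assoc[[paste(co, "survival")]] <- sv[, c("erna_id", "cohort",
                                                   "feature", "test",
                                                   "statistic", "p", "q")]
        }
      }
    }
    out$differential <- if (length(de)) do.call(rbind, de) else NULL
    out$clinical_associations <- if (length(assoc)) {
      do.call(rbind, lapply(assoc, function(a)
        a[, c("erna_id", "cohort", "feature", "test", "statistic", "p", "q")]))
    } else NULL
    out$clinical <- clinical_summary(out$clinical_associations, config)
    if (!is.null(out$differential)) {
      rownames(out$differential) <- NULL
      write_tsv(out$differential, p("differential_expression.tsv"))
    }
    if (!is.null(out$clinical_associations)) {
      rownames(out$clinical_associations) <- NULL
      write_tsv(out$clinical_associations, p("clinical_associations.tsv"))
    }
    write_tsv(out$clinical$per_erna, p("clinically_relevant_ernas.tsv"))
  }

  log <- list(config = unclass(config), stages = stages,
              inputs = lapply(manifest, function(f)
                list(path = unname(f),
                     md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(log, p("run_log.yaml"))
  out
}
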
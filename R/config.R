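#' Pipeline configuration
#'
#' Central container for every tunable threshold in the pipeline. Defaults
#' reproduce the published analysis settings: +/- 3 kb eRNA regions around
#' enhancer midpoints, 1 kb TSS/TES extension and a 500 bp upstream-antisense
#' (uaRNA) window in the exclusion mask, enhancers supported by at least two
#' annotation sources, RPM >= 1 detectability (RPM >= 5 as the stringent
#' robustness cutoff), Spearman Rs >= 0.3 at BH-FDR < 0.05 for regulator and
#' target-gene edges, master regulators covering >= 25% of a cohort's
#' detectable eRNAs, general masters in >= 10 cancer types, <= 1 Mb
#' eRNA-to-TSS distance, |fold change| >= 1.5 paired differential
#' expression, >= 5 samples per clinical group, and 10,000 permutations for
#' the Hi-C enrichment test.
#'
#' @param ... named overrides of the defaults listed above, e.g.
#'   `pipeline_config(flank_bp = 2000)`.
#' @return A validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    flank_bp = 3000L,
    gene_extension_bp = 1000L,
    uaRNA_window_bp = 500L,
    min_sources = 2L,
    rpm_detect = 1.0,
    rpm_strict = 5.0,
    rs_min = 0.3,
    fdr_max = 0.05,
    master_fraction = 0.25,
    general_master_min_types = 10L,
    max_link_distance_bp = 1000000L,
    fc_min = 1.5,
    min_group_size = 5L,
    n_permutations = 10000L,
    hic_oe_min = 1.0,
    hic_bin_bp = 10000L,
    min_pairs_n = 10L,        # complete observations below which a correlation is skipped
    de_pseudocount = 0.1,     # added to RPM before fold change / log2
    regulator_absolute = FALSE, # TRUE: |Rs| >= rs_min instead of Rs >= rs_min
    merge_regions = FALSE,    # TRUE: merge overlapping surviving eRNA regions
    permutation_distance_matched = FALSE,
    survival_mode = "cox",    # or "logrank"
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("flank_bp", "gene_extension_bp", "uaRNA_window_bp", "min_sources",
           "rpm_detect", "rpm_strict", "rs_min", "fdr_max", "master_fraction",
           "general_master_min_types", "max_link_distance_bp", "fc_min",
           "min_group_size", "n_permutations", "hic_oe_min", "hic_bin_bp",
           "min_pairs_n", "de_pseudocount")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("configuration field '", f, "' must be a single positive number")
    }
  }
  if (cfg$fdr_max >= 1) stop("fdr_max must lie in (0, 1)")
  if (cfg$master_fraction > 1) stop("master_fraction must lie in (0, 1]")
  if (!cfg$survival_mode %in% c("cox", "logrank")) {
    stop("survival_mode must be 'cox' or 'logrank'")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [pipeline_config()];
#' fields not present keep their defaults.
#'
#' @param path path to a YAML file of configuration fields.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}
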
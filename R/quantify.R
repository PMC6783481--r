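#' Count reads overlapping eRNA regions
#'
#' A read increments a region's count when it overlaps the region by at
#' least one base; a read overlapping several regions increments each of
#' them (no fractional assignment).
#'
#' @param reads data.frame of read intervals with columns `chrom`, `start`,
#'   `end`, `sample` (0-based half-open), or a `read` [annotation_set()]
#'   whose `id` column carries the sample.
#' @param regions region data.frame from [define_regions()].
#' @param samples optional character vector fixing the column order (samples
#'   without reads get zero columns).
#' @return integer matrix regions x samples.
#' @export
count_overlaps <- function(reads, regions, samples = NULL) {
  if (inherits(reads, "annotation_set")) {
    reads <- data.frame(reads$intervals[c("chrom", "start", "end")],
                        sample = reads$intervals$id,
                        stringsAsFactors = FALSE)
  }
  if (!nrow(regions)) stop("count_overlaps: no regions supplied")
  if (is.null(samples)) samples <- sort(unique(reads$sample))
  counts <- matrix(0L, nrow = nrow(regions), ncol = length(samples),
                   dimnames = list(regions$id, samples))
  if (nrow(reads)) {
    hits <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(reads))
    if (length(hits)) {
      tab <- table(factor(regions$id[S4Vectors::queryHits(hits)],
                          levels = regions$id),
                   factor(reads$sample[S4Vectors::subjectHits(hits)],
                          levels = samples))
      counts <- counts + unclass(tab)
    }
  }
  counts
}

#' Reads-per-million normalization
#'
#' RPM = count * 1e6 / library size, with the library size the total mapped
#' reads of the sample (not reads in regions).
#'
#' @param counts feature x sample count matrix.
#' @param library_sizes named numeric vector of total mapped reads per
#'   sample; names must cover the count columns.
#' @return numeric RPM matrix of the same shape.
#' @export
rpm <- function(counts, library_sizes) {
  miss <- setdiff(colnames(counts), names(library_sizes))
  if (length(miss)) stop("no library size for sample(s): ",
                         paste(miss, collapse = ", "))
  ls <- library_sizes[colnames(counts)]
  if (any(!is.finite(ls)) || any(ls <= 0)) {
    stop("library sizes must be positive and finite")
  }
  sweep(counts, 2L, ls / 1e6, `/`)
}

#' Per-cohort detectability of eRNAs
#'
#' Averages RPM over the tumor samples of each cohort and flags an eRNA
#' detectable in that cohort when the mean is at or above `threshold`
#' (inclusive). Normal samples never enter cohort means; they are used only
#' by the paired differential-expression stage.
#'
#' @param expr RPM matrix (features x samples).
#' @param metadata sample metadata with `sample`, `cohort` and optionally
#'   `condition` (`"tumor"`/`"normal"`; all samples are treated as tumor if
#'   absent).
#' @param threshold detectability cutoff on mean RPM (default 1).
#' @return list of class `detectability`: `means` (feature x cohort matrix),
#'   `detectable` (logical matrix), `n_cohorts` (per feature) and `class`
#'   (see [classify_specificity()]).
#' @export
detectability <- function(expr, metadata, threshold = 1.0) {
  md <- metadata[match(colnames(expr), metadata$sample), , drop = FALSE]
  if (any(is.na(md$sample))) stop("metadata missing for some expression samples")
  tumor <- if ("condition" %in% names(md)) md$condition == "tumor" else rep(TRUE, nrow(md))
  cohorts <- sort(unique(md$cohort))
  means <- sapply(cohorts, function(co) {
    cols <- which(md$cohort == co & tumor)
    if (!length(cols)) stop("cohort with zero tumor samples: ", co)
    rowMeans(expr[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(means))) means <- matrix(means, ncol = length(cohorts),
                                           dimnames = list(rownames(expr), cohorts))
  det <- means >= threshold
  n_cohorts <- rowSums(det)
  structure(list(means = means, detectable = det, n_cohorts = n_cohorts,
                 class = classify_specificity(n_cohorts),
                 threshold = threshold),
            class = "detectability")
}

#' Cancer-type-specificity classes
#'
#' Detectable in >= 10 cohorts: `ubiquitous`; 2-9: `intermediate`; exactly
#' 1: `specific`; 0: `undetected`.
#'
#' @param n_cohorts integer vector (possibly named) of cohorts in which each
#'   eRNA is detectable, or a `detectability` object.
#' @return character vector of classes.
#' @export
classify_specificity <- function(n_cohorts) {
  if (inherits(n_cohorts, "detectability")) n_cohorts <- n_cohorts$n_cohorts
  cls <- ifelse(n_cohorts >= 10L, "ubiquitous",
         ifelse(n_cohorts >= 2L, "intermediate",
         ifelse(n_cohorts == 1L, "specific", "undetected")))
  names(cls) <- names(n_cohorts)
  cls
}

#' Sample-by-sample expression similarity
#'
#' Pairwise Spearman correlation between samples over the union of eRNAs
#' detectable in at least one cohort. A constant-expression sample yields
#' missing similarities for its pairs.
#'
#' @param expr RPM matrix.
#' @param detect optional `detectability` object used to restrict rows to
#'   detectable eRNAs; all rows are used if `NULL`.
#' @return symmetric sample x sample matrix with unit diagonal.
#' @export
sample_similarity <- function(expr, detect = NULL) {
  if (ncol(expr) < 2L) stop("need at least two samples")
  if (!is.null(detect)) {
    keep <- rownames(expr)[detect$n_cohorts[rownames(expr)] >= 1L]
    expr <- expr[keep, , drop = FALSE]
  }
  sim <- suppressWarnings(stats::cor(expr, method = "spearman",
                                     use = "pairwise.complete.obs"))
  diag(sim) <- 1
  sim
}
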
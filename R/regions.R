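#' Consensus enhancers supported by multiple annotation sources
#'
#' Merges all source intervals and keeps each maximal merged interval that
#' contains at least one base covered by intervals from `min_sources`
#' distinct sources. This is the operational reading of "annotated in at
#' least two datasets": one base of multi-source overlap qualifies, and the
#' merged span of the contributing intervals is returned.
#'
#' @param sources list of enhancer [annotation_set()] objects, one per
#'   annotation source.
#' @param min_sources minimum number of distinct sources that must cover a
#'   base (default 2).
#' @return An enhancer [annotation_set()] with source `"consensus"`.
#' @export
consensus_enhancers <- function(sources, min_sources = 2L) {
  if (length(sources) < min_sources) {
    stop(sprintf("need at least %d enhancer sources, got %d",
                 min_sources, length(sources)))
  }
  labels <- vapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    stopifnot(inherits(s, "annotation_set"))
    if (s$role != "enhancer") stop("consensus_enhancers: all sets must have role 'enhancer'")
    if (is.null(s$source) || !nzchar(s$source)) as.character(i) else s$source
  }, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels)

  # Per-source binary coverage, summed across sources, gives the number of
  # distinct sources covering each base.
  per_source <- lapply(sources, function(s) {
    GenomicRanges::reduce(as_granges(s$intervals))
  })
  all_gr <- do.call(c, per_source)
  if (!length(all_gr)) {
    return(annotation_set(data.frame(chrom = character(), start = integer(),
                                     end = integer()),
                          role = "enhancer", source = "consensus"))
  }
  # disjoint pieces covered by >= min_sources distinct sources (each
  # per-source set is reduced, so one overlap hit = one source)
  src_of <- rep(seq_along(per_source), lengths(per_source))
  dj <- GenomicRanges::disjoin(all_gr)
  hits <- GenomicRanges::findOverlaps(dj, all_gr)
  n_src <- tapply(src_of[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(v) length(unique(v)))
  multi <- dj[as.integer(names(n_src))[n_src >= min_sources]]
  blocks <- GenomicRanges::reduce(all_gr)
  keep <- GenomicRanges::countOverlaps(blocks, multi) > 0L
  df <- granges_to_df(blocks[keep])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  annotation_set(df, role = "enhancer", source = "consensus")
}

#' Define candidate eRNA regions around enhancer midpoints
#'
#' Each consensus enhancer yields one region of `flank_bp` on either side of
#' its midpoint (`floor((start + end) / 2)`), clamped to the chromosome.
#'
#' @param consensus consensus enhancer [annotation_set()].
#' @param flank_bp half-width of the region in bp (default 3000).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return data.frame of regions: `id`, `chrom`, `start`, `end`, `midpoint`.
#' @export
define_regions <- function(consensus, flank_bp = 3000L, chrom_lengths) {
  df <- consensus$intervals
  if (!nrow(df)) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      midpoint = integer(), stringsAsFactors = FALSE))
  }
  unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("enhancer on chromosome without a known length: ",
         paste(unknown, collapse = ", "))
  }
  len <- as.numeric(chrom_lengths[df$chrom])
  mid <- (df$start + df$end) %/% 2L
  start <- pmax(0, mid - flank_bp)
  end <- pmin(len, mid + flank_bp)
  out <- data.frame(
    id = sprintf("eRNA:%s:%d", df$chrom, mid),
    chrom = df$chrom,
    start = as.integer(start),
    end = as.integer(end),
    midpoint = as.integer(mid),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the exclusion mask for eRNA regions
#'
#' The mask is the merged union of: every gene and lncRNA span extended by
#' `gene_extension_bp` on both ends; a strand-aware uaRNA window of
#' `uaRNA_window_bp` immediately upstream of each TSS (lower coordinates for
#' `+` genes, higher for `-`); and all blacklist intervals. A region
#' overlapping the mask by a single base is later dropped entirely.
#'
#' @param genes,lncrnas `gene_table` data.frames (either may be `NULL`).
#' @param blacklist a blacklist [annotation_set()] or `NULL`.
#' @param gene_extension_bp extension beyond TSS and TES, bp.
#' @param uaRNA_window_bp width of the upstream-antisense window, bp.
#' @return list of class `exclusion_mask` with merged `intervals` and the
#'   unmerged `provenance` table (`tag` per contributing interval).
#' @export
build_exclusion_mask <- function(genes = NULL, lncrnas = NULL,
                                 blacklist = NULL,
                                 gene_extension_bp = 1000L,
                                 uaRNA_window_bp = 500L) {
  pieces <- list()
  body_and_ua <- function(tbl, tag) {
    if (is.null(tbl) || !nrow(tbl)) return(NULL)
    body <- data.frame(chrom = tbl$chrom,
                       start = pmax(0L, tbl$start - as.integer(gene_extension_bp)),
                       end = tbl$end + as.integer(gene_extension_bp),
                       tag = paste0(tag, "_ext"),
                       stringsAsFactors = FALSE)
    # the uaRNA window sits immediately upstream of the extended TSS: a
    # window anchored at the TSS itself would vanish inside the 1 kb
    # extension and exclude nothing extra
    plus <- tbl$strand == "+"
    ext <- as.integer(gene_extension_bp)
    ua_start <- ifelse(plus, tbl$tss - ext - as.integer(uaRNA_window_bp),
                       tbl$tss + 1L + ext)
    ua_end <- ifelse(plus, tbl$tss - ext,
                     tbl$tss + 1L + ext + as.integer(uaRNA_window_bp))
    ua <- data.frame(chrom = tbl$chrom, start = pmax(0L, ua_start),
                     end = ua_end, tag = "uaRNA", stringsAsFactors = FALSE)
    ua <- ua[ua$end > ua$start, , drop = FALSE]
    rbind(body, ua)
  }
  pieces$gene <- body_and_ua(genes, "gene")
  pieces$lnc <- body_and_ua(lncrnas, "lncRNA")
  if (!is.null(blacklist) && nrow(blacklist$intervals)) {
    bl <- blacklist$intervals
    pieces$bl <- data.frame(chrom = bl$chrom, start = bl$start, end = bl$end,
                            tag = "blacklist", stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, pieces)
  if (is.null(prov) || !nrow(prov)) {
    prov <- data.frame(chrom = character(), start = integer(),
                       end = integer(), tag = character(),
                       stringsAsFactors = FALSE)
  }
  rownames(prov) <- NULL
  merged <- merge_intervals(prov)
  if (nrow(merged)) {
    hits <- GenomicRanges::findOverlaps(as_granges(merged), as_granges(prov))
    tag <- vapply(seq_len(nrow(merged)), function(i) {
      paste(sort(unique(prov$tag[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])),
            collapse = ",")
    }, character(1))
    merged$tag <- tag
  } else {
    merged$tag <- character()
  }
  structure(list(intervals = merged, provenance = prov),
            class = "exclusion_mask")
}

#' Drop eRNA regions overlapping the exclusion mask
#'
#' A region is removed entirely (not trimmed) if it overlaps any mask
#' interval by at least one base; half-open coordinates mean a region ending
#' where a mask interval begins is kept.
#'
#' @param regions region data.frame from [define_regions()].
#' @param mask an `exclusion_mask` from [build_exclusion_mask()].
#' @return list with `regions` (survivors, sorted) and `dropped` (audit
#'   table with the mask tags responsible).
#' @export
filter_regions <- function(regions, mask) {
  stopifnot(inherits(mask, "exclusion_mask"))
  if (!nrow(regions)) {
    return(list(regions = regions,
                dropped = data.frame(id = character(), reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  hit_rows <- overlapping_rows(regions, mask$intervals)
  dropped <- regions[hit_rows, , drop = FALSE]
  reason <- character(nrow(dropped))
  if (nrow(dropped)) {
    hits <- GenomicRanges::findOverlaps(as_granges(dropped),
                                        as_granges(mask$intervals))
    reason <- vapply(seq_len(nrow(dropped)), function(i) {
      tags <- mask$intervals$tag[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
      paste(sort(unique(unlist(strsplit(tags, ",", fixed = TRUE)))), collapse = ",")
    }, character(1))
  }
  keep <- regions[setdiff(seq_len(nrow(regions)), hit_rows), , drop = FALSE]
  keep <- keep[order(keep$chrom, keep$start, keep$end), , drop = FALSE]
  rownames(keep) <- NULL
  list(regions = keep,
       dropped = data.frame(id = dropped$id, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Build eRNA regions end to end
#'
#' Convenience wrapper: consensus over enhancer sources, midpoint +/- flank
#' regions, exclusion masking.
#'
#' @param enhancer_sources list of enhancer [annotation_set()]s.
#' @param genes,lncrnas gene tables; `blacklist` an annotation set.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param config a [pipeline_config()].
#' @return list with `regions`, `consensus`, `mask`, `dropped`.
#' @export
build_erna_regions <- function(enhancer_sources, genes, lncrnas, blacklist,
                               chrom_lengths, config = pipeline_config()) {
  consensus <- consensus_enhancers(enhancer_sources, config$min_sources)
  regions <- define_regions(consensus, config$flank_bp, chrom_lengths)
  mask <- build_exclusion_mask(genes, lncrnas, blacklist,
                               config$gene_extension_bp,
                               config$uaRNA_window_bp)
  filt <- filter_regions(regions, mask)
  if (isTRUE(config$merge_regions) && nrow(filt$regions)) {
    merged <- merge_intervals(filt$regions)
    merged$midpoint <- (merged$start + merged$end) %/% 2L
    merged$id <- sprintf("eRNA:%s:%d", merged$chrom, merged$midpoint)
    filt$regions <- merged[, c("id", "chrom", "start", "end", "midpoint")]
  }
  list(regions = filt$regions, consensus = consensus, mask = mask,
       dropped = filt$dropped)
}
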
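#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom tools md5sum
NULL

# Internal coordinate convention: BED-style 0-based half-open [start, end)
# everywhere in plain-data form; conversion to the 1-based inclusive
# GenomicRanges convention happens only inside the helpers below.

#' Construct an annotation set
#'
#' An annotation set is the package's light container for a collection of
#' genomic intervals sharing one role (`enhancer`, `gene`, `lncRNA`,
#' `blacklist` or `read`) and one source label. Intervals are 0-based
#' half-open.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `strand` (one of `+`, `-`, `.`) and `id`.
#' @param role one of `"enhancer"`, `"gene"`, `"lncRNA"`, `"blacklist"`,
#'   `"read"`.
#' @param source free-text provenance label, e.g. the enhancer catalogue the
#'   intervals came from.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(intervals, role, source = "unknown") {
  role <- match.arg(role, c("enhancer", "gene", "lncRNA", "blacklist", "read"))
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            id = character(), stringsAsFactors = FALSE)
  }
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols)) {
    stop("annotation_set intervals lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(intervals)) intervals$strand <- "."
  if (!"id" %in% names(intervals)) {
    intervals$id <- if (nrow(intervals)) {
      sprintf("%s_%s_%d_%d", role, intervals$chrom,
              as.integer(intervals$start), as.integer(intervals$end))
    } else character()
  }
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$strand <- as.character(intervals$strand)
  intervals$id <- as.character(intervals$id)
  validate_intervals(intervals)
  rownames(intervals) <- NULL
  structure(list(role = role, source = source,
                 intervals = intervals[, c("chrom", "start", "end",
                                           "strand", "id")]),
            class = "annotation_set")
}

validate_intervals <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stop("interval with empty chromosome name")
  }
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("interval with missing coordinate")
  }
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("invalid interval coordinates (need 0 <= start < end) at row %d: %s:%d-%d",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(!df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> role=%s source=%s n=%d\n",
              x$role, x$source, nrow(x$intervals)))
  invisible(x)
}

# data.frame (0-based half-open) -> GRanges (1-based inclusive).
# Strand is deliberately dropped: all overlap logic is strand-agnostic.
as_granges <- function(df) {
  if (!nrow(df)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> 0-based half-open data.frame
granges_to_df <- function(gr) {
  if (!length(gr)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Merge intervals of a 0-based df (union of overlapping/adjacent-at-0-gap
# intervals); returns sorted non-overlapping 0-based df.
merge_intervals <- function(df) {
  out <- granges_to_df(GenomicRanges::reduce(as_granges(df)))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Row indices of `df` that overlap any interval in `mask_df` by >= 1 bp.
overlapping_rows <- function(df, mask_df) {
  if (!nrow(df) || !nrow(mask_df)) return(integer())
  hits <- GenomicRanges::findOverlaps(as_granges(df), as_granges(mask_df))
  sort(unique(S4Vectors::queryHits(hits)))
}
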
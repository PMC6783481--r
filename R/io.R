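#' Read a BED file into an annotation set
#'
#' Accepts 3- to 6-column BED (chrom, start, end, name, score, strand).
#' Coordinates are kept 0-based half-open. Lines failing the BED contract
#' are reported with their line number.
#'
#' @param path path to a tab-separated BED file.
#' @param role interval role, see [annotation_set()].
#' @param source provenance label stored on the returned set.
#' @return An [annotation_set()].
#' @export
read_bed <- function(path, role, source = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(annotation_set(data.frame(chrom = character(), start = integer(),
                                     end = integer()), role, source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated fields",
                 which(nf < 3L)[1], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in %s: non-integer coordinate", bad[1], path))
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(sprintf("coordinate order error at BED line %d in %s: start %d >= end %d",
                 bad[1], path, start[bad[1]], end[bad[1]]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, character(1)), NA_character_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", character(1)), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  if (!all(is.na(name))) df$id <- name
  annotation_set(df, role = role, source = source)
}

#' Write an annotation set as BED
#'
#' Emits 6-column BED (score fixed at 0). Round-trips interval content with
#' [read_bed()].
#'
#' @param x an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  df <- x$intervals
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   df$chrom, df$start, df$end, df$id, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table ("GTF-lite")
#'
#' A tab-separated table with header columns `chrom`, `start`, `end`, `id`,
#' `strand`, `tss`, `tes`, `exon_starts`, `exon_ends` (the exon columns are
#' comma-separated 0-based half-open coordinate lists). GTF-style 1-based
#' inclusive inputs must be converted before loading; this reader expects
#' BED-style coordinates throughout.
#'
#' @param path path to the table.
#' @param role `"gene"` or `"lncRNA"`.
#' @return A `gene_table` data.frame with parsed exon lists.
#' @export
read_gene_table <- function(path, role = "gene") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "start", "end", "id", "strand", "tss", "tes",
                "exon_starts", "exon_ends")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$tss <- as.integer(df$tss); df$tes <- as.integer(df$tes)
  validate_gene_table(df)
  attr(df, "role") <- role
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (any(df$start < 0L | df$start >= df$end)) {
    stop("gene table: need 0 <= start < end")
  }
  in_span <- df$tss >= df$start & df$tss < df$end &
    df$tes >= df$start & df$tes < df$end
  if (any(!in_span)) {
    stop("gene table: tss/tes outside [start, end) for gene ",
         df$id[which(!in_span)[1]])
  }
  if (anyDuplicated(df$id)) stop("gene table: duplicate gene id")
  invisible(df)
}

# Parse one gene's exon columns into a sorted 0-based interval data.frame.
exon_intervals <- function(gene_row) {
  s <- as.integer(strsplit(gene_row$exon_starts, ",", fixed = TRUE)[[1]])
  e <- as.integer(strsplit(gene_row$exon_ends, ",", fixed = TRUE)[[1]])
  if (length(s) != length(e)) stop("exon start/end length mismatch for ", gene_row$id)
  o <- order(s)
  data.frame(start = s[o], end = e[o])
}

#' Write a gene table
#' @param df a `gene_table` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample numeric matrix from TSV
#'
#' First column holds feature IDs, header holds sample IDs. `NA` cells are
#' carried as missing and handled pairwise-complete downstream.
#'
#' @param path path to the TSV.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature (row) ID in matrix: ", ids[duplicated(ids)][1])
  }
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn)) {
    stop("duplicate sample (column) ID in matrix: ", cn[duplicated(cn)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name for the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with at least `sample` and `cohort` columns; recognised
#' optional columns are `condition` (tumor/normal), `patient`, `subtype`,
#' `stage`, `grade`, `smoking`, `time`, `event`.
#'
#' @param path path to the TSV.
#' @return data.frame keyed by `sample`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "cohort") %in% names(df))) {
    stop("metadata needs at least 'sample' and 'cohort' columns")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample in metadata")
  df
}

#' Read Hi-C observed/expected triples
#'
#' TSV with columns `tissue`, `chrom`, `bin_a`, `bin_b`, `oe` where bins are
#' integer indices at the matrix bin size (intra-chromosomal contacts only,
#' the usual form O/E matrices are distributed in).
#'
#' @param path path to the TSV.
#' @return data.frame of O/E records.
#' @export
read_hic <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("tissue", "chrom", "bin_a", "bin_b", "oe")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("Hi-C table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$bin_a <- as.integer(df$bin_a)
  df$bin_b <- as.integer(df$bin_b)
  df$oe <- as.numeric(df$oe)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
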
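# Brute-force per-base oracles for the interval engine, plus small random
# instance generators. Everything here works on 0-based half-open
# coordinates with plain logical vectors, independent of the GRanges-based
# implementation under test.

# intersect intervals with the genome (the per-base oracles are defined on
# [0, chrom_len) only)
clamp_to_genome <- function(df, chrom_lengths) {
  df$end <- pmin(df$end, chrom_lengths[df$chrom])
  df <- df[df$end > df$start, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# per-base coverage vector (length = chrom_len) for one chromosome
.cov_vec <- function(df, chrom, chrom_len) {
  v <- logical(chrom_len)
  d <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    lo <- max(0L, d$start[i]); hi <- min(chrom_len, d$end[i])
    if (hi > lo) v[(lo + 1):hi] <- TRUE
  }
  v
}

# maximal runs of TRUE as a 0-based interval data.frame
.runs_to_df <- function(v, chrom) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

# consensus: bases covered by >= k distinct sources, expanded to the
# maximal union blocks that contain such a base
oracle_consensus <- function(source_dfs, min_sources, chrom_lengths) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    covs <- vapply(source_dfs, .cov_vec, logical(len), chrom = chrom,
                   chrom_len = len)
    if (is.null(dim(covs))) covs <- matrix(covs, ncol = length(source_dfs))
    n_src <- rowSums(covs)
    union_v <- n_src >= 1
    blocks <- .runs_to_df(union_v, chrom)
    keep <- vapply(seq_len(nrow(blocks)), function(i) {
      any(n_src[(blocks$start[i] + 1):blocks$end[i]] >= min_sources)
    }, logical(1))
    out[[chrom]] <- blocks[keep, , drop = FALSE]
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# exclusion mask as merged intervals, built base-by-base
oracle_mask <- function(genes, lncrnas, blacklist_df, ext, ua,
                        chrom_lengths) {
  pieces <- list()
  add_tbl <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return()
    for (i in seq_len(nrow(tbl))) {
      pieces[[length(pieces) + 1L]] <<- data.frame(
        chrom = tbl$chrom[i],
        start = max(0L, tbl$start[i] - ext), end = tbl$end[i] + ext)
      if (tbl$strand[i] == "+") {
        pieces[[length(pieces) + 1L]] <<- data.frame(
          chrom = tbl$chrom[i], start = max(0L, tbl$tss[i] - ext - ua),
          end = max(0L, tbl$tss[i] - ext))
      } else {
        pieces[[length(pieces) + 1L]] <<- data.frame(
          chrom = tbl$chrom[i], start = tbl$tss[i] + 1L + ext,
          end = tbl$tss[i] + 1L + ext + ua)
      }
    }
  }
  add_tbl(genes); add_tbl(lncrnas)
  if (!is.null(blacklist_df) && nrow(blacklist_df)) {
    for (i in seq_len(nrow(blacklist_df))) {
      pieces[[length(pieces) + 1L]] <- blacklist_df[i, c("chrom", "start", "end")]
    }
  }
  all_df <- do.call(rbind, pieces)
  if (is.null(all_df)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (chrom in names(chrom_lengths)) {
    v <- .cov_vec(all_df, chrom, chrom_lengths[[chrom]])
    out[[chrom]] <- .runs_to_df(v, chrom)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# region survives iff zero masked bases inside it
oracle_filter <- function(regions, mask_df, chrom_lengths) {
  keep <- logical(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    v <- .cov_vec(mask_df, chrom, chrom_lengths[[chrom]])
    idx <- which(regions$chrom == chrom)
    for (i in idx) {
      span <- (regions$start[i] + 1):regions$end[i]
      keep[i] <- !any(v[span])
    }
  }
  regions[keep, , drop = FALSE]
}

# O(n*m) all-pairs overlap counting
oracle_count_overlaps <- function(reads, regions, samples) {
  counts <- matrix(0L, nrow(regions), length(samples),
                   dimnames = list(regions$id, samples))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(reads))) {
      if (reads$chrom[j] == regions$chrom[i] &&
          reads$start[j] < regions$end[i] &&
          regions$start[i] < reads$end[j]) {
        s <- reads$sample[j]
        counts[i, s] <- counts[i, s] + 1L
      }
    }
  }
  counts
}

# mid-ranks and Pearson computed from first principles
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v); r <- numeric(length(v)); i <- 1
    sv <- v[o]
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && sv[j + 1] == sv[i]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# random toy genome instance for the interval-engine equivalence checks
random_toy_instance <- function(seed, chrom_len = 100000L, n_chroms = 2L) {
  set.seed(seed)
  chrom_lengths <- stats::setNames(rep(chrom_len, n_chroms),
                                   paste0("c", seq_len(n_chroms)))
  rand_iv <- function(n, min_w, max_w) {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    w <- sample(min_w:max_w, n, replace = TRUE)
    start <- vapply(seq_len(n), function(i)
      sample.int(chrom_len - w[i], 1L), integer(1))
    data.frame(chrom = chrom, start = start, end = start + w,
               stringsAsFactors = FALSE)
  }
  sources <- lapply(1:3, function(s) rand_iv(sample(5:15, 1), 200, 2000))
  mk_genes <- function(n) {
    g <- rand_iv(n, 2000, 10000)
    g$id <- sprintf("g%d", seq_len(n))
    g$strand <- sample(c("+", "-"), n, replace = TRUE)
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
    g$exon_starts <- as.character(g$start)
    g$exon_ends <- as.character(g$end)
    g
  }
  list(chrom_lengths = chrom_lengths,
       sources = sources,
       genes = mk_genes(sample(3:8, 1)),
       lncrnas = mk_genes(sample(1:4, 1)),
       blacklist = rand_iv(sample(1:3, 1), 500, 3000),
       reads = {
         r <- rand_iv(sample(50:200, 1), 50, 150)
         r$sample <- sample(c("s1", "s2", "s3"), nrow(r), replace = TRUE)
         r
       })
}
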
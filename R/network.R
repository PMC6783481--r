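#' Candidate eRNA-gene pairs by distance
#'
#' Pairs every eRNA region with every gene on the same chromosome whose TSS
#' lies within `max_link_distance_bp` (inclusive) of the region midpoint.
#' Pairs where the region lies entirely inside an intron of that gene are
#' flagged intronic and removed.
#'
#' @param regions region data.frame from [define_regions()].
#' @param genes a `gene_table` data.frame (needs `tss`, exon columns).
#' @param max_link_distance_bp maximum midpoint-to-TSS distance (default
#'   1 Mb).
#' @return data.frame `(erna_id, gene_id, distance_bp)`; removed intronic
#'   pairs are available as the `intronic` attribute.
#' @export
candidate_pairs <- function(regions, genes, max_link_distance_bp = 1000000L) {
  if (any(is.na(genes$tss))) {
    stop("gene without TSS: ", genes$id[which(is.na(genes$tss))[1]])
  }
  empty <- data.frame(erna_id = character(), gene_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(genes)) {
    attr(empty, "intronic") <- empty
    return(empty)
  }
  # window of +/- max distance around each midpoint vs TSS points
  win <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = pmax(1L, regions$midpoint + 1L - as.integer(max_link_distance_bp)),
                     end = regions$midpoint + 1L + as.integer(max_link_distance_bp)))
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(start = genes$tss + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(win, tss_gr)
  ri <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  d <- abs(regions$midpoint[ri] - genes$tss[gi])
  keep <- d <= max_link_distance_bp
  ri <- ri[keep]; gi <- gi[keep]; d <- d[keep]
  pairs <- data.frame(erna_id = regions$id[ri], gene_id = genes$id[gi],
                      distance_bp = as.integer(d), stringsAsFactors = FALSE)
  intronic <- region_in_intron(regions[ri, , drop = FALSE],
                               genes[gi, , drop = FALSE])
  out <- pairs[!intronic, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intronic") <- pairs[intronic, , drop = FALSE]
  out
}

# TRUE where region i lies entirely within an intron of gene i (rowwise).
region_in_intron <- function(regions, genes) {
  n <- nrow(regions)
  if (!n) return(logical())
  out <- logical(n)
  inside <- regions$chrom == genes$chrom &
    regions$start >= genes$start & regions$end <= genes$end
  for (i in which(inside)) {
    ex <- exon_intervals(genes[i, , drop = FALSE])
    if (nrow(ex) < 2L) next
    intron_start <- ex$end[-nrow(ex)]
    intron_end <- ex$start[-1]
    out[i] <- any(regions$start[i] >= intron_start &
                    regions$end[i] <= intron_end)
  }
  out
}

#' Correlate candidate pairs into eRNA-target-gene links
#'
#' Spearman correlation per candidate pair over the cohort's tumor samples,
#' BH-FDR over all candidate pairs within the cohort, and the published
#' gates `Rs >= rs_min` (positive only) and `q < fdr_max`.
#'
#' @param pairs candidate pairs from [candidate_pairs()].
#' @param erna_expr,gene_expr expression matrices over the same cohort
#'   samples; `erna_expr` restricted to detectable eRNAs.
#' @param cohort cohort label.
#' @param config a [pipeline_config()].
#' @return list with `links` (passing pairs with `n, Rs, p, q`) and
#'   `tested` (all scored pairs).
#' @export
correlate_links <- function(pairs, erna_expr, gene_expr, cohort,
                            config = pipeline_config()) {
  pairs <- pairs[pairs$erna_id %in% rownames(erna_expr) &
                   pairs$gene_id %in% rownames(gene_expr), , drop = FALSE]
  n_pairs <- nrow(pairs)
  empty <- data.frame(erna_id = character(), gene_id = character(),
                      cohort = character(), distance_bp = integer(),
                      n = integer(), Rs = double(), p = double(),
                      q = double(), stringsAsFactors = FALSE)
  if (!n_pairs) return(list(links = empty, tested = empty))
  er <- rank_rows(erna_expr[unique(pairs$erna_id), , drop = FALSE])
  gr <- rank_rows(gene_expr[unique(pairs$gene_id), , drop = FALSE])
  Rs <- numeric(n_pairs); n <- integer(n_pairs)
  ei <- match(pairs$erna_id, rownames(er)); gi <- match(pairs$gene_id, rownames(gr))
  complete_e <- attr(er, "complete"); complete_g <- attr(gr, "complete")
  for (k in seq_len(n_pairs)) {
    if (complete_e[ei[k]] && complete_g[gi[k]]) {
      Rs[k] <- stats::cor(er[ei[k], ], gr[gi[k], ])
      n[k] <- ncol(er)
    } else {
      st <- spearman_test(erna_expr[pairs$erna_id[k], ],
                          gene_expr[pairs$gene_id[k], ],
                          min_n = config$min_pairs_n)
      Rs[k] <- st$Rs; n[k] <- st$n
    }
  }
  tested <- data.frame(erna_id = pairs$erna_id, gene_id = pairs$gene_id,
                       cohort = cohort, distance_bp = pairs$distance_bp,
                       n = n, Rs = Rs, stringsAsFactors = FALSE)
  tested <- tested[!is.na(tested$Rs) & tested$n >= config$min_pairs_n, , drop = FALSE]
  tested$p <- spearman_p(tested$Rs, tested$n)
  tested$q <- bh_fdr(tested$p)
  links <- tested[tested$Rs >= config$rs_min & tested$q < config$fdr_max, , drop = FALSE]
  rownames(links) <- NULL; rownames(tested) <- NULL
  list(links = links, tested = tested)
}

# Row-wise mid-ranks; rows with any NA are marked incomplete and left as-is.
rank_rows <- function(m) {
  complete <- !apply(is.na(m), 1L, any)
  r <- m
  if (any(complete)) {
    r[complete, ] <- t(apply(m[complete, , drop = FALSE], 1L, rank))
  }
  attr(r, "complete") <- complete
  r
}

hic_key <- function(chrom, bin1, bin2) {
  sprintf("%s:%d:%d", chrom, pmin(bin1, bin2), pmax(bin1, bin2))
}

#' Hi-C observed/expected support for eRNA-gene links
#'
#' Looks up the O/E value at the (region-midpoint bin, gene-TSS bin) pair in
#' each tissue (the contact key is unordered); a tissue supports the link
#' when its O/E is at or above `hic_oe_min`. Missing bin pairs count as
#' unsupported.
#'
#' @param links data.frame with `erna_id`, `gene_id` (e.g. from
#'   [correlate_links()]).
#' @param regions,genes coordinate tables carrying `midpoint` / `tss`.
#' @param hic Hi-C O/E records from [read_hic()] or [simulate_hic()].
#' @param config a [pipeline_config()] (`hic_bin_bp`, `hic_oe_min`).
#' @return `links` with added `supported_tissues`, `supported_any` and one
#'   `oe_<tissue>` column per tissue.
#' @export
hic_support <- function(links, regions, genes, hic,
                        config = pipeline_config()) {
  tissues <- sort(unique(hic$tissue))
  bin <- as.integer(config$hic_bin_bp)
  rb <- regions$midpoint[match(links$erna_id, regions$id)] %/% bin
  gb <- genes$tss[match(links$gene_id, genes$id)] %/% bin
  rchrom <- regions$chrom[match(links$erna_id, regions$id)]
  gchrom <- genes$chrom[match(links$gene_id, genes$id)]
  keys <- hic_key(rchrom, rb, gb)
  same_chrom <- rchrom == gchrom
  out <- links
  support <- matrix(NA_real_, nrow = nrow(links), ncol = length(tissues),
                    dimnames = list(NULL, tissues))
  for (ti in seq_along(tissues)) {
    h <- hic[hic$tissue == tissues[ti], , drop = FALSE]
    hk <- hic_key(h$chrom, h$bin_a, h$bin_b)
    oe <- h$oe[match(keys, hk)]
    oe[!same_chrom] <- NA_real_
    support[, ti] <- oe
    out[[paste0("oe_", tissues[ti])]] <- oe
  }
  out$supported_tissues <- as.integer(rowSums(support >= config$hic_oe_min,
                                              na.rm = TRUE))
  out$supported_any <- out$supported_tissues >= 1L
  out
}

#' Permutation enrichment of Hi-C support over random pairs
#'
#' Compares the fraction of links supported in at least one tissue with the
#' same fraction in `n_permutations` draws of equally many uniform random
#' (region, gene) pairs, genome-wide by default (any chromosome, no distance
#' constraint; distinct pairs within one permutation). The empirical p-value
#' uses the add-one correction `p = (b + 1) / (n_permutations + 1)` where
#' `b` counts permutations whose supported fraction reaches the observed
#' one.
#'
#' @param links supported links from [hic_support()] (needs
#'   `supported_any`).
#' @param regions,genes the full region and gene universes to draw random
#'   pairs from.
#' @param hic Hi-C O/E records.
#' @param config a [pipeline_config()]; `n_permutations`, `hic_bin_bp`,
#'   `hic_oe_min`, `permutation_distance_matched` and `max_link_distance_bp`
#'   are used.
#' @param seed integer seed for the permutation stream.
#' @return list of class `permutation_result`: `observed_fraction`,
#'   `n_permutations`, `b`, `p_empirical`, `perm_fractions`.
#' @export
permutation_enrichment <- function(links, regions, genes, hic,
                                   config = pipeline_config(),
                                   seed = config$seed) {
  m <- nrow(links)
  if (!m) stop("permutation_enrichment: no links supplied")
  if (config$n_permutations < 100L) stop("need at least 100 permutations")
  observed <- mean(links$supported_any)
  bin <- as.integer(config$hic_bin_bp)
  supp <- hic[hic$oe >= config$hic_oe_min, , drop = FALSE]
  supported_keys <- unique(hic_key(supp$chrom, supp$bin_a, supp$bin_b))

  if (isTRUE(config$permutation_distance_matched)) {
    universe <- candidate_pairs(regions, genes, config$max_link_distance_bp)
    ui <- match(universe$erna_id, regions$id)
    uj <- match(universe$gene_id, genes$id)
    n_univ <- nrow(universe)
    draw <- function() {
      k <- sample.int(n_univ, m, replace = FALSE)
      cbind(ui[k], uj[k])
    }
  } else {
    n_r <- nrow(regions); n_g <- nrow(genes)
    n_univ <- as.double(n_r) * n_g
    if (n_univ < m) stop("pair universe smaller than the link set")
    draw <- function() {
      k <- sample(n_univ, m, replace = FALSE) - 1
      cbind(as.integer(k %% n_r) + 1L, as.integer(k %/% n_r) + 1L)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fractions <- vapply(seq_len(config$n_permutations), function(it) {
    idx <- draw()
    rc <- regions$chrom[idx[, 1]]; gc_ <- genes$chrom[idx[, 2]]
    keys <- hic_key(rc, regions$midpoint[idx[, 1]] %/% bin,
                    genes$tss[idx[, 2]] %/% bin)
    mean(rc == gc_ & keys %in% supported_keys)
  }, numeric(1))
  b <- sum(fractions >= observed)
  structure(list(observed_fraction = observed,
                 n_permutations = config$n_permutations,
                 b = b,
                 p_empirical = (b + 1) / (config$n_permutations + 1),
                 perm_fractions = fractions),
            class = "permutation_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Annotate links with signaling-pathway membership
#'
#' A link (and hence its eRNA) belongs to a pathway when its target gene is
#' in the pathway's gene set; genes may carry several pathways.
#'
#' @param links data.frame with `erna_id`, `gene_id`.
#' @param pathway_sets data.frame `(pathway, gene)`.
#' @return list with `link_pathways` (long `(erna_id, gene_id, pathway)`)
#'   and `erna_pathways` (distinct `(erna_id, pathway)`).
#' @export
annotate_pathways <- function(links, pathway_sets) {
  lp <- merge(links[, c("erna_id", "gene_id")], pathway_sets,
              by.x = "gene_id", by.y = "gene")
  lp <- lp[, c("erna_id", "gene_id", "pathway")]
  lp <- lp[order(lp$erna_id, lp$gene_id, lp$pathway), , drop = FALSE]
  rownames(lp) <- NULL
  ep <- unique(lp[, c("erna_id", "pathway")])
  rownames(ep) <- NULL
  list(link_pathways = lp, erna_pathways = ep)
}
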
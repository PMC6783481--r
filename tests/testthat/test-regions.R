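mk_enh <- function(df) annotation_set(df, role = "enhancer")

test_that("consensus keeps only multi-source blocks and merges their span", {
  s1 <- mk_enh(data.frame(chrom = "chr1", start = c(100L, 5000L),
                          end = c(300L, 5500L)))
  s2 <- mk_enh(data.frame(chrom = "chr1", start = 250L, end = 400L))
  cons <- consensus_enhancers(list(s1, s2), min_sources = 2L)
  # bases 250-299 carry two sources; merged span of contributors is [100,400)
  expect_equal(cons$intervals$start, 100L)
  expect_equal(cons$intervals$end, 400L)
  # the single-source enhancer at 5000 is gone
  expect_equal(nrow(cons$intervals), 1L)

  # identical interval in all three sources appears once, unchanged
  s <- mk_enh(data.frame(chrom = "chr2", start = 10L, end = 20L))
  cons3 <- consensus_enhancers(list(s, s, s), 2L)
  expect_equal(cons3$intervals[, c("chrom", "start", "end")],
               data.frame(chrom = "chr2", start = 10L, end = 20L))

  # touching-but-not-overlapping sources do not qualify
  a <- mk_enh(data.frame(chrom = "chr1", start = 0L, end = 100L))
  b <- mk_enh(data.frame(chrom = "chr1", start = 100L, end = 200L))
  expect_equal(nrow(consensus_enhancers(list(a, b), 2L)$intervals), 0L)

  expect_error(consensus_enhancers(list(s1), 2L), "at least 2")
})

test_that("raising min_sources never grows the consensus", {
  for (seed in 1:5) {
    inst <- random_toy_instance(seed)
    sets <- lapply(inst$sources, mk_enh)
    n2 <- nrow(consensus_enhancers(sets, 2L)$intervals)
    n3 <- nrow(consensus_enhancers(sets, 3L)$intervals)
    expect_lte(n3, n2)
  }
})

test_that("regions are midpoint +/- flank, clamped at chromosome ends", {
  cons <- mk_enh(data.frame(chrom = "chr1", start = c(4000L, 0L),
                            end = c(6000L, 2000L)))
  r <- define_regions(cons, 3000L, c(chr1 = 1000000L))
  expect_equal(r$midpoint, c(1000L, 5000L))
  expect_equal(r$start, c(0L, 2000L))   # second enhancer clamped at 0
  expect_equal(r$end, c(4000L, 8000L))
  expect_error(define_regions(cons, 3000L, c(chrX = 1e6)), "without a known length")
})

test_that("exclusion mask merges gene extensions, uaRNA windows and blacklist", {
  g <- data.frame(chrom = "chr1", start = 10000L, end = 20000L, id = "G1",
                  strand = "+", tss = 10000L, tes = 19999L,
                  exon_starts = "10000", exon_ends = "20000",
                  stringsAsFactors = FALSE)
  m <- build_exclusion_mask(genes = g, gene_extension_bp = 1000L,
                            uaRNA_window_bp = 500L)
  # [9000,21000) body+ext and [8500,9000) uaRNA merge into [8500,21000)
  expect_equal(m$intervals$start, 8500L)
  expect_equal(m$intervals$end, 21000L)
  expect_match(m$intervals$tag, "gene_ext")
  expect_match(m$intervals$tag, "uaRNA")

  # minus-strand gene: uaRNA window sits above the extended TSS
  g2 <- g; g2$strand <- "-"; g2$tss <- 19999L; g2$tes <- 10000L
  m2 <- build_exclusion_mask(genes = g2, gene_extension_bp = 1000L,
                             uaRNA_window_bp = 500L)
  expect_equal(m2$intervals$start, 9000L)
  expect_equal(m2$intervals$end, 21500L)  # ua [21000,21500) merges with ext

  # adjacent genes with touching extensions merge into one mask interval
  g3 <- rbind(g, within(g, {start <- 22000L; end <- 30000L; tss <- 22000L
                            tes <- 29999L; id <- "G2"
                            exon_starts <- "22000"; exon_ends <- "30000"}))
  m3 <- build_exclusion_mask(genes = g3, gene_extension_bp = 1000L,
                             uaRNA_window_bp = 500L)
  expect_equal(nrow(m3$intervals), 1L)

  expect_equal(nrow(build_exclusion_mask()$intervals), 0L)
})

test_that("regions overlapping the mask by one base are dropped, not trimmed", {
  regions <- data.frame(id = c("r1", "r2"), chrom = "chr1",
                        start = c(2000L, 2000L), end = c(8000L, 8000L),
                        midpoint = 5000L, stringsAsFactors = FALSE)
  mk_mask <- function(s, e) {
    structure(list(intervals = data.frame(chrom = "chr1", start = s, end = e,
                                          tag = "blacklist",
                                          stringsAsFactors = FALSE),
                   provenance = NULL), class = "exclusion_mask")
  }
  # one-base overlap at 7999 -> dropped
  res <- filter_regions(regions[1, ], mk_mask(7999L, 9000L))
  expect_equal(nrow(res$regions), 0L)
  expect_equal(res$dropped$reason, "blacklist")
  # half-open boundary: mask starting at region end -> kept intact
  res2 <- filter_regions(regions[1, ], mk_mask(8000L, 9000L))
  expect_equal(res2$regions$end, 8000L)
  # filtering is idempotent
  res3 <- filter_regions(res2$regions, mk_mask(8000L, 9000L))
  expect_equal(res3$regions, res2$regions)
})

test_that("interval engine matches the per-base oracle on random genomes", {
  for (seed in 1:8) {
    inst <- random_toy_instance(seed)
    sets <- lapply(inst$sources, mk_enh)
    cons <- consensus_enhancers(sets, 2L)
    expect_equal(cons$intervals[, c("chrom", "start", "end")],
                 oracle_consensus(inst$sources, 2L, inst$chrom_lengths),
                 info = paste("consensus seed", seed))

    mask <- build_exclusion_mask(inst$genes, inst$lncrnas,
                                 annotation_set(inst$blacklist, "blacklist"),
                                 1000L, 500L)
    omask <- oracle_mask(inst$genes, inst$lncrnas, inst$blacklist,
                         1000L, 500L, inst$chrom_lengths)
    expect_equal(clamp_to_genome(mask$intervals[, c("chrom", "start", "end")],
                                 inst$chrom_lengths),
                 omask, info = paste("mask seed", seed))

    regions <- define_regions(cons, 3000L, inst$chrom_lengths)
    surv <- filter_regions(regions, mask)$regions
    osurv <- oracle_filter(regions, mask$intervals, inst$chrom_lengths)
    rownames(osurv) <- NULL
    expect_equal(surv, osurv[order(osurv$chrom, osurv$start, osurv$end), ],
                 info = paste("filter seed", seed))
  }
})

test_that("enlarging the mask never increases the surviving region count", {
  inst <- random_toy_instance(99)
  sets <- lapply(inst$sources, mk_enh)
  cons <- consensus_enhancers(sets, 2L)
  regions <- define_regions(cons, 3000L, inst$chrom_lengths)
  m_small <- build_exclusion_mask(inst$genes, NULL, NULL, 1000L, 500L)
  m_big <- build_exclusion_mask(inst$genes, inst$lncrnas,
                                annotation_set(inst$blacklist, "blacklist"),
                                1000L, 500L)
  n_small <- nrow(filter_regions(regions, m_small)$regions)
  n_big <- nrow(filter_regions(regions, m_big)$regions)
  expect_lte(n_big, n_small)
})
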
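mk_gene <- function(id, chrom, start, end, strand = "+",
                    exon_starts = NULL, exon_ends = NULL) {
  data.frame(chrom = chrom, start = start, end = end, id = id,
             strand = strand,
             tss = if (strand == "+") start else end - 1L,
             tes = if (strand == "+") end - 1L else start,
             exon_starts = if (is.null(exon_starts)) as.character(start)
                           else paste(exon_starts, collapse = ","),
             exon_ends = if (is.null(exon_ends)) as.character(end)
                         else paste(exon_ends, collapse = ","),
             stringsAsFactors = FALSE)
}

test_that("candidate pairing is inclusive at 1 Mb and drops intronic regions", {
  regions <- data.frame(id = "e1", chrom = "chr1", start = 2000L,
                        end = 8000L, midpoint = 5000L,
                        stringsAsFactors = FALSE)
  near <- mk_gene("Gnear", "chr1", 1005000L, 1040000L)     # distance exactly 1e6
  far <- mk_gene("Gfar", "chr1", 1005001L, 1040001L)       # 1e6 + 1
  other <- mk_gene("Gother", "chr2", 5000L, 20000L)
  pairs <- candidate_pairs(regions, rbind(near, far, other), 1000000L)
  expect_equal(pairs$gene_id, "Gnear")
  expect_equal(pairs$distance_bp, 1000000L)

  # region fully inside intron 1 of a host gene is removed and flagged
  host <- mk_gene("Ghost", "chr1", 0L, 60000L,
                  exon_starts = c(0L, 50000L), exon_ends = c(1000L, 60000L))
  pairs2 <- candidate_pairs(regions, host, 1000000L)
  expect_equal(nrow(pairs2), 0L)
  expect_equal(attr(pairs2, "intronic")$gene_id, "Ghost")
  # same geometry but the region pokes into an exon -> kept
  host2 <- mk_gene("Ghost2", "chr1", 0L, 60000L,
                   exon_starts = c(0L, 7000L), exon_ends = c(1000L, 60000L))
  expect_equal(candidate_pairs(regions, host2, 1000000L)$gene_id, "Ghost2")

  bad <- near; bad$tss <- NA_integer_
  expect_error(candidate_pairs(regions, bad, 1e6), "without TSS")
})

test_that("duplicated expression rows give a perfect link", {
  set.seed(6)
  pairs <- data.frame(erna_id = "e1", gene_id = "g1", distance_bp = 1000L,
                      stringsAsFactors = FALSE)
  v <- rlnorm(30)
  e <- matrix(v, 1, 30, dimnames = list("e1", sprintf("s%d", 1:30)))
  g <- matrix(v, 1, 30, dimnames = list("g1", sprintf("s%d", 1:30)))
  res <- correlate_links(pairs, e, g, "A", pipeline_config())
  expect_equal(res$links$Rs, 1)
  expect_equal(res$links$q, 0)
})

test_that("Hi-C support counts tissues at or above the O/E cutoff", {
  regions <- data.frame(id = "e1", chrom = "chr1", start = 2000L, end = 8000L,
                        midpoint = 5000L, stringsAsFactors = FALSE)
  genes <- mk_gene("g1", "chr1", 200000L, 240000L)
  links <- data.frame(erna_id = "e1", gene_id = "g1", stringsAsFactors = FALSE)
  oe <- c(rep(2, 12), rep(0.5, 5))  # 12 of 17 tissues at >= 1, 3 missing
  hic <- data.frame(tissue = sprintf("t%02d", seq_along(oe)), chrom = "chr1",
                    bin_a = 0L, bin_b = 20L, oe = oe,
                    stringsAsFactors = FALSE)
  cfg <- pipeline_config()
  hs <- hic_support(links, regions, genes, hic, cfg)
  expect_equal(hs$supported_tissues, 12L)
  expect_true(hs$supported_any)
  # monotone in the cutoff
  hs2 <- hic_support(links, regions, genes, hic, pipeline_config(hic_oe_min = 3))
  expect_lte(hs2$supported_tissues, hs$supported_tissues)
  # all-missing pair is unsupported
  hs3 <- hic_support(data.frame(erna_id = "e1", gene_id = "g1"),
                     regions, mk_gene("g1", "chr1", 900000L, 940000L),
                     hic, cfg)
  expect_equal(hs3$supported_tissues, 0L)
  expect_false(hs3$supported_any)
})

test_that("permutation p follows the add-one formula and the fixed seed", {
  set.seed(12)
  n_r <- 30; n_g <- 40
  regions <- data.frame(id = sprintf("e%d", 1:n_r), chrom = "chr1",
                        start = 0L, end = 1L,
                        midpoint = as.integer(seq(5000, 2e6, length.out = n_r)),
                        stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(1:n_g, function(i)
    mk_gene(sprintf("g%d", i), "chr1", as.integer(i * 50000),
            as.integer(i * 50000 + 10000))))
  # supported only at the observed links' bins
  links <- data.frame(erna_id = regions$id[1:10], gene_id = genes$id[1:10],
                      stringsAsFactors = FALSE)
  cfg <- pipeline_config(n_permutations = 400L, hic_bin_bp = 10000L)
  bins_r <- regions$midpoint[1:10] %/% 10000L
  bins_g <- genes$tss[1:10] %/% 10000L
  hic <- data.frame(tissue = "t1", chrom = "chr1",
                    bin_a = pmin(bins_r, bins_g), bin_b = pmax(bins_r, bins_g),
                    oe = 10, stringsAsFactors = FALSE)
  hs <- hic_support(links, regions, genes, hic, cfg)
  expect_true(all(hs$supported_any))
  pe <- permutation_enrichment(hs, regions, genes, hic, cfg, seed = 42)
  expect_equal(pe$p_empirical, (pe$b + 1) / 401)
  expect_lte(pe$p_empirical, 5 / 401)  # observed fraction 1 is extreme
  # same seed, same stream
  pe2 <- permutation_enrichment(hs, regions, genes, hic, cfg, seed = 42)
  expect_identical(pe$perm_fractions, pe2$perm_fractions)
  expect_error(permutation_enrichment(hs[0, ], regions, genes, hic, cfg),
               "no links")
})

test_that("pathway annotation labels links through their target gene", {
  links <- data.frame(erna_id = c("e1", "e2"), gene_id = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  sets <- data.frame(pathway = c("p53", "Notch", "p53"),
                     gene = c("g1", "g1", "g3"), stringsAsFactors = FALSE)
  ann <- annotate_pathways(links, sets)
  expect_equal(sort(ann$link_pathways$pathway), c("Notch", "p53"))
  expect_equal(ann$erna_pathways$erna_id, c("e1", "e1"))
  expect_equal(nrow(annotate_pathways(links, sets[0, ])$link_pathways), 0L)
})
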
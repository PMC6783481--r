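test_that("the generator is deterministic under a fixed seed", {
  d <- simulation_design(seed = 3, n_enhancers = 40L, n_genes = 60L,
                         n_lncrnas = 10L, n_planted_links = 5L,
                         n_planted_de = 5L, n_planted_drug = 4L,
                         n_planted_hazard = 2L, n_planted_group = 2L,
                         n_hic_tissues = 4L)
  b1 <- simulate_all(d)
  b2 <- simulate_all(d)
  expect_identical(b1$expr$counts, b2$expr$counts)
  expect_identical(b1$hic, b2$hic)
  expect_identical(b1$auc, b2$auc)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(b1$truth$enhancers, b2$truth$enhancers)
})

test_that("infeasible packing fails with a helpful error", {
  d <- simulation_design(n_chroms = 1L, chrom_length_bp = 1000000L,
                         n_genes = 1000L)
  expect_error(simulate_genome(d), "longer chromosomes")
  # zero genes is fine
  g0 <- simulate_genome(simulation_design(n_genes = 0L, n_lncrnas = 0L))
  expect_equal(nrow(g0$genes), 0L)
})

test_that("cross-source overlap fraction controls the consensus ground truth", {
  base <- list(n_enhancers = 60L, n_genes = 30L, n_lncrnas = 5L)
  for (frac in c(0, 1)) {
    d <- do.call(simulation_design,
                 c(base, list(seed = 11, cross_source_overlap_frac = frac)))
    g <- simulate_genome(d)
    enh <- simulate_enhancers(d, g)
    cons <- consensus_enhancers(enh$sources, 2L)
    if (frac == 0) {
      expect_equal(nrow(cons$intervals), 0L)
    } else {
      expect_equal(nrow(cons$intervals), d$n_enhancers)
    }
    # ledger count equals consensus count in general
    expect_equal(nrow(cons$intervals), sum(enh$truth$n_sources >= 2L))
  }
})

test_that("planted copula correlation is recovered near its analytic Spearman", {
  # Spearman of a bivariate Gaussian copula at latent rho is 6/pi*asin(rho/2);
  # counting noise attenuates it slightly, hence the one-sided-ish band.
  rho <- 0.9
  target <- 6 / pi * asin(rho / 2)
  hits <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    d <- simulation_design(seed = s, link_rho = rho, n_planted_links = 1L,
                           n_planted_de = 0L, n_planted_group = 0L,
                           planted_master = NULL,
                           cohorts = data.frame(cohort = "A", n_tumor = 200L,
                                                n_paired_normal = 0L))
    b <- simulate_expression(d, "eRNA:1", c("G1", "G2"), character(),
                             link_pairs = data.frame(erna_id = "eRNA:1",
                                                     gene_id = "G2"))
    obs <- cor(b$rpm["eRNA:1", ], b$rpm["G2", ], method = "spearman")
    if (abs(obs - target) <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("planted fold change of 4 lands between 3 and 5 with 30 pairs", {
  d <- simulation_design(seed = 17, n_planted_de = 10L, de_fold_change = 4,
                         planted_master = NULL, n_planted_links = 0L,
                         n_planted_group = 0L,
                         cohorts = data.frame(cohort = "A", n_tumor = 30L,
                                              n_paired_normal = 30L))
  b <- simulate_expression(d, sprintf("eRNA:%02d", 1:30),
                           sprintf("G%02d", 1:10), character())
  md <- b$metadata
  tums <- md$sample[md$condition == "tumor"]
  norms <- md$sample[md$condition == "normal"]
  fcs <- vapply(b$truth$de$erna_id, function(e)
    mean(b$rpm[e, tums]) / mean(b$rpm[e, norms]), numeric(1))
  expect_gt(median(fcs), 3)
  expect_lt(median(fcs), 5)
})

test_that("every planted effect is recoverable by ID from the bundle", {
  d <- simulation_design(seed = 9, n_enhancers = 60L, n_genes = 80L,
                         n_planted_links = 8L, n_planted_de = 6L,
                         n_planted_drug = 4L, n_planted_hazard = 2L,
                         n_planted_group = 2L, n_hic_tissues = 4L)
  b <- simulate_all(d)
  with(b$truth, {
    expect_true(all(master$erna_id %in% rownames(b$expr$counts)))
    expect_true(all(master$tf_id %in% b$tf_ids))
    expect_true(all(links$erna_id %in% b$regions$id))
    expect_true(all(links$gene_id %in% b$genome$genes$id))
    expect_true(all(de$erna_id %in% b$regions$id))
    expect_true(all(drug$drug_id %in% rownames(b$auc)))
    expect_true(all(hazard$erna_id %in% rownames(b$expr$counts)))
    # planted Hi-C keys exist in the O/E table of an enriched tissue
    t1 <- strsplit(hic$enriched_tissues[1], ",")[[1]][1]
    h <- b$hic[b$hic$tissue == t1, ]
    keys <- ernascape:::hic_key(h$chrom, h$bin_a, h$bin_b)
    expect_true(all(hic$key %in% keys))
  })
  # written bundle restores the same matrices
  out <- withr::local_tempdir()
  b2 <- simulate_all(d, outdir = out)
  m <- read_matrix(file.path(out, "counts.tsv"))
  expect_equal(m, b2$expr$counts[rownames(m), colnames(m)],
               ignore_attr = TRUE, tolerance = 0)
})
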
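test_that("read counting uses >= 1 bp overlap with half-open semantics", {
  regions <- data.frame(id = "r1", chrom = "chr1", start = 2000L, end = 8000L,
                        midpoint = 5000L, stringsAsFactors = FALSE)
  reads <- data.frame(chrom = "chr1", start = c(2500L, 8000L),
                      end = c(2600L, 8100L), sample = "s1",
                      stringsAsFactors = FALSE)
  cnt <- count_overlaps(reads, regions)
  expect_equal(unname(cnt["r1", "s1"]), 1L)  # the read at 8000 misses

  # a read spanning two regions increments both
  regions2 <- rbind(regions,
                    data.frame(id = "r2", chrom = "chr1", start = 7000L,
                               end = 9000L, midpoint = 8000L))
  reads2 <- data.frame(chrom = "chr1", start = 7500L, end = 7600L,
                       sample = "s1", stringsAsFactors = FALSE)
  cnt2 <- count_overlaps(reads2, regions2)
  expect_equal(unname(cnt2[, "s1"]), c(1L, 1L))
})

test_that("read counting matches the all-pairs oracle on random instances", {
  for (seed in c(3, 11, 42)) {
    inst <- random_toy_instance(seed)
    regions <- data.frame(id = sprintf("r%d", 1:20), chrom = "c1",
                          start = seq(0L, 95000L, length.out = 20),
                          end = seq(0L, 95000L, length.out = 20) + 4000L,
                          stringsAsFactors = FALSE)
    regions$midpoint <- (regions$start + regions$end) %/% 2L
    got <- count_overlaps(inst$reads, regions,
                          samples = c("s1", "s2", "s3"))
    want <- oracle_count_overlaps(inst$reads, regions, c("s1", "s2", "s3"))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("RPM is count/(library/1e6), exactly scale-invariant", {
  counts <- matrix(c(50L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(rpm(counts, c(s1 = 5e6))[, 1]), c(10, 0))
  # joint scaling of counts and library leaves RPM untouched
  m <- matrix(rpois(20, 30), 4, 5,
              dimnames = list(letters[1:4], paste0("s", 1:5)))
  ls <- stats::setNames(runif(5, 1e6, 2e7), paste0("s", 1:5))
  expect_equal(rpm(m, ls), rpm(m * 7L, ls * 7), tolerance = 1e-14)
  expect_error(rpm(m, stats::setNames(c(0, ls[-1]), names(ls))), "positive")
  expect_error(rpm(m, ls[-1]), "no library size")
})

test_that("detectability uses tumor-only cohort means with inclusive cutoff", {
  expr <- matrix(c(1.0, 0.2,    # tumor mean exactly at the cutoff
                   0.99, 50,    # tumor mean just below it
                   0, 50),      # high only in the normal sample
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("hit", "miss", "norm_only"),
                                 c("t1", "n1")))
  md <- data.frame(sample = c("t1", "n1"), cohort = "A",
                   condition = c("tumor", "normal"), stringsAsFactors = FALSE)
  d <- detectability(expr, md, threshold = 1)
  expect_true(d$detectable["hit", "A"])    # mean exactly 1 counts
  expect_false(d$detectable["miss", "A"])
  expect_false(d$detectable["norm_only", "A"])  # normals never enter

  md_bad <- data.frame(sample = c("t1", "n1"), cohort = c("A", "B"),
                       condition = c("tumor", "normal"),
                       stringsAsFactors = FALSE)
  expect_error(detectability(expr, md_bad), "zero tumor samples")
})

test_that("strict detectability is nested and classes partition", {
  set.seed(5)
  b <- simulate_expression(simulation_design(seed = 5, n_planted_de = 0L),
                           sprintf("eRNA:%02d", 1:40),
                           sprintf("G%02d", 1:10), "G01")
  erna <- b$rpm[sprintf("eRNA:%02d", 1:40), ]
  d1 <- detectability(erna, b$metadata, 1)
  d5 <- detectability(erna, b$metadata, 5)
  expect_true(all(d5$detectable <= d1$detectable))  # RPM>=5 set nested in RPM>=1
  cls <- classify_specificity(d1)
  expect_equal(sum(cls != "undetected"), sum(d1$n_cohorts >= 1))
  expect_setequal(unique(cls),
                  intersect(c("ubiquitous", "intermediate", "specific",
                              "undetected"), unique(cls)))
  # boundary mapping
  expect_equal(unname(classify_specificity(c(a = 10, b = 9, c = 2, d = 1, e = 0))),
               c("ubiquitous", "intermediate", "intermediate", "specific",
                 "undetected"))
})

test_that("sample similarity is 1 on duplicates and separates cohorts", {
  set.seed(8)
  x <- matrix(rlnorm(300), 30, 10,
              dimnames = list(sprintf("e%d", 1:30), sprintf("s%d", 1:10)))
  x[, 2] <- x[, 1]
  sim <- sample_similarity(x)
  expect_equal(sim["s1", "s2"], 1)
  expect_true(isSymmetric(sim))
  expect_equal(unname(diag(sim)), rep(1, 10))

  # cohort-specific planted programs: within-cohort mean similarity higher
  b <- simulate_expression(simulation_design(seed = 21, n_planted_de = 0L,
                                             n_planted_group = 0L),
                           sprintf("eRNA:%02d", 1:60),
                           sprintf("G%02d", 1:20), "G01")
  erna <- b$rpm[sprintf("eRNA:%02d", 1:60), b$metadata$condition == "tumor"]
  md <- b$metadata[b$metadata$condition == "tumor", ]
  sim2 <- sample_similarity(erna)
  same <- outer(md$cohort, md$cohort, "==") & upper.tri(sim2)
  diff <- outer(md$cohort, md$cohort, "!=") & upper.tri(sim2)
  expect_gt(mean(sim2[same]), mean(sim2[diff]))
})
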
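mk_paired_md <- function(n_pairs, cohort = "A") {
  rbind(data.frame(sample = sprintf("t%d", 1:n_pairs), cohort = cohort,
                   condition = "tumor", patient = sprintf("p%d", 1:n_pairs),
                   stringsAsFactors = FALSE),
        data.frame(sample = sprintf("n%d", 1:n_pairs), cohort = cohort,
                   condition = "normal", patient = sprintf("p%d", 1:n_pairs),
                   stringsAsFactors = FALSE))
}

test_that("differential calls follow the fold-change and FDR gates", {
  set.seed(14)
  n <- 20
  md <- mk_paired_md(n)
  base <- rlnorm(n, log(10), 0.1)
  expr <- rbind(up = c(base * 4, base),           # FC ~ 4
                flat = c(base * 1.4, base),       # below the 1.5 gate
                dn = c(base, base * 4))
  colnames(expr) <- md$sample
  res <- differential_expression(expr, md, "A", pipeline_config())
  expect_equal(res$call[res$erna_id == "up"], "up")
  expect_equal(res$call[res$erna_id == "flat"], "ns")
  expect_equal(res$call[res$erna_id == "dn"], "down")
  expect_true(all(res$call %in% c("up", "down", "ns")))

  # swapping tumor/normal labels inverts FC and swaps up/down exactly
  md_sw <- md; md_sw$condition <- ifelse(md$condition == "tumor", "normal", "tumor")
  res_sw <- differential_expression(expr, md_sw, "A", pipeline_config())
  expect_equal(res_sw$fold_change, 1 / res$fold_change, tolerance = 1e-12)
  expect_equal(res_sw$call[res$call == "up"], "down")
  expect_equal(res_sw$call[res$call == "down"], "up")

  # cohorts with fewer than 5 pairs are skipped
  expect_null(differential_expression(expr[, c(1:4, 21:24)],
                                      mk_paired_md(4), "A",
                                      pipeline_config()))
  md_bad <- rbind(md, data.frame(sample = "t_extra", cohort = "A",
                                 condition = "tumor", patient = "p1"))
  expr_bad <- cbind(expr, t_extra = expr[, 1])
  expect_error(differential_expression(expr_bad, md_bad, "A",
                                       pipeline_config()),
               "several tumor")
})

test_that("group tests drop small groups and pick t versus ANOVA", {
  set.seed(15)
  n <- 34
  labels <- c(rep("a", 15), rep("b", 15), rep("tiny", 4))
  expr <- matrix(rlnorm(2 * n), 2, n,
                 dimnames = list(c("shift", "null"), sprintf("s%d", 1:n)))
  expr["shift", labels == "a"] <- expr["shift", labels == "a"] * 20
  res <- group_tests(expr, labels, "A", "subtype", pipeline_config())
  expect_equal(unique(res$test), "t")  # "tiny" was dropped -> two groups
  expect_lt(res$q[res$erna_id == "shift"], 0.05)
  expect_gt(res$q[res$erna_id == "null"], 0.05)

  labels3 <- rep(c("a", "b", "c"), each = 12)
  expr3 <- matrix(rlnorm(36), 1, 36, dimnames = list("e", NULL))
  res3 <- group_tests(expr3, labels3, "A", "stage", pipeline_config())
  expect_equal(res3$test, "anova")

  expect_message(
    expect_null(group_tests(expr, c(rep("a", 30), rep("b", 4)), "A",
                            "grade", pipeline_config())),
    "skipped")
})

test_that("survival associations recover direction and skip degenerate input", {
  set.seed(16)
  n <- 120
  z <- rnorm(n)
  rate <- exp(log(2) * z)
  time <- rexp(n, rate); cens <- rexp(n, 0.4)
  event <- as.integer(time <= cens)
  obs <- pmin(time, cens)
  expr <- rbind(risk = exp(z), null = rlnorm(n), flat = rep(1, n))
  colnames(expr) <- sprintf("s%d", 1:n)
  res <- survival_association(expr, obs, event, "A", pipeline_config())
  expect_false("flat" %in% res$erna_id)  # constant expression skipped
  expect_gt(res$effect[res$erna_id == "risk"], 0)
  expect_lt(res$q[res$erna_id == "risk"], 0.05)

  # log-rank quartile mode flags the same eRNA
  res_lr <- survival_association(expr, obs, event, "A",
                                 pipeline_config(survival_mode = "logrank"))
  expect_lt(res_lr$q[res_lr$erna_id == "risk"], 0.05)

  # too few events -> skipped entirely
  expect_message(
    expect_null(survival_association(expr[, 1:30], obs[1:30],
                                     rep(0L, 30), "A", pipeline_config())),
    "skipped")
})

test_that("clinical relevance is the union of the per-category sets", {
  assoc <- data.frame(
    erna_id = c("e1", "e1", "e2", "e3"),
    cohort = "A",
    feature = c("stage", "survival", "subtype", "grade"),
    test = "t", statistic = 1,
    p = c(1e-5, 1e-4, 1e-6, 0.9),
    q = c(1e-4, 1e-3, 1e-5, 0.95),
    stringsAsFactors = FALSE)
  cs <- clinical_summary(assoc, pipeline_config())
  expect_equal(cs$per_erna$relevant, c(TRUE, TRUE, FALSE))
  expect_equal(cs$per_erna$categories[1], "stage,survival")
  # union identity: relevant set equals union over categories
  by_cat <- unique(unlist(lapply(split(cs$per_cohort, cs$per_cohort$feature),
                                 function(d) d$erna_id)))
  expect_setequal(cs$per_erna$erna_id[cs$per_erna$relevant], by_cat)
  empty <- clinical_summary(NULL, pipeline_config())
  expect_equal(nrow(empty$per_erna), 0L)
})
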
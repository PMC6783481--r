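#' Paired tumor/normal differential expression of eRNAs
#'
#' For cohorts with at least 5 tumor-normal pairs: fold change is the ratio
#' of tumor to normal mean RPM (pseudocount added to both), the test is a
#' paired two-sided t-test on `log2(RPM + pseudocount)`, and BH-FDR is
#' applied over eRNAs within the cohort. Calls: `up` when
#' `fold_change >= fc_min` and `q < fdr_max`, `down` when
#' `fold_change <= 1/fc_min` and `q < fdr_max`, otherwise `ns`.
#'
#' @param expr RPM matrix.
#' @param metadata sample metadata with `sample`, `cohort`, `condition`
#'   (`tumor`/`normal`) and `patient`.
#' @param cohort cohort label to test.
#' @param config a [pipeline_config()].
#' @return data.frame of `differential_result` rows, or `NULL` when the
#'   cohort has fewer than 5 pairs.
#' @export
differential_expression <- function(expr, metadata, cohort,
                                    config = pipeline_config()) {
  md <- metadata[metadata$cohort == cohort, , drop = FALSE]
  tum <- md[md$condition == "tumor", , drop = FALSE]
  nor <- md[md$condition == "normal", , drop = FALSE]
  patients <- intersect(tum$patient, nor$patient)
  if (anyDuplicated(tum$patient[tum$patient %in% patients]) ||
      anyDuplicated(nor$patient[nor$patient %in% patients])) {
    stop("pairing table maps one patient to several tumor or normal samples in ", cohort)
  }
  if (length(patients) < 5L) return(NULL)
  ts <- tum$sample[match(patients, tum$patient)]
  ns <- nor$sample[match(patients, nor$patient)]
  eps <- config$de_pseudocount
  tm <- expr[, ts, drop = FALSE]; nm <- expr[, ns, drop = FALSE]
  mean_t <- rowMeans(tm); mean_n <- rowMeans(nm)
  fc <- (mean_t + eps) / (mean_n + eps)
  diffs <- log2(tm + eps) - log2(nm + eps)
  dbar <- rowMeans(diffs)
  dsd <- apply(diffs, 1L, stats::sd)
  n_pairs <- length(patients)
  tstat <- dbar / (dsd / sqrt(n_pairs))
  p <- 2 * stats::pt(-abs(tstat), df = n_pairs - 1)
  p[dsd == 0 & dbar == 0] <- 1
  q <- bh_fdr(p)
  call <- ifelse(is.na(q), "ns",
          ifelse(fc >= config$fc_min & q < config$fdr_max, "up",
          ifelse(fc <= 1 / config$fc_min & q < config$fdr_max, "down", "ns")))
  data.frame(erna_id = rownames(expr), cohort = cohort, n_pairs = n_pairs,
             mean_tumor_rpm = mean_t, mean_normal_rpm = mean_n,
             fold_change = fc, p = p, q = q, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group-wise clinical association tests
#'
#' Drops groups with fewer than `min_group_size` samples; two remaining
#' groups give a Welch t-test, three or more a one-way ANOVA. BH-FDR is
#' applied over eRNAs within the (cohort, feature) scope.
#'
#' @param expr RPM matrix (tumor samples of one cohort).
#' @param labels character vector of group labels aligned to `colnames(expr)`.
#' @param cohort,feature labels stored on the records (feature one of
#'   `subtype`, `stage`, `grade`, `smoking`).
#' @param config a [pipeline_config()].
#' @return data.frame `(erna_id, cohort, feature, test, statistic, p, q)`,
#'   or `NULL` when fewer than two qualifying groups remain.
#' @export
group_tests <- function(expr, labels, cohort, feature,
                        config = pipeline_config()) {
  keep_lab <- names(which(table(labels) >= config$min_group_size))
  keep_lab <- keep_lab[!is.na(keep_lab) & keep_lab != ""]
  cols <- which(labels %in% keep_lab)
  if (length(keep_lab) < 2L) {
    message(sprintf("group_tests: %s/%s skipped (<2 groups with >= %d samples)",
                    cohort, feature, config$min_group_size))
    return(NULL)
  }
  g <- factor(labels[cols])
  sub <- expr[, cols, drop = FALSE]
  res <- t(apply(sub, 1L, function(v) {
    if (length(unique(v)) == 1L) return(c(NA_real_, 1))
    if (nlevels(g) == 2L) {
      tt <- stats::t.test(v ~ g, var.equal = FALSE)
      c(unname(tt$statistic), tt$p.value)
    } else {
      av <- stats::anova(stats::aov(v ~ g))
      c(av$`F value`[1], av$`Pr(>F)`[1])
    }
  }))
  data.frame(erna_id = rownames(expr), cohort = cohort, feature = feature,
             test = if (nlevels(g) == 2L) "t" else "anova",
             statistic = res[, 1], p = res[, 2], q = bh_fdr(res[, 2]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Survival association of eRNA expression
#'
#' Default mode fits a univariate Cox model on z-scored log2 expression (Wald
#' p); `mode = "logrank"` compares the top against the bottom expression
#' quartile by log-rank. Cohorts with fewer than 20 subjects or fewer than
#' 10 events are skipped. BH-FDR over eRNAs within the cohort.
#'
#' @param expr RPM matrix (tumor samples of one cohort).
#' @param time,event numeric survival time and 0/1 event flag aligned to
#'   `colnames(expr)`.
#' @param cohort cohort label.
#' @param config a [pipeline_config()].
#' @param mode `"cox"` or `"logrank"` (defaults to the config field).
#' @return data.frame `(erna_id, cohort, feature, test, statistic, effect,
#'   p, q)` where `effect` is the log hazard ratio per SD (Cox) or the
#'   direction sign (log-rank); `NULL` when the cohort is skipped.
#' @export
survival_association <- function(expr, time, event, cohort,
                                 config = pipeline_config(),
                                 mode = config$survival_mode) {
  ok <- is.finite(time) & !is.na(event)
  if (sum(ok) < 20L || sum(event[ok]) < 10L) {
    message(sprintf("survival: %s skipped (need >= 20 subjects, >= 10 events)", cohort))
    return(NULL)
  }
  expr <- expr[, ok, drop = FALSE]; time <- time[ok]; event <- event[ok]
  surv <- survival::Surv(time, event)
  res <- t(apply(expr, 1L, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
    if (mode == "cox") {
      lv <- log2(v + config$de_pseudocount)  # tames the log-normal tail
      z <- (lv - mean(lv)) / stats::sd(lv)
      fit <- survival::coxph(surv ~ z)
      s <- summary(fit)
      c(s$coefficients[1, "z"], s$coefficients[1, "coef"],
        s$coefficients[1, "Pr(>|z|)"])
    } else {
      qs <- stats::quantile(v, c(0.25, 0.75))
      lo <- v <= qs[1]; hi <- v >= qs[2]
      if (!any(lo) || !any(hi) || qs[1] == qs[2]) return(c(NA_real_, NA_real_, NA_real_))
      grp <- factor(ifelse(hi, "high", ifelse(lo, "low", NA)))
      sel <- !is.na(grp)
      sd_ <- survival::survdiff(survival::Surv(time[sel], event[sel]) ~ grp[sel])
      pval <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
      dir_ <- sign(sd_$obs[1] - sd_$exp[1])  # high group index 1 after factor sort
      c(sd_$chisq, dir_, pval)
    }
  }))
  skipped <- is.na(res[, 3])
  out <- data.frame(erna_id = rownames(expr), cohort = cohort,
                    feature = "survival",
                    test = if (mode == "cox") "cox" else "logrank",
                    statistic = res[, 1], effect = res[, 2], p = res[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[!skipped, , drop = FALSE]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Clinically relevant eRNAs
#'
#' An eRNA is clinically relevant when at least one of its survival,
#' subtype, stage, grade or smoking tests reaches `q < fdr_max` in any
#' cohort; the output lists the contributing categories per (eRNA, cohort).
#'
#' @param associations row-bound outputs of [group_tests()] and
#'   [survival_association()] (needs `erna_id`, `cohort`, `feature`, `q`).
#' @param config a [pipeline_config()].
#' @return list with `per_erna` (`erna_id`, `relevant`, comma-collapsed
#'   `categories`) and `per_cohort` (long `(erna_id, cohort, feature)` of
#'   significant results).
#' @export
clinical_summary <- function(associations, config = pipeline_config()) {
  if (is.null(associations) || !nrow(associations)) {
    return(list(per_erna = data.frame(erna_id = character(),
                                      relevant = logical(),
                                      categories = character(),
                                      stringsAsFactors = FALSE),
                per_cohort = data.frame(erna_id = character(),
                                        cohort = character(),
                                        feature = character(),
                                        stringsAsFactors = FALSE)))
  }
  sig <- associations[!is.na(associations$q) &
                        associations$q < config$fdr_max,
                      c("erna_id", "cohort", "feature"), drop = FALSE]
  rownames(sig) <- NULL
  cats <- tapply(sig$feature, sig$erna_id,
                 function(v) paste(sort(unique(v)), collapse = ","))
  all_ids <- sort(unique(associations$erna_id))
  per_erna <- data.frame(erna_id = all_ids,
                         relevant = all_ids %in% sig$erna_id,
                         categories = ifelse(all_ids %in% names(cats),
                                             cats[all_ids], ""),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(per_erna = per_erna, per_cohort = sig)
}
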
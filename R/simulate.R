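#' Synthetic-cohort simulation design
#'
#' Parameters of the seeded generator that produces every input the
#' pipeline consumes, with planted effects (a master TF, eRNA-gene links,
#' Hi-C enrichment, drug correlations, tumor/normal fold changes, survival
#' and group effects) recorded in a truth ledger. Rank correlations are
#' planted through a Gaussian copula on latent normals, so the expected
#' Spearman correlation of a planted pair is the analytic
#' `6/pi * asin(rho/2)` before counting noise.
#'
#' @param ... named overrides of the defaults (see the function body for
#'   the complete list; notable fields: `cohorts` data.frame with
#'   `cohort`, `n_tumor`, `n_paired_normal`; `planted_master` list with
#'   `fraction` and `rho` or `NULL`; `n_planted_links`/`link_rho`;
#'   `n_planted_de`/`de_fold_change`; `n_planted_drug`/`drug_rho`;
#'   `n_planted_hazard`/`hazard_log_hr`; `n_planted_group`/
#'   `group_shift_sd`; `hic_enrichment`; `nb_dispersion`;
#'   `mean_library_size`; `seed`).
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(...) {
  d <- list(
    n_chroms = 4L, chrom_length_bp = 10000000L,
    n_genes = 250L, n_lncrnas = 40L,
    n_enhancers = 150L, cross_source_overlap_frac = 0.6,
    enhancer_safe_frac = 0.85,
    cohorts = data.frame(cohort = c("cohA", "cohB", "cohC"),
                         n_tumor = 60L, n_paired_normal = 15L,
                         stringsAsFactors = FALSE),
    n_tfs = 25L,
    planted_master = list(fraction = 0.4, rho = 0.6),
    n_planted_links = 40L, link_rho = 0.5,
    n_planted_de = 30L, de_fold_change = 4,
    n_planted_drug = 16L, drug_rho = 0.6,
    n_planted_hazard = 6L, hazard_log_hr = log(2),
    n_planted_group = 6L, group_shift_sd = 2, group_feature = "subtype",
    n_drugs = 30L, n_cell_lines = 100L,
    n_hic_tissues = 20L, hic_enrichment = 10,
    hic_enriched_tissue_frac = 1.0, hic_max_dist_bp = 2000000L,
    nb_dispersion = 0.02, mean_library_size = 5e6, library_sd_log = 0.2,
    base_rpm_meanlog = log(12), base_rpm_sdlog = 0.6,
    gene_rpm_meanlog = log(30),
    latent_sd = 1.2,
    erna_on_prob = 0.7, erna_off_factor = 0.005,
    cohort_program_sd = 0.5, patient_rho = 0.4,
    censoring_rate = 0.45,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(d))
  if (length(unknown)) stop("unknown design field(s): ",
                            paste(unknown, collapse = ", "))
  d[names(overrides)] <- overrides
  for (f in c("link_rho", "drug_rho")) {
    if (abs(d[[f]]) >= 1) stop(f, " must lie in (-1, 1)")
  }
  if (!is.null(d$planted_master)) {
    if (abs(d$planted_master$rho) >= 1) stop("planted_master rho must lie in (-1, 1)")
    if (d$planted_master$fraction < 0 || d$planted_master$fraction > 1) {
      stop("planted_master fraction must lie in [0, 1]")
    }
  }
  for (f in c("cross_source_overlap_frac", "enhancer_safe_frac",
              "erna_on_prob", "hic_enriched_tissue_frac")) {
    if (d[[f]] < 0 || d[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  for (f in c("n_chroms", "chrom_length_bp", "n_genes", "n_enhancers",
              "n_tfs", "n_drugs", "n_cell_lines", "n_hic_tissues")) {
    if (d[[f]] < 0) stop(f, " must be non-negative")
  }
  structure(d, class = "simulation_design")
}

#' A design with every planted effect switched off
#'
#' Used for null-calibration runs: no master TF, no links, no differential
#' expression, no drug/survival/group effects, Hi-C enrichment factor 1.
#'
#' @param ... further overrides passed to [simulation_design()].
#' @return A `simulation_design`.
#' @export
null_design <- function(...) {
  simulation_design(planted_master = NULL, n_planted_links = 0L,
                    n_planted_de = 0L, n_planted_drug = 0L,
                    n_planted_hazard = 0L, n_planted_group = 0L,
                    hic_enrichment = 1, ...)
}

# Rejection-sampled non-overlapping interval placement.
place_intervals <- function(n, len_range, chrom_lengths, existing = NULL,
                            min_gap = 0L, max_tries = 500L) {
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  chroms <- names(chrom_lengths)
  acc <- if (is.null(existing)) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  } else existing[, c("chrom", "start", "end")]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1L, prob = chrom_lengths / sum(chrom_lengths))
      len <- sample(len_range[1]:len_range[2], 1L)
      max_start <- chrom_lengths[[chrom]] - len
      if (max_start < 1) next
      start <- sample.int(max_start, 1L)
      same <- acc$chrom == chrom
      clash <- any(same & acc$start < start + len + min_gap &
                     start < acc$end + min_gap)
      if (!clash) {
        row <- data.frame(chrom = chrom, start = as.integer(start),
                          end = as.integer(start + len),
                          stringsAsFactors = FALSE)
        acc <- rbind(acc, row)
        out[[i]] <- row
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place interval ", i, " of ", n,
           " without overlap; consider longer chromosomes")
    }
  }
  do.call(rbind, out)
}

#' Simulate the synthetic genome annotation
#'
#' Places non-overlapping protein-coding genes (2-5 exons each),
#' lncRNAs and a small blacklist on `n_chroms` chromosomes.
#'
#' @param design a [simulation_design()].
#' @return list with `chrom_lengths`, `genes` and `lncrnas` (gene tables)
#'   and `blacklist` (an [annotation_set()]).
#' @export
simulate_genome <- function(design) {
  set.seed(design$seed + 101L)
  chrom_lengths <- stats::setNames(rep(as.integer(design$chrom_length_bp),
                                       design$n_chroms),
                                   paste0("chr", seq_len(design$n_chroms)))
  gene_iv <- place_intervals(design$n_genes, c(5000L, 30000L), chrom_lengths,
                             min_gap = 200L)
  genes <- build_gene_table(gene_iv, prefix = "G", with_exons = TRUE)
  lnc_iv <- place_intervals(design$n_lncrnas, c(1000L, 10000L), chrom_lengths,
                            existing = gene_iv, min_gap = 200L)
  lncrnas <- build_gene_table(lnc_iv, prefix = "L", with_exons = FALSE)
  bl_n <- 10L
  bl <- data.frame(chrom = sample(names(chrom_lengths), bl_n, replace = TRUE),
                   stringsAsFactors = FALSE)
  bl$start <- vapply(bl$chrom, function(ch)
    sample.int(chrom_lengths[[ch]] - 5000L, 1L), integer(1))
  bl$end <- bl$start + sample(1000:5000, bl_n, replace = TRUE)
  list(chrom_lengths = chrom_lengths,
       genes = genes, lncrnas = lncrnas,
       blacklist = annotation_set(bl, role = "blacklist", source = "synthetic"))
}

build_gene_table <- function(iv, prefix, with_exons) {
  n <- nrow(iv)
  if (!n) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     id = character(), strand = character(), tss = integer(),
                     tes = integer(), exon_starts = character(),
                     exon_ends = character(), stringsAsFactors = FALSE)
    class(df) <- c("gene_table", "data.frame")
    return(df)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exon_starts <- character(n); exon_ends <- character(n)
  for (i in seq_len(n)) {
    len <- iv$end[i] - iv$start[i]
    k <- if (with_exons) sample(2:5, 1L) else 1L
    if (k == 1L) {
      es <- iv$start[i]; ee <- iv$end[i]
    } else {
      cuts <- sort(sample.int(len - 1L, 2L * k - 2L))
      bounds <- c(0L, cuts, len)
      seg_s <- bounds[-length(bounds)]; seg_e <- bounds[-1]
      odd <- seq(1L, 2L * k - 1L, by = 2L)
      es <- iv$start[i] + seg_s[odd]; ee <- iv$start[i] + seg_e[odd]
    }
    exon_starts[i] <- paste(es, collapse = ",")
    exon_ends[i] <- paste(ee, collapse = ",")
  }
  df <- data.frame(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    id = sprintf("%s%04d", prefix, seq_len(n)),
    strand = strand,
    tss = ifelse(strand == "+", iv$start, iv$end - 1L),
    tes = ifelse(strand == "+", iv$end - 1L, iv$start),
    exon_starts = exon_starts, exon_ends = exon_ends,
    stringsAsFactors = FALSE
  )
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Simulate three enhancer annotation sources with known cross-source truth
#'
#' Base enhancers are placed with a minimum gap so each stays its own
#' consensus block; a fraction `cross_source_overlap_frac` is copied into
#' one or two additional sources with a small jitter that always preserves
#' at least one base of overlap. The truth ledger records, per enhancer,
#' how many sources carry it, so the expected consensus set is known
#' exactly.
#'
#' @param design a [simulation_design()].
#' @param genome output of [simulate_genome()].
#' @param config a [pipeline_config()] (flank and exclusion geometry used to
#'   place most enhancers in unmasked space).
#' @return list with `sources` (list of three enhancer
#'   [annotation_set()]s) and `truth` (per-enhancer ledger with
#'   `n_sources` and `safe`).
#' @export
simulate_enhancers <- function(design, genome, config = pipeline_config()) {
  set.seed(design$seed + 202L)
  mask <- build_exclusion_mask(genome$genes, genome$lncrnas, genome$blacklist,
                               config$gene_extension_bp, config$uaRNA_window_bp)
  mask_by_chrom <- split(mask$intervals, mask$intervals$chrom)
  chroms <- names(genome$chrom_lengths)
  n <- design$n_enhancers
  n_safe <- round(n * design$enhancer_safe_frac)
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      chrom <- sample(chroms, 1L)
      width <- sample(300:1500, 1L)
      lo <- config$flank_bp + 1L
      hi <- genome$chrom_lengths[[chrom]] - config$flank_bp - width
      start <- sample(lo:hi, 1L)
      end <- start + width
      same <- placed$chrom == chrom
      if (any(same & placed$start < end + 1000L & start < placed$end + 1000L)) next
      if (i <= n_safe) {
        mid <- (start + end) %/% 2L
        m <- mask_by_chrom[[chrom]]
        if (!is.null(m) && any(m$start < mid + config$flank_bp &
                                 mid - config$flank_bp < m$end)) next
      }
      rows[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                              safe = i <= n_safe, stringsAsFactors = FALSE)
      placed <- rbind(placed, rows[[i]][, 1:3])
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place enhancer ", i, "; consider longer chromosomes")
  }
  base <- do.call(rbind, rows)
  base$id <- sprintf("ENH%04d", seq_len(nrow(base)))
  home <- sample(1:3, n, replace = TRUE)
  multi <- stats::runif(n) < design$cross_source_overlap_frac
  n_extra <- ifelse(multi, sample(1:2, n, replace = TRUE), 0L)
  src_rows <- list(list(), list(), list())
  for (i in seq_len(n)) {
    in_sources <- home[i]
    if (n_extra[i] > 0L) {
      others <- setdiff(1:3, home[i])
      in_sources <- c(in_sources, sample(others, n_extra[i]))
    }
    width <- base$end[i] - base$start[i]
    for (s in in_sources) {
      jit <- if (s == home[i]) 0L else
        sample((-min(150L, width - 10L)):(min(150L, width - 10L)), 1L)
      src_rows[[s]][[length(src_rows[[s]]) + 1L]] <-
        data.frame(chrom = base$chrom[i], start = base$start[i] + jit,
                   end = base$end[i] + jit, id = base$id[i],
                   stringsAsFactors = FALSE)
    }
  }
  sources <- lapply(1:3, function(s) {
    df <- do.call(rbind, src_rows[[s]])
    if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), stringsAsFactors = FALSE)
    annotation_set(df, role = "enhancer", source = paste0("source", s))
  })
  truth <- data.frame(enhancer_id = base$id, chrom = base$chrom,
                      start = base$start, end = base$end,
                      midpoint = (base$start + base$end) %/% 2L,
                      n_sources = 1L + n_extra, safe = base$safe,
                      stringsAsFactors = FALSE)
  list(sources = sources, truth = truth)
}

# Sample sheet for the requested cohorts (tumor + paired normals).
build_samples <- function(cohorts) {
  out <- list()
  for (i in seq_len(nrow(cohorts))) {
    co <- cohorts$cohort[i]
    nt <- cohorts$n_tumor[i]; np <- cohorts$n_paired_normal[i]
    pat <- sprintf("%s_P%03d", co, seq_len(nt))
    out[[length(out) + 1L]] <- data.frame(
      sample = sprintf("%s_T%03d", co, seq_len(nt)),
      cohort = co, condition = "tumor", patient = pat,
      stringsAsFactors = FALSE)
    if (np > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        sample = sprintf("%s_N%03d", co, seq_len(np)),
        cohort = co, condition = "normal", patient = pat[seq_len(np)],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate expression counts with planted copula structure
#'
#' Draws latent standard normals per feature and sample, wires in the
#' planted correlations (master TF to driven eRNAs; eRNA to target gene),
#' shares a patient latent between tumor and paired normal samples, maps
#' latents through a log-normal mean model to negative-binomial counts, and
#' applies planted tumor fold changes and group mean shifts.
#'
#' @param design a [simulation_design()].
#' @param region_ids,gene_ids feature universes (eRNA regions and genes).
#' @param tf_ids subset of `gene_ids` acting as TFs.
#' @param cohorts cohort sheet (defaults to `design$cohorts`).
#' @param link_pairs data.frame `(erna_id, gene_id)` of planted links
#'   (chosen by the caller from the candidate-pair universe so they are
#'   testable downstream); `NULL` for none.
#' @param force_on character vector of eRNA ids expressed in every cohort
#'   regardless of the on/off draw (planted features are forced on).
#' @param seed integer; defaults to a stage-specific offset of the design
#'   seed.
#' @return list with `counts`, `library_sizes`, `metadata`, `rpm`,
#'   `latents` and the `truth` sub-ledgers (`master`, `links`, `de`,
#'   `group`, `on`).
#' @export
simulate_expression <- function(design, region_ids, gene_ids, tf_ids,
                                cohorts = design$cohorts,
                                link_pairs = NULL, force_on = NULL,
                                seed = design$seed + 303L) {
  set.seed(seed)
  samples <- build_samples(cohorts)
  S <- nrow(samples)
  features <- c(gene_ids, region_ids)
  FN <- length(features)
  is_erna <- features %in% region_ids

  # clinical group labels (tumor samples only)
  tum <- samples$condition == "tumor"
  lab <- function(levels) ifelse(tum, sample(levels, S, replace = TRUE), NA)
  samples$subtype <- lab(c("sub1", "sub2", "sub3"))
  samples$stage <- lab(c("I", "II", "III"))
  samples$grade <- lab(c("g1", "g2", "g3"))
  samples$smoking <- lab(c("never", "former", "current"))

  # latent normals with patient sharing for paired samples
  eps <- matrix(stats::rnorm(FN * S), FN, S, dimnames = list(features, samples$sample))
  w <- design$patient_rho
  paired_pat <- samples$patient[duplicated(samples$patient)]
  for (p in paired_pat) {
    cols <- which(samples$patient == p)
    u <- stats::rnorm(FN)
    eps[, cols] <- sqrt(1 - w) * eps[, cols] + sqrt(w) * u
  }
  z <- eps

  # planted master TF -> driven eRNAs
  truth_master <- NULL
  if (!is.null(design$planted_master) && length(tf_ids) &&
      design$planted_master$fraction > 0 && length(region_ids)) {
    rho <- design$planted_master$rho
    master_tf <- tf_ids[1]
    n_driven <- round(design$planted_master$fraction * length(region_ids))
    driven <- sample(region_ids, n_driven)
    z[driven, ] <- rho * matrix(z[master_tf, ], length(driven), S, byrow = TRUE) +
      sqrt(1 - rho^2) * eps[driven, , drop = FALSE]
    truth_master <- data.frame(tf_id = master_tf, erna_id = driven,
                               rho = rho, stringsAsFactors = FALSE)
  }

  # planted eRNA -> gene links (distinct target genes, never TFs)
  truth_links <- NULL
  if (!is.null(link_pairs) && nrow(link_pairs)) {
    if (anyDuplicated(link_pairs$gene_id)) {
      stop("planted link target genes must be distinct")
    }
    if (any(link_pairs$gene_id %in% tf_ids)) {
      stop("planted link targets may not be TFs")
    }
    rho <- design$link_rho
    z[link_pairs$gene_id, ] <- rho * z[link_pairs$erna_id, , drop = FALSE] +
      sqrt(1 - rho^2) * eps[link_pairs$gene_id, , drop = FALSE]
    truth_links <- data.frame(link_pairs[, c("erna_id", "gene_id")],
                              rho = rho, stringsAsFactors = FALSE)
  }

  # mean model
  base <- ifelse(is_erna,
                 stats::rlnorm(FN, design$base_rpm_meanlog, design$base_rpm_sdlog),
                 stats::rlnorm(FN, design$gene_rpm_meanlog, design$base_rpm_sdlog))
  names(base) <- features
  co_levels <- cohorts$cohort
  on <- matrix(TRUE, FN, length(co_levels), dimnames = list(features, co_levels))
  on[is_erna, ] <- stats::runif(sum(is_erna) * length(co_levels)) < design$erna_on_prob
  forced <- unique(c(force_on,
                     if (!is.null(truth_master)) truth_master$erna_id,
                     if (!is.null(truth_links)) truth_links$erna_id))
  forced <- intersect(forced, features)
  on[forced, ] <- TRUE
  prog <- matrix(exp(stats::rnorm(FN * length(co_levels), 0,
                                  design$cohort_program_sd)),
                 FN, length(co_levels), dimnames = list(features, co_levels))

  # choose planted DE / group eRNAs before freezing the on/off state
  truth_de <- NULL
  de_ernas <- character()
  if (design$n_planted_de > 0L && length(region_ids)) {
    pool <- setdiff(region_ids, if (!is.null(truth_links)) truth_links$erna_id else NULL)
    de_ernas <- sample(pool, min(design$n_planted_de, length(pool)))
    on[de_ernas, ] <- TRUE
    truth_de <- data.frame(erna_id = de_ernas,
                           fold_change = design$de_fold_change,
                           stringsAsFactors = FALSE)
  }
  truth_group <- NULL
  g_ernas <- character()
  if (design$n_planted_group > 0L && length(region_ids)) {
    used <- c(de_ernas, if (!is.null(truth_links)) truth_links$erna_id)
    pool <- setdiff(region_ids, used)
    g_ernas <- sample(pool, min(design$n_planted_group, length(pool)))
    on[g_ernas, ] <- TRUE
    feat <- design$group_feature
    target_level <- sort(unique(stats::na.omit(samples[[feat]])))[1]
    truth_group <- data.frame(erna_id = g_ernas, feature = feat,
                              level = target_level,
                              shift_sd = design$group_shift_sd,
                              stringsAsFactors = FALSE)
  }

  co_idx <- match(samples$cohort, co_levels)
  mult <- matrix(1, FN, S)
  for (ci in seq_along(co_levels)) {
    cols <- which(co_idx == ci)
    onoff <- ifelse(on[, ci], 1, design$erna_off_factor)
    mult[, cols] <- (onoff * prog[, ci])
  }
  if (length(de_ernas)) {
    fi <- match(de_ernas, features)
    mult[fi, tum] <- mult[fi, tum] * design$de_fold_change
  }
  if (length(g_ernas)) {
    feat <- design$group_feature
    target_level <- truth_group$level[1]
    hit_cols <- which(!is.na(samples[[feat]]) & samples[[feat]] == target_level)
    fi <- match(g_ernas, features)
    mult[fi, hit_cols] <- mult[fi, hit_cols] *
      exp(design$group_shift_sd * design$latent_sd)
  }

  mu <- base * mult * exp(design$latent_sd * z - design$latent_sd^2 / 2)
  lib <- stats::rlnorm(S, log(design$mean_library_size) - design$library_sd_log^2 / 2,
                       design$library_sd_log)
  names(lib) <- samples$sample
  counts <- matrix(stats::rnbinom(FN * S,
                                  mu = sweep(mu, 2L, lib / 1e6, `*`),
                                  size = 1 / design$nb_dispersion),
                   FN, S, dimnames = list(features, samples$sample))
  list(counts = counts, library_sizes = lib, metadata = samples,
       rpm = rpm(counts, lib), latents = z,
       truth = list(master = truth_master, links = truth_links,
                    de = truth_de, group = truth_group, on = on))
}

#' Simulate per-tissue Hi-C observed/expected contacts
#'
#' Background O/E values are log-normal with median 1 and exist for every
#' same-chromosome (region-midpoint bin, gene-TSS bin) pair within
#' `hic_max_dist_bp`, mirroring the short-range coverage of real O/E
#' matrices; bins of planted links are multiplied by `hic_enrichment` in a
#' fraction `hic_enriched_tissue_frac` of tissues.
#'
#' @param design a [simulation_design()].
#' @param regions region data.frame (needs `id`, `chrom`, `midpoint`).
#' @param genes gene table (needs `id`, `chrom`, `tss`).
#' @param links planted link ledger `(erna_id, gene_id)` or `NULL`.
#' @param config a [pipeline_config()] (`hic_bin_bp`).
#' @param seed integer seed.
#' @return list with `hic` (tissue, chrom, bin_a, bin_b, oe) and `truth`
#'   (per planted pair, the tissues enriched).
#' @export
simulate_hic <- function(design, regions, genes, links = NULL,
                         config = pipeline_config(),
                         seed = design$seed + 404L) {
  set.seed(seed)
  bin <- as.integer(config$hic_bin_bp)
  tissues <- sprintf("tissue%02d", seq_len(design$n_hic_tissues))
  # same-chromosome bin-pair universe within the distance horizon
  pairs <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(r) || !nrow(g)) next
    grid <- expand.grid(ri = seq_len(nrow(r)), gi = seq_len(nrow(g)),
                        KEEP.OUT.ATTRS = FALSE)
    d <- abs(r$midpoint[grid$ri] - g$tss[grid$gi])
    grid <- grid[d <= design$hic_max_dist_bp, , drop = FALSE]
    if (!nrow(grid)) next
    pairs[[ch]] <- data.frame(
      chrom = ch,
      bin_a = pmin(r$midpoint[grid$ri] %/% bin, g$tss[grid$gi] %/% bin),
      bin_b = pmax(r$midpoint[grid$ri] %/% bin, g$tss[grid$gi] %/% bin),
      stringsAsFactors = FALSE)
  }
  univ <- unique(do.call(rbind, pairs))
  if (is.null(univ) || !nrow(univ)) {
    return(list(hic = data.frame(tissue = character(), chrom = character(),
                                 bin_a = integer(), bin_b = integer(),
                                 oe = double(), stringsAsFactors = FALSE),
                truth = NULL))
  }
  rownames(univ) <- NULL
  # keys of planted pairs
  planted_keys <- character()
  truth <- NULL
  if (!is.null(links) && nrow(links)) {
    rb <- regions$midpoint[match(links$erna_id, regions$id)] %/% bin
    gb <- genes$tss[match(links$gene_id, genes$id)] %/% bin
    rc <- regions$chrom[match(links$erna_id, regions$id)]
    planted_keys <- hic_key(rc, rb, gb)
    n_enr <- max(1L, round(design$hic_enriched_tissue_frac *
                             design$n_hic_tissues))
    enriched_tissues <- tissues[seq_len(n_enr)]
    truth <- data.frame(erna_id = links$erna_id, gene_id = links$gene_id,
                        key = planted_keys,
                        enrichment = design$hic_enrichment,
                        n_enriched_tissues = n_enr,
                        enriched_tissues = paste(enriched_tissues,
                                                 collapse = ","),
                        stringsAsFactors = FALSE)
  }
  univ_key <- hic_key(univ$chrom, univ$bin_a, univ$bin_b)
  out <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    oe <- stats::rlnorm(nrow(univ), 0, 0.5)
    if (length(planted_keys) && !is.null(truth) &&
        tissues[ti] %in% strsplit(truth$enriched_tissues[1], ",")[[1]]) {
      oe[univ_key %in% planted_keys] <- oe[univ_key %in% planted_keys] *
        design$hic_enrichment
    }
    out[[ti]] <- data.frame(tissue = tissues[ti], univ, oe = oe,
                            stringsAsFactors = FALSE)
  }
  list(hic = do.call(rbind, out), truth = truth)
}

#' Simulate drug response and clinical outcomes
#'
#' AUC vectors over cell lines get planted Spearman correlations with
#' designated eRNAs through the same copula device (negative rho means the
#' association should be labeled `sensitive`); survival times are
#' exponential with log-hazard `hazard_log_hr` per SD of each planted
#' eRNA's log expression, with independent exponential censoring (about
#' 30%); planted group shifts are applied at expression time (see
#' [simulate_expression()]).
#'
#' @param design a [simulation_design()].
#' @param cell_expr output of [simulate_expression()] for the cell-line
#'   cohort.
#' @param tumor_expr output of [simulate_expression()] for the cancer
#'   cohorts; its metadata gains `time` and `event` columns.
#' @param drug_ernas,hazard_ernas eRNA ids carrying planted drug/survival
#'   effects (chosen by the caller; alternating +/- rho for drugs).
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return list with `auc` (drug x cell line), `metadata` (tumor metadata
#'   with survival), and `truth` (`drug`, `hazard` ledgers).
#' @export
simulate_drug_and_clinical <- function(design, cell_expr, tumor_expr,
                                       drug_ernas = NULL, hazard_ernas = NULL,
                                       config = pipeline_config(),
                                       seed = design$seed + 505L) {
  set.seed(seed)
  lines <- colnames(cell_expr$counts)
  drugs <- sprintf("drug%03d", seq_len(design$n_drugs))
  auc <- matrix(stats::rnorm(design$n_drugs * length(lines)),
                design$n_drugs, length(lines),
                dimnames = list(drugs, lines))
  truth_drug <- NULL
  if (!is.null(drug_ernas) && length(drug_ernas)) {
    k <- length(drug_ernas)
    if (k > design$n_drugs) stop("more planted drug effects than drugs")
    sel_drugs <- sample(drugs, k)
    rho <- design$drug_rho * rep_len(c(-1, 1), k)
    z_e <- cell_expr$latents[drug_ernas, , drop = FALSE]
    auc[sel_drugs, ] <- rho * z_e +
      sqrt(1 - rho^2) * auc[sel_drugs, , drop = FALSE]
    truth_drug <- data.frame(erna_id = drug_ernas, drug_id = sel_drugs,
                             rho = rho,
                             expected_direction = ifelse(rho < 0, "sensitive",
                                                         "resistant"),
                             stringsAsFactors = FALSE)
  }
  auc <- 8 + 2 * auc  # shift/scale to an AUC-like range; ranks unchanged

  md <- tumor_expr$metadata
  tum <- md$condition == "tumor"
  lp <- rep(0, sum(tum))
  truth_hazard <- NULL
  if (!is.null(hazard_ernas) && length(hazard_ernas)) {
    ex <- log2(tumor_expr$rpm[hazard_ernas, tum, drop = FALSE] + 0.1)
    for (co in unique(md$cohort[tum])) {
      cols <- md$cohort[tum] == co
      exs <- ex[, cols, drop = FALSE]
      zs <- t(scale(t(exs)))
      zs[is.na(zs)] <- 0
      lp[cols] <- lp[cols] + colSums(design$hazard_log_hr * zs)
    }
    truth_hazard <- data.frame(erna_id = hazard_ernas,
                               log_hr_per_sd = design$hazard_log_hr,
                               stringsAsFactors = FALSE)
  }
  t_event <- stats::rexp(sum(tum), rate = exp(lp))
  t_cens <- stats::rexp(sum(tum), rate = design$censoring_rate)
  md$time <- NA_real_; md$event <- NA_integer_
  md$time[tum] <- pmin(t_event, t_cens)
  md$event[tum] <- as.integer(t_event <= t_cens)
  list(auc = auc, metadata = md,
       truth = list(drug = truth_drug, hazard = truth_hazard))
}

#' Generate the complete synthetic bundle
#'
#' Runs every simulator in sequence, chooses planted features from the
#' surviving eRNA-region universe (so each planted effect is testable by
#' the stage meant to detect it), and optionally writes all pipeline input
#' files plus the truth ledger to `outdir`.
#'
#' @param design a [simulation_design()].
#' @param config a [pipeline_config()] used for the region geometry the
#'   planting relies on.
#' @param outdir directory to write the file bundle to, or `NULL` to stay
#'   in memory.
#' @return list with all generated objects: `genome`, `enhancers`,
#'   `regions` (built regions), `expr`, `cell_expr`, `hic`, `auc`,
#'   `metadata`, `tf_ids`, `pathways`, `drug_pathways`, `truth`, and
#'   `files` (paths, when written).
#' @export
simulate_all <- function(design = simulation_design(),
                         config = pipeline_config(), outdir = NULL) {
  genome <- simulate_genome(design)
  enh <- simulate_enhancers(design, genome, config)
  built <- build_erna_regions(enh$sources, genome$genes, genome$lncrnas,
                              genome$blacklist, genome$chrom_lengths, config)
  regions <- built$regions
  if (!nrow(regions)) stop("no eRNA regions survived filtering; enlarge the design")
  gene_ids <- genome$genes$id
  tf_ids <- gene_ids[seq_len(min(design$n_tfs, length(gene_ids)))]

  set.seed(design$seed + 606L)
  # planted links drawn from the candidate-pair universe (non-TF targets,
  # distinct genes)
  link_pairs <- NULL
  if (design$n_planted_links > 0L) {
    cand <- candidate_pairs(regions, genome$genes, config$max_link_distance_bp)
    cand <- cand[!cand$gene_id %in% tf_ids, , drop = FALSE]
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    cand <- cand[!duplicated(cand$gene_id) & !duplicated(cand$erna_id), , drop = FALSE]
    if (nrow(cand) < design$n_planted_links) {
      stop("candidate-pair universe too small for the requested planted links")
    }
    link_pairs <- cand[seq_len(design$n_planted_links), c("erna_id", "gene_id")]
  }
  drug_ernas <- if (design$n_planted_drug > 0L) {
    sample(regions$id, min(design$n_planted_drug, nrow(regions)))
  } else NULL
  hazard_ernas <- if (design$n_planted_hazard > 0L) {
    sample(regions$id, min(design$n_planted_hazard, nrow(regions)))
  } else NULL

  expr <- simulate_expression(design, regions$id, gene_ids, tf_ids,
                              cohorts = design$cohorts,
                              link_pairs = link_pairs,
                              force_on = c(drug_ernas, hazard_ernas))
  cell_expr <- simulate_expression(
    design, regions$id, gene_ids, tf_ids,
    cohorts = data.frame(cohort = "cellline",
                         n_tumor = design$n_cell_lines,
                         n_paired_normal = 0L, stringsAsFactors = FALSE),
    link_pairs = NULL, force_on = drug_ernas,
    seed = design$seed + 707L)
  hic <- simulate_hic(design, regions, genome$genes, link_pairs, config)
  dc <- simulate_drug_and_clinical(design, cell_expr, expr,
                                   drug_ernas = drug_ernas,
                                   hazard_ernas = hazard_ernas,
                                   config = config)

  # pathway gene sets and drug targets
  set.seed(design$seed + 808L)
  pw_names <- c("p53", "PI3K", "Myc", "RTK_RAS", "cell_cycle", "Wnt",
                "TGF_beta", "Nrf2", "Notch", "Hippo")
  pathways <- do.call(rbind, lapply(pw_names, function(p) {
    data.frame(pathway = p,
               gene = sample(gene_ids, min(8L, length(gene_ids))),
               stringsAsFactors = FALSE)
  }))
  drug_pathways <- data.frame(drug = rownames(dc$auc),
                              pathway = sample(pw_names, nrow(dc$auc),
                                               replace = TRUE),
                              stringsAsFactors = FALSE)

  truth <- c(list(enhancers = enh$truth), expr$truth,
             list(hic = hic$truth), dc$truth)
  out <- list(genome = genome, enhancers = enh$sources, regions = regions,
              region_build = built, expr = expr, cell_expr = cell_expr,
              hic = hic$hic, auc = dc$auc, metadata = dc$metadata,
              tf_ids = tf_ids, pathways = pathways,
              drug_pathways = drug_pathways, truth = truth,
              design = design, config = config)
  if (!is.null(outdir)) out$files <- write_bundle(out, outdir)
  out
}

# Write every pipeline input file of a simulated bundle.
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  files <- list()
  for (i in seq_along(bundle$enhancers)) {
    files[[paste0("enhancers", i)]] <- p(sprintf("enhancers_source%d.bed", i))
    write_bed(bundle$enhancers[[i]], files[[paste0("enhancers", i)]])
  }
  files$genes <- write_gene_table(bundle$genome$genes, p("genes.tsv"))
  files$lncrnas <- write_gene_table(bundle$genome$lncrnas, p("lncrnas.tsv"))
  files$blacklist <- write_bed(bundle$genome$blacklist, p("blacklist.bed"))
  files$chrom_lengths <- p("chrom_lengths.tsv")
  write_tsv(data.frame(chrom = names(bundle$genome$chrom_lengths),
                       length = as.integer(bundle$genome$chrom_lengths)),
            files$chrom_lengths)
  files$counts <- write_matrix(bundle$expr$counts, p("counts.tsv"))
  files$library_sizes <- p("library_sizes.tsv")
  write_tsv(data.frame(sample = names(bundle$expr$library_sizes),
                       library_size = unname(bundle$expr$library_sizes)),
            files$library_sizes)
  files$metadata <- p("metadata.tsv")
  write_tsv(bundle$metadata, files$metadata)
  files$cell_counts <- write_matrix(bundle$cell_expr$counts, p("cell_counts.tsv"))
  files$cell_library_sizes <- p("cell_library_sizes.tsv")
  write_tsv(data.frame(sample = names(bundle$cell_expr$library_sizes),
                       library_size = unname(bundle$cell_expr$library_sizes)),
            files$cell_library_sizes)
  files$tf_list <- p("tf_list.tsv")
  write_tsv(data.frame(tf_id = bundle$tf_ids), files$tf_list)
  files$hic <- p("hic_oe.tsv"); write_tsv(bundle$hic, files$hic)
  files$auc <- write_matrix(bundle$auc, p("auc.tsv"), id_col = "drug")
  files$pathways <- p("pathways.tsv"); write_tsv(bundle$pathways, files$pathways)
  files$drug_pathways <- p("drug_pathways.tsv")
  write_tsv(bundle$drug_pathways, files$drug_pathways)
  for (nm in names(bundle$truth)) {
    obj <- bundle$truth[[nm]]
    if (is.null(obj)) next
    if (is.matrix(obj)) obj <- data.frame(feature = rownames(obj), obj,
                                          check.names = FALSE)
    files[[paste0("truth_", nm)]] <- p(sprintf("truth_%s.tsv", nm))
    write_tsv(obj, files[[paste0("truth_", nm)]])
  }
  files
}
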
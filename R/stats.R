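#' Spearman correlation with mid-rank ties and t-approximation p-value
#'
#' Ranks (average ranks for ties) each vector over the pairwise-complete
#' observations, takes the Pearson correlation of the ranks, and computes a
#' two-sided p-value from the large-sample t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; missing values are removed
#'   pairwise.
#' @param min_n minimum complete pairs; below it the test is skipped.
#' @return list `(Rs, p, n, skipped, reason)`.
#' @export
spearman_test <- function(x, y, min_n = 10L) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n) {
    return(list(Rs = NA_real_, p = NA_real_, n = n, skipped = TRUE,
                reason = sprintf("n=%d below minimum %d", n, min_n)))
  }
  xr <- rank(x[ok]); yr <- rank(y[ok])
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) {
    return(list(Rs = NA_real_, p = NA_real_, n = n, skipped = TRUE,
                reason = "constant vector"))
  }
  r <- stats::cor(xr, yr)
  p <- spearman_p(r, n)
  list(Rs = r, p = p, n = n, skipped = FALSE, reason = NA_character_)
}

# Two-sided p from the t approximation; |r| = 1 gives p = 0.
spearman_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  p[n < 3] <- NA_real_
  p
}

#' All-pairs Spearman correlation records between two expression matrices
#'
#' Computes Spearman Rs for every (row of `x_mat`) x (row of `y_mat`) pair
#' with pairwise-complete observations, the t-approximation p, and the
#' complete-pair count. Pairs with fewer than `min_n` complete pairs or a
#' constant vector are dropped (counted in the `n_skipped` attribute).
#'
#' @param x_mat,y_mat numeric matrices, features x samples, sharing columns.
#' @param min_n minimum complete pairs per correlation.
#' @return data.frame `(x_id, y_id, n, Rs, p)`.
#' @export
cor_records <- function(x_mat, y_mat, min_n = 10L) {
  stopifnot(ncol(x_mat) == ncol(y_mat))
  empty <- data.frame(x_id = character(), y_id = character(), n = integer(),
                      Rs = double(), p = double(), stringsAsFactors = FALSE)
  if (!nrow(x_mat) || !nrow(y_mat)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  xt <- t(x_mat); yt <- t(y_mat)
  rs <- suppressWarnings(stats::cor(xt, yt, method = "spearman",
                                    use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(xt), !is.na(yt))
  out <- data.frame(
    x_id = rep(rownames(x_mat), times = nrow(y_mat)),
    y_id = rep(rownames(y_mat), each = nrow(x_mat)),
    n = as.integer(n),
    Rs = as.vector(rs),
    stringsAsFactors = FALSE
  )
  keep <- out$n >= min_n & !is.na(out$Rs)
  n_skipped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out$p <- spearman_p(out$Rs, out$n)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")` after
#' validating the inputs). The adjustment scope is the caller's
#' responsibility; the pipeline applies it within one cohort (and, for
#' clinical tests, within one clinical feature).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Combine Spearman correlations across subgroups by Fisher's transformation
#'
#' Each group correlation is transformed with `atanh`, averaged with
#' weights `n - 3` (the inverse variance of the transform), and mapped back
#' with `tanh`. The combined two-sided p-value comes from
#' `Z = zbar * sqrt(sum(n - 3))` against the standard normal.
#'
#' @param rs numeric vector of per-group Spearman correlations, `|Rs| < 1`.
#' @param n integer vector of per-group sample sizes, each `>= 4`.
#' @return list `(Rs_prime, p_prime, z, groups)`.
#' @export
fisher_combine <- function(rs, n) {
  stopifnot(length(rs) == length(n), length(rs) >= 1L)
  if (any(n < 4)) stop("each group needs n >= 4 for Fisher combination")
  if (any(abs(rs) >= 1)) stop("|Rs| = 1 cannot be combined (infinite atanh)")
  w <- n - 3
  z <- atanh(rs)
  zbar <- sum(w * z) / sum(w)
  Z <- zbar * sqrt(sum(w))
  list(Rs_prime = tanh(zbar),
       p_prime = 2 * stats::pnorm(-abs(Z)),
       z = Z,
       groups = data.frame(Rs = rs, n = n))
}
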
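#' TMM normalization factors
#'
#' Standard trimmed-mean-of-M-values scaling factors. The reference sample
#' is the one whose upper quartile (of nonzero-scaled counts) is closest to
#' the mean upper quartile; for every other sample the factor is
#' `2^(weighted trimmed mean of M)` where M values are log2 ratios of
#' library-size-scaled counts against the reference, trimmed by 30% (M) and
#' 5% (A), with inverse-asymptotic-variance weights. Factors are rescaled to
#' geometric mean 1. Multiplying a library size by its factor gives the
#' effective library size used for offsets downstream.
#'
#' @param counts integer matrix, features x samples.
#' @param lib_sizes library sizes; default column sums.
#' @return numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2, all(lib_sizes > 0))
  if (sum(rowSums(counts) > 0) < 2) {
    warning("fewer than two nonzero features; returning unit factors")
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  }
  uq <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib_sizes[j], 0.75), numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# two-sample TMM: weighted trimmed mean of M-values of obs vs ref
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m)) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Common negative-binomial dispersion
#'
#' Pearson-based pseudo-likelihood estimate of a single dispersion shared
#' across features: with group means fitted by maximum likelihood at a given
#' dispersion, the dispersion solves `X^2(phi) = residual df`, where
#' `X^2(phi)` is the total Pearson statistic under Var(y) = mu + phi mu^2.
#' Tagwise shrinkage is deliberately not applied.
#'
#' @param counts integer matrix, features x samples.
#' @param group factor/vector of length `ncol(counts)` with two levels.
#' @param offsets matrix (or vector, recycled by row) of log effective
#'   library sizes; default `log(colSums(counts))`.
#' @param max_features cap on the number of features used (rows subsampled
#'   deterministically for speed); default 1000.
#' @return estimated common dispersion `phi >= 0`.
#' @export
estimate_dispersion <- function(counts, group, offsets = NULL,
                                max_features = 1000) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two conditions are required")
  if (min(table(group)) < 2)
    stop("need >= 2 samples per condition to estimate dispersion")
  if (is.null(offsets)) offsets <- log(colSums(counts))
  if (is.vector(offsets))
    offsets <- matrix(offsets, nrow(counts), ncol(counts), byrow = TRUE)
  use <- which(rowSums(counts) > 0)
  if (length(use) > max_features)
    use <- use[round(seq(1, length(use), length.out = max_features))]
  y <- counts[use, , drop = FALSE]
  o <- offsets[use, , drop = FALSE]
  df <- length(use) * (ncol(y) - 2L)
  pearson <- function(phi) {
    x2 <- 0
    for (g in levels(group)) {
      j <- group == g
      mu <- nb_group_means(y[, j, drop = FALSE], o[, j, drop = FALSE], phi)
      x2 <- x2 + sum((y[, j] - mu)^2 / (mu * (1 + phi * mu)), na.rm = TRUE)
    }
    x2
  }
  if (pearson(0) <= df) return(0)
  upper <- 5
  while (pearson(upper) > df && upper < 500) upper <- upper * 4
  stats::uniroot(function(phi) pearson(phi) - df, c(0, upper),
                 tol = 1e-6)$root
}

# Per-feature NB mean fits within one group: mu_ij = exp(beta_i + o_ij),
# beta_i solving sum_j (y - mu)/(1 + phi mu) = 0 (Newton, vectorized over
# features). Returns the matrix of fitted means. phi = 0 is Poisson
# (closed form).
nb_group_means <- function(y, o, phi) {
  s <- exp(o)
  tot <- rowSums(y)
  rate <- (tot + 0.25) / rowSums(s)        # continuity-corrected start
  beta <- log(rate)
  for (it in 1:50) {
    mu <- exp(beta) * s
    score <- rowSums((y - mu) / (1 + phi * mu))
    info <- rowSums(mu * (1 + phi * y) / (1 + phi * mu)^2)
    info <- pmax(info, 1e-10)
    step <- pmin(pmax(score / info, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  exp(beta) * s
}

# One-group NB fit returning the log2 rate and its variance (observed-
# information Wald). Rows with zero group total get a continuity-corrected
# estimate.
nb_group_fit <- function(y, o, phi) {
  s <- exp(o)
  tot <- rowSums(y)
  beta <- log((tot + 0.25) / rowSums(s))
  free <- tot > 0               # all-zero groups keep the corrected start
  for (it in 1:100) {
    mu <- exp(beta) * s
    score <- rowSums((y - mu) / (1 + phi * mu))
    info <- rowSums(mu * (1 + phi * y) / (1 + phi * mu)^2)
    info <- pmax(info, 1e-10)
    step <- pmin(pmax(score / info, -5), 5)
    step[!free] <- 0
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(beta) * s
  fisher <- rowSums(mu / (1 + phi * mu))     # expected information
  list(log2_rate = beta / log(2), var_log2 = 1 / fisher / log(2)^2)
}

#' Differential promoter usage test
#'
#' For each promoter a negative-binomial GLM with log link and offsets
#' `log(library size x TMM factor)` yields the condition log2 fold change
#' and its Wald variance. Within each gene the promoter log fold changes are
#' contrasted against the gene's inverse-variance-weighted average: the
#' relative log fold change `rel_logfc = logfc - gene average` isolates
#' usage change from gene-level expression change. Its squared standardized
#' value is referred to an F(1, df) distribution with the residual degrees
#' of freedom pooled over all tested promoters. Genes with a single
#' expressed promoter are reported with `p = NA` and excluded from the
#' multiple-testing correction.
#'
#' @param counts integer matrix, promoters x samples (rownames = promoter
#'   ids).
#' @param gene_map character vector mapping each row to a gene id.
#' @param group two-level factor of sample conditions; the log fold change
#'   is level2 - level1.
#' @param phi common NB dispersion; estimated with [estimate_dispersion()]
#'   when `NULL`.
#' @param norm_factors TMM factors; computed with [tmm_factors()] when
#'   `NULL`.
#' @param alpha,fc_min AP thresholds passed to [call_aps()].
#' @return a `data.frame` of class `UsageResult` with one row per expressed
#'   promoter: `promoter_id`, `gene_id`, `logfc_condition`, `rel_logfc`,
#'   `stat`, `p`, `fdr`, `is_ap`, `direction`.
#' @export
diff_usage_test <- function(counts, gene_map, group, phi = NULL,
                            norm_factors = NULL, alpha = 0.05, fc_min = 2) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_map) == nrow(counts))
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two conditions are required")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%05d", seq_len(nrow(counts)))

  expressed <- rowSums(counts) > 0
  if (any(!expressed))
    message(sum(!expressed), " promoters with all-zero counts excluded")
  y <- counts[expressed, , drop = FALSE]
  genes <- gene_map[expressed]

  lib <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts, lib)
  off <- matrix(log(lib * norm_factors), nrow(y), ncol(y), byrow = TRUE)
  if (is.null(phi)) phi <- estimate_dispersion(y, group, off)

  j1 <- group == levels(group)[1]
  j2 <- group == levels(group)[2]
  f1 <- nb_group_fit(y[, j1, drop = FALSE], off[, j1, drop = FALSE], phi)
  f2 <- nb_group_fit(y[, j2, drop = FALSE], off[, j2, drop = FALSE], phi)
  logfc <- f2$log2_rate - f1$log2_rate
  v <- f1$var_log2 + f2$var_log2

  w <- 1 / v
  sw <- stats::ave(w, genes, FUN = sum)
  swc <- stats::ave(w * logfc, genes, FUN = sum)
  gene_avg <- swc / sw
  n_prom <- stats::ave(rep(1, length(genes)), genes, FUN = sum)

  rel <- logfc - gene_avg
  var_rel <- pmax(v - 1 / sw, 1e-12)
  stat <- rel^2 / var_rel
  df_resid <- sum(n_prom > 1) * (ncol(y) - 2L)
  p <- stats::pf(stat, 1, df_resid, lower.tail = FALSE)
  p[n_prom == 1] <- NA_real_
  stat[n_prom == 1] <- NA_real_

  res <- data.frame(promoter_id = rownames(y), gene_id = genes,
                    logfc_condition = logfc, var_logfc = v,
                    rel_logfc = rel, stat = stat, p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res <- call_aps(res, alpha = alpha, fc_min = fc_min,
                  levels = levels(group))
  attr(res, "phi") <- phi
  attr(res, "norm_factors") <- norm_factors
  class(res) <- c("UsageResult", class(res))
  res
}

#' Benjamini-Hochberg step-up FDR
#'
#' `NA` p-values are ignored (they do not count toward the number of
#' tests) and propagate as `NA` q-values.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  q <- rep(NA_real_, length(pvals))
  if (any(ok)) {
    p <- pvals[ok]
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  }
  q
}

#' Call alternative promoters from usage results
#'
#' A promoter is an AP iff `fdr < alpha` (strict) and the usage fold change
#' exceeds `fc_min`, i.e. `|rel_logfc| > log2(fc_min)`. `use_promoter_fc =
#' TRUE` thresholds the promoter-level `logfc_condition` instead. The
#' direction labels name the condition where the promoter is relatively more
#' active.
#'
#' @param results a `UsageResult` data.frame.
#' @param alpha FDR threshold (strict `<`).
#' @param fc_min fold-change threshold (strict `>`, on the linear scale).
#' @param use_promoter_fc threshold on the promoter-level rather than the
#'   usage-level fold change.
#' @param levels the two condition names, in design order.
#' @return `results` with `is_ap` and `direction` columns (re)computed.
#' @export
call_aps <- function(results, alpha = 0.05, fc_min = 2,
                     use_promoter_fc = FALSE,
                     levels = c("condA", "condB")) {
  lfc <- if (use_promoter_fc) results$logfc_condition else results$rel_logfc
  results$is_ap <- !is.na(results$fdr) & results$fdr < alpha &
    abs(lfc) > log2(fc_min)
  results$direction <- ifelse(lfc > 0, paste0("up_", levels[2]),
                              paste0("up_", levels[1]))
  results
}
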
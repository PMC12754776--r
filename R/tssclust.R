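#' Tags-per-million normalization of a CTSS matrix
#'
#' TPM for sample j is `count / library_size(j) * 1e6`, where the library
#' size is the sample's total CTSS count (computed before any filtering).
#' The pooled signal is the across-sample sum of TPM values, the per-base
#' track the clustering step operates on.
#'
#' @param ctss a `CtssMatrix` from [read_ctss()].
#' @return list with `tpm` (real matrix, same shape as counts) and
#'   `pooled_tpm` (vector, one value per CTSS position).
#' @export
tpm_normalize <- function(ctss) {
  lib <- colSums(ctss$counts)
  zero <- which(lib == 0)
  if (length(zero))
    stop("sample with zero library size: ", ctss$sample_ids[zero[1]])
  tpm <- sweep(ctss$counts, 2, lib, "/") * 1e6
  list(tpm = tpm, pooled_tpm = rowSums(tpm))
}

#' Call strand-aware tag clusters from CTSS positions
#'
#' Pools TPM-normalized signal across samples, then single-linkage clusters
#' CTSS positions with pooled signal > 0 on each chromosome and strand:
#' adjacent member positions p < q join one cluster iff `q - p <= merge_dist`.
#' Each cluster spans its min..max member position; counts and TPM are
#' requantified as sums over member positions, and the cluster peak is the
#' member with maximal pooled TPM (ties broken toward the cluster's 5' end).
#'
#' @param ctss a `CtssMatrix`.
#' @param merge_dist maximum gap (bp) between adjacent member positions
#'   (default 20).
#' @return a `data.frame` with one row per cluster: `id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `peak_position`, plus count and
#'   TPM matrices in the attributes `counts` and `tpm` (rows aligned to
#'   cluster rows, columns to samples).
#' @export
call_tag_clusters <- function(ctss, merge_dist = 20) {
  stopifnot(merge_dist >= 0)
  norm <- tpm_normalize(ctss)
  pos <- ctss$positions
  keep <- norm$pooled_tpm > 0
  pos <- pos[keep]
  counts <- ctss$counts[keep, , drop = FALSE]
  tpm <- norm$tpm[keep, , drop = FALSE]
  pooled <- norm$pooled_tpm[keep]

  chrom <- as.character(GenomicRanges::seqnames(pos))
  strand <- as.character(GenomicRanges::strand(pos))
  p <- GenomicRanges::start(pos)
  ord <- order(chrom, strand, p)

  group_key <- paste(chrom, strand)[ord]
  po <- p[ord]
  new_cluster <- c(TRUE, group_key[-1] != group_key[-length(group_key)] |
                     diff(po) > merge_dist)
  cl <- cumsum(new_cluster)

  idx_by_cl <- split(ord, cl)
  rows <- lapply(idx_by_cl, function(ix) {
    pp <- p[ix]
    str <- strand[ix[1]]
    pooled_ix <- pooled[ix]
    best <- pooled_ix == max(pooled_ix)
    peak <- if (str == "-") max(pp[best]) else min(pp[best])
    data.frame(chrom = chrom[ix[1]], start = min(pp), end = max(pp),
               strand = str, peak_position = peak, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cl_counts <- do.call(rbind, lapply(idx_by_cl, function(ix)
    colSums(counts[ix, , drop = FALSE])))
  cl_tpm <- do.call(rbind, lapply(idx_by_cl, function(ix)
    colSums(tpm[ix, , drop = FALSE])))
  ord2 <- order(tab$chrom, tab$start, tab$strand)
  tab <- tab[ord2, , drop = FALSE]
  cl_counts <- cl_counts[ord2, , drop = FALSE]
  cl_tpm <- cl_tpm[ord2, , drop = FALSE]
  tab$id <- sprintf("TC_%05d", seq_len(nrow(tab)))
  rownames(tab) <- rownames(cl_counts) <- rownames(cl_tpm) <- tab$id
  colnames(cl_counts) <- colnames(cl_tpm) <- ctss$sample_ids
  tab <- tab[, c("id", "chrom", "start", "end", "strand", "peak_position")]
  attr(tab, "counts") <- cl_counts
  attr(tab, "tpm") <- cl_tpm
  tab
}

#' Filter tag clusters by cross-sample support
#'
#' Keeps a cluster iff its TPM is strictly above `min_tpm` in at least
#' `min_samples` samples (the default 1 TPM in >= 6 samples corresponds to
#' half of a 12-sample two-cell-line design).
#'
#' @param tcs cluster table from [call_tag_clusters()] (carries a `tpm`
#'   attribute).
#' @param min_tpm TPM threshold (strict `>`).
#' @param min_samples minimum number of supporting samples.
#' @return the filtered cluster table, attributes subset in step.
#' @export
support_filter <- function(tcs, min_tpm = 1, min_samples = 6) {
  tpm <- attr(tcs, "tpm")
  stopifnot(!is.null(tpm), min_samples <= ncol(tpm))
  keep <- rowSums(tpm > min_tpm) >= min_samples
  subset_tcs(tcs, keep)
}

# subset a TC table together with its aligned count/TPM attributes
subset_tcs <- function(tcs, keep) {
  out <- tcs[keep, , drop = FALSE]
  for (a in c("counts", "tpm")) {
    m <- attr(tcs, a)
    if (!is.null(m)) attr(out, a) <- m[keep, , drop = FALSE]
  }
  out
}
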
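#' Promoter activity counts from splice junctions
#'
#' Groups a gene's multi-exon transcripts into promoters by their exact TSS
#' position; the promoter's count in a sample is the sum of uniquely mapping
#' reads over the distinct first introns of its transcripts. Single-exon
#' transcripts contribute no promoter. A promoter is flagged internal — and
#' excluded — when its first exon lies entirely within an internal
#' (non-first) exon of another transcript of the same gene. Junctions with
#' undefined strand (code 0) are used only when they match a unique
#' annotated first intron; junctions matching no annotated first intron are
#' counted and reported, not assigned.
#'
#' @param sj_files named character vector of junction file paths, one per
#'   sample (see [read_sj()]).
#' @param models gene models from [parse_gene_models()].
#' @return list with `counts` (promoters x samples integer matrix),
#'   `promoters` (data.frame `promoter_id`, `gene_id`, `tss`, `chrom`,
#'   `strand`, `internal`), and `unmatched` (per-sample count of junction
#'   reads matching no annotated first intron).
#' @export
junctions_to_promoter_counts <- function(sj_files, models) {
  if (is.null(names(sj_files)))
    names(sj_files) <- sub("\\.[^.]*$", "", basename(sj_files))
  tx <- models$transcripts
  ex <- models$exons
  multi <- tx[tx$n_exons >= 2, , drop = FALSE]

  # first intron per multi-exon transcript: between exon_rank 1 and 2
  e1 <- ex[ex$exon_rank == 1 & ex$transcript_id %in% multi$transcript_id, ]
  e2 <- ex[ex$exon_rank == 2 & ex$transcript_id %in% multi$transcript_id, ]
  e1 <- e1[match(multi$transcript_id, e1$transcript_id), ]
  e2 <- e2[match(multi$transcript_id, e2$transcript_id), ]
  intron_start <- ifelse(multi$strand == "-", e2$end + 1L, e1$end + 1L)
  intron_end <- ifelse(multi$strand == "-", e1$start - 1L, e2$start - 1L)

  prom_key <- paste(multi$gene_id, multi$chrom, multi$strand, multi$tss)
  prom_ids <- unique(prom_key)
  prom <- data.frame(
    promoter_id = NA_character_,
    gene_id = multi$gene_id[match(prom_ids, prom_key)],
    chrom = multi$chrom[match(prom_ids, prom_key)],
    strand = multi$strand[match(prom_ids, prom_key)],
    tss = multi$tss[match(prom_ids, prom_key)],
    stringsAsFactors = FALSE)
  ord <- order(prom$gene_id, prom$tss)
  prom <- prom[ord, ]; prom_ids <- prom_ids[ord]
  idx <- stats::ave(seq_len(nrow(prom)), prom$gene_id, FUN = seq_along)
  prom$promoter_id <- paste0(prom$gene_id, ".P", idx)

  # internal-promoter flag: first exon within an internal exon of another
  # transcript of the same gene
  internal_ex <- ex[ex$exon_rank > 1, ]
  prom$internal <- vapply(seq_len(nrow(prom)), function(i) {
    tx_i <- multi$transcript_id[prom_key == prom_ids[i]]
    fe <- e1[match(tx_i[1], e1$transcript_id), ]
    cand <- internal_ex[internal_ex$gene_id == prom$gene_id[i] &
                          !internal_ex$transcript_id %in% tx_i, ]
    any(cand$start <= fe$start & cand$end >= fe$end)
  }, TRUE)

  # internal promoters are excluded before junction matching, so their
  # reads are reported as unmatched rather than silently dropped
  live_tx <- !prom$internal[match(prom_key, prom_ids)]

  # map each (distinct) first intron of a live promoter to its promoter row
  jkey <- paste(multi$chrom, intron_start, intron_end, multi$strand)[live_tx]
  j2p <- tapply(match(prom_key, prom_ids)[live_tx], jkey, unique)
  ambiguous <- vapply(j2p, length, 1L) > 1  # same intron, two promoters
  jkey_nostrand <- sub(" [+-]$", "", names(j2p))

  counts <- matrix(0L, nrow(prom), length(sj_files),
                   dimnames = list(prom$promoter_id, names(sj_files)))
  unmatched <- setNames(integer(length(sj_files)), names(sj_files))
  for (s in seq_along(sj_files)) {
    sj <- read_sj(sj_files[s])
    key <- paste(sj$chrom, sj$intron_start, sj$intron_end, sj$strand)
    hit <- match(key, names(j2p))
    und <- sj$strand == "*"
    if (any(und)) {  # undefined strand: accept only a unique stranded match
      k0 <- paste(sj$chrom, sj$intron_start, sj$intron_end)[und]
      mm <- lapply(k0, function(k) which(jkey_nostrand == k))
      hit[und] <- ifelse(vapply(mm, length, 1L) == 1,
                         vapply(mm, function(x) x[1], 1L), NA_integer_)
    }
    ok <- !is.na(hit) & !ambiguous[ifelse(is.na(hit), 1L, hit)]
    unmatched[s] <- sum(sj$unique_reads[!ok])
    for (j in which(ok)) {
      ps <- j2p[[hit[j]]]
      counts[ps, s] <- counts[ps, s] + sj$unique_reads[j]
    }
  }
  keep <- !prom$internal
  list(counts = counts[keep, , drop = FALSE],
       promoters = prom[keep, , drop = FALSE],
       unmatched = unmatched)
}

#' Counts-per-million expression filter
#'
#' Keeps rows with CPM strictly above `min_cpm` in at least `min_samples`
#' samples; library sizes are recalculated from the retained rows.
#'
#' @param counts integer matrix, promoters x samples.
#' @param min_cpm CPM threshold (strict `>`, default 1).
#' @param min_samples minimum number of passing samples (default 1).
#' @return the filtered matrix, with recomputed library sizes in the
#'   attribute `lib_sizes`.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 1) {
  lib <- colSums(counts)
  stopifnot(all(lib > 0))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "lib_sizes") <- colSums(out)
  out
}

#' Differential promoter usage under G4-ligand treatment
#'
#' Thin wrapper over [diff_usage_test()] for the ligand-treatment design:
#' promoter counts come from splice junctions, the common dispersion is used
#' without tagwise shrinkage, and two calling modes are offered — `strict`
#' (FDR < 0.05, |fold change| > 2) and `relaxed` (unadjusted p < 0.05,
#' |fold change| > 1), the latter mirroring low-power reanalyses where few
#' promoters survive FDR correction.
#'
#' @param counts promoters x samples matrix (after [cpm_filter()]).
#' @param gene_map gene id per row.
#' @param group two-level condition factor (control first).
#' @param mode `"strict"` or `"relaxed"`.
#' @return a `UsageResult` data.frame (see [diff_usage_test()]).
#' @export
ligand_diff_usage <- function(counts, gene_map, group,
                              mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  res <- diff_usage_test(counts, gene_map, group)
  if (mode == "relaxed") {
    lev <- levels(as.factor(group))
    res$is_ap <- !is.na(res$p) & res$p < 0.05 & abs(res$rel_logfc) > 0
    res$direction <- ifelse(res$rel_logfc > 0, paste0("up_", lev[2]),
                            paste0("up_", lev[1]))
  }
  res
}

#' Distance from promoters to the nearest predicted G4
#'
#' The distance is 0 when the promoter interval overlaps a G4 hit and
#' otherwise the gap in bases to the nearest hit edge on the same
#' chromosome, ignoring strand. A random baseline of `n_random` promoters
#' (default: the AP set size) is drawn, seeded, from the expressed non-AP
#' promoters, and a one-tailed rank-sum test asks whether AP distances are
#' smaller.
#'
#' @param ap_promoters `GRanges` of AP promoter intervals.
#' @param g4 `GRanges` of predicted G4 hits (e.g. [g4_scan_fasta()] output).
#' @param background_promoters `GRanges` of expressed non-AP promoters.
#' @param n_random size of the random baseline; default `length(ap_promoters)`.
#' @param seed RNG seed for the baseline draw.
#' @return list with `distances_ap`, `distances_random`, and `p` (one-tailed
#'   Wilcoxon rank-sum). Promoters on chromosomes with no G4 hit are
#'   excluded with a warning.
#' @export
nearest_g4_distance <- function(ap_promoters, g4, background_promoters,
                                n_random = length(ap_promoters), seed = 1) {
  dist_to_g4 <- function(pr) {
    d <- rep(Inf, length(pr))
    hits <- GenomicRanges::distanceToNearest(pr, g4, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    if (any(is.infinite(d)))
      warning(sum(is.infinite(d)), " promoters on chromosomes without G4 ",
              "hits excluded")
    d[is.finite(d)]
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  take <- sample(length(background_promoters),
                 min(n_random, length(background_promoters)))
  d_ap <- dist_to_g4(ap_promoters)
  d_rand <- dist_to_g4(background_promoters[take])
  list(distances_ap = d_ap, distances_random = d_rand,
       p = stats::wilcox.test(d_ap, d_rand, alternative = "less")$p.value)
}
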
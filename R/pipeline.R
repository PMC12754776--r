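#' Run the full promoter-usage pipeline
#'
#' Chains the stages on file inputs: CTSS ingestion, tag-cluster calling,
#' support filter, TSS-overlap filter (with optional enhancer exclusion),
#' gene assignment, composition filter, TMM-normalized differential usage
#' testing, and — when peak files are supplied — G4 association and
#' enrichment. Every filtering stage is logged in a manifest that itemizes
#' records in, records out and records dropped, so no record is silently
#' lost.
#'
#' @param ctss_paths named character vector of CTSS files (names = sample
#'   ids).
#' @param sample_conditions condition per sample (two levels; the log fold
#'   change is level2 vs level1).
#' @param gtf_path gene models GTF.
#' @param peak_paths optional named character vector (one BED per
#'   condition) of G4 ChIP-seq peaks.
#' @param exclusion_bed optional BED of intervals to exclude (e.g. predicted
#'   enhancers).
#' @param merge_dist,min_tpm,min_samples,min_fraction,upstream_ext,alpha,fc_min,upstream
#'   stage parameters; defaults are the pipeline's canonical thresholds
#'   (20 bp merge, >1 TPM in >= 6 samples, >10% composition, 100 bp
#'   upstream association window, FDR < 0.05, fold change > 2).
#' @return list with `results` (UsageResult joined with cluster
#'   coordinates), `clusters`, `association`, `enrichment` (when peaks are
#'   given), and `manifest`.
#' @export
run_pipeline <- function(ctss_paths, sample_conditions, gtf_path,
                         peak_paths = NULL, exclusion_bed = NULL,
                         merge_dist = 20, min_tpm = 1, min_samples = 6,
                         min_fraction = 0.10, upstream_ext = 1000,
                         alpha = 0.05, fc_min = 2, upstream = 100) {
  manifest <- list(parameters = list(
    merge_dist = merge_dist, min_tpm = min_tpm, min_samples = min_samples,
    min_fraction = min_fraction, upstream_ext = upstream_ext,
    alpha = alpha, fc_min = fc_min, upstream = upstream))
  stage <- function(name, n_in, n_out, reason) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out,
                                     n_dropped = n_in - n_out,
                                     reason = reason)
  }
  ctss <- read_ctss(ctss_paths, names(ctss_paths))
  tcs <- call_tag_clusters(ctss, merge_dist = merge_dist)
  stage("tag_clusters", nrow(tcs), nrow(tcs), "none")

  n0 <- nrow(tcs)
  tcs <- support_filter(tcs, min_tpm = min_tpm, min_samples = min_samples)
  stage("support_filter", n0, nrow(tcs),
        sprintf("TPM <= %g in more than %d samples", min_tpm,
                ncol(attr(tcs, "tpm")) - min_samples))

  models <- parse_gene_models(gtf_path)
  excl <- if (!is.null(exclusion_bed)) read_bed(exclusion_bed)
  n0 <- nrow(tcs)
  tcs <- tss_overlap_filter(tcs, models, exclusion = excl)
  stage("tss_overlap_filter", n0, nrow(tcs),
        "no same-strand annotated TSS overlap, or exclusion overlap")

  n0 <- nrow(tcs)
  tcs <- assign_genes(tcs, models, upstream_ext = upstream_ext)
  stage("assign_genes", n0, nrow(tcs),
        "no gene, non-protein-coding, missing symbol, or off chr1-22/X")

  n0 <- nrow(tcs)
  tcs <- composition_filter(tcs, min_fraction = min_fraction,
                            min_samples = min_samples)
  stage("composition_filter", n0, nrow(tcs),
        sprintf("usage fraction <= %g in more than enough samples",
                min_fraction))

  group <- factor(sample_conditions)
  res <- diff_usage_test(attr(tcs, "counts"), tcs$gene_id, group,
                         alpha = alpha, fc_min = fc_min)
  stage("diff_usage", nrow(tcs), nrow(res),
        "all-zero counts across samples")
  res <- merge(res, tcs[, c("id", "chrom", "start", "end", "strand",
                            "peak_position")],
               by.x = "promoter_id", by.y = "id", sort = FALSE)
  res$position <- res$peak_position

  out <- list(results = res, clusters = tcs, manifest = manifest)
  if (!is.null(peak_paths)) {
    stopifnot(length(peak_paths) == 2, !is.null(names(peak_paths)))
    peaks <- lapply(peak_paths, read_bed)
    gr <- GenomicRanges::GRanges(tcs$chrom,
                                 IRanges::IRanges(tcs$start, tcs$end),
                                 strand = tcs$strand, id = tcs$id)
    assoc <- associate_g4(gr, peaks, upstream = upstream)
    assoc <- merge(assoc, res[, c("promoter_id", "is_ap", "direction")],
                   by = "promoter_id", sort = FALSE)
    enr <- category_enrichment(assoc$category[assoc$is_ap %in% TRUE],
                               assoc$category)
    out$association <- assoc
    out$enrichment <- enr
  }
  out$manifest <- manifest
  out
}
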
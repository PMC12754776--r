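#' Parse gene models from a GTF file
#'
#' Reads a GENCODE-dialect GTF (gene/transcript/exon features with
#' `gene_id`, `transcript_id` and `gene_type` attributes) and derives, per
#' transcript, the TSS (the 5'-most exon base on the transcript strand) and
#' the ordered exon structure needed by the splice-junction branch. Version
#' suffixes are stripped from Ensembl gene and transcript identifiers.
#'
#' @param gtf_path path to a GTF file.
#' @return a list with
#'   `genes`: data.frame (`gene_id`, `symbol`, `biotype`, `chrom`, `start`,
#'   `end`, `strand`; 1-based inclusive span);
#'   `transcripts`: data.frame (`transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tss`, `n_exons`);
#'   `exons`: data.frame of exon coordinates per transcript, ordered 5' to 3'.
#' @export
parse_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gtf <- rtracklayer::import(gtf_path, format = "gtf")
  need <- c("type", "gene_id")
  miss <- setdiff(need, names(S4Vectors::mcols(gtf)))
  if (length(miss)) stop("GTF lacks required attributes: ",
                         paste(miss, collapse = ", "))
  strip <- function(x) sub("\\.\\d+$", "", x)
  exons <- gtf[gtf$type == "exon"]
  if (!length(exons)) stop("GTF contains no exon features")
  if (is.null(exons$transcript_id) || anyNA(exons$transcript_id))
    stop("exon feature without transcript_id attribute")
  tx_id <- strip(exons$transcript_id)
  gene_id <- strip(exons$gene_id)

  ex <- data.frame(transcript_id = tx_id, gene_id = gene_id,
                   chrom = as.character(GenomicRanges::seqnames(exons)),
                   start = GenomicRanges::start(exons),
                   end = GenomicRanges::end(exons),
                   strand = as.character(GenomicRanges::strand(exons)),
                   stringsAsFactors = FALSE)
  # order exons 5'->3' within transcript
  ex <- ex[order(ex$transcript_id, ifelse(ex$strand == "-", -ex$start, ex$start)), ]
  ex$exon_rank <- stats::ave(seq_len(nrow(ex)), ex$transcript_id,
                             FUN = seq_along)

  first <- ex[ex$exon_rank == 1, ]
  transcripts <- data.frame(
    transcript_id = first$transcript_id,
    gene_id = first$gene_id,
    chrom = first$chrom,
    strand = first$strand,
    tss = ifelse(first$strand == "-", first$end, first$start),
    n_exons = as.integer(table(ex$transcript_id)[first$transcript_id]),
    stringsAsFactors = FALSE)

  gfeat <- gtf[gtf$type == "gene"]
  if (length(gfeat)) {
    genes <- data.frame(
      gene_id = strip(gfeat$gene_id),
      symbol = if (!is.null(gfeat$gene_name)) gfeat$gene_name else NA_character_,
      biotype = if (!is.null(gfeat$gene_type)) gfeat$gene_type else NA_character_,
      chrom = as.character(GenomicRanges::seqnames(gfeat)),
      start = GenomicRanges::start(gfeat),
      end = GenomicRanges::end(gfeat),
      strand = as.character(GenomicRanges::strand(gfeat)),
      stringsAsFactors = FALSE)
  } else {
    # derive gene spans from transcripts when gene features are absent
    sp <- split(ex, ex$gene_id)
    genes <- do.call(rbind, lapply(sp, function(e) data.frame(
      gene_id = e$gene_id[1], symbol = NA_character_,
      biotype = NA_character_, chrom = e$chrom[1],
      start = min(e$start), end = max(e$end), strand = e$strand[1],
      stringsAsFactors = FALSE)))
    rownames(genes) <- NULL
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in GTF")
  list(genes = genes, transcripts = transcripts,
       exons = ex[, c("transcript_id", "gene_id", "chrom", "start", "end",
                      "strand", "exon_rank")])
}

#' Keep tag clusters overlapping annotated TSSs
#'
#' Drops any cluster overlapping an exclusion interval (strand-blind;
#' typically predicted enhancers supplied as a BED file), then keeps a
#' cluster iff it shares at least one base with an annotated TSS position on
#' the same strand — de novo promoters are deliberately out of scope.
#'
#' @param tcs cluster table from [call_tag_clusters()].
#' @param models gene models from [parse_gene_models()].
#' @param exclusion optional `GRanges` of intervals to remove (any overlap).
#' @return the filtered cluster table.
#' @export
tss_overlap_filter <- function(tcs, models, exclusion = NULL) {
  gr <- GenomicRanges::GRanges(tcs$chrom, IRanges::IRanges(tcs$start, tcs$end),
                               strand = tcs$strand)
  keep <- rep(TRUE, nrow(tcs))
  if (!is.null(exclusion) && length(exclusion)) {
    keep <- keep & !IRanges::overlapsAny(gr, exclusion, ignore.strand = TRUE)
  }
  tss <- GenomicRanges::GRanges(models$transcripts$chrom,
                                IRanges::IRanges(models$transcripts$tss, width = 1L),
                                strand = models$transcripts$strand)
  keep <- keep & IRanges::overlapsAny(gr, tss, ignore.strand = FALSE)
  subset_tcs(tcs, keep)
}

#' Assign tag clusters to genes
#'
#' A cluster is assigned to the same-strand gene whose span, extended
#' `upstream_ext` bp upstream of its 5' end, overlaps the cluster. Ties are
#' broken by (1) the gene owning a TSS the cluster overlaps, (2) the largest
#' overlap, (3) lexicographic gene id. Clusters without an assignment, on
#' non-protein-coding genes, on genes without a symbol, or outside
#' chromosomes 1-22 and X are dropped.
#'
#' @inheritParams tss_overlap_filter
#' @param upstream_ext bp by which each gene span is extended upstream for
#'   the purpose of assignment (default 1000).
#' @param chromosomes chromosomes retained (default chr1-chr22 and chrX).
#' @return cluster table with `gene_id` and `symbol` columns added.
#' @export
assign_genes <- function(tcs, models, upstream_ext = 1000,
                         chromosomes = paste0("chr", c(1:22, "X"))) {
  if (!nrow(tcs)) {
    tcs$gene_id <- character(); tcs$symbol <- character(); return(tcs)
  }
  genes <- models$genes
  gspan <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start, genes$end),
                                  strand = genes$strand)
  gspan <- GenomicRanges::promoters(GenomicRanges::resize(
    gspan, GenomicRanges::width(gspan), fix = "start"),
    upstream = upstream_ext, downstream = GenomicRanges::width(gspan))
  gr <- GenomicRanges::GRanges(tcs$chrom, IRanges::IRanges(tcs$start, tcs$end),
                               strand = tcs$strand)
  ov <- GenomicRanges::findOverlaps(gr, gspan, ignore.strand = FALSE)

  # TSS containment per (cluster, gene) pair, for tie-breaking
  tss <- GenomicRanges::GRanges(models$transcripts$chrom,
                                IRanges::IRanges(models$transcripts$tss, width = 1L),
                                strand = models$transcripts$strand)
  tss_ov <- GenomicRanges::findOverlaps(gr, tss, ignore.strand = FALSE)
  tss_pairs <- unique(paste(S4Vectors::queryHits(tss_ov),
                            models$transcripts$gene_id[S4Vectors::subjectHits(tss_ov)]))

  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ovw <- GenomicRanges::width(IRanges::pintersect(gr[qh], gspan[sh]))
  has_tss <- paste(qh, genes$gene_id[sh]) %in% tss_pairs
  gid <- genes$gene_id[sh]
  pick <- rep(NA_integer_, nrow(tcs))
  for (i in unique(qh)) {
    j <- which(qh == i)
    j <- j[order(-has_tss[j], -ovw[j], gid[j])]
    pick[i] <- sh[j[1]]
  }
  tcs$gene_id <- ifelse(is.na(pick), NA_character_, genes$gene_id[pick])
  tcs$symbol <- ifelse(is.na(pick), NA_character_, genes$symbol[pick])
  ok_bio <- is.na(genes$biotype[pick]) | genes$biotype[pick] == "protein_coding"
  keep <- !is.na(tcs$gene_id) & !is.na(tcs$symbol) & ok_bio &
    tcs$chrom %in% chromosomes
  # genes lacking a biotype annotation are treated as protein-coding only if
  # the GTF carried no gene features at all; GENCODE input always has them
  if (!all(is.na(models$genes$biotype)))
    keep <- keep & !is.na(genes$biotype[pick]) &
      genes$biotype[pick] == "protein_coding"
  subset_tcs(tcs, keep)
}

#' Per-gene composition filter
#'
#' For each gene and sample, a cluster's usage fraction is its TPM divided
#' by the summed TPM of all the gene's clusters in that sample. A cluster is
#' kept iff its fraction is strictly above `min_fraction` in at least
#' `min_samples` samples; samples where the gene is silent count as not
#' passing. Retained fractions are not re-normalized afterwards.
#'
#' @param tcs cluster table with gene assignments (from [assign_genes()]).
#' @param min_fraction minimum usage fraction (strict `>`, default 0.10).
#' @param min_samples minimum number of passing samples (default 6).
#' @return the filtered cluster table.
#' @export
composition_filter <- function(tcs, min_fraction = 0.10, min_samples = 6) {
  tpm <- attr(tcs, "tpm")
  stopifnot(!is.null(tpm), !is.null(tcs$gene_id))
  if (!nrow(tcs)) return(tcs)
  gene_tot <- rowsum(tpm, tcs$gene_id)          # gene x sample totals
  frac <- tpm / gene_tot[tcs$gene_id, , drop = FALSE]
  frac[!is.finite(frac)] <- 0                    # silent gene in a sample
  keep <- rowSums(frac > min_fraction) >= min_samples
  subset_tcs(tcs, keep)
}
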
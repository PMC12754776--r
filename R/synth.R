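#' Synthetic-world configuration
#'
#' Assembles and validates the parameters of the synthetic data generator.
#' Defaults describe a small but realistic two-condition NET-CAGE design:
#' 6 replicates per condition, 87.7% single-promoter genes, a mean depth of
#' 200 tags per promoter, NB dispersion 0.05, 4-fold planted usage
#' switches in half of the multi-promoter genes, and G4 peaks coupled to
#' the up-regulated side of each switch with probability `g4_coupling`.
#'
#' @param seed master RNG seed (mandatory; all streams derive from it).
#' @param n_genes number of genes.
#' @param p_single probability a gene has a single promoter (default 0.877);
#'   multi-promoter genes draw 2-4 promoters uniformly.
#' @param n_samples replicates per condition (default 6).
#' @param depth mean tags per promoter per sample (default 200).
#' @param phi NB dispersion of promoter counts (default 0.05).
#' @param switch_fraction fraction of multi-promoter genes with a planted
#'   promoter switch (default 0.5).
#' @param switch_effect usage fold change of a planted switch (default 4:
#'   the switched pair moves between 80%/20% and 20%/80% of its summed
#'   share).
#' @param g4_coupling probability that each up-regulated side of a planted
#'   switch receives a condition-specific G4 peak (default 0.5).
#' @param g4_background background probability that any promoter carries a
#'   G4 peak (default 0.15; planted in both conditions half the time).
#' @param gene_de_fraction fraction of genes with a gene-level (not usage)
#'   2-fold expression change between conditions (default 0.2).
#' @param noncoding_fraction fraction of genes annotated as lincRNA, to
#'   exercise the protein-coding filter (default 0.05).
#' @param conditions names of the two conditions.
#' @return a validated list of class `SynthConfig`.
#' @export
synth_config <- function(seed, n_genes = 200, p_single = 0.877,
                         n_samples = 6, depth = 200, phi = 0.05,
                         switch_fraction = 0.5, switch_effect = 4,
                         g4_coupling = 0.5, g4_background = 0.15,
                         gene_de_fraction = 0.2, noncoding_fraction = 0.05,
                         conditions = c("condA", "condB")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              p_single = p_single, n_samples = n_samples, depth = depth,
              phi = phi, switch_fraction = switch_fraction,
              switch_effect = switch_effect, g4_coupling = g4_coupling,
              g4_background = g4_background,
              gene_de_fraction = gene_de_fraction,
              noncoding_fraction = noncoding_fraction,
              conditions = conditions)
  probs <- c(p_single, switch_fraction, g4_coupling, g4_background,
             gene_de_fraction, noncoding_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_genes < 1 || n_samples < 2 || depth <= 0 || phi < 0 ||
      switch_effect <= 1) stop("invalid configuration")
  if (length(conditions) != 2) stop("exactly two conditions")
  class(cfg) <- "SynthConfig"
  cfg
}

# one deterministic sub-seed per (output kind, index); keeps streams
# independent so adding samples does not perturb existing ones
derive_seed <- function(seed, kind, i = 0) {
  ((as.numeric(seed) %% 1000003) * 131 + kind * 10007 + i) %% 2147483629
}

G4_MOTIF <- "GGGGTTGGGGTTGGGGTTGGGGTT"  # mean run score 2.56 at window 25

#' Simulate a complete synthetic world
#'
#' Generates, with known ground truth, every input the pipeline consumes: a
#' genome FASTA with planted G4 motifs, a GENCODE-dialect GTF of two-exon
#' transcripts (one per promoter), per-sample CTSS files with NB-distributed
#' counts spread over +-3 bp around each TSS, per-condition G4 peak BED and
#' signal bedGraph files, per-sample splice-junction files, and truth
#' tables. Identical `cfg` (including seed) gives byte-identical outputs.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional directory; when given all files are written and
#'   their paths returned alongside the in-memory objects.
#' @return a list: `genome` (named character), `gtf` (data.frame of GTF
#'   fields), `ctss` (list of per-sample data.frames), `peaks` / `signal`
#'   (per-condition `GRanges`), `sj` (list of per-sample data.frames),
#'   `truth` (per-promoter data.frame), `truth_genes` (per-gene
#'   directionality), `samples`, `conditions`, and `paths` when `out_dir`
#'   is given.
#' @export
simulate_world <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  conds <- cfg$conditions
  samples <- paste0(rep(conds, each = cfg$n_samples), "_rep",
                    rep(seq_len(cfg$n_samples), 2))
  sample_cond <- rep(conds, each = cfg$n_samples)

  ## gene layout -------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1))
  n <- cfg$n_genes
  k <- ifelse(stats::runif(n) < cfg$p_single, 1L,
              sample(2:4, n, replace = TRUE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- ifelse(stats::runif(n) < cfg$noncoding_fraction,
                    "lincRNA", "protein_coding")
  chrom <- rep(c("chr1", "chr2"), length.out = n)
  span <- 400 + (pmax(k, 1) - 1) * 800 + 600      # promoters 800 bp apart
  gene_start <- integer(n)
  for (cc in unique(chrom)) {
    ix <- which(chrom == cc)
    gene_start[ix] <- cumsum(c(1000, utils::head(span[ix], -1) + 1500))
  }
  gene_id <- sprintf("G%04d", seq_len(n))
  symbol <- sprintf("SYM%04d", seq_len(n))

  ## promoter table ----------------------------------------------------
  prom <- do.call(rbind, lapply(seq_len(n), function(i) {
    off <- 200 + (seq_len(k[i]) - 1) * 800
    tss <- if (strand[i] == "+") gene_start[i] + off
    else gene_start[i] + span[i] - off
    data.frame(gene_id = gene_id[i], promoter_id = paste0(gene_id[i], ".P",
                                                          seq_len(k[i])),
               chrom = chrom[i], strand = strand[i], tss = tss,
               stringsAsFactors = FALSE)
  }))

  ## usage shares and planted switches ---------------------------------
  set.seed(derive_seed(cfg$seed, 2))
  hi <- cfg$switch_effect / (cfg$switch_effect + 1)   # 0.8 for 4-fold
  multi <- which(k >= 2)
  switched <- multi[stats::runif(length(multi)) < cfg$switch_fraction]
  gene_fc <- ifelse(stats::runif(n) < cfg$gene_de_fraction,
                    2^(sample(c(-1, 1), n, replace = TRUE)), 1)
  gene_size <- exp(stats::rnorm(n, 0, 0.5))
  share <- matrix(NA_real_, nrow(prom), 2,
                  dimnames = list(prom$promoter_id, conds))
  prom$is_switch <- FALSE
  prom$truth_direction <- NA_character_
  for (i in seq_len(n)) {
    rows <- which(prom$gene_id == gene_id[i])
    ki <- length(rows)
    if (i %in% switched) {
      pair_w <- if (ki == 2) 1 else 0.7
      rest <- if (ki > 2) rep((1 - pair_w) / (ki - 2), ki - 2) else numeric()
      share[rows, 1] <- c(hi * pair_w, (1 - hi) * pair_w, rest)
      share[rows, 2] <- c((1 - hi) * pair_w, hi * pair_w, rest)
      prom$is_switch[rows[1:2]] <- TRUE
      prom$truth_direction[rows[1]] <- paste0("up_", conds[1])
      prom$truth_direction[rows[2]] <- paste0("up_", conds[2])
    } else {
      s <- stats::rgamma(ki, shape = 5)
      share[rows, 1] <- share[rows, 2] <- s / sum(s)
    }
  }

  ## G4 peaks, coupled to switch direction -----------------------------
  set.seed(derive_seed(cfg$seed, 3))
  g4 <- matrix(FALSE, nrow(prom), 2, dimnames = list(prom$promoter_id, conds))
  for (r in seq_len(nrow(prom))) {
    coupled <- FALSE
    if (prom$is_switch[r]) {
      up <- match(sub("^up_", "", prom$truth_direction[r]), conds)
      if (stats::runif(1) < cfg$g4_coupling) {
        g4[r, up] <- TRUE
        coupled <- TRUE
      }
    }
    # every promoter is exposed to the background peak process, so at
    # coupling 0 switched promoters are indistinguishable from background
    if (!coupled && stats::runif(1) < cfg$g4_background) {
      if (stats::runif(1) < 0.5) g4[r, ] <- TRUE
      else g4[r, sample(2, 1)] <- TRUE
    }
  }
  prom$g4_site_start <- ifelse(prom$strand == "+", prom$tss - 70,
                               prom$tss + 47)
  prom$g4_site_end <- prom$g4_site_start + nchar(G4_MOTIF) - 1L
  has_motif <- rowSums(g4) > 0

  ## genome ------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 4))
  genome <- vapply(unique(chrom), function(cc) {
    len <- max(gene_start[chrom == cc] + span[chrom == cc]) + 2000
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  }, character(1))
  revcomp <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  for (r in which(has_motif)) {
    motif <- if (prom$strand[r] == "+") G4_MOTIF else revcomp(G4_MOTIF)
    cc <- prom$chrom[r]
    substr(genome[cc], prom$g4_site_start[r], prom$g4_site_end[r]) <- motif
  }
  # generation-time guarantee: the planted motif scores past the default cutoff
  stopifnot(nrow(g4_extract_hits(G4_MOTIF, window = 24, threshold = 1.5)) == 1)

  ## CTSS counts -------------------------------------------------------
  mu_base <- cfg$depth * gene_size[match(prom$gene_id, gene_id)]
  spread_off <- -3:3
  spread_w <- c(1, 2, 4, 6, 4, 2, 1) / 20
  ctss <- vector("list", length(samples)); names(ctss) <- samples
  counts_true <- matrix(0L, nrow(prom), length(samples),
                        dimnames = list(prom$promoter_id, samples))
  for (s in seq_along(samples)) {
    set.seed(derive_seed(cfg$seed, 5, s))
    cj <- match(sample_cond[s], conds)
    mu <- mu_base * share[, cj] *
      ifelse(cj == 2, gene_fc[match(prom$gene_id, gene_id)], 1)
    tot <- if (cfg$phi > 0)
      stats::rnbinom(nrow(prom), mu = mu, size = 1 / cfg$phi)
    else stats::rpois(nrow(prom), mu)
    counts_true[, s] <- tot
    rows <- lapply(which(tot > 0), function(r) {
      parts <- stats::rmultinom(1, tot[r], spread_w)[, 1]
      keep <- parts > 0
      data.frame(chrom = prom$chrom[r],
                 pos = prom$tss[r] + spread_off[keep],
                 strand = prom$strand[r], count = parts[keep],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$chrom, tab$pos, tab$strand), ]
    ctss[[s]] <- tab
  }

  ## peaks and signal per condition ------------------------------------
  peaks <- signal <- list()
  for (cj in 1:2) {
    r <- which(g4[, cj])
    pk <- GenomicRanges::GRanges(prom$chrom[r],
                                 IRanges::IRanges(prom$g4_site_start[r] - 20,
                                                  prom$g4_site_end[r] + 20))
    pk <- pk[order(as.character(GenomicRanges::seqnames(pk)),
                   GenomicRanges::start(pk))]
    peaks[[conds[cj]]] <- pk
    sg <- pk
    sg$score <- 10
    signal[[conds[cj]]] <- sg
  }

  ## splice junctions --------------------------------------------------
  # two-exon transcript per promoter: exon1 = 100 bp at the TSS, 300 bp
  # intron, 200 bp second exon, laid out 5'->3' on the gene strand
  plus <- prom$strand == "+"
  e1s <- ifelse(plus, prom$tss, prom$tss - 100L)
  e1e <- ifelse(plus, prom$tss + 100L, prom$tss)
  e2s <- ifelse(plus, prom$tss + 401L, prom$tss - 600L)
  e2e <- ifelse(plus, prom$tss + 600L, prom$tss - 401L)
  int_s <- ifelse(plus, e1e + 1L, e2e + 1L)
  int_e <- ifelse(plus, e2s - 1L, e1s - 1L)
  sj <- vector("list", length(samples)); names(sj) <- samples
  for (s in seq_along(samples)) {
    set.seed(derive_seed(cfg$seed, 6, s))
    cj <- match(sample_cond[s], conds)
    mu <- mu_base * share[, cj] *
      ifelse(cj == 2, gene_fc[match(prom$gene_id, gene_id)], 1)
    reads <- if (cfg$phi > 0)
      stats::rnbinom(nrow(prom), mu = mu, size = 1 / cfg$phi)
    else stats::rpois(nrow(prom), mu)
    tab <- data.frame(chrom = prom$chrom, intron_start = int_s,
                      intron_end = int_e,
                      strand_code = ifelse(plus, 1L, 2L),
                      motif = 1L, annotated = 1L, unique_reads = reads,
                      multi_reads = 0L, overhang = 30L,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$chrom, tab$intron_start), ]
    sj[[s]] <- tab
  }

  ## GTF ---------------------------------------------------------------
  gtf <- synth_gtf(prom, gene_id, symbol, biotype, chrom, strand,
                   gene_start, span, e1s, e1e, e2s, e2e)

  ## truth -------------------------------------------------------------
  truth <- prom[, c("promoter_id", "gene_id", "chrom", "strand", "tss",
                    "is_switch", "truth_direction", "g4_site_start",
                    "g4_site_end")]
  truth$share_condA <- share[, 1]
  truth$share_condB <- share[, 2]
  truth[[paste0("assoc_", conds[1])]] <- g4[, 1]
  truth[[paste0("assoc_", conds[2])]] <- g4[, 2]
  truth$biotype <- biotype[match(truth$gene_id, gene_id)]
  ap_truth <- truth[truth$is_switch & truth$biotype == "protein_coding", ]
  truth_genes <- if (nrow(ap_truth)) {
    at <- data.frame(gene_id = ap_truth$gene_id,
                     direction = ap_truth$truth_direction,
                     stringsAsFactors = FALSE)
    at[[paste0("assoc_", conds[1])]] <- ap_truth[[paste0("assoc_", conds[1])]]
    at[[paste0("assoc_", conds[2])]] <- ap_truth[[paste0("assoc_", conds[2])]]
    classify_directionality(at)
  } else data.frame(gene_id = character(), pattern = character())

  world <- list(genome = genome, gtf = gtf, ctss = ctss, peaks = peaks,
                signal = signal, sj = sj, truth = truth,
                truth_genes = truth_genes, samples = samples,
                sample_condition = sample_cond, conditions = conds,
                counts_true = counts_true, cfg = cfg)
  if (!is.null(out_dir)) world$paths <- write_world(world, out_dir)
  world
}

# GTF lines for the synthetic gene models (GENCODE attribute dialect)
synth_gtf <- function(prom, gene_id, symbol, biotype, chrom, strand,
                      gene_start, span, e1s, e1e, e2s, e2e) {
  n <- length(gene_id)
  lines <- list()
  for (i in seq_len(n)) {
    rows <- which(prom$gene_id == gene_id[i])
    gs <- min(e1s[rows], e2s[rows]); ge <- max(e1e[rows], e2e[rows])
    attr_g <- sprintf(
      'gene_id "%s.1"; gene_type "%s"; gene_name "%s";',
      gene_id[i], biotype[i], symbol[i])
    lines[[length(lines) + 1]] <- data.frame(
      chrom = chrom[i], source = "synth", type = "gene", start = gs, end = ge,
      score = ".", strand = strand[i], frame = ".", attrs = attr_g,
      stringsAsFactors = FALSE)
    for (j in seq_along(rows)) {
      r <- rows[j]
      tid <- sprintf("%s.T%d", gene_id[i], j)
      attr_t <- sprintf(
        'gene_id "%s.1"; transcript_id "%s.1"; gene_type "%s"; gene_name "%s";',
        gene_id[i], tid, biotype[i], symbol[i])
      ts <- min(e1s[r], e2s[r]); te <- max(e1e[r], e2e[r])
      lines[[length(lines) + 1]] <- data.frame(
        chrom = chrom[i], source = "synth", type = "transcript", start = ts,
        end = te, score = ".", strand = strand[i], frame = ".",
        attrs = attr_t, stringsAsFactors = FALSE)
      for (ex in list(c(e1s[r], e1e[r]), c(e2s[r], e2e[r]))) {
        lines[[length(lines) + 1]] <- data.frame(
          chrom = chrom[i], source = "synth", type = "exon", start = ex[1],
          end = ex[2], score = ".", strand = strand[i], frame = ".",
          attrs = attr_t, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, lines)
}

# write every world component to disk; returns the named list of paths
write_world <- function(world, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "ctss"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "sj"), showWarnings = FALSE)
  paths <- list()
  paths$fasta <- file.path(out_dir, "genome.fa")
  writeLines(unlist(lapply(names(world$genome), function(cc)
    c(paste0(">", cc), world$genome[[cc]]))), paths$fasta)
  paths$gtf <- file.path(out_dir, "genes.gtf")
  g <- world$gtf
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     g$chrom, g$source, g$type, g$start, g$end, g$score,
                     g$strand, g$frame, g$attrs), paths$gtf)
  paths$ctss <- setNames(file.path(out_dir, "ctss",
                                   paste0(world$samples, ".ctss")),
                         world$samples)
  for (s in world$samples) {
    t <- world$ctss[[s]]
    writeLines(sprintf("%s\t%d\t%s\t%d", t$chrom, t$pos, t$strand, t$count),
               paths$ctss[[s]])
  }
  paths$peaks <- setNames(file.path(out_dir, paste0(
    "peaks_", world$conditions, ".bed")), world$conditions)
  paths$signal <- setNames(file.path(out_dir, paste0(
    "signal_", world$conditions, ".bedGraph")), world$conditions)
  for (cond in world$conditions) {
    write_bed(world$peaks[[cond]], paths$peaks[[cond]])
    sg <- gr_to_bed(world$signal[[cond]])
    writeLines(sprintf("%s\t%d\t%d\t%g", sg$chrom, sg$start, sg$end,
                       world$signal[[cond]]$score), paths$signal[[cond]])
  }
  paths$sj <- setNames(file.path(out_dir, "sj",
                                 paste0(world$samples, ".SJ.out.tab")),
                       world$samples)
  for (s in world$samples) {
    t <- world$sj[[s]]
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                       t$chrom, t$intron_start, t$intron_end, t$strand_code,
                       t$motif, t$annotated, t$unique_reads, t$multi_reads,
                       t$overhang), paths$sj[[s]])
  }
  paths$truth <- file.path(out_dir, "truth_promoters.tsv")
  utils::write.table(world$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth_genes <- file.path(out_dir, "truth_genes.tsv")
  utils::write.table(world$truth_genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Recall, precision and direction accuracy against planted truth
#'
#' Matches result promoters to planted promoters by gene id and position
#' (`|position - planted TSS| <= tol`), then scores the AP calls: recall =
#' recovered planted switches / planted switches, precision = called APs
#' that are planted / called APs (`NA` when nothing is called), direction
#' accuracy = fraction of recovered planted switches whose direction label
#' matches the truth.
#'
#' @param results data.frame with `gene_id`, `position`, `is_ap`,
#'   `direction` (e.g. a `UsageResult` joined with cluster peak positions).
#' @param truth the `truth` table from [simulate_world()].
#' @param tol matching tolerance in bp (default 5).
#' @return list with `recall`, `precision`, `direction_accuracy`, `n_planted`,
#'   `n_called`, `n_recovered`.
#' @export
truth_recall <- function(results, truth, tol = 5) {
  need <- c("gene_id", "position", "is_ap", "direction")
  if (!all(need %in% names(results)))
    stop("results must carry columns: ", paste(need, collapse = ", "))
  planted <- truth[truth$is_switch, , drop = FALSE]
  match_row <- function(g, pos) {
    cand <- which(planted$gene_id == g & abs(planted$tss - pos) <= tol)
    if (length(cand)) cand[1] else NA_integer_
  }
  m <- if (nrow(results)) vapply(seq_len(nrow(results)), function(i)
    match_row(results$gene_id[i], results$position[i]), integer(1))
  else integer()
  called <- which(results$is_ap)
  recovered <- called[!is.na(m[called])]
  n_planted <- nrow(planted)
  recall <- if (n_planted) length(unique(m[recovered])) / n_planted else NA
  precision <- if (length(called)) length(recovered) / length(called) else NA
  dir_ok <- results$direction[recovered] ==
    planted$truth_direction[m[recovered]]
  list(recall = recall, precision = precision,
       direction_accuracy = if (length(recovered)) mean(dir_ok) else NA,
       n_planted = n_planted, n_called = length(called),
       n_recovered = length(recovered))
}

#' Simulate a bare promoter count matrix
#'
#' A lightweight generator for testing the usage statistics without file
#' I/O: NB counts for `n_genes` genes with `k` promoters each, optional
#' planted usage switches in a fraction of genes, optional gene-level
#' expression changes, and a two-condition design.
#'
#' @inheritParams synth_config
#' @param k promoters per gene (default 2).
#' @return list with `counts`, `gene_map`, `group`, and `truth` (logical
#'   vector per promoter: part of a planted switch).
#' @export
simulate_usage_counts <- function(seed, n_genes = 200, k = 2, n_samples = 6,
                                  depth = 200, phi = 0.05,
                                  switch_fraction = 0, switch_effect = 4,
                                  gene_de_fraction = 0.2) {
  set.seed(seed)
  hi <- switch_effect / (switch_effect + 1)
  n_prom <- n_genes * k
  gene_map <- rep(sprintf("G%04d", seq_len(n_genes)), each = k)
  switched <- stats::runif(n_genes) < switch_fraction
  gene_fc <- ifelse(stats::runif(n_genes) < gene_de_fraction,
                    2^(sample(c(-1, 1), n_genes, replace = TRUE)), 1)
  gene_size <- exp(stats::rnorm(n_genes, 0, 0.5))
  shareA <- shareB <- matrix(1 / k, n_genes, k)
  for (i in which(switched)) {
    pair_w <- if (k == 2) 1 else 2 / k
    shareA[i, 1:2] <- c(hi, 1 - hi) * pair_w
    shareB[i, 1:2] <- c(1 - hi, hi) * pair_w
  }
  group <- factor(rep(c("condA", "condB"), each = n_samples))
  counts <- matrix(0L, n_prom, 2 * n_samples,
                   dimnames = list(paste0(gene_map, ".P",
                                          rep(seq_len(k), n_genes)),
                                   paste0(group, "_rep",
                                          rep(seq_len(n_samples), 2))))
  for (s in seq_len(2 * n_samples)) {
    sh <- if (group[s] == "condA") t(shareA) else t(shareB)
    mu <- depth * rep(gene_size, each = k) * as.numeric(sh) *
      rep(ifelse(group[s] == "condB", gene_fc, 1), each = k)
    counts[, s] <- if (phi > 0)
      stats::rnbinom(n_prom, mu = mu, size = 1 / phi)
    else stats::rpois(n_prom, mu)
  }
  truth <- rep(switched, each = k) & rep(seq_len(k), n_genes) <= 2
  list(counts = counts, gene_map = gene_map, group = group, truth = truth,
       direction = ifelse(truth & rep(seq_len(k), n_genes) == 1, "up_condA",
                          ifelse(truth, "up_condB", NA)))
}
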
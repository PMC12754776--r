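#' Per-base G4Hunter run-length scores
#'
#' Assigns every base an integer score in `[-4, 4]` reflecting its maximal
#' homopolymer run: a lone G scores +1, each G in a run of two scores +2, in
#' a run of three +3, and every G in a run of four or more scores +4.
#' Cytosines score the same magnitudes with negative sign (a C-rich stretch
#' means the G4 would form on the complementary strand). A, T, U and N are
#' neutral (0); case is ignored, so soft-masked sequence scores identically.
#'
#' @param sequence a single character string over the alphabet
#'   `A,C,G,T,U,N` (either case).
#' @return integer vector of per-base scores, one per base.
#' @examples
#' g4_base_scores("AAGGGGGAA")  # run of five Gs scores +4 each
#' @export
g4_base_scores <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (is.na(sequence) || nchar(sequence) == 0) stop("empty input")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad))
    stop("illegal character '", chars[bad[1]], "' at position ", bad[1])
  key <- ifelse(chars == "G", 1L, ifelse(chars == "C", -1L, 0L))
  r <- rle(key)
  run_score <- r$values * pmin(r$lengths, 4L)
  rep.int(run_score, r$lengths)
}

#' Sliding-window mean of a score profile
#'
#' @param scores numeric vector of per-base scores.
#' @param window window width in bp.
#' @return numeric vector of window means, one per window start
#'   (length `length(scores) - window + 1`).
#' @export
g4_sliding_mean <- function(scores, window) {
  stopifnot(is.numeric(scores), length(window) == 1, window >= 1)
  n <- length(scores)
  if (window > n) stop("sequence shorter than window")
  cs <- c(0, cumsum(as.numeric(scores)))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Extract candidate G4 regions from a sequence
#'
#' Scores the sequence with [g4_base_scores()], slides a window of
#' `window` bp, and collects every window whose mean score has absolute
#' value at or above `threshold`. Overlapping or adjacent qualifying windows
#' of the same sign are merged; each merged region is trimmed so that it
#' starts and ends on a scored base (G for positive regions, C for
#' negative), and the mean score is recomputed over the trimmed interval.
#' A negative mean marks a C-rich region whose G4 would form on the
#' complementary strand, reported with strand `-`.
#'
#' @inheritParams g4_base_scores
#' @param window window width in bp (default 25).
#' @param threshold minimum absolute window mean (default 1.5, a
#'   conservative cutoff; 1.2 is the permissive default of the original
#'   scoring scheme).
#' @return a `data.frame` with 1-based inclusive `start`, `end`,
#'   `mean_score` (signed, over the trimmed interval) and `strand`
#'   (`-` iff `mean_score < 0`), sorted by `start`.
#' @examples
#' g4_extract_hits("GGGGTTGGGGTTGGGGTTGGGGTTT", window = 25)
#' @export
g4_extract_hits <- function(sequence, window = 25, threshold = 1.5) {
  stopifnot(window >= 1, threshold > 0)
  scores <- g4_base_scores(sequence)
  if (length(scores) < window)
    return(data.frame(start = integer(), end = integer(),
                      mean_score = numeric(), strand = character()))
  means <- g4_sliding_mean(scores, window)
  out <- list()
  for (sgn in c(1, -1)) {
    qual <- which(sgn * means >= threshold)
    if (!length(qual)) next
    win <- IRanges::IRanges(qual, qual + window - 1L)
    merged <- IRanges::reduce(win)  # overlapping or adjacent windows join
    for (k in seq_along(merged)) {
      lo <- IRanges::start(merged)[k]
      hi <- IRanges::end(merged)[k]
      member <- lo:hi
      on_base <- member[scores[member] * sgn > 0]
      lo <- min(on_base); hi <- max(on_base)
      out[[length(out) + 1L]] <- data.frame(
        start = lo, end = hi,
        mean_score = mean(scores[lo:hi]),
        strand = if (sgn > 0) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      mean_score = numeric(), strand = character()))
  hits <- do.call(rbind, out)
  hits[order(hits$start, hits$end), , drop = FALSE]
}

#' Scan a FASTA file for candidate G4 regions
#'
#' Runs [g4_extract_hits()] on every record (optionally restricted to a set
#' of chromosomes) and reports hits on both strands in plus-strand
#' coordinates: C-rich plus-strand regions carry strand `-` because the G4
#' forms on the complementary strand. Output order is deterministic
#' (chromosome, then start).
#'
#' @param fasta_path path to a FASTA file.
#' @inheritParams g4_extract_hits
#' @param chromosomes optional character vector restricting the scan (the
#'   canonical human analysis set is the 22 autosomes plus chrX).
#' @param out optional path; when given the hits are also written as BED6
#'   (score column = mean score, three decimals).
#' @return a `GRanges` of hits with metadata columns `name` (auto id) and
#'   `score` (signed window mean over the trimmed region).
#' @export
g4_scan_fasta <- function(fasta_path, window = 25, threshold = 1.5,
                          chromosomes = NULL, out = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs)) stop("empty FASTA: ", fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  if (!is.null(chromosomes)) seqs <- seqs[names(seqs) %in% chromosomes]
  per_chrom <- lapply(order(names(seqs)), function(i) {
    hits <- g4_extract_hits(as.character(seqs[[i]]), window, threshold)
    if (!nrow(hits)) return(NULL)
    cbind(chrom = names(seqs)[i], hits)
  })
  tab <- do.call(rbind, per_chrom)
  if (is.null(tab))
    tab <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_score = numeric(),
                      strand = character())
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$name <- if (nrow(tab)) sprintf("G4_%06d", seq_len(nrow(tab)))
  else character()
  gr$score <- tab$mean_score
  if (!is.null(out)) write_bed(gr, out)
  gr
}
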
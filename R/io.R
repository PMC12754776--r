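#' Read and write BED6 interval files
#'
#' Minimal BED6 I/O on the 0-based half-open convention. `read_bed()` returns
#' a `GRanges` with `name` and `score` metadata columns; `write_bed()` writes
#' one and is its inverse for records the pipeline emits. Scores are written
#' with three decimals (sufficient for window-mean G4 scores).
#'
#' @param path file path.
#' @param gr a `GRanges` with optional `name` and `score` metadata columns.
#' @param digits decimals used for the score column.
#' @return `read_bed()`: a `GRanges`; `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:max(3, ncol_tsv(path))])
  if (ncol(tab) < 3) stop("BED file ", path, ": fewer than 3 columns")
  strand <- if ("strand" %in% names(tab)) sub("^\\.$", "*", tab$strand)
  else "*"
  gr <- bed_to_gr(tab$chrom, tab$start, tab$end, strand)
  if ("name" %in% names(tab)) gr$name <- as.character(tab$name)
  if ("score" %in% names(tab)) gr$score <- as.numeric(tab$score)
  gr
}

ncol_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path, digits = 3) {
  bed <- gr_to_bed(gr)
  bed$name <- if (!is.null(gr$name)) gr$name else "."
  bed$score <- if (!is.null(gr$score)) formatC(gr$score, digits = digits,
                                               format = "f") else "0"
  bed$strand[bed$strand == "*"] <- "."
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value; 0-based
#'   half-open).
#' @return a `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr
}

#' Read per-base CTSS count files
#'
#' Each file holds whitespace-delimited records `chrom position strand count`
#' with 1-based positions, one file per sample. The union of positions across
#' samples forms the rows of the returned count matrix; a position absent
#' from a sample counts 0 there.
#'
#' @param paths character vector of file paths.
#' @param sample_ids sample names; default the file base names.
#' @return a list with elements `positions` (a stranded width-1 `GRanges`),
#'   `counts` (integer matrix, positions x samples) and `sample_ids`.
#' @export
read_ctss <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(sample_ids) == length(paths), !anyDuplicated(sample_ids))
  per_sample <- lapply(seq_along(paths), function(i) {
    path <- paths[i]
    if (!file.exists(path)) stop("CTSS file not found: ", path)
    tab <- tryCatch(
      utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = c("character", "integer", "character",
                                       "integer")),
      error = function(e) stop("malformed CTSS file ", path, ": ",
                               conditionMessage(e)))
    if (ncol(tab) != 4)
      stop("CTSS file ", path, ": expected 4 columns, got ", ncol(tab))
    names(tab) <- c("chrom", "pos", "strand", "count")
    bad <- which(!tab$strand %in% c("+", "-"))
    if (length(bad))
      stop("CTSS file ", path, " line ", bad[1], ": strand must be + or -")
    bad <- which(is.na(tab$count) | tab$count < 0)
    if (length(bad))
      stop("CTSS file ", path, " line ", bad[1], ": count must be a ",
           "non-negative integer")
    bad <- which(is.na(tab$pos) | tab$pos < 1)
    if (length(bad))
      stop("CTSS file ", path, " line ", bad[1], ": position must be >= 1")
    tab
  })
  keys <- lapply(per_sample, function(t) paste(t$chrom, t$pos, t$strand))
  all_keys <- sort(unique(unlist(keys)))
  counts <- matrix(0L, nrow = length(all_keys), ncol = length(paths),
                   dimnames = list(all_keys, sample_ids))
  for (i in seq_along(per_sample)) {
    idx <- match(keys[[i]], all_keys)
    counts[idx, i] <- counts[idx, i] + per_sample[[i]]$count
  }
  parts <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  positions <- GenomicRanges::GRanges(parts[, 1],
                                      IRanges::IRanges(as.integer(parts[, 2]),
                                                       width = 1L),
                                      strand = parts[, 3])
  keep <- rowSums(counts) > 0L
  structure(list(positions = positions[keep],
                 counts = counts[keep, , drop = FALSE],
                 sample_ids = sample_ids),
            class = "CtssMatrix")
}

#' Read STAR-style splice-junction files
#'
#' Expects the nine-column `SJ.out.tab` layout: chrom, 1-based intron start,
#' 1-based intron end, strand code (0 undefined, 1 `+`, 2 `-`), intron motif,
#' annotation flag, uniquely mapping reads, multi-mapping reads, overhang.
#'
#' @param path file path.
#' @return a `data.frame` with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `unique_reads`.
#' @export
read_sj <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 9)
    stop("junction file ", path, ": expected 9 columns, got ", ncol(tab))
  names(tab) <- c("chrom", "intron_start", "intron_end", "strand_code",
                  "motif", "annotated", "unique_reads", "multi_reads",
                  "overhang")
  bad <- which(!tab$strand_code %in% 0:2)
  if (length(bad))
    stop("junction file ", path, " line ", bad[1],
         ": strand code must be 0, 1 or 2")
  data.frame(chrom = tab$chrom,
             intron_start = tab$intron_start,
             intron_end = tab$intron_end,
             strand = c("*", "+", "-")[tab$strand_code + 1L],
             unique_reads = tab$unique_reads,
             stringsAsFactors = FALSE)
}
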
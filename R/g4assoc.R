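#' Flag promoters associated with G4 peaks
#'
#' A promoter is G4-associated in a condition iff at least one peak shares a
#' base with the promoter interval or with its strand-aware upstream window
#' of `upstream` bp (for a `+` promoter the window sits immediately left of
#' the interval; for a `-` promoter immediately right). Peaks are treated as
#' unstranded.
#'
#' @param promoters a stranded `GRanges` (names or `$id` used as promoter
#'   ids).
#' @param peaks named list of `GRanges`, one per condition.
#' @param upstream upstream window width in bp (default 100); `strand_aware
#'   = FALSE` extends leftward regardless of strand.
#' @param strand_aware logical (default TRUE).
#' @return a `data.frame` with one row per promoter: `promoter_id`, one
#'   logical `assoc_<condition>` column per condition, and `category`
#'   (`neither` / `one` / `both` for the two-condition case, otherwise the
#'   count of associated conditions).
#' @export
associate_g4 <- function(promoters, peaks, upstream = 100,
                         strand_aware = TRUE) {
  if (upstream < 0) stop("upstream must be non-negative")
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  ids <- if (!is.null(promoters$id)) promoters$id
  else if (!is.null(names(promoters))) names(promoters)
  else sprintf("P%05d", seq_along(promoters))
  win <- promoters
  if (!strand_aware) GenomicRanges::strand(win) <- "+"
  win <- GenomicRanges::punion(
    win, GenomicRanges::flank(win, width = upstream, start = TRUE))
  out <- data.frame(promoter_id = ids, stringsAsFactors = FALSE)
  for (cond in names(peaks)) {
    out[[paste0("assoc_", cond)]] <-
      IRanges::overlapsAny(win, peaks[[cond]], ignore.strand = TRUE)
  }
  n_assoc <- rowSums(as.matrix(out[, -1, drop = FALSE]))
  out$category <- if (length(peaks) == 2)
    c("neither", "one", "both")[n_assoc + 1L] else as.character(n_assoc)
  out
}

#' G4-association enrichment of APs over background
#'
#' Builds the 2 x 3 contingency table of AP status against G4-association
#' category (neither / one / both) and tests it with Fisher's exact test —
#' exact network enumeration when the table total is at most `exact_max`,
#' otherwise a seeded Monte-Carlo approximation. Per-category ratios are the
#' category proportions among APs divided by the proportions among the
#' background (all retained promoters).
#'
#' @param ap_categories character vector of categories for APs.
#' @param background_categories categories for all retained promoters (the
#'   background includes the APs).
#' @param exact_max largest table total for which the exact test is used
#'   (default 200).
#' @param mc_B Monte-Carlo replicates for large tables (default 1e5).
#' @param mc_seed seed for the Monte-Carlo fallback.
#' @return list with `table` (2 x categories), `fisher_p`, and `ratios`.
#' @export
category_enrichment <- function(ap_categories, background_categories,
                                exact_max = 200, mc_B = 1e5, mc_seed = 1) {
  lev <- intersect(c("neither", "one", "both"),
                   unique(c(ap_categories, background_categories)))
  if (!length(lev)) lev <- sort(unique(background_categories))
  ap <- table(factor(ap_categories, levels = lev))
  bg <- table(factor(background_categories, levels = lev))
  non_ap <- bg - ap
  if (any(non_ap < 0))
    stop("background must include all AP promoters")
  tab <- rbind(AP = as.integer(ap), nonAP = as.integer(non_ap))
  colnames(tab) <- lev
  keep <- colSums(tab) > 0
  p <- if (any(rowSums(tab) == 0) || sum(keep) < 2) {
    warning("degenerate contingency table; p = 1")
    1
  } else if (sum(tab) <= exact_max) {
    stats::fisher.test(tab[, keep, drop = FALSE])$p.value
  } else {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(mc_seed)
    stats::fisher.test(tab[, keep, drop = FALSE],
                       simulate.p.value = TRUE, B = mc_B)$p.value
  }
  ratios <- (ap / max(sum(ap), 1)) / (bg / sum(bg))
  list(table = tab, fisher_p = p, ratios = as.numeric(ratios),
       categories = lev)
}

#' Relative G4 density around promoters
#'
#' Computes a coverage-mode density profile at 10 bp resolution over
#' promoter regions plus flanks, with every promoter body rescaled to a
#' common `target_width` (flanks unscaled) and minus-strand promoters
#' flipped so the profile reads 5' to 3'. For window n the density is
#' `d_n = sum_i w_i / (width * M)`, where `w_i` is the number of bases of
#' window n covered by G4s in region i and `M` is the number of regions —
#' a per-window coverage fraction in `[0, 1]`. `denominator = "N"`
#' reproduces the literal alternative of dividing by `width * N` (N = number
#' of windows), which is not a coverage fraction; see the vignette.
#'
#' @param promoters stranded `GRanges` of promoter regions.
#' @param g4 `GRanges` of G4 intervals (strand ignored).
#' @param width window width in bp (default 10).
#' @param flank flank length in bp on each side (must be a multiple of
#'   `width`; default 2000).
#' @param target_width common width promoter bodies are scaled to (multiple
#'   of `width`; default 500).
#' @param denominator `"M"` (default, per-region coverage fraction) or
#'   `"N"`.
#' @return list with `values` (length-N numeric), `M`, `N`, `width`,
#'   `flank`, and `body_windows` (index range of the scaled body).
#' @export
relative_density <- function(promoters, g4, width = 10, flank = 2000,
                             target_width = 500, denominator = c("M", "N")) {
  denominator <- match.arg(denominator)
  if (flank %% width != 0) stop("flank must be a multiple of the window width")
  if (target_width %% width != 0)
    stop("target_width must be a multiple of the window width")
  M <- length(promoters)
  n_win <- as.integer((2 * flank + target_width) / width)
  if (M == 0) return(list(values = rep(NA_real_, n_win), M = 0, N = n_win,
                          width = width, flank = flank))
  cov <- GenomicRanges::coverage(GenomicRanges::reduce(g4, ignore.strand = TRUE))
  profiles <- matrix(0, M, 2 * flank + target_width)
  for (i in seq_len(M)) {
    p <- promoters[i]
    chrom <- as.character(GenomicRanges::seqnames(p))
    minus <- as.character(GenomicRanges::strand(p)) == "-"
    s <- GenomicRanges::start(p); e <- GenomicRanges::end(p)
    covc <- if (chrom %in% names(cov)) cov[[chrom]] else S4Vectors::Rle(0L, 0)
    at <- function(from, to) {          # per-base 0/1 coverage, 0 off-contig
      idx <- from:to
      v <- numeric(length(idx))
      ok <- idx >= 1 & idx <= length(covc)
      if (any(ok)) v[ok] <- as.numeric(covc[idx[ok]])
      v
    }
    body <- at(s, e)
    scaled <- rescale_vec(body, target_width)
    up <- at(s - flank, s - 1)
    down <- at(e + 1, e + flank)
    prof <- c(up, scaled, down)
    if (minus) prof <- rev(prof)
    profiles[i, ] <- prof
  }
  win <- rep(seq_len(n_win), each = width)
  covered <- colSums(profiles)                  # per-base, summed over regions
  w_sum <- as.numeric(tapply(covered, win, sum))
  denom <- if (denominator == "M") width * M else width * n_win
  list(values = w_sum / denom, M = M, N = n_win, width = width,
       flank = flank,
       body_windows = c(flank / width + 1L, (flank + target_width) / width))
}

# Area-averaging resampling of a per-base vector to `target` bins: bin t
# averages the step function over ((t-1) * n / target, t * n / target].
rescale_vec <- function(v, target) {
  n <- length(v)
  if (n == target) return(as.numeric(v))
  cs <- c(0, cumsum(as.numeric(v)))
  F <- function(x) {                    # integral of the step fn over [0, x]
    i <- pmin(floor(x), n - 1e-9)
    i0 <- floor(i)
    cs[i0 + 1] + (x - i0) * v[pmin(i0 + 1, n)]
  }
  b <- seq(0, n, length.out = target + 1)
  diff(F(b)) / (n / target)
}

#' Mean signal over promoters and AP vs non-AP comparisons
#'
#' The per-promoter mean is the base-weighted average of the track value
#' over the promoter interval (bases without signal count as 0). With two
#' condition tracks, `delta` is `mean(first) - mean(second)` in the order of
#' `tracks`. `compare_groups()` runs the one-tailed Wilcoxon rank-sum test
#' of a location shift between two sets of values.
#'
#' @param promoters `GRanges` of promoter intervals.
#' @param tracks named list of signal `GRanges` (with `score`), one per
#'   condition, e.g. from [read_bedgraph()].
#' @return data.frame with `promoter_id`, one `mean_<condition>` column per
#'   track, and `delta` when there are exactly two tracks.
#' @export
signal_at_promoters <- function(promoters, tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  ids <- if (!is.null(promoters$id)) promoters$id
  else sprintf("P%05d", seq_along(promoters))
  out <- data.frame(promoter_id = ids, stringsAsFactors = FALSE)
  for (cond in names(tracks)) {
    tr <- tracks[[cond]]
    cov <- GenomicRanges::coverage(tr, weight = tr$score)
    vals <- numeric(length(promoters))
    for (i in seq_along(promoters)) {
      chrom <- as.character(GenomicRanges::seqnames(promoters[i]))
      if (!chrom %in% names(cov)) {
        warning("contig ", chrom, " absent from track ", cond,
                "; mean set to 0")
        next
      }
      covc <- cov[[chrom]]
      s <- GenomicRanges::start(promoters[i])
      e <- GenomicRanges::end(promoters[i])
      idx <- s:e
      ok <- idx >= 1 & idx <= length(covc)
      vals[i] <- sum(as.numeric(covc[idx[ok]])) / length(idx)
    }
    out[[paste0("mean_", cond)]] <- vals
  }
  if (length(tracks) == 2)
    out$delta <- out[[paste0("mean_", names(tracks)[1])]] -
      out[[paste0("mean_", names(tracks)[2])]]
  out
}

#' @rdname signal_at_promoters
#' @param x,y numeric vectors of per-promoter values (e.g. `delta` for APs
#'   and non-APs).
#' @param alternative passed to [stats::wilcox.test()]; `"greater"` tests
#'   that `x` is shifted upward relative to `y`.
#' @export
compare_groups <- function(x, y, alternative = "greater") {
  stats::wilcox.test(x, y, alternative = alternative, exact = NULL,
                     correct = TRUE)$p.value
}

#' Classify the direction of the G4 effect per gene
#'
#' Per AP the G4 "effect" is *promoting* when the promoter is G4-associated
#' only in the condition where it is relatively more active, *repressing*
#' when associated only in the other condition, and *neutral* when
#' associated in both or neither. Genes are then labelled: `promotes`
#' (single direction of AP bias, >= 1 promoting AP, no repressing),
#' `represses` (mirror), `bidirectional_promotes` (APs up in both
#' directions, each direction backed by a promoting AP, none repressing),
#' `bidirectional_represses` (mirror), and `mixed` otherwise.
#'
#' @param ap_table data.frame with one row per AP: `gene_id`, `direction`
#'   (the two values of `up_<condition>`), and logical `assoc_<condition>`
#'   columns for the two conditions (condition names must match the
#'   direction labels).
#' @return data.frame `gene_id`, `pattern`.
#' @export
classify_directionality <- function(ap_table) {
  stopifnot(all(c("gene_id", "direction") %in% names(ap_table)))
  acols <- grep("^assoc_", names(ap_table), value = TRUE)
  if (length(acols) != 2) stop("exactly two assoc_<condition> columns required")
  conds <- sub("^assoc_", "", acols)
  up_cond <- sub("^up_", "", ap_table$direction)
  if (!all(up_cond %in% conds))
    stop("direction labels do not match the assoc_ condition names")
  a_up <- mapply(function(i, cond) ap_table[[paste0("assoc_", cond)]][i],
                 seq_len(nrow(ap_table)), up_cond)
  a_down <- mapply(function(i, cond)
    ap_table[[paste0("assoc_", setdiff(conds, cond))]][i],
    seq_len(nrow(ap_table)), up_cond)
  effect <- ifelse(a_up & !a_down, "promoting",
                   ifelse(!a_up & a_down, "repressing", "neutral"))
  res <- lapply(split(seq_len(nrow(ap_table)), ap_table$gene_id), function(ix) {
    dirs <- unique(up_cond[ix])
    eff <- effect[ix]
    pattern <- if (length(dirs) == 1) {
      if (any(eff == "promoting") && !any(eff == "repressing")) "promotes"
      else if (any(eff == "repressing") && !any(eff == "promoting")) "represses"
      else "mixed"
    } else {
      per_dir_prom <- vapply(dirs, function(d)
        any(eff[up_cond[ix] == d] == "promoting"), TRUE)
      per_dir_rep <- vapply(dirs, function(d)
        any(eff[up_cond[ix] == d] == "repressing"), TRUE)
      if (all(per_dir_prom) && !any(eff == "repressing"))
        "bidirectional_promotes"
      else if (all(per_dir_rep) && !any(eff == "promoting"))
        "bidirectional_represses"
      else "mixed"
    }
    data.frame(gene_id = ap_table$gene_id[ix[1]], pattern = pattern,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
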
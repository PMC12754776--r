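# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops, enumeration, or closed forms only.

# per-base run scores by explicit left/right run counting
oracle_base_scores <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  out <- integer(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1] == ch[i]) j <- j + 1
    len <- j - i + 1
    val <- if (ch[i] == "G") min(len, 4) else if (ch[i] == "C") -min(len, 4) else 0
    out[i:j] <- val
    i <- j + 1
  }
  out
}

# enumerate all windows, merge qualifying same-sign windows by per-base
# membership, trim to scored bases, recompute means
oracle_extract_hits <- function(seq, window = 25, threshold = 1.5) {
  sc <- oracle_base_scores(seq)
  n <- length(sc)
  if (n < window) return(data.frame(start = integer(), end = integer(),
                                    mean_score = numeric(),
                                    strand = character()))
  hits <- list()
  for (sgn in c(1, -1)) {
    member <- rep(FALSE, n)
    for (i in 1:(n - window + 1)) {
      m <- mean(sc[i:(i + window - 1)])
      if (sgn * m >= threshold) member[i:(i + window - 1)] <- TRUE
    }
    r <- rle(member)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      idx <- starts[g]:ends[g]
      scored <- idx[sign(sc[idx]) == sgn]
      lo <- min(scored); hi <- max(scored)
      hits[[length(hits) + 1]] <- data.frame(
        start = lo, end = hi, mean_score = mean(sc[lo:hi]),
        strand = if (sgn > 0) "+" else "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer(),
                                       mean_score = numeric(),
                                       strand = character()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$end), , drop = FALSE]
}

# single-linkage clustering of integer positions by explicit scanning
oracle_cluster_positions <- function(pos, merge_dist) {
  pos <- sort(pos)
  groups <- list()
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= merge_dist) cur <- c(cur, p)
    else { groups[[length(groups) + 1]] <- cur; cur <- p }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(g)
    data.frame(start = min(g), end = max(g))))
}

# textbook step-up BH by sorting and explicit cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# exact Fisher p for an r x c table by full enumeration of tables with the
# same margins (recursive over cells), conditional hypergeometric weights
oracle_fisher_exact <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  log_dmultihyper <- function(m) {
    # P(table | margins) = prod(rs!) prod(cs!) / (n! prod(cells!))
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(m + 1))
  }
  tables <- list()
  gen <- function(filled, row) {
    if (row == nrow(tab)) {
      last <- cs - colSums(matrix(unlist(filled), ncol = ncol(tab),
                                  byrow = TRUE))
      if (all(last >= 0)) tables[[length(tables) + 1]] <<-
          rbind(do.call(rbind, filled), last)
      return(invisible())
    }
    # enumerate all compositions of rs[row] over ncol cells within margins
    rem_cols <- cs - if (length(filled))
      colSums(matrix(unlist(filled), ncol = ncol(tab), byrow = TRUE))
    else rep(0, ncol(tab))
    comp <- function(prefix, left, col) {
      if (col == ncol(tab)) {
        if (left <= rem_cols[col]) gen(c(filled, list(c(prefix, left))),
                                       row + 1)
        return(invisible())
      }
      for (v in 0:min(left, rem_cols[col])) comp(c(prefix, v), left - v,
                                                 col + 1)
    }
    comp(integer(), rs[row], 1)
    invisible()
  }
  gen(list(), 1)
  lp <- vapply(tables, log_dmultihyper, numeric(1))
  obs <- log_dmultihyper(tab)
  sum(exp(lp[lp <= obs + 1e-9])) / sum(exp(lp))
}

# exact one-tailed rank-sum p by enumerating all group assignments
oracle_ranksum_less <- function(x, y) {
  all_v <- c(x, y)
  nx <- length(x)
  combs <- utils::combn(length(all_v), nx)
  w_obs <- sum(rank(all_v)[seq_len(nx)])
  w_all <- apply(combs, 2, function(ix) sum(rank(all_v)[ix]))
  mean(w_all <= w_obs)  # alternative: x shifted downward
}
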
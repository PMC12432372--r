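# Independent reference implementations used as oracles. Deliberately naive:
# plain loops, probabilities by explicit summation of hypergeometric terms,
# no code shared with the package internals.

# hypergeometric upper tail P(X >= a) for the 2x2 table (a b / c d),
# X ~ Hyper(m = a + c, n = b + d, k = a + b), by direct summation
oracle_fisher_tail <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  xs <- a:min(k, m)
  xs <- xs[k - xs <= n]
  if (length(xs) == 0L) return(0)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# Brute-force kataegis caller for a single sample: enumerate every
# 10-mutation window, exact tail by summation, pool overlapping candidate
# chains and split them back into maximal passing prefixes.
oracle_kataegis <- function(pos_by_chrom, window_n = 10L, max_span = 10000L,
                            threshold = 1e-4) {
  all_d <- unlist(lapply(pos_by_chrom, function(p) diff(sort(p))))
  if (length(all_d) == 0L) return(NULL)
  adl <- mean(all_d) / 10
  tot_below <- 0L; tot_above <- 0L
  for (d in all_d) {
    if (d < adl) tot_below <- tot_below + 1L else tot_above <- tot_above + 1L
  }
  events <- list()
  for (cn in names(pos_by_chrom)) {
    p <- sort(pos_by_chrom[[cn]])
    if (length(p) < window_n) next
    cand <- list()
    for (i in 1:(length(p) - window_n + 1L)) {
      j <- i + window_n - 1L
      if (p[j] - p[i] > max_span) next
      a <- 0L
      for (q in i:(j - 1L)) if (p[q + 1L] - p[q] < adl) a <- a + 1L
      b <- (window_n - 1L) - a
      pv <- oracle_fisher_tail(a, b, tot_below, tot_above)
      if (pv < threshold) cand[[length(cand) + 1L]] <- c(i, j, pv)
    }
    if (length(cand) == 0L) next
    region_p <- function(i, j) {
      a <- 0L
      for (q in i:(j - 1L)) if (p[q + 1L] - p[q] < adl) a <- a + 1L
      oracle_fisher_tail(a, (j - i) - a, tot_below, tot_above)
    }
    # group candidates into transitive overlap chains
    chains <- list(); cur <- list(cand[[1L]])
    if (length(cand) > 1L) for (k in 2:length(cand)) {
      reach <- max(vapply(cur, function(x) x[2], numeric(1)))
      if (cand[[k]][1] <= reach) cur[[length(cur) + 1L]] <- cand[[k]]
      else { chains[[length(chains) + 1L]] <- cur; cur <- list(cand[[k]]) }
    }
    chains[[length(chains) + 1L]] <- cur
    for (chain in chains) {
      j <- 1L
      while (j <= length(chain)) {
        lo <- chain[[j]][1]; hi <- chain[[j]][2]
        pv <- region_p(lo, hi)
        jj <- j
        while (jj < length(chain)) {
          nxt <- chain[[jj + 1L]]
          if (nxt[1] > hi) break
          try_hi <- max(hi, nxt[2])
          try_p <- region_p(lo, try_hi)
          if (try_p < threshold) { hi <- try_hi; pv <- try_p; jj <- jj + 1L }
          else break
        }
        events[[length(events) + 1L]] <-
          data.frame(chrom = cn, start = as.integer(p[lo]),
                     end = as.integer(p[hi]),
                     n_mut = as.integer(hi - lo + 1), p = pv)
        j <- jj + 1L
      }
    }
  }
  if (length(events) == 0L) return(NULL)
  ev <- do.call(rbind, events)
  ev[order(ev$chrom, ev$start), , drop = FALSE]
}

# NNLS on a 2-column design by dense grid refinement around the best point
oracle_nnls2 <- function(A, b, hi = NULL) {
  if (is.null(hi)) hi <- 2 * sum(abs(b))
  best <- c(0, 0)
  width <- hi
  center <- c(hi / 2, hi / 2)
  for (round in 1:40) {
    g1 <- pmax(seq(center[1] - width / 2, center[1] + width / 2,
                   length.out = 21), 0)
    g2 <- pmax(seq(center[2] - width / 2, center[2] + width / 2,
                   length.out = 21), 0)
    obj <- outer(g1, g2, Vectorize(function(x, y) {
      sum((A %*% c(x, y) - b)^2)
    }))
    ix <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    center <- c(g1[ix[1]], g2[ix[2]])
    width <- width / 5
  }
  center
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(vals), n)
  obs <- sum(rank(vals)[seq_len(n)])
  stats <- apply(combs, 2L, function(ii) sum(rank(vals)[ii]))
  mu <- n * (length(vals) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# uniform background positions with optional tight planted runs
make_positions <- function(n_bg, genome_len, runs = NULL) {
  pos <- sort(sample.int(genome_len, n_bg))
  planted <- integer(0)
  if (!is.null(runs)) for (r in runs) {
    # r: c(start, n, spacing)
    pr <- r[1] + (seq_len(r[2]) - 1L) * r[3]
    planted <- c(planted, pr)
    pos <- sort(unique(c(pos, pr)))
  }
  list(pos = pos, planted = planted)
}

# mutation records drawn from a signature's channels (contexts consistent
# with the channel, stored on the pyrimidine strand)
make_signature_mutations <- function(n, signature, sample = "S1",
                                     chrom = "chr1", start = 1000L,
                                     spacing = 5L) {
  ch <- sbs96_channels()
  ids <- sample.int(96L, n, replace = TRUE, prob = signature)
  data.frame(sample = sample, chrom = chrom,
             pos = start + (seq_len(n) - 1L) * spacing,
             ref = substr(ch[ids], 3L, 3L),
             alt = substr(ch[ids], 5L, 5L),
             context = paste0(substr(ch[ids], 1L, 1L), substr(ch[ids], 3L, 3L),
                              substr(ch[ids], 7L, 7L)),
             stringsAsFactors = FALSE)
}
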
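#' Abnormal distance line (ADL) for one sample
#'
#' The ADL is one-tenth of the sample's mean adjacent intermutation distance.
#' Distances are computed between consecutive mutations within each
#' chromosome (never across chromosome boundaries) and pooled genome-wide.
#' Distances strictly below the ADL count as "below"; a distance exactly
#' equal to the ADL counts as "above" (conservative toward fewer calls).
#'
#' @param muts mutation records of a single sample (`chrom`, `pos`).
#' @return list with `sample`, `mean_imd`, `adl`, `n_below`, `n_above`, and
#'   `distances` (per-chromosome list of adjacent distances).
#' @export
#' @examples
#' m <- data.frame(sample = "S1", chrom = "chr1", pos = c(0, 100, 300, 600))
#' compute_adl(m)$adl  # mean distance 200 -> ADL 20
compute_adl <- function(muts) {
  if (length(unique(muts$sample)) > 1L) {
    stop("compute_adl expects mutations of a single sample")
  }
  d_by_chrom <- lapply(split(muts$pos, muts$chrom), function(p) {
    p <- sort(p)
    if (length(p) < 2L) numeric(0) else diff(p)
  })
  d <- unlist(d_by_chrom, use.names = FALSE)
  if (length(d) == 0L) stop("insufficient mutations for ADL")
  adl <- mean(d) / 10
  list(sample = if (nrow(muts)) muts$sample[1] else NA_character_,
       mean_imd = mean(d), adl = adl,
       n_below = sum(d < adl), n_above = sum(d >= adl),
       distances = d_by_chrom)
}

#' One-tailed Fisher's exact test for below-ADL enrichment
#'
#' Exact hypergeometric upper-tail probability of observing at least `a`
#' below-ADL distances in the window, given the table margins: with
#' `X ~ Hypergeometric(a + c, b + d, a + b)`, returns `P(X >= a)`.
#'
#' @param a,b below-/above-ADL distance counts in the window.
#' @param c,d below-/above-ADL counts in the comparison background.
#' @return the one-tailed p-value.
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Scan one sample for clustered-mutation candidate windows
#'
#' Slides over every run of `window_n` consecutive same-chromosome mutations
#' whose span (first to last member position, inclusive) is at most
#' `max_span_bp`. Each window's `window_n - 1` internal adjacent distances
#' are split at the ADL and compared against the sample-wide below/above
#' counts by the one-tailed Fisher test (enrichment of below-ADL distances).
#' By default the background includes the window's own distances, i.e. the
#' overall distribution observed across all mutations in the sample;
#' `background = "exclude"` subtracts them.
#'
#' @param muts mutation records of one sample.
#' @param adl result of [compute_adl()] for the same records (computed if
#'   missing).
#' @param window_n window size in mutations.
#' @param max_span_bp maximum window span in bp.
#' @param background `"include"` or `"exclude"` the window's own distances
#'   from the comparison counts.
#' @return data.frame of candidate windows: `sample`, `chrom`, `start_idx`,
#'   `end_idx` (indices into the chromosome's sorted positions), `start`,
#'   `end`, `n_below`, `n_above`, `p`. Empty when the sample has fewer than
#'   `window_n` mutations on every chromosome.
#' @export
scan_windows <- function(muts, adl = NULL, window_n = 10L,
                         max_span_bp = 10000L,
                         background = c("include", "exclude")) {
  background <- match.arg(background)
  if (is.null(adl)) adl <- compute_adl(muts)
  tot_below <- adl$n_below; tot_above <- adl$n_above
  out <- list()
  for (cn in names(adl$distances)) {
    p <- sort(muts$pos[muts$chrom == cn])
    n <- length(p)
    if (n < window_n) next
    d <- diff(p)
    below <- as.integer(d < adl$adl)
    cum <- c(0L, cumsum(below))
    i <- seq_len(n - window_n + 1L)
    span <- p[i + window_n - 1L] - p[i]
    keep <- span <= max_span_bp
    if (!any(keep)) next
    i <- i[keep]
    a <- cum[i + window_n - 1L] - cum[i]          # below in the 9 distances
    b <- (window_n - 1L) - a
    if (background == "include") {
      cc <- tot_below; dd <- tot_above
    } else {
      cc <- tot_below - a; dd <- tot_above - b
    }
    pv <- fisher_one_tailed(a, b, cc, dd)
    out[[cn]] <- data.frame(sample = adl$sample, chrom = cn,
                            start_idx = i, end_idx = i + window_n - 1L,
                            start = p[i], end = p[i + window_n - 1L],
                            n_below = a, n_above = b, p = pv,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(sample = character(), chrom = character(),
                      start_idx = integer(), end_idx = integer(),
                      start = integer(), end = integer(),
                      n_below = integer(), n_above = integer(),
                      p = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge overlapping candidate windows into kataegis events
#'
#' Same-chromosome candidates that overlap (share at least one bp or one
#' member mutation) are pooled transitively, left to right. The pooled
#' region's Fisher p is recomputed on its full set of adjacent distances
#' (first to last member); the merge is kept only if the recomputed p stays
#' below `threshold`. When a pooled chain fails, it is split back greedily
#' into maximal passing prefixes. Output events never overlap.
#'
#' @param candidates output of [scan_windows()], already filtered to
#'   `p < threshold`.
#' @param muts the same sample's mutation records.
#' @param adl the sample's [compute_adl()] result.
#' @param threshold calling threshold on the Fisher p (default 1e-4).
#' @param background as in [scan_windows()].
#' @return data.frame of events: `sample`, `chrom`, `start`, `end`,
#'   `start_idx`, `end_idx`, `n_mut`, `p`.
#' @export
merge_events <- function(candidates, muts, adl, threshold = 1e-4,
                         background = c("include", "exclude")) {
  background <- match.arg(background)
  empty <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      start_idx = integer(), end_idx = integer(),
                      n_mut = integer(), p = numeric())
  if (nrow(candidates) == 0L) return(empty)
  stopifnot(all(candidates$p < threshold))
  out <- list()
  for (cn in unique(candidates$chrom)) {
    cand <- candidates[candidates$chrom == cn, , drop = FALSE]
    cand <- cand[order(cand$start_idx), , drop = FALSE]
    p_chr <- sort(muts$pos[muts$chrom == cn])
    pooled_p <- function(i0, i1) {
      d <- diff(p_chr[i0:i1])
      a <- sum(d < adl$adl); b <- length(d) - a
      if (background == "include") {
        fisher_one_tailed(a, b, adl$n_below, adl$n_above)
      } else {
        fisher_one_tailed(a, b, adl$n_below - a, adl$n_above - b)
      }
    }
    # transitive chains of overlapping candidates (overlap = shared bp or
    # shared member; with stride-1 windows, index overlap implies both)
    chain_id <- cumsum(c(1L, cand$start_idx[-1L] >
                           cummax(cand$end_idx)[-nrow(cand)]))
    for (ch in unique(chain_id)) {
      cc <- cand[chain_id == ch, , drop = FALSE]
      j <- 1L
      while (j <= nrow(cc)) {
        i0 <- cc$start_idx[j]; i1 <- cc$end_idx[j]
        last_pass <- c(i0, i1, pooled_p(i0, i1))
        jj <- j
        while (jj < nrow(cc)) {
          nxt <- jj + 1L
          if (cc$start_idx[nxt] > last_pass[2]) break  # no longer overlapping
          cand_i1 <- max(last_pass[2], cc$end_idx[nxt])
          pv <- pooled_p(last_pass[1], cand_i1)
          if (pv < threshold) {
            last_pass <- c(last_pass[1], cand_i1, pv)
            jj <- nxt
          } else break
        }
        out[[length(out) + 1L]] <- data.frame(
          sample = cc$sample[1], chrom = cn,
          start = p_chr[last_pass[1]], end = p_chr[last_pass[2]],
          start_idx = as.integer(last_pass[1]),
          end_idx = as.integer(last_pass[2]),
          n_mut = as.integer(last_pass[2] - last_pass[1] + 1L),
          p = last_pass[3], stringsAsFactors = FALSE)
        j <- jj + 1L
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect kataegis events in a cohort
#'
#' Per sample: compute the ADL, scan all 10-mutation windows within 10 kb,
#' keep windows with one-tailed Fisher `p < threshold`, and merge overlapping
#' candidates. Samples with fewer than two mutations, or fewer than
#' `window_n` on every chromosome, yield no events.
#'
#' @param muts a `mutation_set` data.frame for the whole cohort.
#' @param threshold calling threshold (default 1e-4).
#' @inheritParams scan_windows
#' @return data.frame of events across samples (see [merge_events()]).
#' @export
detect_kataegis <- function(muts, threshold = 1e-4, window_n = 10L,
                            max_span_bp = 10000L,
                            background = c("include", "exclude")) {
  background <- match.arg(background)
  res <- lapply(split(seq_len(nrow(muts)), muts$sample), function(ii) {
    ms <- muts[ii, , drop = FALSE]
    if (nrow(ms) < 2L) return(NULL)
    adl <- compute_adl(ms)
    cand <- scan_windows(ms, adl, window_n = window_n,
                         max_span_bp = max_span_bp, background = background)
    cand <- cand[cand$p < threshold, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    merge_events(cand, ms, adl, threshold = threshold,
                 background = background)
  })
  res <- do.call(rbind, Filter(Negate(is.null), unname(res)))
  if (is.null(res)) {
    res <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      start_idx = integer(), end_idx = integer(),
                      n_mut = integer(), p = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Decompose kataegis events into K1/K2 contributions
#'
#' Builds each event's 96-channel catalog from its member mutations and
#' refits it against the fixed K1/K2 profiles by NNLS
#' (via [refit_exposures()]). The K1 contribution is
#' `K1 / (K1 + K2)`; events with contribution > 0.5 are labeled
#' `K1-dominant`, otherwise `K2-dominant`. Events whose exposures are both
#' zero are flagged `degenerate` with contribution `NA`.
#'
#' @param events event table from [detect_kataegis()].
#' @param muts the cohort `mutation_set` (members are recovered from each
#'   event's sample/chromosome/position span; contexts required).
#' @param signatures a two-column [signature_set()] ordered (K1, K2).
#' @return `events` with columns `k1_contribution`, `dominance`,
#'   `degenerate` appended.
#' @export
decompose_events <- function(events, muts,
                             signatures = builtin_signatures(c("K1.like",
                                                               "K2.like"))) {
  if (ncol(signatures) != 2L) stop("signatures must hold exactly K1 and K2")
  k1 <- numeric(nrow(events)); degen <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    mem <- muts[muts$sample == events$sample[i] &
                  muts$chrom == events$chrom[i] &
                  muts$pos >= events$start[i] &
                  muts$pos <= events$end[i], , drop = FALSE]
    cat96 <- build_catalog(mem, samples = events$sample[i])
    expo <- refit_exposures(cat96, signatures)
    tot <- sum(expo)
    if (tot <= 0) { degen[i] <- TRUE; k1[i] <- NA_real_ }
    else k1[i] <- expo[1, 1] / tot
  }
  events$k1_contribution <- k1
  events$dominance <- ifelse(is.na(k1), NA_character_,
                             ifelse(k1 > 0.5, "K1-dominant", "K2-dominant"))
  events$degenerate <- degen
  events
}

#' Per-sample kataegis summaries and the K1-high/low split
#'
#' The per-sample K1 contribution is the unweighted mean over that sample's
#' events. Samples with at least one event are split at the cohort median of
#' these means: strictly above the median is `K1-high`, at or below is
#' `K1-low` (so a single-sample cohort is `K1-low`). Samples without events
#' are labeled `no-kataegis` and excluded from the median.
#'
#' @param events decomposed event table (needs `k1_contribution`).
#' @param samples character vector of all cohort sample ids (so event-free
#'   samples appear in the output).
#' @return data.frame: `sample`, `n_events`, `mean_k1`, `group`.
#' @export
summarize_samples <- function(events, samples = unique(events$sample)) {
  mean_k1 <- vapply(samples, function(s) {
    k <- events$k1_contribution[events$sample == s]
    k <- k[!is.na(k)]
    if (length(k)) mean(k) else NA_real_
  }, numeric(1))
  n_ev <- vapply(samples, function(s) sum(events$sample == s), integer(1))
  med <- stats::median(mean_k1[n_ev > 0], na.rm = TRUE)
  group <- ifelse(n_ev == 0L, "no-kataegis",
                  ifelse(mean_k1 > med, "K1-high", "K1-low"))
  data.frame(sample = samples, n_events = n_ev, mean_k1 = unname(mean_k1),
             group = unname(group), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a BED file into GRanges with validation
#'
#' Accepts 3+ column BED (0-based half-open); column 4, when present, is the
#' interval name (used for Ig subclasses V / S / J&C). Malformed lines are
#' reported with their line numbers.
#'
#' @param path BED file path.
#' @return a `GRanges` (1-based closed intervals) with a `name` column.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- vapply(fields, function(f) {
    length(f) < 3L || is.na(suppressWarnings(as.numeric(f[2]))) ||
      is.na(suppressWarnings(as.numeric(f[3]))) ||
      as.numeric(f[2]) < 0 || as.numeric(f[3]) <= as.numeric(f[2])
  }, logical(1))
  if (any(bad)) {
    stop("malformed BED line(s) in ", path, " at line(s): ",
         paste(utils::head(lineno[bad], 10L), collapse = ", "))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  end <- vapply(fields, function(f) as.numeric(f[3]), numeric(1))
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[4] else ".",
                 character(1))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end),
                         name = name)
}

#' Annotate kataegis events by genomic region class
#'
#' Events overlapping an Ig interval inherit its subclass (`Ig:V`, `Ig:S`,
#' `Ig:J&C`; ties broken by largest overlap). All other events are classed by
#' the distance from the event midpoint to the nearest TSS anchor:
#' `non-Ig TSS-proximal` when <= `proximal_bp` (2 kb, boundary inclusive),
#' else `non-Ig TSS-distal`.
#'
#' @param events event table.
#' @param ig GRanges (or BED path) of Ig segments, names in {V, S, J&C}.
#' @param tss GRanges (or BED path) of single-position TSS anchors.
#' @param proximal_bp TSS-proximal cutoff in bp.
#' @return `events` with a `region_class` column appended.
#' @export
annotate_events <- function(events, ig, tss, proximal_bp = 2000L) {
  if (is.character(ig)) ig <- read_bed(ig)
  if (is.character(tss)) tss <- read_bed(tss)
  if (nrow(events) == 0L) {
    events$region_class <- character(0)
    return(events)
  }
  ev <- GenomicRanges::GRanges(events$chrom,
                               IRanges::IRanges(events$start, events$end))
  cls <- rep(NA_character_, nrow(events))
  hits <- GenomicRanges::findOverlaps(ev, ig)
  if (length(hits)) {
    ovl <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(ev)[S4Vectors::queryHits(hits)],
      IRanges::ranges(ig)[S4Vectors::subjectHits(hits)]))
    best <- tapply(seq_along(hits), S4Vectors::queryHits(hits),
                   function(ii) ii[which.max(ovl[ii])])
    qh <- as.integer(names(best))
    cls[qh] <- paste0("Ig:",
                      S4Vectors::mcols(ig)$name[
                        S4Vectors::subjectHits(hits)[unlist(best)]])
  }
  rest <- which(is.na(cls))
  if (length(rest)) {
    # distance is plain position arithmetic |midpoint - anchor|, not the
    # gap-based GRanges distance (which is one less between disjoint points)
    tss_chrom <- as.character(GenomicRanges::seqnames(tss))
    tss_pos <- GenomicRanges::start(tss)
    mid <- floor((events$start[rest] + events$end[rest]) / 2)
    dist <- vapply(seq_along(rest), function(i) {
      same <- tss_chrom == events$chrom[rest[i]]
      if (!any(same)) return(Inf)
      min(abs(tss_pos[same] - mid[i]))
    }, numeric(1))
    cls[rest] <- ifelse(dist <= proximal_bp, "non-Ig TSS-proximal",
                        "non-Ig TSS-distal")
  }
  events$region_class <- cls
  events
}
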
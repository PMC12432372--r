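test_that("the ADL is one-tenth of the pooled mean adjacent distance", {
  m <- data.frame(sample = "S1", chrom = "chr1", pos = c(0, 100, 300, 600))
  a <- compute_adl(m)
  expect_equal(a$mean_imd, 200)
  expect_equal(a$adl, 20)
  # distances never span chromosomes
  m2 <- data.frame(sample = "S1", chrom = rep(c("chr1", "chr2"), each = 2),
                   pos = c(0, 1000, 0, 1000))
  a2 <- compute_adl(m2)
  expect_equal(a2$adl, 100)
  expect_identical(a2$n_below + a2$n_above, 2L)
  expect_error(compute_adl(data.frame(sample = "S1", chrom = "chr1",
                                      pos = 5)),
               "insufficient")
})

test_that("the ADL of uniform mutations approaches spacing / 10", {
  set.seed(3)
  m <- data.frame(sample = "S1", chrom = "chr1",
                  pos = sort(sample.int(1e8, 10000)))
  expect_equal(compute_adl(m)$adl, 1000, tolerance = 0.05)
})

test_that("the one-tailed Fisher tail equals explicit hypergeometric summation", {
  tables <- list(c(9, 0, 0, 9000), c(5, 4, 100, 900), c(9, 0, 180, 1800),
                 c(3, 6, 600, 1200), c(0, 9, 50, 500))
  for (tb in tables) {
    expect_equal(fisher_one_tailed(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher_tail(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
  # no below-ADL distances in the window: p = 1 in the enrichment direction
  expect_equal(fisher_one_tailed(0, 9, 100, 900), 1)
  # a window at the margins' expectation is not significant
  expect_gt(fisher_one_tailed(1, 8, 100, 800), 0.05)
  expect_error(fisher_one_tailed(-1, 1, 1, 1), "non-negative")
})

test_that("window scanning respects the span rule and flags tight runs", {
  set.seed(11)
  bg <- sort(sample.int(2e6, 1000))
  run <- 500000 + (0:9)  # 10 mutations 1 bp apart
  m <- data.frame(sample = "S1", chrom = "chr1",
                  pos = sort(unique(c(bg, run))))
  adl <- compute_adl(m)
  w <- scan_windows(m, adl)
  hit <- w[w$start >= 499000 & w$end <= 501100, ]
  expect_gt(nrow(hit), 0)
  expect_lt(min(hit$p), 1e-4)
  # equally spaced sample: every window ratio equals the sample ratio; p = 1
  meq <- data.frame(sample = "S1", chrom = "chr1", pos = seq(0, 4900, by = 100))
  weq <- scan_windows(meq, compute_adl(meq))
  expect_true(all(weq$p >= 0.5))
  # 10 mutations spanning 10,001 bp form no window
  wide <- data.frame(sample = "S1", chrom = "chr1",
                     pos = c(0, 1:8 * 1000, 10001))
  expect_identical(nrow(scan_windows(wide, compute_adl(wide))), 0L)
})

test_that("overlapping candidates merge when the pooled region stays significant", {
  set.seed(5)
  bg <- sort(sample.int(5e6, 800))
  runA <- 1e6 + (0:10) * 3        # 11 tight mutations
  runB <- 3e6 + (0:9) * 4         # 10 tight mutations, 2 Mb away
  m <- data.frame(sample = "S1", chrom = "chr1",
                  pos = sort(unique(c(bg, runA, runB))))
  adl <- compute_adl(m)
  cand <- scan_windows(m, adl)
  cand <- cand[cand$p < 1e-4, ]
  ev <- merge_events(cand, m, adl)
  near_a <- ev[abs(ev$start - 1e6) < 5000, ]
  near_b <- ev[abs(ev$start - 3e6) < 5000, ]
  expect_identical(nrow(near_a), 1L)
  expect_identical(nrow(near_b), 1L)
  expect_gte(near_a$n_mut, 11L)
  expect_lt(near_a$p, 1e-4)
  # disjoint clusters stay separate events
  expect_gte(nrow(ev), 2L)
  # empty candidate list -> empty event list
  expect_identical(nrow(merge_events(cand[0, ], m, adl)), 0L)
})

test_that("detection is invariant to input record order", {
  set.seed(23)
  bg <- sort(sample.int(2e6, 1500))
  run <- 7e5 + (0:11) * 5
  m <- as_mutation_set(data.frame(sample = "S1", chrom = "chr1",
                                  pos = sort(unique(c(bg, run))),
                                  ref = "C", alt = "T"))
  ev1 <- detect_kataegis(m)
  shuf <- m[sample(nrow(m)), ]
  ev2 <- detect_kataegis(as_mutation_set(shuf))
  expect_equal(ev1, ev2)
  expect_gt(nrow(ev1), 0)
})

test_that("K1/K2 decomposition reflects the generating fixture", {
  k12 <- builtin_signatures(c("K1.like", "K2.like"))
  set.seed(13)
  mk_event <- function(sig_name, n = 60) {
    mm <- make_signature_mutations(n, k12[, sig_name])
    ev <- data.frame(sample = "S1", chrom = "chr1", start = min(mm$pos),
                     end = max(mm$pos), start_idx = 1L, end_idx = n,
                     n_mut = n, p = 1e-9)
    decompose_events(ev, as_mutation_set(mm), k12)
  }
  pure1 <- mk_event("K1.like")
  expect_equal(pure1$k1_contribution, 1.0)
  expect_identical(pure1$dominance, "K1-dominant")
  pure2 <- mk_event("K2.like")
  expect_equal(pure2$k1_contribution, 0.0)
  expect_identical(pure2$dominance, "K2-dominant")
  # 50/50 mixture of the orthogonal fixtures
  mixed <- replicate(40, {
    mm <- make_signature_mutations(60, 0.5 * k12[, 1] + 0.5 * k12[, 2])
    ev <- data.frame(sample = "S1", chrom = "chr1", start = min(mm$pos),
                     end = max(mm$pos), start_idx = 1L, end_idx = 60L,
                     n_mut = 60L, p = 1e-9)
    decompose_events(ev, as_mutation_set(mm), k12)$k1_contribution
  })
  expect_equal(mean(mixed), 0.5, tolerance = 0.05)
})

test_that("per-sample summaries split the cohort at the median K1 contribution", {
  ev <- data.frame(sample = c("A", "A", "B", "C", "D"),
                   k1_contribution = c(1.0, 0.0, 0.2, 0.6, 0.8))
  s <- summarize_samples(ev, samples = c("A", "B", "C", "D", "E"))
  expect_equal(s$mean_k1[s$sample == "A"], 0.5)
  # cohort means {0.5, 0.2, 0.6, 0.8}: median 0.55; above -> K1-high
  expect_identical(s$group[s$sample %in% c("C", "D")],
                   rep("K1-high", 2))
  expect_identical(s$group[s$sample %in% c("A", "B")],
                   rep("K1-low", 2))
  expect_identical(s$group[s$sample == "E"], "no-kataegis")
  expect_true(is.na(s$mean_k1[s$sample == "E"]))
  # single-sample cohort sits at its own median: K1-low by convention
  s1 <- summarize_samples(ev[1:2, ], samples = "A")
  expect_identical(s1$group, "K1-low")
})

test_that("events are classed by Ig overlap and TSS distance with a 2 kb boundary", {
  dir <- withr::local_tempdir()
  ig <- file.path(dir, "ig.bed")
  tss <- file.path(dir, "tss.bed")
  writeLines(c("chr1\t10000\t12000\tS",
               "chr1\t20000\t25000\tV",
               "chr1\t30000\t31000\tJ&C"), ig)
  writeLines("chr1\t100000\t100001\tGENE1", tss)
  ev <- data.frame(sample = "S1", chrom = "chr1",
                   start = c(10500, 20100, 30050, 97902, 97900),
                   end = c(10900, 20200, 30100, 98102, 98100))
  # TSS anchor is 100001; the last two midpoints are 98002 (1999 bp away,
  # boundary-inclusive proximal) and 98000 (2001 bp, distal)
  out <- annotate_events(ev, ig, tss)
  expect_identical(out$region_class,
                   c("Ig:S", "Ig:V", "Ig:J&C",
                     "non-Ig TSS-proximal", "non-Ig TSS-distal"))
  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t1\t100\tok", "chr1\tx\t100"), bad)
  expect_error(read_bed(bad), "line\\(s\\): 2")
})
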
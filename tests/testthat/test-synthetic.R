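sigs <- builtin_signatures()

test_that("background mutation counts follow the requested rate and are reproducible", {
  g <- simulate_genome(c(chr1 = 3e5, chr2 = 3e5), seed = 7)
  spec <- cohort_spec(3, 1000, c(0, 0, 0, 1), seed = 21)
  m <- simulate_mutations(spec, sigs, g)
  counts <- table(m$sample)
  # Poisson(1000): each count within 5 sd of the mean
  expect_true(all(abs(counts - 1000) < 5 * sqrt(1000)))
  expect_false(any(m$planted))
  expect_true(all(m$pos[m$chrom == "chr1"] <= 3e5))
  # positions sorted within (sample, chromosome)
  by_sc <- split(m$pos, paste(m$sample, m$chrom))
  expect_true(all(vapply(by_sc, function(p) !is.unsorted(p), logical(1))))
  # fixed seed: identical output across runs
  m2 <- simulate_mutations(spec, sigs, g)
  expect_identical(m, m2)
})

test_that("planted kataegis runs appear exactly as specified", {
  g <- simulate_genome(c(chr1 = 4e5), seed = 3)
  plan <- data.frame(sample = 1, chrom = "chr1", locus = 2e5,
                     n_mutations = 15, max_span_bp = 5000,
                     source_signature = "K1.like")
  spec <- cohort_spec(1, 200, c(1, 0, 0, 0), kataegis_plan = plan, seed = 5)
  m <- simulate_mutations(spec, sigs, g)
  kat <- m[m$planted, ]
  expect_identical(nrow(kat), 15L)
  expect_true(all(kat$pos >= 2e5 & kat$pos <= 2e5 + 5000))
  expect_lte(max(kat$pos) - min(kat$pos), 5000)
  expect_true(all(kat$signature == "K1.like"))
  # locus beyond the chromosome end is an error naming the locus
  plan_bad <- transform(plan, locus = 9e5)
  spec_bad <- cohort_spec(1, 200, c(1, 0, 0, 0), kataegis_plan = plan_bad,
                          seed = 5)
  expect_error(simulate_mutations(spec_bad, sigs, g), "chr1:9e\\+05|outside")
})

test_that("generated channel frequencies converge to the generating signature", {
  g <- simulate_genome(c(chr1 = 1e6), seed = 11)
  for (sig in c("K1.like", "CpG.deamination")) {
    mix <- as.numeric(colnames(sigs) == sig)
    spec <- cohort_spec(1, 5000, mix, seed = 31)
    m <- simulate_mutations(spec, sigs, g)
    emp <- colSums(build_catalog(m))
    expect_gt(cosine_similarity(emp, sigs[, sig]), 0.95)
  }
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(0, 100, c(1, 0, 0, 0)), "n_samples")
  expect_error(cohort_spec(2, 100, c(-1, 1, 0, 0)), "non-negative")
  expect_error(cohort_spec(2, 100, c(1, 0), kataegis_plan = data.frame(x = 1)),
               "columns")
})

test_that("lesion simulation reproduces the planted enrichment structure", {
  ls <- simulate_lesions(cluster_spec(n_clusters = 3, markers_per_cluster = 40,
                                      samples_per_cluster = 40,
                                      enrichment_own = 0.9,
                                      enrichment_other = 0.05,
                                      n_null_markers = 0, seed = 2))
  expect_identical(nrow(ls$truth), 120L)
  expect_identical(nrow(ls$markers), 120L)
  # own-cluster prevalence of each cluster's markers is near 0.9
  lm <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  prev <- vapply(seq_len(nrow(ls$markers)), function(i) {
    own <- ls$truth$cluster == ls$markers$cluster[i]
    mean(lm[own, ls$markers$marker[i]] > 0)
  }, numeric(1))
  expect_equal(mean(prev), 0.9, tolerance = 0.03)
  expect_error(simulate_lesions(cluster_spec(markers_per_cluster = 0)),
               "markers_per_cluster")
  expect_error(cluster_spec(enrichment_own = 1.2), "\\[0, 1\\]")
})

test_that("under equal enrichment no marker is preferentially significant", {
  # null: own == other, so marker-cluster Fisher tests reject at ~alpha
  ls <- simulate_lesions(cluster_spec(n_clusters = 3, markers_per_cluster = 30,
                                      samples_per_cluster = 40,
                                      enrichment_own = 0.3,
                                      enrichment_other = 0.3,
                                      n_null_markers = 0, seed = 8))
  lm <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  mk <- cluster_markers(lm, ls$truth$cluster)
  # 270 (marker, cluster) tests; Fisher is conservative, so the rejection
  # rate stays at or below ~alpha (binomial 99.9% upper bound at p = 0.05)
  expect_lte(sum(mk$p <= 0.05),
             qbinom(0.999, nrow(mk), 0.05))
})

test_that("CNV gain tiers sampled above 3.7 copies always encode as score 2", {
  ls <- simulate_lesions(cluster_spec(seed = 13))
  gain <- ls$markers$marker[ls$markers$kind == "cnv_gain_peak"]
  calls <- ls$calls[ls$calls$marker %in% gain & ls$calls$kind == "cnv", ]
  cn <- as.numeric(calls$detail)
  high <- calls[cn > 3.7, ]
  expect_gt(nrow(high), 0)
  lm <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  scores <- mapply(function(s, mk) lm[s, mk], high$sample, high$marker)
  expect_true(all(scores == 2L))
})

test_that("a written cohort round-trips losslessly through the readers", {
  g <- simulate_genome(c(chr1 = 2e5), seed = 17)
  spec <- cohort_spec(3, 150, c(0.25, 0.25, 0.25, 0.25), seed = 19)
  m <- simulate_mutations(spec, sigs, g)
  ls <- simulate_lesions(cluster_spec(n_clusters = 2, markers_per_cluster = 3,
                                      samples_per_cluster = 4, seed = 1))
  outdir <- withr::local_tempdir()
  files <- write_cohort(m, ls, outdir)
  vcfs <- grep("\\.vcf$", files, value = TRUE)
  expect_length(vcfs, 3L)
  expect_true(file.exists(file.path(outdir, "lesions.tsv")))
  back <- as_mutation_set(do.call(rbind, lapply(vcfs, read_mutations_vcf)))
  expect_identical(back$pos, m$pos)
  expect_identical(back$ref, m$ref)
  expect_identical(back$alt, m$alt)
  expect_identical(back$sample, m$sample)
  expect_identical(back$context, m$context)
  lback <- read_lesions(file.path(outdir, "lesions.tsv"))
  expect_identical(lback$marker, ls$calls$marker)
  expect_identical(lback$detail, as.character(ls$calls$detail))
})

test_that("an empty sample still yields a valid header-only VCF", {
  outdir <- withr::local_tempdir()
  empty <- as_mutation_set(data.frame(
    sample = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), context = character()))
  path <- file.path(outdir, "empty.vcf")
  write_vcf <- getFromNamespace("write_vcf", "flsubtype")
  write_vcf(empty, path, sample = "S_empty")
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  expect_true(any(startsWith(lines, "#CHROM")))
  back <- read_mutations_vcf(path)
  expect_identical(nrow(back), 0L)
})
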
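boundary_markers <- data.frame(
  marker = c("GAIN", "LOSS", "MUT", "SV"),
  kind = c("cnv_gain_peak", "cnv_loss_peak", "mutation", "sv"))

test_that("lesion scores follow the printed tiers exactly", {
  cns <- c(0.79, 0.80, 1.6, 1.61, 2.39, 2.4, 3.7, 3.71)
  # at a loss peak: high-grade loss <= 0.80 -> 2; (0.80, 1.6] -> 1; else 0
  loss_calls <- data.frame(sample = sprintf("P%d", seq_along(cns)),
                           marker = "LOSS", kind = "cnv",
                           detail = as.character(cns))
  lm <- encode_lesions(loss_calls, boundary_markers,
                       samples = loss_calls$sample)
  expect_identical(unname(lm[, "LOSS"]), c(2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L))
  # at a gain peak: [2.4, 3.7] -> 1; > 3.7 -> 2; else 0
  gain_calls <- transform(loss_calls, marker = "GAIN")
  lm <- encode_lesions(gain_calls, boundary_markers,
                       samples = gain_calls$sample)
  expect_identical(unname(lm[, "GAIN"]), c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L))
  # mutation consequences and SVs
  mut_calls <- data.frame(
    sample = c("P1", "P2", "P3", "P4"), marker = "MUT", kind = "mutation",
    detail = c("nonsilent", "indel", "synonymous", "none"))
  lm <- encode_lesions(mut_calls, boundary_markers, samples = mut_calls$sample)
  expect_identical(unname(lm[, "MUT"]), c(2L, 2L, 1L, 0L))
  sv_calls <- data.frame(sample = c("P1", "P2"), marker = "SV", kind = "sv",
                         detail = c("1", "0"))
  lm <- encode_lesions(sv_calls, boundary_markers, samples = sv_calls$sample)
  expect_identical(unname(lm[, "SV"]), c(3L, 0L))
})

test_that("gains at loss peaks (and vice versa) score zero; bad input errors", {
  calls <- data.frame(sample = c("P1", "P2"), marker = c("LOSS", "GAIN"),
                      kind = "cnv", detail = c("5.0", "0.5"))
  lm <- encode_lesions(calls, boundary_markers, samples = c("P1", "P2"))
  expect_identical(sum(lm), 0L)
  expect_error(encode_lesions(
    data.frame(sample = "P1", marker = "GAIN", kind = "cnv", detail = "-1"),
    boundary_markers), "negative copy number")
  expect_error(encode_lesions(
    data.frame(sample = "P1", marker = "NOPE", kind = "sv", detail = "1"),
    boundary_markers), "missing from the marker list")
  # encoding is a pure function: identical calls -> identical matrix
  ls <- simulate_lesions(cluster_spec(seed = 3))
  m1 <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  m2 <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  expect_identical(m1, m2)
})

test_that("the cophenetic coefficient separates structure from noise", {
  # perfect two-block consensus
  block <- matrix(0, 40, 40)
  block[1:20, 1:20] <- 1
  block[21:40, 21:40] <- 1
  expect_equal(cophenetic_coefficient(block), 1.0)
  expect_equal(cophenetic_coefficient(matrix(c(1, 0.3, 0.3, 1), 2)), 1.0)
  # noise consensus scores lower than planted structure at the same size
  set.seed(4)
  noise_lab <- replicate(50, sample(1:2, 60, replace = TRUE))
  noise <- Reduce(`+`, lapply(seq_len(50), function(r) {
    outer(noise_lab[, r], noise_lab[, r], "==") * 1
  })) / 50
  diag(noise) <- 1
  struct_lab <- rep(1:2, each = 30)
  struct <- outer(struct_lab, struct_lab, "==") * 1
  expect_lt(cophenetic_coefficient(noise), cophenetic_coefficient(struct))
  expect_warning(cophenetic_coefficient(matrix(1, 5, 5)), "undefined")
})

test_that("consensus clustering recovers planted structure and is equivariant", {
  ls <- simulate_lesions(cluster_spec(n_clusters = 3, markers_per_cluster = 20,
                                      samples_per_cluster = 20, seed = 6))
  lm <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  cons <- nmf_consensus(lm, k_range = 2:4, n_runs = 30, seed = 11)
  expect_identical(cons$selected_k, 3L)
  co <- cons$consensus[["3"]]
  expect_true(all(abs(co - t(co)) < 1e-12))
  expect_true(all(diag(co) == 1))
  expect_true(all(co >= 0 & co <= 1))
  # duplicated sample blocks co-cluster perfectly
  dup <- lm[c(1:10, 1:10, 41:50), ]
  rownames(dup) <- sprintf("D%02d", 1:30)
  cons_dup <- nmf_consensus(dup, k_range = 2, n_runs = 30, seed = 2)
  expect_true(all(cons_dup$consensus[["2"]][1:20, 1:20] == 1))
  # permuting samples permutes the consensus exactly (same seed stream)
  perm <- sample(nrow(lm))
  c1 <- nmf_consensus(lm, k_range = 3, n_runs = 30, seed = 7)$consensus[["3"]]
  c2 <- nmf_consensus(lm[perm, ], k_range = 3, n_runs = 30,
                      seed = 7)$consensus[["3"]]
  expect_equal(c1[perm, perm], c2, tolerance = 1e-12)
  expect_error(nmf_consensus(matrix(1, 30, 5), k_range = 2, n_runs = 30),
               "degenerate")
})

test_that("marker discovery matches the closed-form hypergeometric case", {
  lm <- matrix(0L, 30, 2, dimnames = list(sprintf("P%02d", 1:30),
                                          c("M1", "M2")))
  labels <- rep(c(1, 2), c(10, 20))
  lm[1:10, "M1"] <- 2L   # present in all of cluster 1, absent elsewhere
  mk <- cluster_markers(lm, labels)
  row <- mk[mk$marker == "M1" & mk$cluster == 1, ]
  expect_equal(row$p, 1 / choose(30, 10), tolerance = 1e-12)
  expect_true(row$assigned)
  # marker absent everywhere: p = 1, never assigned
  rowm2 <- mk[mk$marker == "M2", ]
  expect_true(all(rowm2$p == 1) && !any(rowm2$assigned))
  # identical prevalence in all clusters: p = 1
  lm[, "M2"] <- rep(c(1L, 0L), 15)
  lm[, "M2"] <- 0L; lm[c(1:5, 11:20), "M2"] <- 1L  # 50% in both clusters
  mk2 <- cluster_markers(lm, labels)
  expect_true(all(mk2$p[mk2$marker == "M2"] == 1))
  expect_error(cluster_markers(lm, rep(1, 30)), "two clusters")
})

test_that("Fisher marker p-values agree with enumeration over small tables", {
  set.seed(9)
  for (i in 1:30) {
    n1 <- sample(3:60, 1); n2 <- sample(3:60, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    lm <- matrix(0L, n1 + n2, 1, dimnames = list(NULL, "M"))
    labels <- rep(c(1, 2), c(n1, n2))
    if (a > 0) lm[seq_len(a), 1] <- 1L
    if (b > 0) lm[n1 + seq_len(b), 1] <- 1L
    p_pkg <- cluster_markers(lm, labels)$p[1]
    # enumeration: sum of hypergeometric atoms no larger than the observed
    m <- a + b; k <- n1; N <- n1 + n2
    xs <- max(0, m - (N - k)):min(k, m)
    dens <- exp(lchoose(m, xs) + lchoose(N - m, k - xs) - lchoose(N, k))
    p_ref <- sum(dens[dens <= dens[xs == a] * (1 + 1e-7)])
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
})

test_that("new samples are assigned to the nearest centroid", {
  ls <- simulate_lesions(cluster_spec(n_clusters = 3, markers_per_cluster = 15,
                                      samples_per_cluster = 15, seed = 21))
  lm <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  labels <- ls$truth$cluster
  # every training sample reclassifies to its own label
  reclass <- vapply(seq_len(nrow(lm)), function(i) {
    classify_new_sample(lm[i, ], lm, labels)$label
  }, numeric(1))
  expect_gte(mean(reclass == labels), 0.95)
  # a centroid classifies as itself
  cen <- colMeans(lm[labels == 2, , drop = FALSE])
  expect_identical(classify_new_sample(cen, lm, labels)$label, 2L)
  # all-zero row: smallest-norm centroid, flagged
  z <- classify_new_sample(numeric(ncol(lm)), lm, labels)
  expect_true(z$low_confidence)
  expect_error(classify_new_sample(lm[1, 1:5], lm, labels), "marker")
})

test_that("lesion matrices round-trip through TSV", {
  ls <- simulate_lesions(cluster_spec(n_clusters = 2, markers_per_cluster = 5,
                                      samples_per_cluster = 6, seed = 2))
  lm <- encode_lesions(ls$calls, ls$markers, samples = ls$truth$sample)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_lesion_matrix(lm, tmp)
  back <- read_lesion_matrix(tmp)
  expect_identical(unclass(back)[, ], unclass(lm)[, ])
})
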
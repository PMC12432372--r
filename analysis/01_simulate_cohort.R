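#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic FL cohort.
#
# Builds a 40-genome cohort over a 2 x 2 Mb synthetic reference: background
# SNVs at 2,000 per genome drawn from a four-signature mixture, plus two
# planted kataegis runs per genome (12 mutations within 2 kb; K1-like at the
# first locus, K2-like at the second). Lesion calls come from the planted
# 3-cluster, 127-marker structure. Everything downstream reads the files
# written here.

suppressPackageStartupMessages(library(flsubtype))

seed <- 20240901L
outdir <- "results/cohort"
cfg <- run_config(outdir = "results", seed = seed)

sigs <- builtin_signatures()
genome <- simulate_genome(cfg$chrom_lengths, seed = seed)
plan <- do.call(rbind, lapply(seq_len(cfg$n_samples), function(s) {
  data.frame(sample = s, chrom = "chr1", locus = c(50000, 250000),
             n_mutations = 12L, max_span_bp = 2000L,
             source_signature = c("K1.like", "K2.like"))
}))
# per-sample mixture heterogeneity around the configured base weights:
# signature extraction is only identifiable when exposures vary across
# samples, as they do in real cohorts
base <- cfg$signature_mix / sum(cfg$signature_mix)
set.seed(seed + 3L)
mixm <- t(vapply(seq_len(cfg$n_samples), function(s) {
  w <- rgamma(length(base), shape = 8 * base + 0.2)
  w / sum(w)
}, numeric(length(base))))
spec <- cohort_spec(cfg$n_samples, cfg$background_rate, mixm,
                    kataegis_plan = plan, seed = seed + 1L)
muts <- simulate_mutations(spec, sigs, genome)
lesions <- simulate_lesions(cluster_spec(seed = seed + 2L))
write_cohort(muts, lesions, outdir)

message("cohort: ", length(unique(muts$sample)), " genomes, ",
        nrow(muts), " SNVs (", sum(muts$planted), " in planted kataegis), ",
        nrow(lesions$calls), " lesion calls over ",
        nrow(lesions$markers), " markers")
message("written to ", outdir)
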
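# flsubtype

Genomic characterization of follicular lymphoma (FL) cohorts from somatic
variant calls: mutational-signature analysis, kataegis detection with AID /
POLH attribution, and NMF consensus subtyping of genetic lesions. The
package is aimed at cancer-genomics analysts who have per-sample somatic SNV
calls (VCF or TSV), gene-level lesion calls (mutation consequence, absolute
copy number, SV flags), and genomic annotation (Ig segments, TSS anchors),
and want the downstream statistical layer as tested, reusable functions. A
synthetic cohort generator with planted ground truth makes every stage
testable — and demonstrable — without access to patient data.

## What it computes

**96-channel catalogs and signatures.** SNVs are classified
pyrimidine-centered into the 96 trinucleotide substitution channels
(purine-reference records folded by reverse complement). De-novo signatures
are extracted by NMF with multiplicative updates minimizing generalized
Kullback–Leibler divergence, with restart-stability (mean silhouette over
matched components) guiding the choice of rank; extracted profiles are
matched to reference signatures by cosine similarity, and per-sample
exposures are refit against fixed profiles by non-negative least squares
(Lawson–Hanson).

**Kataegis.** Per tumor, the abnormal distance line (ADL) is one tenth of
the mean adjacent intermutation distance. Every run of 10 consecutive
mutations within 10 kb is tested for enrichment of below-ADL spacings
against the sample-wide distance distribution by a one-tailed Fisher's exact
test; windows with p < 1e-4 are merged when the pooled region stays
significant. Each event's member catalog is refit against fixed K1 (AID)
and K2 (POLH) profiles; the K1 contribution `K1/(K1+K2)` labels events
K1- or K2-dominant, per-sample means split the cohort at the median into
K1-high / K1-low, and events are classed as Ig (V / S / J&C) or TSS-proximal
(≤ 2 kb) / TSS-distal.

**Genetic subtypes.** Lesion calls are encoded 0–3 (nonsilent/indel 2,
synonymous 1; high/low-grade CNV gain or loss 2/1 with the printed
copy-number tiers; SV 3) into a samples × markers matrix, clustered by NMF
consensus (Frobenius objective, 100 seeded runs per K, cophenetic
coefficient selecting K over 2..10), with cluster markers identified by
Fisher's exact tests.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions;
running the five scripts in order reproduces a complete cohort analysis
under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 40 genomes, lesions, VCFs
Rscript analysis/02_signatures.R        # catalog, extraction, refitting
Rscript analysis/03_kataegis.R          # events, K1/K2, region classes
Rscript analysis/04_subtyping.R         # lesion matrix, consensus, markers
Rscript analysis/05_report.R            # group comparisons, report.md
```

A recent run printed:

```
cohort: 40 genomes, 81108 SNVs (959 in planted kataegis), 5220 lesion calls over 127 markers
extraction: selected k = 4 (silhouettes: 2=0.95, 3=0.99, 4=0.91, 5=0.76)
  extracted       reference    cosine
1      Sig1 CpG.deamination 0.9982290
2      Sig2         K1.like 0.9971242
3      Sig3         K2.like 0.9789805
4      Sig4            flat 0.8666212
81 kataegis events across 39/40 genomes; 38 K1-dominant, 43 K2-dominant
region classes: Ig:S=38, non-Ig TSS-distal=14, non-Ig TSS-proximal=29
K1-high genomes: 19; K1-low: 20; no kataegis: 1
cophenetic by K: 2=0.999, 3=1, 4=0.999, ... 10=0.987
selected K = 3; adjusted Rand index vs planted clusters: 1
126 marker-cluster assignments at p <= 0.05
 k1_contribution_vs_region  rank-sum  p = 9.9e-15
 dominance_vs_region        Fisher    p = 5.5e-24
```

Reading it: the four generating signatures are recovered from the simulated
catalogs (cosine similarity per extracted profile); the planted kataegis
runs are found and decomposed so that K1-dominant events sit in the Ig
switch annotation while K2-dominant events sit at TSS-proximal loci (the
two group-comparison p-values quantify that contrast); and consensus
clustering of the 127-marker lesion matrix picks exactly three subtypes
that coincide with the planted clusters, with all 126 cluster-specific
markers rediscovered at p ≤ 0.05.

The same end-to-end run is available in one call as
`run_pipeline(run_config(outdir, seed = 1))`, which also writes a manifest
with MD5 checksums — reruns with the same seed are byte-identical.

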
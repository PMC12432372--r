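#!/usr/bin/env Rscript
# Stage 5 — group comparisons and the assembled report.
#
# Reproduces the cohort-level statistical readouts on the synthetic events
# (rank-sum for the continuous K1 contribution, Fisher for the dominance
# label, both contrasted by genomic region class) and renders the markdown
# report from the saved stage outputs; the report never recomputes a number.

suppressPackageStartupMessages(library(flsubtype))

ev <- read.delim("results/kataegis_events.tsv")
rows <- list()
if (nrow(ev) > 0 && "region_class" %in% names(ev)) {
  in_ig <- ifelse(startsWith(ev$region_class, "Ig"), "Ig", "non-Ig")
  ok <- !is.na(ev$k1_contribution)
  if (length(unique(in_ig[ok])) == 2) {
    rows$k1 <- cbind(variable = "k1_contribution_vs_region",
                     compare_groups(ev$k1_contribution[ok], in_ig[ok],
                                    "ranksum"))
    rows$dom <- cbind(variable = "dominance_vs_region",
                      compare_groups(ev$dominance[ok], in_ig[ok], "fisher"))
  }
}
cmp <- do.call(rbind, rows)
if (!is.null(cmp)) {
  write.table(cmp, "results/group_comparisons.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  print(cmp, row.names = FALSE)
}

path <- render_report("results")
message("report written to ", path)
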
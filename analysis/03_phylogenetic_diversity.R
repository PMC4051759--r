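#!/usr/bin/env Rscript

## Phylogenetic and trait diversity: mean pairwise distance of the liana
## and tree groups and their standardized effect sizes (SES_MPD, and
## SES_MTD per trait) under the label-shuffling null with 999
## randomizations.  Reads the tables written by 02 (the pipeline computes
## all three stages together) and reports the diversity block.

suppressMessages(library(lianevol))

ses_tab <- read.csv("results/ses.csv")
cat("SES of mean pairwise phylogenetic distance (pooled",
    sum(ses_tab$n[ses_tab$metric == "MPD"]), "species):\n")
print(ses_tab[ses_tab$metric == "MPD",
              c("group", "n", "obs", "z", "p")], digits = 4)

cat("\nSES of mean pairwise trait distance, per trait:\n")
print(ses_tab[grepl("^MTD", ses_tab$metric),
              c("group", "metric", "n", "obs", "z", "p")], digits = 4)

cat("\ninterpretation: p > 0.95 = evenness (species less related/",
    "similar than chance), p < 0.05 = clustering\n")
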
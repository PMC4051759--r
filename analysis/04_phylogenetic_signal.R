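#!/usr/bin/env Rscript

## Phylogenetic signal: Blomberg's K (permutation test on the variance of
## standardized independent contrasts, 1000 randomizations) and Pagel's
## lambda (likelihood ratio test against lambda = 1) for each trait and
## growth form, on trees pruned per trait/group.  Reads the signal table
## written by 02 and summarizes it.

suppressMessages(library(lianevol))

sig <- read.csv("results/signal.csv")
cat("phylogenetic signal per trait and growth form:\n")
print(sig[, c("trait", "group", "K", "p_K", "lambda", "p_lambda", "n")],
      digits = 3)

cat("\nsignificant K (p < 0.05):",
    sum(sig$p_K < 0.05), "of", nrow(sig), "analyses\n")
cat("lambda at the upper bracket (boundary = upper):",
    sum(sig$boundary == "upper"), "of", nrow(sig), "\n")
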
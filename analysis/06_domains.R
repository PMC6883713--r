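#!/usr/bin/env Rscript
# Stage 6: exon-to-domain assignment. Exon GC should track isochore GC;
# AT exons should concentrate in LADs (the lowest-GC isochore blocks);
# individual isochores/TADs should be dominated by one exon class.

suppressMessages(library(gcatex))

bundle <- read_bundle("results/bundle")
labels <- read.delim("results/exon_labels.tsv")
ids <- labels$exon_id[labels$label %in% c("GC", "AT")]
ex <- bundle$exons[bundle$exons$exon_id %in% ids, ]

for (kind in c("isochore", "TAD", "LAD")) {
  asg <- assign_domains(ex, bundle$domains, kind = kind)
  cnt <- domain_exon_counts(labels, asg,
                            bundle$domains[bundle$domains$kind == kind, ])
  write.table(asg, paste0("results/assignment_", kind, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cnt, paste0("results/domain_counts_", kind, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  kept <- cnt[cnt$passes_min_filter, ]
  cat(sprintf("%s: %d domains pass the >=5-exon filter; %d GC-dominated, %d AT-dominated\n",
              kind, nrow(kept), sum(kept$n_gc_exons > kept$n_at_exons),
              sum(kept$n_at_exons > kept$n_gc_exons)))
}

asg_iso <- assign_domains(ex, bundle$domains, kind = "isochore")
dgc <- bundle$domains$gc_percent[match(asg_iso$domain_id,
                                       bundle$domains$domain_id)]
egc <- base_set_percent(extract_sequence(bundle$genome, ex$chrom, ex$start,
                                         ex$end, ex$strand))
cat(sprintf("exon GC ~ isochore GC: Pearson r = %.3f\n",
            exon_domain_gc_correlation(egc, dgc)))

asg_lad <- assign_domains(ex, bundle$domains, kind = "LAD")
lp <- class_proportion_in_kind(labels[labels$exon_id %in% ids, ], asg_lad)
asg_tad <- assign_domains(ex, bundle$domains, kind = "TAD")
tp <- class_proportion_in_kind(labels[labels$exon_id %in% ids, ], asg_tad)
write.table(
  data.frame(kind = c("LAD", "LAD", "TAD", "TAD"),
             class = c("GC", "AT", "GC", "AT"),
             percent_inside = c(lp[["GC"]], lp[["AT"]], tp[["GC"]], tp[["AT"]])),
  "results/domain_proportions.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("inside LADs: %.1f %% of AT exons vs %.1f %% of GC exons\n",
            lp[["AT"]], lp[["GC"]]))
cat(sprintf("inside TADs: %.1f %% of AT exons vs %.1f %% of GC exons\n",
            tp[["AT"]], tp[["GC"]]))
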
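#!/usr/bin/env Rscript
# Stage 5: coverage metaprofiles and CLIP positional maps. Nucleosome-like
# coverage should be enriched on GC exons (positive GC-AT ratio); the CLIP
# peak proportion should dominate upstream of AT exons, where the planted
# U2AF2-like binding sites sit.

suppressMessages(library(gcatex))

bundle <- read_bundle("results/bundle")
labels <- read.delim("results/exon_labels.tsv")
gc_ids <- labels$exon_id[labels$label == "GC"]
at_ids <- labels$exon_id[labels$label == "AT"]

mc_gc <- mean_coverage(exon_center_windows(
  bundle$exons[bundle$exons$exon_id %in% gc_ids, ]), bundle$coverage)
mc_at <- mean_coverage(exon_center_windows(
  bundle$exons[bundle$exons$exon_id %in% at_ids, ]), bundle$coverage)
ratio <- gc_at_ratio(mc_gc$group_mean, mc_at$group_mean)
write.table(
  data.frame(group = c("GC", "AT"),
             mean_coverage = c(mc_gc$group_mean, mc_at$group_mean),
             gc_at_ratio = ratio),
  "results/coverage_groups.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("exon-window mean coverage: GC %.2f, AT %.2f, GC-AT ratio %.3f\n",
            mc_gc$group_mean, mc_at$group_mean, ratio))

spec <- metaplot_spec("internal_exons")
prof <- binned_profile(gene_region_list(bundle$exons, bundle$genes, spec),
                       bundle$coverage, spec)
write.table(as.data.frame(prof), "results/metaprofile_internal_exons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("internal-exon metaprofile: %d bins (first 199 dropped), mean %.2f\n",
            nrow(prof), mean(prof$value)))

cl <- chrom_lengths(bundle$genome)
for (set in list(list("GC", gc_ids), list("AT", at_ids))) {
  p <- clip_positional_proportion(
    bundle$exons[bundle$exons$exon_id %in% set[[2]], ], bundle$peaks, cl,
    anchor = "3ss")
  write.table(cbind(set = set[[1]], as.data.frame(p)),
              paste0("results/clip_", tolower(set[[1]]), ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  up <- p$offset < 0
  cat(sprintf("CLIP proportion upstream of %s exons: mean %.3f, max %.3f\n",
              set[[1]], mean(p$proportion[up]), max(p$proportion[up])))
}
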
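#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study genome (seed 1) and write it out.
# The bundle plants the compositional structure the later stages must
# recover: isochore-level GC tiers, GC/AT-context genes, decoy splice
# signals upstream of AT-class exons, foldable 5' ss flanks on GC-class
# exons, CLIP-like peaks and nucleosome-like coverage.

suppressMessages(library(gcatex))

bundle <- simulate_bundle(simulation_config(seed = 1))
write_bundle(bundle, "results/bundle")
print(bundle)

ex_gc <- base_set_percent(extract_sequence(
  bundle$genome, bundle$exons$chrom, bundle$exons$start, bundle$exons$end,
  bundle$exons$strand))
gene_gc <- bundle$genes$gc_percent[match(bundle$exons$gene_id,
                                         bundle$genes$gene_id)]
mfi <- smallest_flanking_intron(bundle$exons)
ok <- !is.na(mfi)
cat(sprintf("exon GC ~ hosting-gene GC: Pearson r = %.3f\n",
            cor(ex_gc, gene_gc)))
cat(sprintf("exon GC ~ smallest flanking intron: Pearson r = %.3f\n",
            cor(ex_gc[ok], mfi[ok])))
cat("bundle written to results/bundle/\n")
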
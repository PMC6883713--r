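# gcatex

Nucleotide composition bias and exon recognition during splicing, as a
tested, reusable R pipeline.

Alternative exons fall into two regimes set by the GC content of their
genomic neighborhood. GC-rich exons sit in GC-rich genes and isochores,
are flanked by small introns, can fold stable RNA structures across their
5' splice site, and depend on U1 snRNP–associated factors (SNRPC, SNRNP70,
DDX5/17). AT-rich exons sit in AT-rich, large-intron context where the
sequence upstream of the 3' splice site accumulates decoy signals —
spurious branch points, TNA motifs (SF1-like sites) and T-rich stretches
(U2AF2-like sites) — and depend on U2 snRNP–associated factors (SF1,
U2AF2, SF3A3, SF3B4). gcatex implements the analyses that establish this
picture, for anyone who wants to run them on their own regulation tables,
genomes and coverage tracks — or on a fully synthetic genome with planted
structure, used to validate every stage end to end.

## What the package computes

* **Exon classes** — per-factor activated exon sets from regulation tables
  (activated in ≥ 1 sample, never repressed by the same factor), factor
  classification by the two-threshold rule (median exon GC vs 49.3 %,
  median smallest flanking intron vs 691 bp), GC/AT exon labels with
  overlap exclusion, control sets, U1/U2 exon sets, and the GA/CT
  purine–pyrimidine generalization.
* **Splice-signal features** — YTNAY consensus branch-point calls (or
  imported SVM calls), hydrogen bonds of the best branch point duplexed
  with the U2 snRNA binding sequence GUGUAGUA (G:C = 3, A:U = G:U = 2,
  maximized over non-crossing pairings), TNA and T-rich decoy counts, and
  junction folding energies from a Nussinov-style bond-maximization engine
  (thermodynamic engines pluggable).
* **RFreq statistics** — `100 · (median(D_S) − median(D_C)) / median(D_C)`
  per feature and factor set, as heatmap matrices, plus 20-nt sliding
  window composition profiles across splice junctions.
* **The V value** — a subsampling randomization statistic,
  `v = log10(p_emp) · s`, quantifying whether a spliceosome-associated
  factor's regulation concentrates in GC exons (v > 0) or AT exons
  (v < 0), with `p_emp = max(min(k, l)/n_iter, 1/n_iter)` over 10,000 AT
  subsamples of GC-set size.
* **Coverage metaplots and CLIP maps** — 1000-bin metaprofiles over gene
  parts (with the first 199 bins dropped for internal exons and introns),
  exon-centered mean coverage, the `(GC − AT)/max(GC, AT)` ratio, and
  per-position CLIP peak proportions over splice-site regions.
* **Genomic domains** — maximal-overlap assignment of exons to
  isochores/TADs/LADs, per-domain class counts with the ≥ 5-exon filter,
  class proportions per domain kind, and exon-vs-domain GC correlations.
* **A synthetic genome generator** — isochore-tiled chromosome, genes and
  exons inheriting compartment GC, planted decoys, hairpin-competent 5'
  splice sites, CLIP-like peaks, nucleosome-like coverage, and ground-truth
  labels for recovery tests.

Standard formats only: FASTA (genome), TSV (annotation, regulation,
domains, all outputs), BED (peaks), bedGraph (coverage).

## Worked example

The `analysis/` directory is a six-stage narrative workflow over the
package. Stage 1 simulates the study genome, later stages analyze it and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
Rscript analysis/04_vvalue.R
```

Stage 1 and 2 print:

```
synthetic_bundle: 1040161 bp genome, 60 genes, 823 exons, 1115 regulation records, 174 peaks
  truth: 221 GC / 286 AT planted exons
exon GC ~ hosting-gene GC: Pearson r = 0.860
exon GC ~ smallest flanking intron: Pearson r = -0.616

  factor n_exons median_comp median_min_intron class
1  MBNL1     150    43.08457            1306.5    AT
2  PCBP1     150    58.91686             250.0    GC
...
labels: 221 GC exons, 286 AT exons, 121 control exons
recovery of planted classes: 100.0 % correct, 0 class swaps
```

Exon GC tracks hosting-gene GC and anti-correlates with flanking intron
size; the two-threshold rule classifies every auxiliary factor correctly,
and the exon labels recover the planted classes without a single
GC-for-AT swap. Stage 4 then tests each spliceosome-associated factor:

```
   factor n_iter     k     l  p_emp       v significant group
2 SNRNP70  10000     0 10000 0.0001  4.0000        TRUE    u1
4     SF1  10000 10000     0 0.0001 -4.0000        TRUE    u2
5   U2AF2  10000  9922   320 0.0320 -1.4949        TRUE    u2
significance line at |v| = 1.301
```

U1-associated factors reach the positive ceiling (v = +4: no AT subsample
matches the GC-exon proportion), U2-associated factors the negative side —
the planted U1/U2 dependency, read back from the regulation tables alone.
Stages 3, 5 and 6 report the decoy, coverage and domain contrasts (AT
exons: more branch points, TNA and T-rich motifs, 13.5 % vs 2.1 % CLIP
signal upstream; GC exons: more stable 5' ss folding, 3-fold coverage
enrichment, exon-vs-isochore GC correlation r = 0.87, and 51 % of AT vs
0 % of GC exons inside LADs).

## Layout

```
R/                  package code (one file per stage)
tests/testthat/     unit, property and acceptance tests with
                    brute-force oracles
analysis/01..06_*.R the narrative workflow
scripts/acceptance.R headline-quantity reproduction
vignettes/          methods vignette: models, parameters, design choices
```
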
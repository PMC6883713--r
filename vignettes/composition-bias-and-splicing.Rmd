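---
title: "Methods: nucleotide composition bias and exon recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleotide composition bias and exon recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific model

Exon recognition during splicing depends on short, degenerate signals — the
5' splice site bound by U1 snRNA, and the branch point (BP), polypyrimidine
tract and 3' splice site recognized by SF1, U2AF2 and U2AF1 ahead of U2
snRNP recruitment. gcatex implements an analysis built on one organizing
observation: the GC content of an exon tracks the GC content of its
flanking introns, hosting gene, isochore and topological domain, and this
regional composition bias creates two distinct regimes of splicing
constraint.

* In a **GC-rich context**, introns are small and G/C-rich flanks can fold
  into stable secondary structures across the 5' splice site, occluding it.
  Exons in this regime depend on U1 snRNP-associated factors (SNRPC,
  SNRNP70, the DDX5/DDX17 helicases).
* In an **AT-rich context**, introns are large and the A/T-rich sequence
  upstream of the 3' splice site is littered with *decoy* signals — spurious
  BP consensus sites, TNA motifs (SF1-like sites) and T-rich low-complexity
  stretches (U2AF2-like sites) — that can sequester the 3'-end recognition
  machinery. Exons in this regime depend on U2 snRNP-associated factors
  (SF1, U2AF2, SF3A3, SF3B4).

The pipeline classifies splicing-factor-activated exons into these two
classes, scores the splice-signal features that separate them, tests the
U1/U2 dependency with a randomization statistic, and relates the classes to
coverage (nucleosome-like) signal and to genomic domains.

Throughout, thymine stands for both T and U so that DNA-level and RNA-level
features share one alphabet, and all windows are taken in transcript
orientation after strand resolution, because every feature is defined
relative to the 5' or 3' splice site rather than to the genome's plus
strand. Coordinates are 0-based half-open internally (BED convention); N
bases are excluded from composition denominators and never match a motif
position.

# Exon classification

`build_activated_sets()` turns a regulation table (factor, sample, exon,
direction) into per-factor activated sets: an exon counts if it is
activated in at least one sample and never repressed by the same factor;
exons regulated in opposite directions by one factor are eliminated, and
conflicting duplicate records for one (factor, sample, exon) are an input
error.

`classify_factor()` applies the two-threshold rule: a factor is GC-class
when the median GC of its activated exons exceeds **49.3 %** *and* the
median size of their smallest flanking intron is below **691 bp**; AT-class
when both comparisons flip; otherwise unclassified (this is the fate of
factors activating GC-rich exons flanked by large introns). Both thresholds
are pinned configuration defaults rather than being recomputed from the
supplied control set: they were calibrated on genome-wide annotation
medians, and pinning makes classification deterministic on any subset of
data. Passing `gc_threshold = NULL` recomputes the composition threshold
from the control set when that is preferred. Equality at a threshold leaves
a factor unclassified, following the strict higher/lower reading of the
rule. The smallest flanking intron is defined only for internal exons;
terminal exons are excluded from that median.

Exon labels then follow from factor classes (`assemble_class_exons()`): an
exon is GC (or AT) if activated by at least one factor of that class and
none of the other; exons claimed by both classes are excluded from further
analysis, and every exon receives exactly one of GC / AT /
`excluded_overlap` / `none`. The control set is the constitutive internal
exons minus everything activated by any analyzed factor. The purine /
pyrimidine generalization (GA and CT exon sets) reuses the same machinery
on GA or CT composition; the intron criterion is off by default there
because those sets are defined by composition alone.

# Splice-signal features

All geometry lives in `feature_windows()` (defaults in parentheses):

| feature | window |
|---|---|
| BP search | last 100 nt of the upstream intron |
| BP context | 5 nt before + BP + 3 nt after (9 nt) |
| TNA motifs | last 50 intronic nt |
| T-rich windows | positions −75..−35, window 4, ≥ 3 Ts |
| folding windows | 25 nt each side of the splice site |
| CLIP maps | 200 intronic + 50 exonic nt |

**Branch points.** The built-in caller scans for adenines in a full YTNAY
5-mer context and scores them as consensus matches minus 2, so a perfect
consensus scores 2, one mismatch scores 1, and two mismatches fail; calls
with score > 0 are retained. External support-vector calls can be imported
(`read_bp_calls()`) and are used identically downstream. One property of
this stand-in matters for interpretation: because one mismatch still
passes, genomic background produces on the order of ten retained calls per
100-nt window (about 8 in GC-context, about 13 in AT-context introns on the
synthetic genome), so the *fraction of exons with ≥ 2 retained calls*
saturates at 1 for every class and cannot display the class contrast that a
selective caller produces. The feature table therefore also reports
*strong* calls (score ≥ 2, a perfect consensus — the grade of site the
generator plants): total retained counts and the ≥ 2-strong-call fraction
both recover the expected AT > GC direction, and the directional analyses
use them.

**U2 duplex bonds.** For the best-scoring BP per exon (ties break toward
the 3' splice site), the 9-nt context minus the branch adenine gives an
8-nt target. `u2_binding_bonds()` finds the antiparallel, non-crossing set
of base pairs against the U2 snRNA branch-point binding sequence
(GUGUAGUA) that maximizes hydrogen bonds, with G:C = 3 and A:U = G:U = 2
and no loop or position penalties — the reported quantity is a bond sum,
so the simplest maximizing duplex model is the appropriate contract. The
dynamic program is checked in the tests against exhaustive enumeration of
pairings.

**Decoy counters.** TNA motifs are positions with T at i and A at i+2,
overlaps allowed. T-rich low-complexity windows are 4-nt windows (step 1)
with at least three Ts between −75 and −35. Both are plain positional
scans verified against independent brute-force oracles.

**Junction folding.** The default engine maximizes hydrogen bonds over
non-crossing pairs with a minimum hairpin loop of 3 unpaired bases
(Nussinov-style) and returns the negated bond total: a monotone stand-in
for folding stability with the same orientation as a thermodynamic energy
(lower = more stable, 0 = unpairable). A real thermodynamic engine can be
plugged in via the `engine` argument; results should then be interpreted
on that engine's scale. Absolute values of the default engine are not
free energies and only class *contrasts* are meaningful.

# The V value

For a spliceosome-associated factor, `v_value()` draws `n_iter = 10,000`
subsamples of AT exons of GC-set size (without replacement within a draw,
independent across draws) and counts `k` subsamples whose activated
proportion reaches the observed GC proportion and `l` at or below it; ties
increment both. Then `p_emp = max(min(k, l)/n_iter, 1/n_iter)` and
`v = log10(p_emp) * s` with `s = 1` if `k > l` and `-1` otherwise
(equality gives `-1`, the verbatim rule). Positive V means regulation
concentrated in GC exons. Proportions share a denominator, so the
implementation compares integer counts exactly and no floating-point
tie-breaking enters. Significance is called on `|v| >= -log10(alpha)`;
the plotted line sits at about 1.30 for alpha = 0.05 (the magnitude is
used because `log10(0.05)` itself is negative). A Benjamini-Hochberg
column is appended to the factor table for convenience only; the
randomization procedure itself applies no multiple-testing correction and
the significance flags use raw empirical p-values.

**Calibration regime.** The subsampling p-value is exactly calibrated when
the observed GC-set proportion is distributed like a subsample proportion
— in practice when the AT pool is much larger than the GC set, so that the
without-replacement correction is negligible. The package's calibration
experiment therefore uses a GC set of 100, an AT pool of 10,000 and a null
factor hitting both at rate 0.1: across 200 replicates the two-tailed
rejection at the 0.05 line stays in the mid-single-digit percent range
(the ties-inclusive discrete p is conservative). When the pools are of
comparable size — as in the headline exon sets, where the AT/GC ratio is
only about 1.3 — the observed proportion has binomial variance while
subsample proportions are shrunk by the finite-population factor, and the
statistic over-rejects under a cross-replicate null (measured above 50 %
at ratio 1.3). The V value remains a valid *descriptive* randomization
measure of how extreme the GC set is relative to AT subsets, which is how
it is used; it should not be read as a calibrated two-sample test when the
two sets are of similar size. This is a property of the procedure itself,
not of this implementation.

# Metaplots, coverage and CLIP maps

`binned_profile()` concatenates a gene's region coverages in genomic order
(flipped to transcript orientation for minus-strand genes), resamples the
concatenation into 1000 bins — bin *b* averages positions
`[floor((b−1)L/1000), floor(bL/1000))` — drops the first 199 bins for the
internal-exon and intron kinds (removing promoter-dominated signal) and
averages bins across genes with equal weight per gene (matching an
average over annotations, not over base pairs). Genes shorter than the
bin count leave empty bins; these are filled by linear interpolation
between neighboring bins so profile shape does not depend on gene length.
Constant coverage is exactly conserved through this resampling at every
region geometry, which the tests assert. Promoters span −1500/+500 around
the TSS; exon-centered coverage windows span ±100 nt around the exon
center; `gc_at_ratio()` reports `(GC − AT)/max(GC, AT)` of the group mean
coverages, a signed quantity in [−1, 1].

CLIP positional maps report, for each of the 251 positions of a splice-site
region (200 intronic + 50 exonic + the junction position), the fraction of
exons with at least one peak overlapping that genomic position — interval
overlap, not summit identity, because peaks stand in for converted
coverage. Offset 0 is the first base after the junction in transcript
direction; windows extending past a chromosome end count as no-signal
while the exon stays in the denominator.

# Domains

Exons are assigned to the isochore/TAD/LAD with maximal overlap
(`assign_domains()`); ties break toward the smaller domain start so
assignment is deterministic, and exons spanning a boundary go to the side
holding more of them. Domains of one kind must not overlap. Per-domain
GC/AT counts feed the ≥ 5-exon display filter; class proportions inside a
kind and the Pearson correlation between exon GC and hosting-domain GC
complete the stage. Domain GC is taken from the annotation when supplied
and computed from the genome otherwise. A full-scale mixed-model test
of per-TAD feature concentration is out of scope here; the per-domain
count tables support permutation-style analyses when needed.

# The synthetic genome

`simulation_config()` defines the study conditions; all randomness flows
from one integer seed, so bundles are byte-identical given a seed.

* **Architecture**: 10 planted isochores cycling through GC levels
  {35, 42, 48, 55} % (levels ≥ 46 % count as GC context) plus 2 control
  isochores at 46 %, each hosting 5 genes of 12–16 exons; exon lengths are
  lognormal with median ≈ 120 nt; intron lengths are lognormal with median
  300 nt in GC context and 1500 nt in AT context, straddling the 691-bp
  threshold the classifier uses; control introns sit near that median.
  Genes inherit their isochore's GC with 1.5-point jitter, exons sit 5
  points above their gene, and intergenic background follows the isochore
  level — producing the planted exon–gene–isochore GC correlation
  (measured r ≈ 0.86) and the negative exon-GC vs intron-size correlation
  (r ≈ −0.6). Genome size is about 1 Mb so every stage runs in seconds.
* **Splice signals**: every intron gets GT/AG ends, one canonical
  perfect-consensus BP with its adenine at −23, and a pyrimidine tract at
  −20..−9 whose T fraction decreases with gene GC (T-rich in AT context,
  C-rich in GC context). Upstream of each planted AT exon the generator
  adds, in disjoint sub-windows so plants never overwrite each other,
  2 extra perfect BP sites (−99..−77), 3 T-runs (−72..−45) and 4 TNA
  motifs (−42..−28), all scaled by `decoy_enrichment` (0 disables).
  Planted GC exons receive an 8-nt G/C-rich flank pair able to base-pair
  across the 5' splice site (`hairpin_rate` controls this).
* **Regulation**: three GC-class and three AT-class auxiliary factors each
  activate 150 exons drawn from their context pool (truth labels are the
  union, ≈ 220 GC and ≈ 290 AT exons — an AT/GC ratio near the 1.27 of
  the real exon sets); U1-group factors activate 28 % of GC and 14 % of
  AT exons, U2-group factors 17 % and 27 %, matching the reported
  regulation rates; each auxiliary factor also represses a few control
  exons so the opposite-regulation elimination path is exercised.
* **Coverage and peaks**: piecewise-constant background depth (blocks of
  100 bp, ±30 % noise) multiplied by 3 on planted GC exons emulates the
  nucleosome-like enrichment; CLIP-like peaks of 50 nt land in the
  −200..−60 window upstream of 60 % of AT exons and 10 % of GC exons.
* **Domains**: isochores tile the chromosome contiguously; TADs are
  isochore halves; LADs are the lowest-GC (35 %) isochore blocks. This
  reproduces the observed overlap structure without modeling 3D contacts.

**What passing tests do and do not show.** The generator plants exactly
the structure the pipeline is designed to detect, with independent
per-base sampling inside each compartment. Recovery therefore
demonstrates that the implementation measures what it claims to measure
— not that real transcriptomes behave this way: real sequence has
dinucleotide and repeat structure, regulation tables carry quantification
noise and factor cross-talk, real nucleosome signal is far from
piecewise-constant, and real LAD/TAD boundaries do not coincide with
isochores. The null configuration (equal GC levels, equal intron lengths,
no planting) gives the complementary guarantee: with nothing planted, the
feature distributions of the two context groups are statistically
indistinguishable, so the pipeline does not manufacture contrasts.

# Numerical choices and degenerate inputs

* Sliding-window profile values are assigned to the window's center
  position (left-of-center for even windows); only full windows are used,
  and offsets skip zero so positions are symmetric around the splice site.
* Exons lacking the required flank are dropped from junction profiles with
  a warning; feature columns whose window is unavailable are NA rather
  than silently shortened, except the T-rich and BP windows, which are
  computed over the available sequence and flagged.
* The folding DP forbids pairs enclosing fewer than 3 unpaired bases;
  all-N or unpairable windows score 0.
* `v_value()` restores the caller's RNG state, so seeding a single
  statistic does not perturb surrounding analyses; table seeds are derived
  per factor from one base seed.
* Problem sizes in the shipped analyses — a ~1 Mb genome, ~800 exons,
  10,000 subsamples per V value, 200 calibration replicates — were chosen
  so the full workflow reruns from scratch in about a minute while keeping
  every planted class above 200 exons.

# Known limitations

* The default folding and duplex engines are combinatorial bond
  maximizers, not thermodynamic models; only comparisons between exon
  classes are meaningful, and plugging in a thermodynamic engine changes
  scales.
* The consensus BP caller is deliberately permissive at its score > 0
  cutoff (see above); fraction-type summaries should use the strong-call
  columns unless an external selective caller is imported.
* The V value is a descriptive randomization statistic; its empirical p is
  calibrated only when the AT pool dwarfs the GC set.
* Regulation tables are taken as pre-thresholded truth; no differential
  inclusion calling, read processing or peak calling is performed.
* The generator emits annotation directly; it does not simulate reads.
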
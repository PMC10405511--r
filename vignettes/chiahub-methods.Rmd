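---
title: "Methods: loop annotation, hubs, CRE states and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop annotation, hubs, CRE states and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiahub)
```

## The analysis layer

ChIA-PET experiments yield, per chromatin mark (H3K4me3, RNAPII, H3K4me1,
H3K27me3, H3K9me2, or a transcription factor), a set of *loops*: pairs of
genomic anchor intervals with a PET count and an FDR. `chiahub` implements
the downstream layer that turns such loop calls, together with gene models,
ChIP-seq peaks, accessible regions, SNPs and a gene-by-tissue FPKM matrix,
into regulatory annotations:

* **anchor vs basal status** — a peak is an *anchor* peak when it overlaps a
  loop anchor of its own mark; a gene inherits anchor status from the peaks
  overlapping its association window;
* **loop categories** — promoter-promoter (P-P), promoter-intergenic (P-I)
  and intergenic-intergenic (I-I), plus span classes below 1 Mb, 1-10 Mb
  and above 10 Mb;
* **CRE states** — accessible regions classified as proximal (PRE, promoter),
  distal (DRE, intergenic) or intragenic elements, and as active, poised
  (H3K27me3 only) or poiAct (bivalent: H3K27me3 plus active marks), each
  anchor or basal, with nearest and long-range connected target genes;
* **chromatin hubs** — merged anchors from which at least five loops
  emanate, with TF-target enrichment against a size-matched random control,
  and a two-condition classifier for hub disassembly;
* **connectivity networks** — one- or two-hop expansion of loop-mediated
  gene-gene edges from seed genes;
* **co-expression statistics** — expression breadth, mean Pearson
  correlation of interacting gene pairs, and a distance-matched permutation
  null;
* **contact-map architecture** — binned contact matrices, iterative
  correction, A/B compartment eigenvector calls, an aggregate chromosome
  map, and interacting-domain segmentation.

All records are tibbles with fixed column contracts (`?read_gff3`,
`?read_bedpe`), all coordinates are 0-based half-open internally, and GFF3's
1-based closed convention is converted only at I/O.

## Decision rules and their parameters

**Promoters and gene regions.** The promoter is 1 kb upstream to 0.5 kb
downstream of the TSS, strand-aware and clipped at chromosome bounds. The
gene *association region* used for anchor-gene assignment runs from 1 kb
upstream of the TSS to the TTS; the gene body (intragenic space) runs from
0.5 kb downstream of the TSS to the TTS; intergenic space is the complement
of the association regions. All offsets are arguments.

**Anchor status.** The peak-to-anchor overlap threshold is 1 bp by default
(`min_bp`): participation in an interaction is a qualitative property, and
1 bp is the weakest consistent reading; a stricter fraction can be set. The
gene rule uses the association region at 1 bp overlap, with anchor status
dominating basal when a gene sees both kinds of peak. Genes touched by no
peak carry no status: they belong to neither comparison group.

**Loop categories.** Each anchor is labelled promoter if it touches any
promoter window, else intergenic if it reaches outside the union of gene
regions, else genic. Promoter takes precedence because active-mark loop sets
are dominated by promoter contacts; pairs involving a genic anchor fall into
`other`. Span is measured midpoint to midpoint and the 1 Mb and 10 Mb
boundaries belong to the middle class (read as inclusive).

**CRE classification.** A category (PRE > DRE > intragenic, in that
priority) qualifies when at least 50% of the CRE's length lies in its space;
the fraction is of the CRE, not of the genomic feature, so short accessible
regions remain classifiable. When nothing reaches 50% the maximal overlap
decides and the row is flagged `sub_threshold` — an explicit extension for
a case the rule set leaves open. The DRE state rule inspects peaks within
500 bp edge-to-edge (a distance of exactly 500 bp is outside); the PRE rule
inspects overlapping peaks. The active-mark set for bivalence detection is
{H3K4me3, RNAPII, H3K4me1} and is configurable.

**Anchor-gene assignment.** An anchor is assigned to the gene(s) whose
association region contains at least 50% *of the anchor's length* — the
anchor-fraction reading keeps short anchors assignable against long genes.
For active marks the highest-FPKM candidate wins (ties: longer overlap,
then lexicographic id); H3K27me3 anchors keep all candidates, reflecting
the one-to-many nature of Polycomb domains. FPKM comes from the `seedling`
column when present, otherwise the first tissue column.

**Hubs.** Overlapping loop anchors are merged; a node with degree ≥ 5
(member loops) is a hub. Between conditions, hubs sharing a node gene are
the same hub; with `Nc` and `Nm` connecting genes in the two conditions
and `Ns = Nc − Nm`:

* EDH (entirely disassembled): `Ns/Nc ≥ 0.7` and `Ns ≥ 3`;
* PDH (partially disassembled): `0.3 ≤ Ns/Nc < 0.7` and `Ns ≥ 3`;
* FH (newly formed or markedly grown): `−Ns/Nm ≥ 0.3` and `Nc − Nm ≤ −3`;
* stable otherwise.

Each rule's conditions are conjunctions and the rules are evaluated in the
order above; the grid test in the suite verifies that every `(Nc, Nm)` pair
receives exactly one label and that the labels agree with an independently
coded brute-force evaluation. Hubs without an assignable node gene fall
back to reciprocal anchor overlap for matching and are flagged. TF-target
enrichment uses a one-sided Fisher exact test at raw `p < 0.05` (the
screening convention for this analysis); BH-adjusted values are reported
alongside but do not drive the flag.

**Co-expression null.** "Random pairs at the same physical distance" is
operationalised as matching within log2 distance bins of width 0.25
(configurable): exact distance matching is infeasible on a finite gene set,
and logarithmic bins preserve the null's intent across the orders of
magnitude a loop span covers. Mode A draws matched pairs from all genes,
mode B from the anchor-gene set. The empirical p uses the add-one
convention, `p = (1 + #{null ≥ observed})/(1 + n_sim)`, so `p` is never 0
and its minimum at 1,000 simulations is 1/1001. Expression breadth counts
tissues with FPKM ≥ 1 (the threshold is an argument and is reported with
the output; "detected" has no universal definition).

**Contact maps.** Binning adds each intrachromosomal loop's PET count to
the two symmetric cells of its anchor-midpoint bins. Iterative correction
divides rows and columns by their marginals (renormalised to mean 1 each
round) until the coefficient of variation of retained-bin marginals falls
below `tol` (1e-4); the marginal target is the mean marginal rather than 1
so the matrix keeps its total mass, and biases are returned so either
convention is recoverable (`raw = bias_i · bias_j · balanced`). On sparse
toy matrices the iteration can stall above tolerance; the result is then
returned with `converged = FALSE` and a warning rather than an error.
Compartments are the sign of the leading eigenvector of the Pearson
correlation matrix of observed/expected rows, where expected values are
exact per-bin-distance means (no smoothing — matrices here are small). The
eigenvector sign is arbitrary, so it is oriented by a per-bin track — gene
density by default — and the positive side is A. The aggregate chromosome
map block-averages each chromosome onto a common lattice and sums.

**Interacting domains.** The segmentation algorithm is this package's own
operationalisation (the source analyses describe theirs only as based on
connectivity and contact frequency): 10 kb bins covered by anchors of
exactly one mark group — active, H3K27me3, H3K9me2 — become AID/RID/HID
after bridging gaps of at most one uncovered bin; bins covered by two or
more groups become MID; the rest are gaps. Its coverage percentages are
descriptive of the inputs and are not claimed to reproduce any published
genome-wide coverage figures.

## What the synthetic data emulate

`sim_config()` fixes the study conditions for all tests: 2 chromosomes of
20 Mb with a central 10% centromeric block, 2,000 non-overlapping genes on
the arms, 43 tissues, and 1,000 H3K4me3 + 300 H3K27me3 + 200 H3K9me2
loops. The planted structure mirrors the qualitative organisation of the
plant interactome the package targets:

* active-mark loops are ≥ 96% P-P; H3K9me2 loops are ~88% I-I, confined to
  the centromeric block, with log-normal spans of median 105 kb (the
  log-normal is a modelling choice; only the range and median are
  constrained by observation);
* anchor genes carry a 2× FPKM boost; planted interacting pairs share a
  log-scale latent factor calibrated analytically so the *linear-scale*
  expected Pearson correlation equals `planted_pair_pcc` (0.5 by default) —
  for equal-variance log-normals,
  `cor(e^X, e^Y) = (e^{ρσ²} − 1)/(e^{σ²} − 1)`, which is inverted for ρ;
* 20 hubs of size 8-12 are planted as stars of P-P loops around a node
  promoter; TF targets concentrate in hubs (80% of 150 targets);
* the second condition removes all loops of 10% of hubs (EDH), removes
  `max(3, ⌈0.3·Nc⌉)` connecting genes from 20% (PDH, sized so the hub stays
  detectable), and adds `max(3, ⌈3Nc/7⌉)` genes to 5% (FH); separated genes
  are down-regulated 2× in the second condition's expression table;
* CREs are placed in contexts whose class/state/status are known by
  construction at the 80/13/7 active/poised/poiAct composition, and SNPs
  are planted into group-exclusive loop anchors at 23/11/11% with the rest
  outside all anchors.

One master seed fans out to per-component seeds by fixed offsets, so a
component is reproducible even when unrelated configuration changes;
identical configurations yield byte-identical files.

What the generator does **not** emulate: read-level noise, peak-calling
uncertainty, overlapping gene models, interchromosomal loops, realistic
span distributions for active marks (their spans arise from gene spacing),
tissue-correlated expression backgrounds, or any sequence-level feature.
Passing the planted-recovery tests therefore demonstrates correctness of
the decision rules and statistics on clean inputs, not robustness to the
noise structure of real sequencing data.

## Numerical and degenerate-input choices

* Pearson correlations use the sample (n−1) convention; zero-variance
  profiles are excluded pairwise and counted.
* Loops are deduplicated on (anchors, mark) keeping the maximal PET count,
  and anchors are stored sorted; the FDR filter (< 0.05) is applied at
  read time and can be disabled.
* Nearest-gene ties break to the lexicographically smaller gene id; this is
  deterministic and documented rather than meaningful.
* Compartment calling refuses fewer than 10 retained bins (the eigenvector
  is unstable); an all-masked matrix is an error for balancing.
* Empty groups in the expression-category builder are emitted with a
  warning, not dropped silently.
* Problem sizes in the test suite: the shared dataset uses the default
  configuration above; the hub-fraction recovery test plants 200 hubs on a
  4,000-gene genome; the null-calibration test uses a 400-gene genome with
  50 pairs, 199 simulations and 50 replicate seeds. These sizes give each
  statistic enough resolution for its stated tolerance while keeping the
  suite fast.

## Known limitations

* The interacting-domain segmentation and the compartment pipeline are
  deliberately minimal re-statements of the described algorithms; they do
  not reproduce the numerics of juicer, HiC-Pro or HiCExplorer.
* The hub "others" category of two-condition comparisons maps to FH here;
  residual cases a richer taxonomy might separate are absorbed by `stable`.
* Two-hop networks carry both mark categories without enforcing
  category-consistency between hops.
* ChromHMM-style multivariate state discovery is out of scope; the
  rule-based CRE states stand on their own definitions.
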
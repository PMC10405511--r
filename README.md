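# chiahub

Downstream annotation of ChIA-PET chromatin loops: anchor/basal
classification, loop categories, cis-regulatory element (CRE) states,
chromatin hubs and their differential disassembly, connectivity networks,
distance-matched co-expression nulls, and a lightweight contact-map
architecture layer — with a seeded synthetic-data generator so the whole
stack is testable without sequencing data.

## The problem

ChIA-PET (chromatin interaction analysis with paired-end tags) yields, per
chromatin mark or transcription factor, a set of *loops*: pairs of anchor
intervals with a PET count and an FDR. Turning loop calls into regulatory
biology requires a consistent downstream layer:

* a ChIP-seq peak is an **anchor** peak when it overlaps a loop anchor of
  its mark, otherwise **basal**; genes inherit anchor status through their
  association window (1 kb upstream of the TSS through the TTS);
* loops are **P-P**, **P-I** or **I-I** by whether each anchor touches a
  promoter (1 kb upstream to 0.5 kb downstream of a TSS) or intergenic
  space, with span classes < 1 Mb, 1–10 Mb, > 10 Mb;
* accessible regions become **PRE** (promoter), **DRE** (intergenic) or
  intragenic elements at a 50% overlap rule with priority
  PRE > DRE > intragenic, and are **active**, **poised** (H3K27me3 only
  nearby) or **poiAct** (bivalent), each anchor or basal, with nearest and
  long-range target genes linked through loops;
* a **chromatin hub** is a merged anchor with degree ≥ 5; between two
  conditions, with `Nc`/`Nm` connecting genes and `Ns = Nc − Nm`, a hub is
  **EDH** (entirely disassembled) when `Ns/Nc ≥ 0.7` and `Ns ≥ 3`, **PDH**
  when `0.3 ≤ Ns/Nc < 0.7` and `Ns ≥ 3`, **FH** (newly formed/grown) when
  `−Ns/Nm ≥ 0.3` and `Nc − Nm ≤ −3`, and **stable** otherwise; TF-target
  enrichment per hub is a one-sided Fisher exact test against a
  size-matched random control;
* co-expression of interacting gene pairs is tested against 1,000 random
  pair sets matched on genomic distance (log2 bins), with the add-one
  empirical p `p = (1 + #{null ≥ observed})/(1 + n_sim)`;
* contact matrices are binned from loops, balanced by iterative correction,
  A/B compartments called from the leading eigenvector of the O/E
  correlation matrix, and the genome segmented into AID/RID/HID/MID/gap
  interacting domains.

Everything is a tibble with a fixed column contract and pipes through
dplyr; result objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` views.

## Worked example

```r
library(chiahub)

# a synthetic dataset with planted structure (deterministic under the seed)
ds <- simulate_dataset(sim_config(seed = 1))

# anchor/basal classification and loop categories
peaks  <- classify_anchor_peaks(ds$peaks, ds$loops)
genes  <- classify_anchor_genes(ds$genes, peaks, chrom_sizes = ds$chrom_sizes)
cats   <- categorize_loops(ds$loops, ds$genes, ds$chrom_sizes)
dplyr::count(cats, mark, category)
#> # A tibble: 9 × 3
#>   mark     category     n
#>   <chr>    <chr>    <int>
#> 1 H3K27me3 II          90
#> 2 H3K27me3 PI          90
#> 3 H3K27me3 PP         120
#> 4 H3K4me3  II          10
#> 5 H3K4me3  PI          30
#> 6 H3K4me3  PP         960
#> 7 H3K9me2  II         176
#> 8 H3K9me2  PI          20
#> 9 H3K9me2  PP           4
```

960/1000 active loops are promoter-promoter and 176/200 H3K9me2 loops are
intergenic-intergenic — the planted composition, recovered exactly.

```r
# co-expression of interacting pairs vs the distance-matched null
cx <- distance_matched_null(ds$truth$pairs, ds$genes, ds$expr,
                            n_sim = 1000, mode = "A", seed = 2)
cx
#> Distance-matched co-expression null (mode A)
#>   observed mean PCC: 0.5146 over 200 pairs
#>   null mean +/- sd:  0.0013 +/- 0.0111 (1000 simulations)
#>   empirical p:       0.000999
```

The 200 interacting pairs carry a planted mean Pearson correlation of 0.5
across 43 tissues; the distance-matched null sits at zero, and the
empirical p attains its minimum 1/1001.

```r
# differential hubs between the two conditions
h1 <- detect_hubs(ds$condition$loops_1[ds$condition$loops_1$mark == "H3K4me3", ],
                  ds$genes, ds$expr)
h2 <- detect_hubs(ds$condition$loops_2[ds$condition$loops_2$mark == "H3K4me3", ],
                  ds$genes, ds$expr)
deltas <- compare_conditions(h1, h2)
table(deltas$category[deltas$node_gene %in% ds$truth$hub_changes$node_gene])
#>
#>    EDH     FH    PDH stable
#>      2      1      4     13
```

Of the 20 planted hubs, 10% were entirely disassembled, 20% partially,
5% grew — exactly the planted fractions, every label matching the truth
table.

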
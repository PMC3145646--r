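# orburb

Tools for separating the *active* fraction of the human gut microbiota from
the *total* community in multiplexed 16S rDNA amplicon surveys of
flow-sorted cell fractions.

Stool samples can be sorted by cellular RNA content into "active"
subpopulations (pyronin-Y activated **PA**, low-Cy5 **LC**, high-Cy5 **HC**)
and compared against "total" views of the same community (fecal suspension
**FS** and density-gradient ring **R**). Each library is amplified with a
primer of structure

```
MID + PERMUTAG + TC + primer + insert
```

where the MID is the per-library barcode and the PERMUTAG is an 8-base
degenerate tag (`WGNGNNGW`, 2·1·4·1·4·4·1·2 = 256 concrete tags) that lets
exact dereplication remove emulsion-PCR duplicates — byte-identical copies
of one template molecule — while keeping genuinely independent templates
that happen to share a sequence.

## What the package does

- **Tag-aware read preparation** — parse the MID–PERMUTAG–linker–primer
  structure, demultiplex, dereplicate reads identical in length and full
  tagged sequence (PERMUTAG included), strip tags
  (`parse_reads`, `dereplicate`, `strip_tags`, `demux_report`).
- **LCA taxonomic assignment** — assign each clean read to the deepest
  taxonomy node shared by the lineages of its retained similarity-search
  hits, roll counts up to any rank, and export the best-hit-identity
  "fingerprint" (`assign_reads`, `rank_counts`, `identity_fingerprint`).
- **Community statistics** — percentage normalization, Bray–Curtis
  dissimilarity `d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`, complete-linkage
  clustering with newick export, analytic rarefaction
  `E[Sₙ] = Σᵢ (1 − C(N−Nᵢ,n)/C(N,n))`, Shannon diversity
  `H = −Σ pᵢ ln pᵢ`, and a sequential PERMANOVA on the distance matrix
  (`G = −½·J·D²·J`; term SS via incremental orthogonal projectors;
  permutation p-values), with terms ordered actives-vs-totals, samples,
  fractions (`permanova`).
- **ORB/URB classification** — the ordered family-percentage distribution of
  each library is smoothed on the log scale, its second derivative located
  by finite differences, and the percentage at the **last inflection point**
  taken as that library's cut-off; the most recurrent cut-off across
  libraries (modal log-scale bin) splits families into over-represented
  (ORB, above) and under-represented (URB, at or below), and per-family
  Welch t-tests on per-subject medians compare active versus total
  fractions (`cutoff_analysis`, `classify`, `welch_family_test`).
- **Synthetic data with known truth** — a generator for taxonomy trees,
  two-regime heavy-tailed communities with a planted knee and planted
  active-vs-total fold changes, tagged reads with emulsion-PCR duplicates,
  and simulated hit tables (`gen_taxonomy`, `gen_community`, `gen_reads`,
  `gen_hits`), so every pipeline stage can be validated against a ledger.

## Worked example

```r
library(orburb)

tree   <- gen_taxonomy(n_phyla = 13, n_families = 79, seed = 1)
design <- make_design(n_samples = 4)            # 4 subjects x {PA,LC,HC,FS,R}
truth  <- gen_community(tree, design, knee_pct = 1, n_orb = 8, n_urb = 40, seed = 2)
truth  <- gen_community(tree, design, effects = default_effects(truth), seed = 2)
pct    <- normalize_percent(sample_counts(truth, reads_per_library = 10000, seed = 3))

permanova(bray_curtis_matrix(pct), design,
          terms = c("group", "sample", "fraction"), n_perm = 999, seed = 4)
#> Sequential PERMANOVA (999 permutations)
#>           Df SumsOfSqs MeanSqs F.Model    R2 Pr(>F)
#> group      1     0.520   0.520  45.286 0.735  0.001
#> sample     3     0.026   0.009   0.752 0.037  0.557
#> fraction   3     0.024   0.008   0.689 0.034  0.644
#> Residuals 12     0.138   0.011      NA 0.195     NA
#> Total     19     0.707      NA      NA 1.000     NA
```

The active-vs-total contrast carries one degree of freedom and (here) 73%
of the distance variance; the five-level fraction factor keeps only three
degrees of freedom because its active/total contrast was already absorbed,
leaving 12 residual df among the 20 libraries.

```r
co <- cutoff_analysis(pct)
co$consensus
#> [1] 1.778279
cls <- classify(pct, co$consensus, design)
cls$counts
#>    group label Freq
#> 1 active   ORB    8
#> 2  total   ORB    8
#> 3 active   URB   36
#> 4  total   URB   36
```

Every library shows a single prominent inflection near the planted 1% knee
(consensus 1.78%, within a factor two), and the 8 planted head families are
recovered as ORB in both groups.

```r
w <- welch_family_test(pct, design)
head(w[order(w$p), c("family", "active_median", "total_median", "t", "df", "p")], 3)
#>       family active_median total_median     t   df        p
#> 8 Family_050          2.91        22.13 -19.8 4.55 1.35e-05
#> 5 Family_008          9.73         2.44  14.7 5.23 1.85e-05
#> 7 Family_041          3.99        17.35 -11.7 4.96 8.38e-05
```

`Family_050` carries the planted 9-fold total enrichment (realized median
ratio 22.1/2.9 ≈ 7.6 after renormalization) and is flagged highly
significant; `Family_008` is one of the planted active-enriched families.

The whole read-level pipeline — FASTA in, stage tables out — runs from one
call (or from `inst/scripts/orburb-pipeline.R` on a shell):

```r
res <- run_all("my_run", reads_per_library = 10000L, seed = 23)
```

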
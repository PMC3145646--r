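---
title: "Methods: profiling the active gut microbiota against the total community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling the active gut microbiota against the total community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orburb)
```

## The problem

Most 16S rDNA surveys of the human gut describe the *total* community:
everything with a genome, dormant or dead included. Sorting cells by RNA
content (pyronin-Y staining, flow cytometry) isolates the
*transcriptionally active* subpopulation, and sequencing both views of the
same stool sample asks a sharper question: which taxa are merely present,
and which are actually doing something? orburb implements the
computational half of that comparison: tag-aware read preparation,
taxonomic profiling, community statistics, and a classifier that separates
each library's family-abundance distribution into an over-represented head
(ORB) and an under-represented tail (URB).

The five fractions per subject are PA, LC and HC (the "active" group) and
FS and R (the "total" group). Four subjects times five fractions gives the
20-library design all defaults assume.

## Tag-aware read preparation

Reads carry the structure `MID + PERMUTAG + TC + primer + insert`. The MID
is a designed per-library barcode and is matched exactly: tolerating
mismatches in a code that exists to discriminate libraries would
cross-assign reads. The PERMUTAG is the degenerate 8-mer `WGNGNNGW`
(256 concrete expansions); it is validated positionwise against the IUPAC
pattern and never "repaired", because its whole job is to distinguish
template molecules — a corrected tag is a fabricated identity. The two-base
linker leaves no room for tolerance and is matched exactly; the primer, a
biological priming site, is matched IUPAC-aware with up to two
substitutions (no indels, which keeps the parser alignment-free).

Dereplication removes reads identical in length and full tagged sequence,
*PERMUTAG included*. Emulsion-PCR duplicates are byte-identical copies of
one template, so they collapse; two reads with identical inserts but
different PERMUTAGs came from different templates and both survive. The
first occurrence in file order is the retained representative (a
deterministic, content-neutral tie-break). Conservation holds at every
stage: assigned plus categorized failures equals the input count, and
retained multiplicities sum to the assigned count.

## LCA assignment

Each read's similarity-search hits (12-column tabular format) are filtered
to `pident >= min_identity` (default 80%) and then to bitscores within
`score_window` (default 0.9) of the read's best hit — a conventional
top-fraction retention rule; both knobs are exposed because reference
databases differ. The read is assigned to the deepest taxonomy node on the
lineage of every retained subject. Reads whose LCA lands above family rank
are counted as "unclassified" at family rank (they still count at the
ranks they do reach); reads with no retained hits are excluded from tables
but reported, so column sums always reconcile.

## Community statistics

Counts are normalized to column percentages; Bray–Curtis dissimilarity,
complete-linkage clustering, analytic (hypergeometric) rarefaction and the
natural-log Shannon index follow their textbook definitions. The variance
decomposition is a sequential PERMANOVA: from the distance matrix `D`,
`G = -1/2 J D^2 J` (with `J` the centering projector); total SS is
`trace(G)`; each term's SS is `trace(H_k G)` where `H_k` projects onto the
column space the term adds beyond its predecessors (QR-based, so aliased
contrasts are simply absorbed — in the standard design the five-level
fraction factor keeps 3 df after the actives-vs-totals contrast).
Significance comes from freely permuting library labels; with `n_perm`
permutations the p-value uses the `(count + 1)/(n_perm + 1)` convention,
which cannot report zero. Term order is fixed to actives-vs-totals,
samples, fractions by default and is configurable; being sequential, the
SS change with the order, which is the point of putting the contrast of
interest first. Permutations are free (no strata); restricting them to
within-subject exchanges is a documented possible refinement that the
current implementation does not perform.

## The ORB/URB classifier

For each library the present families are sorted by descending percentage
(ties broken alphabetically for determinism). The classifier then:

1. smooths `log10(percentage)` against rank with a local *linear*
   regression (loess, default span 0.5 of the points, widened to keep at
   least five points in a window);
2. takes the second derivative of the smoothed curve by central finite
   differences at integer ranks;
3. marks sign changes of that second derivative as inflection points,
   ignoring curvature below `min_prominence` (default 0.2) times the
   curve's maximum absolute second derivative;
4. takes the smoothed percentage at the *last* inflection — the one
   nearest the low-abundance end — as the library's cut-off;
5. histograms the per-library cut-offs on the log10 scale in bins of 0.25
   (centred on multiples of the bin width) and returns the geometric
   midpoint of the modal bin as the consensus cut-off, ties going to the
   lower bin.

Two numerical choices deserve explanation. *Degree 1 rather than degree 2
smoothing*: on strongly two-regime curves — a geometric head, a sharp drop,
a slowly decaying tail — a local quadratic fit overshoots around the drop
and its oscillation writes spurious curvature sign changes into the tail;
since the rule keeps the *last* inflection, a single echo there hijacks the
cut-off. The damped local linear fit shows no such ringing, and planted
knees are recovered stably across spans 0.4–0.6. *The prominence filter*:
families sampled at a handful of reads wrinkle the tail, and those
sampling-jitter reversals are tiny in curvature compared with the
head-to-tail regime change; requiring a fifth of the maximum curvature on
both sides of a sign change suppresses them without touching the dominant
knee. Exactly log-linear curves additionally get an absolute curvature
floor (`zero_tol`, default 1e-6) so floating-point dust is never a sign.

A family is ORB in a library if its percentage exceeds the cut-off and URB
if it is positive but at or below it — the boundary goes to URB, a
convention that must simply be fixed and documented since a family exactly
at the threshold is not meaningfully "over-represented". At group level
the family's median percentage across the group's libraries decides.

Direction of "last": the implementation reads the descending-sorted curve
toward the low-abundance end, where the head hands over to the tail, which
is the reading under which the cut-off separates regimes; the opposite
reading (`direction = "first"`) is available.

## Active-vs-total Welch comparison

For each family, each subject's three active-fraction percentages are
summarized by their median, and likewise the two total-fraction
percentages, giving one active and one total value per subject (n = 4 per
group by default). The two vectors are compared with Welch's
unequal-variance t statistic and Satterthwaite degrees of freedom,
two-sided, at alpha 0.05. Summarizing per subject first keeps subjects —
not libraries — as the exchangeable unit; pooling the per-library values
instead (n = 12 vs 8) is available via `per_sample_medians = FALSE`.
Subjects in which the family is absent from a whole group drop out of that
group's vector rather than contributing zeros (`include_zeros` reverses
this); imputed zeros would manufacture variance for families at the
detection limit. Degenerate inputs are explicit: zero variance in both
groups with equal means gives t = 0, p = 1; with unequal means the result
is flagged degenerate rather than silently divided. No multiple-testing
correction is applied by default, matching the convention of reporting
per-family significance marks; `p.adjust` on the returned p-values is one
line for users who want it.

## What the synthetic generator emulates

The generator plants, per library, a two-regime rank-abundance curve: a
geometric head of `n_orb` families whose smallest member sits at three
times the knee, and a log-series tail of `n_urb` families whose largest
member sits at a third of the knee, so a curvature change exists exactly at
the planted knee (default 1% — a round mid-scale value; the defaults
`n_orb = 8`, `n_urb = 40` give the short head and long tail that
family-level gut surveys show, and the taxonomy default of 13 phyla and 79
families matches that survey scale). Per-library lognormal noise
(`noise_sd = 0.25` on the natural-log scale, i.e. about ±25% abundance
scatter) keeps the head/tail margins intact. Active-vs-total effects are
multiplicative fold changes applied to total-fraction libraries and
renormalized; the default effect map enriches one moderately abundant
family about 9-fold and another about 5-fold in totals and depletes several
others 3-fold, mirroring the strong taxon shifts such sorting experiments
report. Because renormalization redistributes mass, the realized
total/active ratio of the 9-fold family is about 7.5 — the generator's
ledger, not the nominal fold, is the recovery target.

Reads are windows of 460–520 nt from per-species reference sequences (the
27F–530R amplicon scale) with substitution errors at `error_rate`
(default 0.005/base); a `dup_rate` share of each library's reads are
byte-identical emulsion-duplicate copies drawn *after* error injection,
matching the dereplication definition. Hit tables give the true species
the top bitscore and add lower-scoring decoys from the same family or
genus. All randomness descends from one seed through labelled child seeds
(`child_seed`), so stages are independently reproducible.

What the generator does **not** emulate: 454 flowgrams, homopolymer or
quality-correlated errors, chimeras, reference databases with missing
clades, and compositional correlations between families. Passing recovery
tests therefore shows the procedure is internally correct and calibrated,
not that real gut data meets its assumptions.

## Problem sizes and runtime choices

The validation suite runs the full read-level pipeline once at 10,000
reads per library over the 20-library design (the depth at which the
planted tail is resolvable), uses 500 replicates for type-I-error
calibration of the PERMANOVA and Welch tests, 10,000 resampling replicates
for the rarefaction oracle, and 60–100 seeded replicates for power checks;
permutation counts in tests are 49–199, while the analysis default is 999.

## Known limitations

- The consensus cut-off is quantized to the 0.25-log-unit bin grid, so its
  resolution is a factor of about 1.8; within-factor-2 recovery of a
  planted knee is the designed accuracy, not a limitation of sampling.
- The inflection detector assumes a single dominant regime change; curves
  with several comparable knees will report several prominent inflections
  and the "last" rule picks the rarest-end one.
- Sequential SS depend on term order by construction; reported R² values
  are order-conditional.
- Exact dereplication treats any two reads differing by one error as
  distinct, so residual duplicates with sequencing errors survive (as they
  do for any exact-identity rule).
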
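---
title: "Exact-p-value motif scanning of promoter sets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-p-value motif scanning of promoter sets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscan)
```

# The scoring model and its assumptions

A transcription-factor motif enters the package as a position frequency
matrix (PFM): per-position counts of A, C, G, T over an alignment of known
binding sites. The scoring model assumes positional independence — each
column contributes additively — and a fixed background base distribution
$b$ (uniform, $b_a = 0.25$, unless the user supplies another). A window
$s_1 \ldots s_L$ scores

$$S \;=\; \sum_{i=1}^{L} \ln \frac{f_{s_i,i}}{b_{s_i}},$$

where $f_{a,i}$ is the column probability of base $a$. Both strands are
scanned (PFMs carry no strand information); a reverse-strand hit is
anchored at the leftmost forward-strand base of the interval it covers,
which keeps hit intervals BED-compatible. Palindromic motifs therefore
report both a `+` and a `-` hit over the same interval; both are kept, and
downstream counts treat them as two predictions.

Windows containing any base outside A, C, G, T are skipped: the model
assigns no defensible likelihood to ambiguity codes, and imputing one
would silently manufacture scores in repeat-masked or gappy regions.

## Pseudocount

JASPAR-style count matrices regularly contain zero cells, which would give
$-\infty$ weights. Counts are regularized as
$f_{a,i} = (n_{a,i} + p b^{0}_a)/(N_i + p)$ with the pseudocount $p$
spread by a uniform reference $b^0_a = 0.25$. The default $p = 0.8$
(0.2 per base) barely perturbs matrices built from tens of sites but keeps
every weight finite. $p = 0$ is allowed; building a model from a matrix
with zero cells then fails loudly rather than producing infinite weights.
Models whose columns all equal the background have no score range and are
rejected at build time ("degenerate"), because their normalized score
would be 0/0.

# Exact p-values

Scores are calibrated by the classical dynamic-programming convolution:
weights are scaled by a granularity $\kappa$ (grid units per nat) and
rounded half-up to integers $\delta_{a,i}$, and the null distribution of
the integer score is built column by column,

$$D_i(t) = \sum_a b_a \, D_{i-1}(t - \delta_{a,i}),$$

with the survival function $P(S \ge t)$ as a reverse cumulative sum. For
the discretized model this is *exact* — the test suite checks it against
exhaustive enumeration of all $4^L$ words, where it agrees to floating-point
precision.

Three numerical choices matter:

* **Granularity.** The default $\kappa = 10^4$ bounds the rounding error
  of any single weight at $5\times10^{-5}$ nats and keeps the grid for a
  motif-length model in the low millions of bins — exact p-values at
  negligible memory. Doubling $\kappa$ never moves a p-value further from
  the continuous-score enumeration oracle (a property test covers two
  decades of refinement).
* **Scanning on the grid.** A raw window score is a sum of *unrounded*
  weights; rounding that sum onto the grid can drift up to $L/2$ grid
  units from the sum of *rounded* weights the distribution was built
  from. For models whose score spectrum is a sparse lattice (e.g. motifs
  with identical columns), that drift crosses survival-function steps and
  would mis-classify windows near the threshold. The scanner therefore
  scores every window a second time with the rounded integer weights and
  takes its p-value by direct lookup — each hit's p-value is the exact
  tail probability of its discretized score. The reported `raw_score`
  remains the exact sum. `pvalueOfScore()` on a user-supplied raw score
  rounds half-up and clamps overshoot above the grid maximum within the
  $L/2$ band, so the maximum score always maps to $p_{\min}$.
* **Strict threshold.** A hit is a window with $p < \text{cutoff}$
  (strictly). `scoreThreshold()` returns the smallest grid score whose
  p-value is below the cutoff; when even the maximum score is not
  ($p_{\min} \ge \text{cutoff}$) the cutoff is *unreachable* for that
  model and the function returns `NA` — a value, not an error, because
  "which motifs can still produce hits at this stringency" is itself an
  analysis output (`minPvalueTable()`). A cutoff of exactly 1 is treated
  as "no cutoff": every scoreable window counts, which anchors the 100%
  baseline of cutoff sweeps by construction.

# Promoter construction

Promoters are genomic windows `[anchor − flank, anchor + flank)` (0-based
half-open throughout; default flank 2000), anchored at the TSS or, for
genes without an annotated TSS, at the coding sequence start. The CSS
fallback is worthwhile because TSS–CSS distances are strongly skewed
towards small values: for most genes the CSS sits within a few hundred
bases of the TSS, so a ±2 kb window around the CSS still covers the
active promoter. `tssCssDistances()` quantifies this on any gene table.

Conventions chosen where the design was genuinely open:

* **Deduplication.** Annotation sources map some accessions to several
  locations. One record is kept per version-stripped accession: the one
  whose chromosome name sorts first lexicographically (ties: lowest
  anchor). This prefers chr1 over chr1_random, the desired behavior; it
  also makes chr11 sort before chr2, which is documented rather than
  special-cased — the rule's purpose is a deterministic preference for
  primary assemblies, not numeric chromosome ordering.
* **Clipping.** Windows that would overrun a chromosome end are clipped
  and flagged, not dropped: edge genes remain queryable, and the
  positional statistics divide by per-bin promoter coverage so clipped
  promoters do not bias profiles.
* **Anchor-relative coordinates.** Sequences are stored 5′→3′ of the
  gene; position $j$ of an unclipped promoter maps to anchor-relative
  coordinate $j - \text{flank}$ on **both** strands, so coordinates span
  exactly `[-flank, flank)` and position `flank` is the anchor base. On
  the minus strand this places the anchor in the half-open slot one base
  differently than naive genomic mirroring would; the symmetric span was
  chosen so that profiles from + and − genes superimpose without a
  one-base offset.

# The annotation store and queries

The store keeps, per genome, the promoter set and its hit table, each
tagged by layer (`default`/`user`); queries always see the union, so a
user can overlay private hits or novel promoters on a shared baseline.
Querying is two-step by design: `queryGenes()` returns only accessions
(cheap, combinatorial — AND/OR over count-thresholded feature terms, pair
terms with a separation window, optional homology requirement), and
`hitsForGene()` fetches full hit detail for one promoter on demand.

The cross-genome filter keeps a gene only if some homolog in the target
genome also carries a hit of the same feature. In enrichment, the
homology-filtered variant restricts both gene sets to genes that have
homologs and zeroes a gene's count for a feature whose homolog lacks that
feature. Chance background hits are rarely conserved, so filtering
suppresses them in both sets and moves the ratio toward the planted
(true) rate ratio — the amplification the acceptance checks measure.

# Enrichment statistics

For feature $t$, $\bar P_t$ and $\bar N_t$ are mean hits per gene in the
positive and negative set and $r = \bar P_t / \bar N_t$. Features absent
from the negative set get an undefined ratio: they are flagged and ranked
last, never silently dropped, since "seen only in positives" is
informative. Confidence intervals are percentile bootstrap over genes
(resample genes with replacement, take the 2.5%/97.5% quantiles of the
resampled means) — the minimal bootstrap variant, deterministic given a
seed. No multiple-testing correction is applied to ratios; they are
descriptive rankings, not hypothesis tests.

**Pairs.** Site pairs are counted per promoter over *hit pairs* (not
promoter presence/absence): every unordered pair of hits — same feature
allowed — whose gap (end of the upstream hit to start of the downstream
hit) lies in `[minSep, maxSep]`, defaults 10–100 bases, inclusive bounds.
Overlapping hits never pair and strand is ignored. "Separation" is
deliberately the inter-site gap, not the start-to-start distance: the
biological constraint being modeled is spacing between adjacent bound
factors.

# The synthetic-data generator

The generator exists so that every pipeline stage is testable without
downloads, with known ground truth:

* **Genomes** are i.i.d. bases at a stated GC content or a linear GC
  ramp. This emulates composition, not chromatin, repeats, or
  higher-order sequence structure.
* **Gene tables** place genes uniformly (with an end margin), draw
  TSS–CSS distances from a log-normal law — defaults `meanlog = log(373)`,
  `sdlog = 1.76`, matching the skewed distances seen in mammalian
  annotation (median ≈ 373, quartiles ≈ 114 and ≈ 4280) — and can leave a
  stated fraction of TSS unannotated and duplicate a stated fraction of
  accessions onto `_random` chromosome copies, the two annotation
  pathologies the promoter builder must handle.
* **Planting** inserts a motif's word into promoter windows with Poisson
  counts (`ratePos` in the positive set, `rateNeg` in the negative),
  replacing bases so coordinates stay stable, re-drawing overlaps, and
  optionally copying each planted site into the homologous promoter of a
  second genome with a stated conservation probability. The truth table
  records every insertion.

One parent seed fans out into per-component child seeds, so identical
seeds reproduce files byte-for-byte while components can be regenerated
independently.

What passing tests on this generator do **not** show: performance on real
promoters, whose GC structure, repeats and motif clustering violate the
i.i.d. background; the false-positive calibration in particular is a
statement about the null model, and real sequence will always produce
more (and spatially structured) hits than the nominal p-value suggests.

# Problem sizes and runtime choices

The test and acceptance fixtures are sized to be decisive yet quick: 50
random models up to $L = 8$ for the enumeration oracle ($4^8$ words each);
200 promoters × 4 kb × 5 models for cutoff nesting and sweeps; $10^6$
scanned positions for false-positive calibration; 400 genes (flank 500)
for planted-enrichment recovery and 300 for homology amplification; 1000
random hit layouts for the pair-counting oracle. Gene fixtures for the
enrichment checks space promoters so windows never overlap — overlapping
windows share planted sites between neighboring genes and would dilute
the recovered ratio for reasons unrelated to the statistics under test.

# Known limitations

* Zeroth-order background only; no dinucleotide or Markov background.
* No motif discovery, no TRANSFAC parsing, no hit clustering or merging
  of palindromic double-reports.
* The in-memory store targets promoter-scale data (tens of thousands of
  promoters × hundreds of motifs), not whole-genome hit inventories.
* Ratios carry no significance calibration beyond the bootstrap CIs of
  the underlying means.
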
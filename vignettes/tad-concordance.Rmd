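---
title: "Quantifying concordance between TAD datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concordance between TAD datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadconcord)
```

## The problem

Topologically associating domains (TADs) are contiguous genomic regions with
elevated internal chromatin contact frequency, visible as blocks along the
diagonal of a Hi-C contact matrix. Dozens of TAD callers exist, built on
quite different principles (linear scoring, clustering, statistical
segmentation), and on the same matrix they disagree — in how many domains
they find, how large those domains are, and where exactly the boundaries
fall. No experimental gold standard exists, so the practical question is not
"which caller is right" but "where do callers agree, and how much". This
package answers that question quantitatively for any collection of two or
more TAD datasets on a common chromosome region.

## Data model

All comparisons happen on a shared coordinate frame, the `genomic_binning`:
one chromosome, a resolution (bin width in bp) and a bin count. Bin `i`
(0-based) covers the half-open bp interval `[i*res, (i+1)*res)`. A `tad_set`
is an ordered list of non-overlapping half-open bin intervals; gaps between
domains are allowed, because real TAD maps rarely tile a chromosome.
Adjacent domains may share a corner (`end == next start`); in boundary
analyses that corner counts once (set semantics).

TAD files arrive either as BED3 (`chrom start end`, 0-based half-open, bp)
or as headerless two-column `start end` text. Because caller outputs are
inconsistently scaled, coordinates may be bp or bin indices; with
`units = "auto"` the reader treats a file whose largest coordinate is below
`2 * n_bins` as bin-indexed, otherwise as bp, reports the choice, and lets
the user override it. bp intervals are snapped to bins *outward*
(`floor` for starts, `ceiling` for ends), so a partially aligned interval
keeps its full coverage. Overlapping input domains are an error rather than
being clipped silently: every downstream statistic assumes disjoint domains,
and silent repair would corrupt the concordance scores.

## Tolerance-based sharing

Two boundaries are shared at tolerance `t` (in bins) when they lie within
`t` bins of each other; `t` bins equals `t * resolution` bp. A domain is
shared when *both* its rising and falling boundary match those of some
domain in the other dataset within the tolerance. Matching is existential:
an element of `a` is shared if *any* element of `b` is close enough. This
is deterministic and needs no tie-breaking; the price is that two elements
of `a` may match the same element of `b`, so the count is not a bipartite
matching size and is asymmetric between datasets. Counts are non-decreasing
in `t` by construction. The default tolerance range for the report tables
is 0–3 bins.

A consequence worth knowing when designing analyses: exact (tolerance-0)
matching is the only setting that can distinguish boundary noise of ±1 bin
from perfect agreement, because any jitter of magnitude `<= t` is invisible
at tolerance `t`. The package's own perturbation-recovery validation
therefore measures its jitter ladder at tolerance 0.

## Measure of Concordance

For domains `A_i` of one dataset and `B_j` of another, each pair contributes
`|A_i ∩ B_j|^2 / (|A_i| · |B_j|)`; summing over all pairs gives `S`, and

```
MoC = (S - 1) / (sqrt(N_A * N_B) - 1)
```

with `N_A`, `N_B` the domain counts and the convention `MoC = 1` when
`N_A = N_B = 1`. Identical partitions score exactly 1, the score is
symmetric, and for partitions that fully tile the region it is nonnegative
(a Cauchy–Schwarz argument). Overlaps are computed in bins; the per-pair
term is scale-invariant, so any common unit gives the same value. Gapped
datasets are accepted, and in pathological near-disjoint cases the score
can dip below 0 — it is then reported raw with a warning, not clamped,
because a negative MoC is a data problem the user should see.

```{r moc-example}
bn <- genomic_binning("chr1", 1L, 20L)
x <- tad_set("halves", bn, c(0L, 10L), c(10L, 20L))
y <- tad_set("offset", bn, c(0L, 12L), c(12L, 20L))
moc(x, y)   # (5/3 - 1) / (2 - 1) = 2/3
```

The report computes MoC pairwise (a symmetric matrix with unit diagonal),
one-vs-all against a chosen reference, and as the all-vs-all average —
each dataset's mean MoC over the other `K - 1`.

## Matrix balancing

The preprocessing front end ingests dense square text, 3-column triplets
(bin indices or bp, auto-detected), and cooler/HDF5 containers
(single-resolution and `/resolutions/<res>` multi-resolution layouts; an
absent chromosome errors listing the available ones, and a multi-resolution
container requires an explicit resolution). Five balancing methods are
provided: vanilla coverage (VC), its square-root variant, Knight–Ruiz-style
diagonal scaling (KR), iterative correction (ICE) and sequential component
normalization (SCN). Bins with zero marginal sum are masked before
balancing and restored as zero rows/columns, since all these iterations
diverge on zero marginals. Defaults: tolerance `1e-5`, 200 iterations for
ICE/SCN, 3000 for the cheap KR fixed-point updates. KR targets unit row
sums exactly; ICE equalizes row sums up to a global scale and is rescaled
to unit mean over unmasked entries; VC and SQRT-VC preserve the total sum
of the input. All methods preserve symmetry and nonnegativity, and KR/ICE
are idempotent up to tolerance.

## Similarity embeddings

To place whole datasets in a common space, each `tad_set` is vectorized
per bin. Three representations are available: a boundary indicator, a
domain-occupancy indicator, and the default *dilated* boundary indicator
(boundaries widened by ±1 bin), which makes near-miss boundaries contribute
similarity, consistent with tolerance matching. PCA projects the centred
vectors onto the top two principal axes; each axis is oriented against a
fixed reference direction so the output is reproducible and invariant to
the order in which datasets are supplied (the naive "largest loading
positive" rule is ambiguous here, because binary features produce exactly
tied loadings). t-SNE (exact, `theta = 0`) uses perplexity
`min(30, (K - 1)/3)` and is initialized from the two leading principal
components at the conventional 1e-4 scale: with the small `K` typical of
TAD comparisons, a random start frequently scrambles global structure,
while a PCA start preserves it — the standard recommendation for modern
t-SNE use. A seeded random initialization remains available
(`init = "random"`). Identical inputs and seed give bit-identical
coordinates either way.

## The synthetic generator

Validation needs inputs with known structure, so the package generates
them. `generate_partition()` lays domains left-to-right with sizes uniform
on `min_size..max_size` bins and, with probability `gap_prob`, a gap of
1–`gap_max` bins, stopping when the next domain would overrun the region.
The defaults — 500 bins, sizes 5–25, `gap_prob = 0.1`, `gap_max = 3` —
emulate a 20 Mb region at 40 kb resolution carrying 0.2–1 Mb TADs with
occasional unassigned gaps, the regime in which human TAD callers operate.

Three perturbation operators model the disagreement modes observed between
real callers: `jitter_tads()` shifts each boundary by a bounded uniform
offset (boundaries processed left to right; a shared corner moves as one
unit; moves clamp one bin short of the neighbouring boundary so validity
is preserved by construction), and `merge_split()` merges adjacent domains
("fewer, larger TADs") or splits domains at a uniform interior point
("many small TADs"). `generate_matrix()` produces a symmetric Poisson
block matrix with elevated intra-domain rates for exercising the
balancing code.

What the generator does *not* emulate: genomic distance decay of contact
frequency, nested sub-TAD hierarchy, caller-specific biases, and empirical
TAD-size distributions (sizes are uniform; the validation properties
depend only on effect *ordering*, not on the size law). Passing the
synthetic checks therefore demonstrates correctness of the comparison
machinery, not that any particular caller is accurate on real Hi-C data.

## Numerical and design choices

- Quartiles of domain sizes use linear interpolation between order
  statistics (R's type-7 default), so summary values are exactly
  reproducible.
- Sparse triplet ingestion sums duplicate cells (in either orientation)
  with a warning rather than erroring; conflicting duplicates usually mean
  a file was exported twice, and the sum is the only lossless resolution.
- The triplet bp/bin auto-detection calls coordinates bp only when all are
  divisible by the resolution *and* the largest reaches `n_bins` — bin
  indices cannot reach bp scale, so the rule cannot misfire on valid input.
- Reports omit wall-clock timestamps from provenance so that re-running a
  config yields byte-identical files; determinism is part of the report
  contract and is tested at the byte level.
- Validation problem sizes: 100 random datasets for identity/symmetry and
  round-trip properties, 200 random pairs against brute-force enumeration,
  100-seed perturbation ladders on 500-bin partitions, 50 block-model
  fixtures of 200 bins for balancing, and 100-seed two-family designs
  (5 + 5 replicates on 200 bins) for cluster recovery.

## Limitations

One chromosome per comparison; multi-chromosome sets must be split
beforehand. BED fields beyond the third column are ignored; GFF and
Juicer `.hic` input are not supported. No statistical significance is
attached to boundary overlaps (no permutation test), and no alternative
partition-similarity indices are provided. The balancing front end
handles intra-chromosomal matrices only and offers no distance-decay
(observed/expected) normalization.
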
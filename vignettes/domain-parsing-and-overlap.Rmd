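---
title: "Parsing predicted structures into domains and comparing segmentations"
author: "DomainScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing predicted structures into domains and comparing segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomainScope)
```

## The problem

Predicted protein models arrive without domain boundaries. Two families
of methods draw them: purely structural segmentation (geometric
compactness of the fold) and evolution-aware parsing (which also asks
whether residue pairs co-occur in known reference domains). The two
disagree in systematic ways — inserts and terminal extensions get
promoted to independent domains by one and absorbed by the other, and
repeat arrays get cut at different granularities. DomainScope
implements one evolution-aware parser, a four-way quality
classification of domain-to-reference assignments, and a quantitative
comparison of two segmentations of the same proteins, all exercised on
synthetic ground truth.

## Data model

`SegmentList` is the primitive: sorted, disjoint, non-adjacent, 1-based
inclusive residue intervals, built on `IRanges`. Adjacent or
overlapping input intervals are merged on construction because a
segment list denotes a residue *set*; `"5-10,11-12"` and `"5-12"` are
the same domain. All range strings accept both hyphens and en-dashes,
since printed ranges in the literature use the latter. `ProteinModel`
carries CA coordinates (Å), the PAE matrix (Å, values in [0, 35],
asymmetric), optional per-residue pLDDT and secondary-structure labels.
`DomainAnnotation` adds protein/domain identifiers and a source label
(`dpam` for the parser side, `ted` for the alternative segmentation,
`truth` for synthetic ground truth).

## The parser

### Disorder and linker masking

Residues that are disordered or sit in inter-domain linkers carry
uniformly high predicted error and must not seed domains. A residue is
masked when the median symmetrized PAE between it and its sequence
neighbors within ±10 positions exceeds 20 Å, or when its pLDDT is below
50 (when available).

The window is deliberately *sequence-local* rather than row-global. A
residue in a domain that covers less than half of a multi-domain chain
has high PAE to most of the protein — the row median would mark the
entire domain disordered — but its error against its own neighborhood
stays low; only genuinely disordered residues have high error even
locally. The local median is robust to the window straddling a domain
boundary (half the window is still low-error). After masking, included
runs shorter than one segment (5 residues) flanked by masked residues
are absorbed into the mask: they are linker fragments, not domains.

### Pair probability

Each unmasked residue pair is scored

$$P_{ij} = \sigma\!\left(w_0 - w_d\,\frac{d_{ij}}{D} - w_e\,\frac{e_{ij}}{E} + w_s\,s_{ij}\right)$$

with $d_{ij}$ the CA–CA distance, $e_{ij}$ the symmetrized PAE
($e_{ij} = (\mathrm{PAE}_{ij}+\mathrm{PAE}_{ji})/2$) and
$s_{ij}\in[0,1]$ the co-alignment support — the fraction of
homology-search evidence placing the pair in the same reference domain.
Defaults: $w_0 = 1$, $w_d = w_e = w_s = 2$, $D = 20$ Å, $E = 10$ Å. The
logistic form is chosen for monotonicity (never increasing in distance
or error, never decreasing in support) and calibration simplicity; the
weights are exposed in `parserConfig()` and are not a claim about any
published parser's internal model. Under these defaults a typical
intra-domain pair (d ≈ 8 Å, PAE ≈ 3 Å, supported) scores
σ(1.6) ≈ 0.83, while an inter-domain pair (PAE ≈ 25 Å) scores
essentially 0; the PAE term dominates the separation, and support
carries pairs at the far side of large domains across the 0.5 line.

### Segmentation and clustering

Unmasked runs are tiled left-to-right into 5-residue segments; a
terminal remainder shorter than 5 is merged into the preceding window
so no spurious mini-segment arises. Segments are merged by average
linkage — the linkage of two clusters is the mean of $P_{ij}$ over
their residue cross product — while the best linkage is at least 0.5
(the probability midpoint). Average linkage resists single noisy pairs;
the running sums make merges exact rather than approximated from
segment-level averages. Ties in the best pair are broken toward the
pair whose leftmost residue is smallest, making the procedure fully
deterministic. Clusters that end below 25 residues are attached to
their best neighbor if that linkage reaches half the cutoff, and
otherwise dropped as linker; 25 residues is the conventional lower end
of domain-scale granularity.

```{r}
tr <- genProtein(generatorParams(seed = 7))
set.seed(7)
parseProtein(truthProtein(tr), genSupport(tr))
```

## Assignment classification

Each domain carries assignment metadata: a confidence score in [0, 1]
for its best reference assignment, `Best_Seq_Rel` (the best
sequence-profile match probability, on [0, 1]), a structural Z-score,
architecture and X-group labels, and a reference length. Categories are
assigned with this precedence:

1. **simple_topology** — at most 2 secondary-structure elements. A
   helix needs ≥ 4 consecutive H residues, a strand ≥ 3 consecutive E;
   runs broken by a range discontinuity are counted piecewise. The
   structural condition is checked first: a two-helix hairpin is
   simple-topology no matter how confident its match.
2. **partial** — confidence > 0.9 but length < 0.5 × reference length:
   a confident hit to a much longer reference domain.
3. **well_assigned** — confidence > 0.9 otherwise.
4. **unassigned** — the rest.

The "one or two SSEs" boundary is the only quantitative anchor for
simple topology, so "a significant number of SSEs" is operationalized
as ≥ 3; the 0.5 length ratio for "much longer reference" is a package
choice, exposed in `defaultThresholds()`. All printed thresholds are
strict in their printed direction ("above 0.9" is > 0.9), so boundary
values fall to the unassigned/intermediate side; `binBestSeqRel()`
likewise puts 0.95 in the intermediate bin and its four bins partition
[0, 1].

## Comparing two segmentations

For a parser-side domain A and an alternative-side domain B of one
protein, `overlapFractions()` reports
$f_A = |A \cap B| / |A|$ and $f_B = |A \cap B| / |B|$. Pairs are formed
by matching each B-side domain to the A-side domain with maximal
intersection (ties toward the smaller first residue; one B domain per
pair, A domains may recur); pairs where neither fraction strictly
exceeds 0.5 are dropped as insignificant. Categories:

| category | condition |
|---|---|
| consistent | $f_A > 0.8$ and $f_B > 0.8$ |
| ted_embedded | $f_B > 0.8$ and $f_A < 0.6$ |
| dpam_embedded | $f_A > 0.8$ and $f_B < 0.6$ |
| intermediate | otherwise |

All comparisons are made on exact integer counts
(`intersection × 5 > length × 4` rather than `f > 0.8`), so a fraction
that is exactly a threshold is never misclassified by floating-point
rounding. Swapping the roles of the two segmentations swaps the two
fractions and the two embedded categories; if B ⊆ A then $f_B = 1$.

```{r}
pairDomains(list(DomainAnnotation("S0G0I7", "D01", "1-370", "dpam")),
            list(DomainAnnotation("S0G0I7", "TED02",
                                  "198-234,282-371", "ted")))
```

Note one consequence of the rule set: when a single parser-side domain
faces two equal halves on the other side, each half has $f_B = 1$ and
$f_A = 0.5 < 0.6$ and is therefore classified as embedded — the
embedded categories capture "B is a fragment of A" regardless of
whether B arose as an insert or as a split half.

## The synthetic generator

`genProtein()` emulates exactly the features the parser consumes, and
no more:

- **Geometry.** Per-domain CA clouds are confined random walks (3.8 Å
  steps) within radius $2.3\,L^{0.38}$ Å of centers spaced 40 Å apart —
  the empirical size scaling of globular domains — joined by
  interpolated linkers and flanked by free-walk disordered tails.
  Coordinates are realistic only at the level of the distance feature;
  they are not foldable backbones, and no physics is implied.
- **PAE.** Block-normal: mean 4 Å (sd 1) within domains, 25 Å (sd 2)
  between, 28 Å on disordered rows/columns, clipped to [0.2, 31.75] —
  the AFDB encoding ceiling — and left asymmetric for the parser to
  symmetrize.
- **Support.** Bernoulli 0.9 within domains, 0.05 elsewhere, zero on
  disordered residues, symmetric.
- **Annotation.** pLDDT high (85–98) in domains, low (25–45) in
  disorder; SSE labels are *assigned* per domain as alternating
  helix/strand runs rather than computed from geometry — counts, not
  shapes, are what the classifier consumes, and a geometric SSE
  assignment is out of scope.
- **Lengths.** Domains 60–150 residues, linkers 5–15, tails 5–25 per
  terminus: typical scales for predicted multi-domain proteins.

`perturbAnnotation()` produces the alternative segmentation by
splitting a domain, merging two, trimming termini, or carving an
interior insertion out (the insert becomes its own discontinuous
domain, mirroring the embedded-insert geometry above). Split, merge and
carve conserve the parent residue set exactly; trim removes residues by
design. `genMetadata()` draws confidence from a two-component mixture
(high component near 0.97), bimodal `Best_Seq_Rel`, a gamma structural
Z-score (default mean 9.18, sd 6.99), architecture labels from an
18-name catalog, and log-normal reference lengths. All generator
distributions are the package's own modeling choices — the generator
defines test conditions; it is not fitted to any database.

Reproducibility: one master seed per cohort, with per-protein
substreams derived by a fixed integer recurrence, so cohorts regenerate
byte-identically and proteins stay independent.

### What passing tests do and do not show

The generator's PAE contrast (4 Å vs 25 Å) is cleaner than real
predicted models, where inter-domain error varies with relative-domain
confidence and intra-domain error rises toward surfaces and termini.
Recovery of ground truth on this synthetic cohort (the test suite
demands ≥ 95% correct domain counts with boundaries within ±10 residues
on 200 seeded two-domain proteins, and observes exact recovery)
validates the *machinery* — masking, feature scoring, clustering,
bookkeeping — not parsing accuracy on real AlphaFold models, which
depends on feature weights no synthetic benchmark can calibrate.

## Numerical conventions

- Percentages round half away from zero (`percentage(1, 8)` is 13),
  matching printed tables; complementary parts may sum to 99–101.
- The structural-Z summary uses the sample (n−1) standard deviation and
  the midpoint median; a single value reports sd 0 with a warning.
- Degenerate inputs: an all-masked protein parses to zero domains; an
  empty cohort renders an all-zero report; readers reject malformed
  inputs (reversed intervals, ragged PAE payloads, duplicate chopping
  keys) rather than repairing them, with two documented exceptions —
  adjacent-segment merging and PAE clipping to [0, 35] (with a
  warning).
- Problem sizes in the shipped tests — 200 recovery proteins, 1,000
  random segment-list pairs against the brute-force intersection
  oracle, 2,000-domain metadata samples — are chosen so the whole suite
  runs in about half a minute while keeping sampling error well inside
  the asserted tolerances.

## Limitations

- The parser's probability model is a documented stand-in with exposed
  weights, not a reimplementation of any published parser; likewise the
  5-residue segmentation is tiled, and whether published tools tile or
  overlap their segments is not modeled.
- Assignment confidence, `Best_Seq_Rel` and structural Z-scores are
  *inputs* (or synthetically generated): no homology search, structure
  alignment or neural assignment is performed.
- Single-chain models only; CA-level coordinates only; no mmCIF
  output.
- Many-to-many boundary disagreements are resolved by best-intersection
  pairing; summing overlaps across multiple partners is not offered.
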
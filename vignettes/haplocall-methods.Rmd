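---
title: "Classifying mitochondrial haplogroups with haplocall: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mitochondrial haplogroups with haplocall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplocall)
```

## The classification model

Human mtDNA phylogenies label each branch with the variants that arose on
it, relative to a reference sequence (conventionally the 16,569 bp rCRS).
The expected profile `E(h)` of a haplogroup `h` is obtained by replaying
the branch events from the root to `h`. Three event semantics matter:

* a forward variant adds itself to the profile, superseding any earlier
  event at the same position, kind and insertion slot;
* a back mutation (`"!"` suffix) removes the matching ancestral event —
  matching is by position, kind and insertion slot, deliberately ignoring
  the written allele, because the reversion targets the site, not a
  specific alternate;
* a later forward event at a reverted site re-adds it.

Resolved profiles therefore never contain back-mutation marks.

Samples are scored against every haplogroup (exhaustive scoring; at a few
thousand nodes and samples this is well within desk budgets and avoids the
corner cases of greedy descent). Both variant sets are first restricted to
the sample's analysed range and stripped of hotspot *positions* — filtering
by position rather than by exact label makes the classifier insensitive to
allele spelling at hypervariable sites. The default quality is the weighted
Kulczynski similarity

$$S = \frac{1}{2}\left(\frac{W_{O\cap E}}{W_E} + \frac{W_{O\cap E}}{W_O}\right),$$

with the conventions that an empty denominator contributes its term as 1
(so an empty-vs-empty comparison scores 1, and a reference-identical sample
classifies to the root with quality 1 plus an explicit notice — the
behaviour for such samples is genuinely ambiguous, and the notice makes the
choice visible). Weighted Jaccard ($W_{O\cap E}/W_{O\cup E}$) and a
Hamming-derived quality ($1 - W_{O\triangle E}/(W_E + W_O)$) are selectable
alternatives; all three are exactly 1 for identical sets and 0 for disjoint
non-empty sets, which the test suite verifies against brute-force set
arithmetic together with monotonicity under adding shared/unshared mass.

Variants missing from the weights table receive the default weight 10; with
no weights file at all every metric degrades gracefully to unweighted set
counting.

Ranking ties are broken lexicographically by haplogroup name: determinism
across platforms is worth more than any arbitrary alternative.

### Tree distance and clusters

The distance between two haplogroups is the number of variants by which
their expected profiles differ after back mutations along the connecting
path are resolved, hotspots excluded. A raw count of edge variants on the
path was the obvious alternative, but it double-counts an event pair when a
branch both acquires and reverts a variant along the path; the resolved
form is symmetric, zero exactly for identical profiles, and provably
satisfies the triangle inequality (it is the symmetric-difference metric on
profiles), which the suite checks exhaustively on small trees. Top-level
cluster assignment takes the cluster label with minimal distance, preferring
an ancestor on ties, then lexicographic order. The cluster list is data in
the tree package (`clusters.txt`), not code.

## Ranges on a circular genome

Analysed ranges are unions of inclusive 1-based intervals; an interval with
start > end wraps the origin (the control region, roughly 16024–576, is the
canonical case). Genotyping arrays only assay selected positions, so in
array mode the range is exactly the typed sites (adjacent positions merged);
expected variants at untyped positions then cannot penalize a sample.
Partial FASTA records get the reference span covered by their alignment,
minus positions aligned to N.

## Indel normalization

Pairwise aligners left-align indels; mitochondrial nomenclature right-aligns
them (the classic C insertion in the 303–315 homopolymer is written
315.1C). Generic right-alignment shifts every indel to the rightmost
position at which the implied haplotype sequence is unchanged — for
insertions the inserted string rotates as it shifts. The tree package's rule
table (`rules.txt`, `source<TAB>target`, applied in file order when *all*
source variants are present) then handles residual aligner-specific
spellings that position shifting cannot express. Running generic
right-alignment first keeps the rule table small. Rules are context-free
(they do not condition on haplogroup), and the engine is idempotent by
construction provided rule targets do not re-match rule sources.

## Input handling

**hsd** is parsed as-is: profiles are already in tree nomenclature, so no
normalization is applied. Malformed variant tokens become per-sample
warnings rather than parse failures, because a single bad token should not
discard a biobank row.

**VCF** records are split per alternate allele, MNPs decompose into
per-base substitutions, and indels are reduced to minimal representation
before conversion. Heteroplasmy fractions are read from the first of the
per-genotype fields `AF`, `HF`, `VAF`; absent fields mean homoplasmic.
Calls below `het_threshold` (default 0.9) are excluded —
`"keep-above-threshold"` additionally records the fraction of retained
heteroplasmic calls. The conservative default reflects that sub-threshold
heteroplasmies are more often artefacts or somatic than phylogenetically
informative.

**FASTA** records are aligned with a pluggable aligner. The built-in one is
a global-local affine-gap alignment (gap opening 10, extension 1, match 2,
mismatch −3 on the IUPAC-aware matrix, so N aligns neutrally to any base
instead of forcing spurious gaps). Records under 70% identity are flagged
and excluded from classification rather than silently misclassified.
Dynamic-programming alignment is quadratic, so full rCRS-scale references
are slow with the built-in aligner; a seed-and-extend aligner can be plugged
in behind the same three-field interface. Alignments do not cross the
circular origin: a fragment spanning the origin aligns as its longer arm.

## VCF quality control

Before classification each VCF batch is profiled: sample and site counts;
overlap of sites with haplogroup-defining positions; monomorphic sites;
sites whose REF disagrees with the tree reference (fail); strand-flip
suspects among those (REF equal to the complement of the true base and ALT
equal to the complement of a tree-known alternate — the classical signature
of an array processed on the wrong strand); and per-sample/per-variant call
rates. Thresholds are configurable with defaults: call rate below 0.9
warns, below 0.5 fails; tree overlap below 0.5 warns (array data
legitimately sits low). QC annotates rather than drops samples;
`fail_on_qc` makes failures blocking.

## The synthetic-data generator

`simulation_spec()` fixes the study conditions: a random rooted tree
(default 40 haplogroups, depth ≤ 6, 1–3 variants per branch, 5% back
mutations, 10% indels), random weights (85% of variants weighted 1–15, the
rest exercising the default), three hotspot variants, two inert rewrite
rules, clusters = the depth-1 nodes, and a uniform-random reference genome.
Samples are planted at random nodes with Poisson(1) private extra
substitutions at tree-unused positions and emitted consistently as hsd,
VCF 4.2 and FASTA — the FASTA path actually mutates the reference sequence,
so alignment, variant calling and right-alignment are exercised end to end.
All randomness derives from the single seed; a spec reproduces a
byte-identical package.

The default reference is 2,000 bp rather than rCRS-scale: a desk-scale
choice that keeps the quadratic alignment step fast while preserving every
structural property under test (the format parsers are length-agnostic).
Problem sizes used by the tests and the acceptance script: exhaustive
planted recovery on a 100-node tree, 100 random trees for back-mutation
replay, 1,000 random weighted sets for metric algebra, 500 random indels,
50 samples for three-format consistency, 200 noisy planted samples.

What the simulation does *not* emulate — and what passing therefore does
not show — includes realistic mutation-rate heterogeneity, recurrent
mutation at hypervariable sites, NUMT contamination, sequencing error
profiles, and real aligner idiosyncrasies (the published nomenclature rule
sets exist precisely because of the latter). Results on real data depend on
the quality of the external tree package used.

## Known limitations

* Reference-identical samples are assigned the root haplogroup with a
  warning; distinguishing deeper placements for them requires information a
  variant profile does not carry.
* Nomenclature rules are context-free; haplogroup-conditional rewrites are
  not expressible.
* The built-in aligner is exact but quadratic; very long references call
  for a plugged-in heuristic aligner.
* Wrap-origin FASTA fragments are not aligned across the origin.
* Multi-base insertions shift as a unit during right-alignment only for
  insertion slot 1; stacked insertion slots are left where the caller put
  them.
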
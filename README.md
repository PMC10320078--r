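# haplocall

Haplogroup classification for human mitochondrial DNA (and any other
phylogeny expressed the same way). Medical, forensic and evolutionary
studies routinely need to place sequenced or genotyped mtDNA samples into
the named clades of a phylogenetic tree; `haplocall` does this for batches
of samples supplied as hsd variant profiles, multi-sample VCFs or (possibly
partial) FASTA sequences, with pre-classification quality control, ranked
candidate haplogroups, top-level cluster summaries and variant-level
annotation joins.

## The method

A phylogenetic tree assigns every haplogroup `h` an expected variant set
`E(h)`: the variants accumulated on the path from the root to `h`, with
back mutations (written `263G!`) removing the matching ancestral variant.
Given a sample's observed variant set `O`, restricted to the sample's
analysed range and stripped of hypervariable hotspot positions, every
haplogroup is scored with the weighted Kulczynski similarity

```
S(O, E) = 1/2 * ( W(O ∩ E) / W(E) + W(O ∩ E) / W(O) )
```

where `W(.)` sums per-variant phylogenetic weights (rare, clade-defining
variants weigh more than recurrent ones; an empty side contributes its term
as 1). Samples receive the `top_n` (default 20) highest-scoring haplogroups,
ranked; weighted Jaccard and Hamming qualities are available as alternative
metrics. A rule-based status flags hits with low quality, missing expected
variants on fully covered ranges, or many unexplained private variants.

Trees ship as decoupled *tree packages*: a directory with the tree XML (or
a flat TSV), per-variant weights, hotspot list, nomenclature rules,
reference FASTA, top-level cluster labels and metadata. FASTA input is
aligned to the tree reference; called indels are right-aligned (phylogenetic
nomenclature places them at the rightmost equivalent position, e.g. 315.1C)
and rewritten through the tree's rule table. VCF input gets a QC report
(site counts, tree overlap, monomorphic sites, reference concordance,
strand-flip suspects, call rates) before classification.

## Worked example

Everything below is synthetic and self-contained — the package bundles a
simulator that emits a complete tree package plus a matched sample batch in
all three formats:

```r
library(haplocall)

spec  <- simulation_spec(n_haplogroups = 40, n_samples = 5, seed = 1)
tree  <- load_tree_package(make_tree_package(spec))
batch <- make_samples(tree, spec)

results <- parse_hsd(batch$hsd) |> classify_profiles(tree)
results[, c("id", "haplogroup", "quality", "cluster", "status", "n_remaining")]
#> # A tibble: 5 × 6
#>   id    haplogroup quality cluster status  n_remaining
#>   <chr> <chr>        <dbl> <chr>   <chr>         <int>
#> 1 S001  C1a1a        0.876 C       warning           3
#> 2 S002  B1c1         1     B       ok                0
#> 3 S003  B1           0.643 B       warning           2
#> 4 S004  B1           0.722 B       warning           1
#> 5 S005  D1           0.865 D       warning           1
```

Each sample lands on its planting node; qualities below 1 reflect the
simulated private variants (`n_remaining`), which also trigger the
conservative warning status. `tidy(results)` unnests the full ranked hit
tables, `glance(results)` gives the batch summary, `autoplot(results)` and
`plot_cluster_summary(summarize_clusters(results))` plot them. The VCF path
adds QC:

```r
vcf <- parse_vcf(batch$vcf, tree)
qc  <- run_vcf_qc(vcf, tree)
qc
#> <haplo_qc> 5 sample(s), 30 site(s)
#>   tree overlap 0.73; monomorphic 0; ref mismatches 0; strand-flip suspects 0
#>   flags: pass=11
```

The same pipeline is scriptable: `inst/cli/haplocall classify --in
samples.vcf --tree treedir --out results` (also `distance`, `trees`,
`install-trees`, `simulate`, `server`).

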
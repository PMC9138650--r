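---
title: "CpG-based phylo-epigenetic inference: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CpG-based phylo-epigenetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

Vertebrate DNA methylation happens at CpG dinucleotides. Methylated CpGs
are hypermutable: spontaneous deamination of 5-methylcytosine converts a
CpG into TpG at a transition rate some 10–50 times higher than other
transitions, while CpGs inside unmethylated CpG islands — typically the
functionally important, promoter-associated ones — are exempt from this
erosion. Functionally relevant CpGs should therefore diverge more slowly
between closely related species than the genomic background, and the
*pattern of which CpGs are still intact in which species* carries
phylogenetic signal of its own.

`cpgphylo` turns that observation into a reproducible two-track analysis
of a multiple sequence alignment:

1. **SNP mode** — the conventional track: pairwise p-distances over all
   alignment columns, clustered by UPGMA into a rooted ultrametric tree.
2. **CpG mode** — the phylo-epigenetic track: every preserved CpG site is
   recoded, per taxon, into a binary character — `A` if that taxon's
   dinucleotide is exactly `CG`, `T` if it is mutated in at least one of
   the two positions — and the tree is built from p-distances over those
   characters alone.

Alongside the trees, the package reports dinucleotide divergence
statistics (how often preserved CpG sites are altered, compared with AG,
TG and GG control dinucleotides), and ships a sequence-evolution
simulator with explicit CpG hypermutability so that every claim can be
validated against known ground truth.

## Site classification

A *dinucleotide site* is a pair of adjacent alignment columns. For a
scan type such as `CG`, a site is reported when it "belongs to" the type
under a *reference rule*:

* `majority` (default): more than half of the taxa show the dinucleotide
  there. The notion of sites "largely preserved" across species has no
  single formal definition, so the rule is a parameter; majority is the
  default because it is symmetric in the taxa and robust to a single
  divergent lineage.
* `reference:<taxon>`: the named taxon shows it (use this to anchor the
  scan on, say, the human sequence).
* `any`: at least one taxon shows it.

Each reported site gets one of four classes, and the class is anchored
to majority semantics regardless of the reporting rule (so permissive
rules can report `not_preserved` sites rather than silently promoting
them): `gapped` (any taxon has `-` or `N` in either column; checked
first), `conserved_all` (every taxon intact), `preserved_variable` (a
majority intact, at least one taxon deviates in at least one position),
`not_preserved` (half or fewer intact). A `preserved_variable` site
counts **once**, no matter how many taxa or how many of its two
positions differ.

Two denominators matter and are easily conflated:

* the **alteration fraction** = variable sites / preserved sites
  (preserved = `conserved_all` + `preserved_variable`);
* the **genome fraction** = variable sites / total alignment columns.
  The numerator counts *sites* (column pairs) against a denominator of
  *columns* — the most conservative reading of "percent of the whole
  aligned sequence"; a per-column accounting would be up to twice as
  large.

Gapped sites are excluded from both numerators but the column
denominator always stays the full alignment length. Only the written
(plus) strand is scanned; CpG is strand-symmetric, but promoter
alignments are analysed as written.

## Recoding and trees

`recodeCpGMatrix()` applies the A/T rule per taxon per admitted site.
The per-taxon reading is essential: a per-site global assignment would
give all taxa identical strings and an uninformative star tree.
All-conserved (all-`A`) columns are kept by default
(`includeConstant = TRUE`); they dilute every pairwise distance by the
same factor and cannot change the UPGMA topology, only its depth — the
flag exists for users who prefer variable-only matrices. Because all
characters live in the shared alignment coordinate frame they are
already positionally homologous, and no realignment step is performed.

Distances are plain p-distances (proportion of mismatching positions);
no multiple-hit correction is applied, keeping the dissimilarity the
minimal one compatible with an agglomerative clustering. With
`ignoreGaps` (default) a position is dropped for a pair when either row
has `-` or `N`; a pair with zero comparable positions is an error, not a
silent zero.

`upgmaTree()` is classical UPGMA: merge the closest pair of clusters;
the new cluster's distance to the rest is the arithmetic mean over all
between-leaf distances, maintained by cluster-size weighting; merge
height is half the pair distance, giving a rooted ultrametric tree (the
molecular-clock assumption puts the root at the last merge). Ties in
the closest-pair search are broken by the smallest pair of cluster
indices in creation order — leaves first, in label order — so repeated
runs are identical; with an all-zero matrix the result is the
deterministic left-to-right pairing. Children of each merge are written
taller-subtree-first in the Newick output. Heights are in p-distance
units; no claim is made that they equal divergence times.

## The simulator

`evolveAlongTree()` exists to answer: *if CpG hypermutability works as
described, does the pipeline recover what we put in?* It evolves a root
sequence down a known rooted tree under a Kimura-style model
(transversions at a common rate, transitions at `tiTvRatio` times that
rate, total non-CpG leaving rate `baseRate` per unit branch length — 1
by default, so branch lengths are expected substitutions per site).
Wherever the *current* sequence has a CpG outside a protected island,
the C→T transition at its cytosine and, symmetrically, the G→A
transition at its guanine are multiplied by `cpgMultiplier`.

Because substitutions create and destroy CpGs, site rates depend on the
current sequence context. The process is therefore simulated by
Gillespie-style event sampling — draw an exponential waiting time from
the total rate, pick a site proportionally to its rate, pick a target
state, apply it, and re-evaluate the rates of the site and its two
neighbours — rather than by a site-independent matrix exponential,
which cannot express the context dependence. "Methylated" is
operationalized as "CpG outside a protected island"; per-site
methylation states are not modelled further. There are no indels, so
the leaves are born aligned — deliberately bypassing any external
alignment step, which is out of scope. All randomness flows from the
single config seed, and identical configs give byte-identical bundles.

`generateRootSequence()` plants CpGs explicitly at the target density
(odds `d/(1-d)` per emitted unit) and never draws a `G` directly after
a background `C`, so the planted count *is* the CpG count and its
expectation matches the target exactly; base composition is otherwise
uniform, which slightly under-represents G after C and is documented
rather than corrected.

### Default study conditions

The simulator defaults mirror the promoter-assembly setting the package
is aimed at, chosen once: five taxa (human, gorilla, chimp, bonobo,
orangutan) on the great-ape tree with chimp+bonobo joining at height
0.010, human+gorilla at 0.015, those two pairs at 0.022 and orangutan at
0.030 — few-percent promoter divergence, in p-distance units; a 1600-bp
sequence of five 320-bp blocks, each with one centred ~100-bp CpG island
(CpG density 0.10 inside, 0.01 outside); `cpgMultiplier = 25`, the
midpoint of the reported 10–50× range; `tiTvRatio = 2`; and half the
islands protected (the first `round(0.5 * n)` in order, deterministic).
The simulation emulates block-structured promoter homologs with island
protection; it does **not** emulate indels/alignment error, selection,
rate heterogeneity beyond the CpG effect, or recombination — so passing
tests demonstrate correctness of the method under its stated model, not
robustness to those real-data complications.

## Numerical and degenerate-input choices

* Coordinates are 1-based throughout (a site at column *i* occupies
  columns *i* and *i+1*), matching R and Bioconductor convention.
* Ambiguity codes other than `N` are rejected at read time, as is the
  `.` gap character; silent coercion would corrupt CpG calls.
* A CpG-mode request on an alignment with no usable CpG sites is an
  explicit error (exit code 1 from the command line), never an empty
  tree.
* Ultrametricity of UPGMA output is exact by construction up to
  floating-point accumulation; tests assert it to 1e-9.
* The UPGMA working matrix uses the size-weighted update; the test
  oracle recomputes cluster means from the original matrix by
  definition, so agreement checks both routes.

## Validation in the test suite

The suite validates, among others: scan/classify/recode against
brute-force enumeration on random alignments; UPGMA against a
definition-based agglomeration oracle on 200 random matrices and
against average-linkage `hclust`; exact reconstruction of ultrametric
inputs; leaf-by-leaf replay of the simulator's mutation log; Poisson
event counts when the multiplier is 1; a null check that CG divergence
is then statistically indistinguishable from AG/TG/GG; the
corresponding signal check at multiplier 25; and SNP-pipeline topology
recovery on 10-kb five-taxon simulations (problem sizes chosen as the
smallest at which the statistical checks are stable). The quantities in
`scripts/acceptance.R` are recomputed from scratch on each run from the
same study-scale configuration.

## Limitations

Site classes are a sequence-level proxy for epigenetic state: nothing
here measures methylation. The statistics condition on present-day
majority preservation, which is not an ancestral-state reconstruction.
UPGMA assumes a molecular clock; strongly rate-heterogeneous lineages
will distort both tracks. CpG-mode matrices from short alignments can
rest on few sites (the per-site counts are always reported alongside
the fractions for exactly this reason).
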
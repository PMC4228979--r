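---
title: "Annotating promoter families: cis-motif scanning, conserved modules and diversity statistics"
author: "promcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating promoter families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promcis)
```

## The problem

Seed-storage-protein (SSP) genes in cereals — prolamins, glutenins and
their relatives — are regulated by a small lexicon of short cis-elements
in their proximal promoters: the GCN4-like motif (GLM) bound by bZIP
factors, the prolamin box bound by DOF factors, AACA/GATA motifs bound by
MYB proteins, the RY repeat bound by B3 factors, and general elements such
as the TATA variant, CAAT and E boxes. Because individual elements are
short and degenerate, single-sequence annotation is noisy; the informative
signal is *positional conservation*: a motif that recurs at the same
ATG-relative coordinate across the alleles, homoeologs or orthologs of a
promoter family is far more likely to be functional, and clusters of such
motifs form conserved cis-regulatory modules (CCRMs).

`promcis` implements that comparative-annotation workflow end to end:

1. **motif scanning** of promoters against a catalog of IUPAC-degenerate
   motifs, with hits anchored at the translation start codon;
2. **nested-hit resolution** keeping only the longest motif where one
   motif's match lies inside another's;
3. **indel-aware consensus** across a promoter set, classifying motifs as
   conserved (all members) or majority (more than half), and grouping
   conserved motifs into CCRMs;
4. **diversity statistics** over an aligned allele panel — segregating
   sites, indel events, haplotypes, haplotype diversity `Hd`, nucleotide
   diversity `pi`, Watterson's `theta_W`, and Tajima's `D`;
5. a **synthetic family generator** that plants motif modules into
   ancestral promoters and derives allele panels with known truth, so the
   entire pipeline is testable without any sequence download.

## Coordinates

All positions are ATG-relative: position −1 is the base immediately 5' of
the A of the start codon and there is no position 0, matching the
convention of promoter maps such as "TATA box at −90". Input FASTA records
must therefore end at the base before the start codon. A minus-strand hit
is reported on plus-strand coordinates (leftmost base = start) with a
strand flag. GFF3 output uses 1-based positive within-record coordinates,
as the format requires, and carries the ATG-relative start in an
`atg_offset` attribute.

## Motif catalogs

Two built-in presets cover the SSP regulatory lexicon. `table2` is the
full 24-motif annotation catalog (22 PLACE-derived motifs plus the
non-PLACE GAMYB-binding `AACNNA` and the SSP TATA variant `TATAWA`);
`table6` is the 19-pattern counting preset used for per-gene tabulation.
The RY repeat appears as `CATGCAY` in `table2` but as `CATGCA` in
`table6`; the two forms are kept distinct per preset rather than silently
merged, so counts produced with either preset are reproducible as
printed. Custom catalogs load from 4/5-column TSV or JSON.

Matching semantics: each IUPAC code matches exactly its base set; a
subject `N` matches nothing (conservative rule — an ambiguous base never
creates a motif call). All windows are reported, including overlapping
self-matches of one motif; the catalog is scanned on both strands by
default.

## Nested resolution

Several catalog motifs are substrings or sub-patterns of others (the DOF
core `AAAG` inside the prolamin boxes, `GATA` inside `GGATA`, `ACGT`
inside the G boxes). Counting both the container and the contained hit
would double-count one binding site, so `resolve_nested()` removes every
hit strictly contained within a longer hit on the same strand of the same
promoter. The rule is purely positional — TF family is not consulted —
and chains of containment collapse onto the longest motif. Co-extensive
equal-length hits of different motifs are all kept (strict containment
requires a longer container, so ties cannot trigger removal). The
operation is idempotent.

## Indel-aware consensus and CCRMs

Indels shift every motif 5' of them along the allele's own coordinate
axis, so naive coordinate comparison across alleles breaks as soon as one
allele carries a deletion. `promcis` therefore projects each member's hit
coordinates into a common reference frame through an alignment
(`build_offset_maps()`): a member coordinate maps to the reference
coordinate of its alignment column, and where the reference itself is
gapped, to the nearest reference base 5' of the column. The projection is
applied *before* the coordinate tolerance: the tolerance absorbs residual
jitter, not indel shifts.

Per motif and strand, the projected starts are clustered by
single-linkage with link distance equal to the tolerance (default 5 bp,
i.e. "same coordinate ±5 bp"); a cluster whose total spread exceeds twice
the tolerance is split at its largest internal gap so no cluster ever
stretches beyond the ±tolerance reading. Support is the fraction of
distinct members contributing to a cluster. Two classes are kept
explicitly: **conserved** (support ≥ 1.0 by default — present in all
members) and **majority** (support > 0.5 but below conserved), the latter
used for distance reporting. The cluster representative is the median
start, rounded toward the start codon on ties (the paper-style annotation
plots anchor proximally; the choice is arbitrary but fixed).

CCRMs are detected by walking the conserved motifs from the start codon
outward and opening a new module whenever the start-to-start gap exceeds
`ccrm_max_gap` (default 100 bp — chosen so that modules of 2–5 elements
separated by >100 bp of unconserved background, the structure typical of
SSP promoters, are resolved as distinct); modules with fewer than
`ccrm_min_motifs` (default 2) motifs are discarded and survivors are
numbered CCRM1..k from the start codon outward.

Per-set consensuses can be merged into an overall consensus
(`merge_consensuses()`): each input's conserved motifs become pseudo-hits
of one pseudo-member and clustering is re-run at `merge_tolerance`
(default 10 bp, wider than the within-set 5 bp because between-set
coordinate drift includes unshared indel history). Motifs present in all
inputs form the merged conserved class. Merging one consensus is defined
as the identity: no re-clustering is applied, so a single set's motifs
pass through unchanged even when two of its motifs lie within the merge
tolerance of each other. When multiple sets are merged, same-motif
clusters closer than the merge tolerance do coalesce (their representative
moves to the cluster median) — the merged consensus trades coordinate
resolution for cross-set support, which is the point of the operation.

Strand handling: scanning covers both strands, but consensus and counting
default to plus-strand hits, the convention of published promoter
annotation tables; both are switchable.

## Diversity statistics

For an aligned allele panel (gap character `-`, anchored at the ATG):

* **Sites.** SNP sites are columns where all rows carry a base and at
  least two bases occur. Columns containing any gap are excluded from the
  per-site denominator `L_valid` (complete-deletion rule); maximal runs
  of gap columns sharing one presence/absence pattern are collapsed into
  a single indel event with its length recorded. Columns containing `N`
  are excluded from both. Indels are excluded from `pi`/`theta`/`S` but
  included in haplotype vectors and reported separately — diversity
  tables conventionally report "polymorphic sites / indels" as separate
  quantities, and haplotypes do distinguish indel carriers.
* **Haplotypes.** A haplotype is the allele vector over all polymorphic
  sites (SNP bases plus indel presence/absence); labels h1..hH are
  assigned by descending frequency, ties by first occurrence.
  `Hd = n/(n−1) (1 − Σ p_i²)`.
* **`pi`** is the mean pairwise difference count over complete columns,
  divided by `C(n,2) · L_valid`; **`theta_W = S/(a1 · L_valid)`** with
  `a1 = Σ 1/i`.
* **Tajima's `D`** uses the standard 1989 variance constants
  (a1, a2, b1, b2, c1, c2, e1, e2) on `S` and the mean pairwise
  difference count. Significance classes (`NS`, `P<0.05`, `P<0.01`) come
  from the beta-distribution approximation of the same paper: `D`
  rescaled onto its attainable range `[Dmin, Dmax]` follows an
  approximate beta law with mean 0 and variance 1, and the two-tailed
  beta probability is thresholded. This analytic classification is used
  rather than coalescent simulation; it is the textbook approximation
  and is deterministic. With `S = 0`, `D` is undefined (`NA`, class
  `"undefined"`), not an error.

Sequences are treated as haploid alleles; heterozygous lines are out of
scope.

## The synthetic family generator

`generate_family()` emulates the structure of a resequenced
promoter-allele panel: an ancestral promoter of configurable length
(default 1000 bp) with concrete motif instances planted at fixed
ATG-relative positions, and `n_alleles` (default 8) derived alleles with

* a per-site polymorphism probability `snp_rate` (default 0.01 — about
  one polymorphism per 100 bp, the density typical of wheat storage
  protein promoter panels);
* a singleton-rich haplotype structure: by default non-private sites
  split the panel into two major haplotype groups while a configurable
  fraction of sites is private to designated singleton alleles (each
  singleton line carries one or a few private SNPs), reproducing the
  "two major haplotypes plus singleton lines" pattern of real panels.
  A `"neutral"` mode draws derived-allele counts from the 1/i neutral
  frequency spectrum — under it the expected numerator of Tajima's D is
  exactly zero, which is what the neutrality calibration tests use — and
  a `"star"` mode makes every mutation private.
* deletions of configured lengths and carriers (e.g. a 54-bp deletion in
  two lines), never overlapping planted motifs when `protect_planted` is
  on.

The emitted alignment is exact by construction (gap columns at
deletions, ancestor frame), and the truth record (ancestor, mutation
lists, per-allele shifted placements, expected haplotype count) replays
to byte-identical alleles.

Backgrounds are uniform A/C/G/T (GC configurable). A random background
can itself contain catalog motifs — real promoters do too — so truth
comparisons on random backgrounds test *containment* of planted hits. For
exact-recovery tests the `motif_free` background removes every catalog
match outside the planted spans by iterative scrubbing: the ancestor is
scanned, and each offending hit has one of its background bases mutated
to a base outside that pattern position's IUPAC set (positions under `N`
slots are never chosen, since no base breaks a wildcard), iterating until
clean. Both the slot and the replacement base are drawn randomly, so the
search cannot lock into a cycle where two overlapping motifs keep
recreating each other; rejection sampling of whole backgrounds, the
obvious alternative, is only feasible for sequences of a few hundred
bases because expected catalog-hit counts per kilobase are far above
zero. Planted spans are never mutated, and a hit lying wholly inside one
planted placement is left alone (nested sub-motifs of a planted motif
are expected and are removed downstream by `resolve_nested()`).

The `plant_renan_like()` presets encode two module layouts used
throughout the tests: `ccrm5` plants five modules (2, 2, 2, 5 and 2
motifs; a proximal TATA-variant + CAAT pair, a G-box + E-box pair, a
GATA-box pair, a five-motif composite of two GATA+GLM units separated by
a third GGATA, and a distal prolamin-box + CAAT pair) with >100 bp
between modules, and `glm_gata_box` plants the composite box alone.

What passing synthetic tests do and do not show: the generator emulates
allele panels with simple two-group-plus-singletons or per-site-neutral
structure, unlinked sites, deletions only (no insertions relative to the
ancestor), and uniform base composition. Real promoter panels have
linkage, mutation-rate heterogeneity, shared indel history and biased
composition; recovery and calibration results transfer to real data only
insofar as the pipeline's operations (projection, clustering, counting)
are exercised identically — which they are — not because the generator is
a demographic model.

## Numerical and design choices

* Alignment is a convenience (`align_members()`: global affine-gap
  alignment of each member to a reference, match +1, mismatch −1, gap
  open −5, gap extend −0.5/base, stitched star-fashion); a user-supplied
  aligned FASTA always takes precedence, since real panels usually come
  with curated alignments or known indels. The reference defaults to the
  first record.
* Degenerate inputs: an empty hit set gives an empty consensus; CCRM
  detection of an empty consensus gives an empty module list; scanning a
  sequence shorter than the shortest pattern gives an empty annotation;
  `S = 0` gives `theta = 0`, `pi = 0` and an undefined Tajima class.
* Determinism: scanning, resolution, consensus and CCRM detection are
  fully deterministic; the generator is deterministic given its seed, and
  the seed is restored around generation so callers' RNG streams are
  untouched.
* Problem sizes in the test-suite calibrations — 100 random sequences up
  to 1 kb for the scanner/containment oracles, 200 replicates for the
  segregating-site and neutrality calibrations, 8–42 allele families —
  were chosen as the smallest sizes at which the binomial and
  3-standard-error bands are tight enough to be informative.

## Known limitations

* No position-weight-matrix scoring or de-novo motif discovery; the
  catalog defines the motif space.
* Module conservation carries no statistical significance measure; CCRMs
  are descriptive clusters.
* The consensus treats strands independently; palindromic motifs appear
  on both strands at the same interval and are counted per strand.
* Linkage disequilibrium, sliding-window diversity and haplotype networks
  are out of scope.
* The accession-based workflow (`fetch_genbank()`,
  `fetch_upstream_fasta()`) needs network access to NCBI; everything else,
  including the whole test suite, runs offline on synthetic data.
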
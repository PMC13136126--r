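---
title: "Mining bacterial genomes for AHL quorum-sensing genes with ahlqs"
author: "ahlqs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bacterial genomes for AHL quorum-sensing genes with ahlqs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahlqs)
```

## The problem

Many bacteria regulate group behaviours through *N*-acyl homoserine lactones
(AHLs): an AHL synthase of the LuxI family produces the signal, and a LuxR
family receptor — canonically an N-terminal autoinducer-binding domain (ABD)
fused to a C-terminal helix-turn-helix (HTH) DNA-binding domain — responds to
it. In well-studied Pseudomonadota the two genes usually sit next to each
other as a cognate *luxI/luxR* pair; in many other lineages one finds
"solos" (a synthase or a receptor with no partner nearby) and LuxR homologs
that retain the HTH but lack a recognizable ABD ("HTH-only").

`ahlqs` implements the computational side of an AHL-QS survey as a tested,
reusable pipeline:

1. **curation** — build LuxI/LuxR reference sets from a protein collection
   using declarative rules;
2. **profile calibration** — build position-specific scoring profiles and
   calibrate an e-value inclusion cutoff against a negative set;
3. **genome scan** — extract proteomes from annotated genomes and emit
   coordinate-anchored homolog hits;
4. **architecture** — classify LuxR hits as ABD+HTH (canonical), HTH-only,
   ABD-only or none;
5. **topology** — signed intergenic distances, orientations, cognate pairs
   versus solos, and flank inventories with functional category tags;
6. **phylo** — gap-threshold alignment trimming, distance trees and
   monophyly tests;
7. **mrm** — AHL mass arithmetic and matching of LC-MRM-MS transitions
   against a standards panel;
8. **synthetic data** — ground-truthed generators that make every stage
   testable offline.

## Curation rules

Reference sets are built mechanically from a protein FASTA plus metadata
(taxonomy lineage, description, domain annotations). The default rules
retain bacterial entries of 100–500 aa (inclusive bounds, mirroring an
inclusive range query) that carry the family's domain annotations
(LuxI: IPR001690; LuxR: IPR000792, IPR005143 or IPR036693), and drop LuxR
entries whose description contains "two-component" (case-insensitive
substring), since those can belong to non-AHL signalling systems. Manual
curation of borderline gene-product descriptions cannot be formalized; only
these mechanical rules are implemented, and every exclusion carries a
machine-readable reason code so a curator can audit the result. Duplicate
accessions and duplicate sequences are removed, first occurrence winning.

## The scoring engine and its calibration

The field-standard tool for family search is a profile HMM; `ahlqs` ships a
deliberately simpler, fully deterministic **position-specific scoring
engine** with the same contract (bit score + e-value per sequence), plus a
hook that delegates to HMMER (`engine = "external_hmm"`) when the binaries
are available. The built-in engine:

* takes match columns (< 50 % gaps) of the family alignment (inputs of equal
  length are taken as aligned; otherwise MAFFT is invoked through a
  pluggable aligner step);
* forms per-column log-odds scores in bits with add-0.5 pseudocounts against
  a uniform residue background;
* scores a query by its best *ungapped local segment* (the maximum-sum
  contiguous diagonal run of at least `minOverlap = 30` aligned positions),
  so a conserved domain scores the same whether it stands alone or is
  embedded in an unrelated protein — which is exactly what HTH-only LuxR
  detection requires;
* converts scores to e-values through an empirical null: the best-segment
  scores of 200 composition-preserving residue shuffles of the training
  sequences, to which a Gumbel distribution is fitted by maximum likelihood.
  (Shuffling preserves composition rather than higher-order structure;
  dinucleotide-style constraints have no analogue for amino-acid sequences.)
  E-values scale with the size of the searched set (`z`), following
  database-search convention; `scoreSequences()` defaults to a per-query
  e-value (`z = 1`).

This is *not* a Plan-7 forward/backward implementation and makes no claim
to HMMER's sensitivity on remote homologs; it is a calibrated stand-in that
keeps the pipeline self-contained and its statistics testable.

**Calibration.** `calibrate()` scans a negative set, counts false hits at a
reporting threshold (default e-value 10, the conventional reporting
threshold — the threshold at which a negative counts as a "false positive"
is a design choice, exposed as a parameter), and reports the false-positive
rate together with a suggested inclusion cutoff: the geometric mean of the
false-hit e-values (arithmetic mean of their log10 values), or the
configured default of 1e-10 when no false hits occur. The geometric-mean
reading of "average false-positive e-value" is deliberate: e-values span
orders of magnitude, and averaging them on the log scale is the only
average that lands on round log-scale cutoffs. The raw false-hit e-value
list is kept on the report so either reading can be audited.

```{r calibration, eval = FALSE}
fam <- generateFamily(30, length = 200, mutationRate = 0.1, seed = 1)
model <- buildProfile(fam, family = "LuxI")
decoys <- generateDecoys(1000, lengths = 200, seed = 2)
calibrate(model, decoys)
```

## Genome scanning and coordinates

Coordinates are 1-based inclusive throughout (the GFF3/GenBank convention),
and all distance arithmetic downstream assumes this. CDS features are
translated with the bacterial/archaeal code (table 11); minus-strand
features are reverse-complemented first. Codons are translated literally —
no initiation-codon forcing — so that generated genomes round-trip exactly;
when the annotation supplies a `translation` attribute it is trusted, with
a warning on mismatch. CDS whose length is not a multiple of 3 are excluded
as `partial`, CDS with internal stops as `pseudogene`; both are logged, not
silently dropped. Hits are flagged `typical`/`atypical` by family-specific
length ranges (LuxI 157–257 aa, canonical LuxR 210–272 aa, inclusive); the
flag never filters.

## Architecture classification

ABD evidence is any of IPR005143, IPR036693, PF03472 (or a built-in ABD
mini-profile hit); HTH evidence is IPR000792 (or the HTH mini-profile). The
class is read off the 2×2 presence table; domain "presence" requires
e-value ≤ 1e-5 (configurable — no canonical threshold exists for this).
Domain evidence can come from a consumed InterProScan-style TSV or from the
package's own mini-profiles, so no external annotation service is required;
the evidence source is recorded on the table. A hit whose ABD midpoint lies
C-terminal of its HTH midpoint violates the expected N-ABD/C-HTH layout and
raises an advisory anomaly flag, but the flag never changes the class —
classification is on presence/absence only.

## Topology

The signed intergenic distance is a single scalar: the bp gap between
disjoint features (0 = abutting), or minus the overlap length. This
reproduces both "77 bp intergenic region" and "overlap by 46 bp" in one
convention. Orientation follows the strands of the positionally ordered
pair: equal strands are co-directional, `+/-` convergent (3′ ends facing),
`-/+` divergent. Cognate pairs require |distance| ≤ 3000 bp (inclusive),
the conventional "local neighborhood" radius; among multiple candidates the
selection prefers canonical architecture, then smallest |distance|, then
smallest e-value. Every unpaired hit becomes a solo carrying the *exact*
distance to its nearest same-contig partner — even when that distance is
hundreds of kb — plus a `withinWindow` flag for the corner case of a
candidate that lost the pairing tie-break yet sits inside the window.
Cross-contig distances are undefined (`NA`), never large numbers.
Neighborhood inventories list every gene intersecting the ±3 kb (or
±10 kb) flank with signed offsets and deterministic first-match keyword
categories (redox/electron transfer, sulfur/tRNA modification, secondary
metabolism, stress/sensing, regulator, transport, hypothetical, other).

## Phylogenetics

`trimAlignment()` keeps a column iff its non-gap fraction is ≥ the gap
threshold (default 0.5, *inclusive*: a column with exactly half its rows
gapped is kept); the kept-column mask is returned so trimming is auditable
and idempotent. Distances ignore columns gapped or `X` in either member of
a pair (a pair with no comparable columns is an error naming the pair);
`p_distance` or Poisson-corrected `-log(1-p)` are available. Tree building
is neighbor-joining (via `ape::nj`) over those distances, with rows sorted
lexicographically first so ties break deterministically. Maximum-likelihood
inference, model selection and bootstrap support are deliberately out of
scope: they belong to an external engine that consumes the trimmed
alignment and returns Newick, and the built-in NJ path keeps the pipeline
self-contained. `checkMonophyly()` treats the tree as unrooted and tests
whether the leaf set forms an existing bipartition; singletons and the full
leaf set are monophyletic by convention.

## MRM screening

An unsubstituted Cn-HSL has formula C(n+4)H(2(n+4)-3)NO3; the 3-oxo variant
C(n+4)H(2(n+4)-5)NO4. Nominal (integer) masses mirror unit-resolution
triple-quadrupole practice; monoisotopic masses are reported to 4 decimals
alongside. All transitions share the diagnostic product ion of the
protonated homoserine-lactone ring, C4H7NO2 + H = m/z 102. A peak matches a
standard iff product ≈ 102 (± `mzTol`), precursor within `mzTol` of the
standard's [M+H]+, and retention time within `rtTol` when the standard has
one; defaults are ±0.5 Da and ±0.2 min, reflecting unit-resolution
quadrupole practice, and both are configurable and logged. A peak with the
102 fragment but no precursor match is a "putative unknown AHL", reported
with its retention time; other peaks are ignored; every peak receives
exactly one verdict. C7-HSL and 3-oxo-C6-HSL share nominal [M+H]+ 214 and
are separable only by retention time — when reference times are missing the
ambiguity is surfaced on the verdict, never silently resolved. Peak areas
support relative comparison only; no absolute quantification is attempted.

```{r mrm}
precursorMz(c(6, 12), is3oxo = c(FALSE, TRUE))
hslFragmentMz()
```

## What the synthetic data emulate — and what they do not

`generateFamily()` mutates a random ancestor i.i.d. per position, so family
members have a known expected pairwise identity; `generateDecoys()` draws
residues from the same uniform background the scoring null uses, making
decoys a proper sample from the null. `qsFamilySet()` assembles the
LuxI (200 aa), ABD (160 aa) and HTH (80 aa) families and composes canonical
LuxR members (ABD+HTH, 240 aa) and HTH-only members (random 120 aa region +
HTH); the defaults — 30 members per family, mutation rate 0.1 — were fixed
once as the benchmark's study conditions. `demoGenomePlan()` plants the
canonical neighborhood layouts: a convergent pair at +77 bp, co-directional
pairs with regulators 82 bp and 92 bp upstream of their synthases, a
solitary synthase in a redox/sulfur neighborhood with an
electron-transfer-flavoprotein gene 124 bp downstream whose partner subunit
overlaps it by 46 bp, the nearest receptor tens of kb away, and 18
scattered HTH-only receptors, all > 3 kb from any synthase. Back-translation
uses uniform synonymous codon choice (codon bias is irrelevant to every
downstream computation here), and intergenic space is uniform random DNA.

These fixtures do **not** emulate real genome composition, repeats,
assembly artifacts, annotation errors, or the sequence divergence structure
of real protein families (site-rate heterogeneity, indels, conserved
motifs). Passing the planted-truth tests therefore demonstrates that the
pipeline's logic — coordinates, strand handling, distances, pairing,
classification, calibration arithmetic — is correct, not that the built-in
engine matches profile-HMM sensitivity on remote real-world homologs.

## Numerical and design choices

* Gumbel null fitted by maximum likelihood to 200 shuffle scores; e-values
  are computed on the log10 scale throughout and floored at 1e-320 to avoid
  underflow, with `log10Evalue` reported unfloored.
* Minimum scored segment length 30 columns: short spurious diagonal runs
  otherwise dominate the null's upper tail.
* Inclusive boundaries everywhere a range is quoted inclusively: curation
  lengths, typical-length flags, the 3 kb pairing window, the 0.5 gap
  threshold.
* Pair selection prefers architecture before distance because a canonical
  receptor is the biologically expected cognate partner even when an
  HTH-only gene sits closer.
* NJ tie-breaking via lexicographic label order; negative NJ branch lengths
  are clamped to 0.
* Problem sizes in the test suite (30-member families, 1000 decoys, two
  contigs of ~100 kb and ~40 kb, 4–8-leaf tree oracles) were chosen as the
  smallest instances that still exercise every code path meaningfully.

## Known limitations

* The built-in engine scores ungapped local segments; families whose
  conservation is spread across many short motifs separated by indels will
  score worse than under a true profile HMM. The `external_hmm` engine
  exists for exactly that case.
* Curation reproduces only the mechanical filtering rules; any
  judgement-based curation of product descriptions must happen upstream.
* GenBank flat files are not parsed; annotations enter as GFF3 + FASTA.
* No operon prediction, promoter/lux-box motif search, ab initio gene
  calling, or absolute MRM quantification.
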
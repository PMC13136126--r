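# ahlqs — discovery and characterization of AHL quorum-sensing genes

Many bacteria coordinate group behaviour through *N*-acyl homoserine
lactone (AHL) signalling: a LuxI-family synthase produces the signal and a
LuxR-family regulator — canonically an N-terminal autoinducer-binding
domain (ABD) plus a C-terminal helix-turn-helix (HTH) domain — responds to
it. `ahlqs` is an R package for microbial genomicists who want to mine
annotated genomes for these systems and characterize what they find:

* **Curation** of LuxI/LuxR reference sets from protein collections
  (taxonomy, inclusive 100–500 aa length window, required domain
  annotations such as IPR001690 for LuxI, exclusion of "two-component"
  LuxR entries, deduplication with reason-coded exclusion reports).
* **Profile search with empirical calibration**: a deterministic
  position-specific scoring engine (per-column log-odds with add-0.5
  pseudocounts; best ungapped local segment scoring; Gumbel e-values from
  a 200-shuffle null) with an e-value inclusion cutoff calibrated against
  a negative set, `E* = 10^mean(log10 E_false)`, defaulting to 1e-10 when
  no false hits occur. HMMER can be swapped in (`engine = "external_hmm"`)
  with an identical report schema.
* **Genome scanning**: proteome extraction from FASTA + GFF3 (translation
  table 11, 1-based inclusive coordinates, strand-aware), hit tables
  anchored to coordinates, typical/atypical length flags (LuxI 157–257 aa,
  LuxR 210–272 aa).
* **Domain architecture**: CANONICAL (ABD+HTH) vs HTH_ONLY vs ABD_ONLY vs
  NONE, from InterProScan-style TSVs or built-in ABD/HTH mini-profiles.
* **Neighborhood topology**: signed intergenic distances (negative =
  overlap, 0 = abutting), convergent/divergent/co-directional orientation,
  cognate *luxI/R* pairs within an inclusive 3 kb window vs solos with
  exact nearest-partner distances, and ±3/±10 kb flank inventories with
  functional category tags.
* **Phylogenetics**: gap-threshold alignment trimming (keep a column iff
  non-gap fraction ≥ 0.5, inclusive), p/Poisson distances, neighbor-joining
  trees, unrooted monophyly testing, annotated Newick export.
* **MRM screening**: AHL formulas C(n+4)H(2(n+4)−3)NO3 (3-oxo:
  C(n+4)H(2(n+4)−5)NO4), nominal [M+H]+ values, the diagnostic
  homoserine-lactone fragment at m/z 102, transition matching against a
  ten-standard panel, putative-unknown-AHL flagging, presence matrices.
* **Synthetic data**: seed-reproducible generators for protein families,
  decoys, planted-locus genomes (FASTA+GFF3+truth tables) and MRM peak
  lists, so the entire pipeline is testable without downloads.

## Worked example

Calibrate a LuxI profile on synthetic ground truth:

```r
library(ahlqs)
fam    <- generateFamily(30, length = 200, mutationRate = 0.1, seed = 1)
model  <- buildProfile(fam, family = "LuxI")
decoys <- generateDecoys(1000, lengths = 200, seed = 2)
calibrate(model, decoys)
#> CalibrationReport: 1000 negatives, 3 false hits at E <= 10 (FPR 0.3%)
#>   mean log10(e-value) of false hits: 0.4598
#>   suggested inclusion cutoff: 2.88301
```

Three of 1000 unrelated decoys score below the conventional reporting
threshold (E ≤ 10), an empirical false-positive rate of 0.3 %; the
suggested inclusion cutoff is the geometric mean of those false-hit
e-values. At that cutoff every family member is recovered (sensitivity
1.0) and the decoy hit rate is ≤ 0.5 %.

Mass arithmetic for the MRM panel:

```r
precursorMz(c(6, 12), is3oxo = c(FALSE, TRUE))
#> [1] 200 298
hslFragmentMz()
#> [1] 102
```

C6-HSL ionizes at nominal [M+H]+ 200 and 3-oxo-C12-HSL at 298; every
transition monitors the protonated homoserine-lactone ring at m/z 102.

A full planted-genome run (simulate → scan → topology) is available from
the shell via the thin wrapper in `inst/scripts/ahlqs`:

```sh
ahlqs simulate --out sim --seed 3
ahlqs scan --genome sim/genome.fna --gff sim/genome.gff3 \
      --profile sim/profile_luxI.json --out sim/scanI
ahlqs topology --hits sim/scanI/hits_LuxI.tsv,sim/scanR/hits_LuxR.tsv --out sim/topo
```

which recovers the planted cognate pairs (intergenic distances 77, 82 and
92 bp with their orientations) and the solitary synthase with its exact
nearest-partner distance.

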
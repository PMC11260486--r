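---
title: "Methods: architecture of linear actinomycete chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: architecture of linear actinomycete chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linchrom)
```

## Scope and model

Most *Streptomyces* chromosomes are linear, end-capped by terminal
inverted repeats (TIRs), and organised around the replication
initiation gene *dnaA*: near-universal core genes concentrate in a
central compartment, while biosynthetic gene cluster (BGC)
protoclusters and duplicate gene copies accumulate on the distal arms.
linchrom quantifies this architecture on chromosome-level assemblies
through five connected analyses — TIR detection, dnaA-based
orientation, centre-relative placement densities, MinHash/Mash species
delineation, and marker-domain plasmid classification — plus a
synthetic-genome generator that provides planted ground truth for all
of them.

Conventions used throughout: coordinates are 0-based half-open
internally and converted exactly once at the GFF3/GenBank parsing and
writing boundary (1-based inclusive outside), so write∘parse is the
identity on well-formed input. A feature is always reduced to its
real-valued midpoint `(start + end) / 2` — no rounding, so long and
short features carry equal weight in positional analyses and no
half-base bias enters the densities. The chromosome centre is the
mathematical midpoint `L/2`; the signed offset of a feature is
`midpoint − L/2` (negative upstream of the centre in the dnaA-forward
frame) and the arm-normalised position is `arm_pos = offset / (L/2)`.

## TIR detection

A TIR appears as a local alignment between the chromosome `S` and
`revcomp(S)` whose query start lies within the first `W` bp and whose
subject end lies within the last `W` bp of `S`. `W = 99` bp by default,
allowing for polishing artifacts at assembly ends. Because
`revcomp(S)`'s prefix is the reverse complement of `S`'s suffix, the
search reduces to aligning the two prefixes with both starts anchored
in a `W × W` corner.

The detector is seed-and-extend. A shared exact `seed_k`-mer
(default 15) near both starts gates the alignment; chromosomes without
one are reported TIR-free without running the dynamic program, which
makes scanning TIR-free genomes cheap. The extension is a banded
affine-gap dynamic program (band half-width 200 bp) over the first
`⌊L/2⌋` bases of each side. Restricting to the half chromosome caps the
reported length at `L/2`, so a perfectly palindromic chromosome yields
a TIR fraction of exactly 1; the reported fraction `2·tir_len/L`
counts both repeat copies. Full quadratic alignment is deliberately
avoided: real TIRs reach megabase scale, and near-identical repeats
stay within a narrow diagonal band.

Scoring is match +1, mismatch −2, gap open −2, gap extend −1 (a gap of
length *g* costs `2 + g`), the conventional blastn-compatible pairing
for those gap costs; all scores are configurable through
`tir_params()`. The reported alignment ends at the maximum-score cell;
ties go to the alignment with fewer columns, then the smaller left
start. The compact tie-break matters: score-neutral gapped extensions
past a repeat boundary (a mismatch paid back by chance matches) would
otherwise inflate the reported length, and preferring the most compact
optimum keeps recovered lengths exact on planted repeats. The
`min_report` floor is 20 bp — well below the ~100 bp smallest repeats
worth reporting — and X-drop termination (default 500) stops the
extension once the score falls that far below the running optimum.

No identity threshold is applied beyond the scoring itself, and a
chromosome reported TIR-free may simply have ends truncated by
assembly or polishing; the detector cannot distinguish absent repeats
from damaged ends.

## Orientation and placement

Deposited assemblies arrive in arbitrary orientation, so all genomes
are put into a canonical frame with *dnaA* on the forward strand
before placement analysis. Flipping maps every feature by
`(start', end') = (L − end, L − start)` with strand inversion and
reverse-complements the sequence; the transform is an involution and
preserves `|offset|` for every feature. Multiple *dnaA* copies are
tolerated when they agree in strand; the copy nearest the centre is
used for the dnaA-to-centre statistic, consistent with the
primary-copy rule below. Opposite-strand copies raise an error — there
is no defensible orientation rule for that case.

For duplicated gene models the copy with minimal `|offset|` is ranked
*primary* and the rest *secondary*; exact ties go to the smaller start
coordinate so the ranking is deterministic. A consequence worth
keeping in mind when reading duplicate-copy densities: the convention
itself forces secondary copies to be at least as distal as their
primaries.

Positional densities are exact (non-binned) Gaussian kernel density
estimates evaluated on a 512-point grid spanning
`[min − 3h, max + 3h]`, with bandwidth `h = 0.5 · n^(−1/5) · σ` —
Scott's rule, the base bandwidth that the 0.5 smoothing factor
adjusts. Exact evaluation (chunked sums of Gaussians rather than FFT
binning) costs a little speed and buys testability: the estimator can
be checked against a direct sum-of-Gaussians oracle to 1e-9. Curves
are computed on `arm_pos` so chromosomes of different lengths pool on
a common axis; the alternative (raw bp offsets) is supported by
passing offsets directly. Each curve integrates to one over its own
observations, so heights are not comparable between categories — only
x-positions are. Two boundary caveats are documented rather than
corrected: kernel mass within ~3h of a chromosome end smears past it
(densities tend toward zero at the ends even where the data do not),
and with very few observations the 3h grid margin clips ~0.1% of the
total mass per extreme point. Categories need at least two distinct
observations for a curve; smaller ones are counted but not drawn.

Arm asymmetry is summarised as the fraction of features with positive
offset (downstream of the centre in the dnaA frame), with exact-zero
offsets counted separately rather than assigned a side. BGC abundance
versus genome size is an ordinary least-squares fit of protocluster or
region count on genome length per group, with the Pearson correlation;
groups with fewer than two genomes or no length variance are skipped
with a warning rather than fitted degenerately.

## Species delineation

Genomes are sketched as the `s = 1000` smallest 53-bit hashes of their
canonical 21-mers (the lexicographic minimum of each k-mer and its
reverse complement, so a genome and its reverse complement sketch
identically; k-mers containing `N` are skipped). The cited method's
defaults k = 21, s = 1000 are adopted and configurable; 53-bit hashes
(a splitmix64 mix masked to the double-precision integer range) keep
hash values exactly representable as R numerics, and at sketch sizes
of a few thousand the additional collision probability (~1e-10) is
immaterial to the estimator. The Jaccard index is estimated from the
bottom-`s` of the merged hash sets — not the plain
intersection-over-union of the two sketches — and converted to
`D = −(1/k)·ln(2j/(1+j))`, capped at 1, with `D = 0` at `j = 1`.

The similarity network joins genomes at `D ≤ 0.05`, the 95%
whole-genome-similarity convention for species boundaries; edges are
unweighted because the delineation is a cutoff rule, not a weighted
flow. Louvain community detection (via igraph) assigns species; the
node-visit order is randomised, so the seed is recorded with the
result, and isolated genomes become singleton species. `modularity_direct()`
recomputes Q from the adjacency formula independently of the community
algorithm for verification. Community counts can differ between seeds
on ambiguous networks — one reason exact replication of any published
community count is not guaranteed, along with unpinned sketching
implementations upstream.

## Plasmid classification and assembly classes

An extrachromosomal replicon is classified as a plasmid iff it carries
at least one hit against a curated list of plasmid-specific protein
domains; no e-value threshold is applied (the rule is presence). The
rule, not any particular list, is the method: the package ships only a
small synthetic placeholder list for examples and accepts any list
file at runtime. Whether a replicon is the chromosome is the caller's
call (a flag), not inferred. Assembly quality classes follow the
completeness rule: complete/chromosome level → HQ; ≤ 100 contigs → MQ;
otherwise LQ.

## The synthetic generator

The generator emulates exactly the structure the analyses assume, and
nothing more. Sequences are i.i.d. draws at a target GC (default 0.72,
the upper-60s-to-mid-70s range typical of these taxa); there are no
repeats beyond the planted TIR, no genes in the sequence itself, no
indel divergence. Features are planted in the dnaA-forward frame and
the genome is then stored reverse-complemented with probability 1/2,
emulating arbitrary deposition orientation (empirically about half of
deposited genomes are reversed).

Positional models are Gaussian mixtures on the `arm_pos` scale:

* *dnaA*: mean −0.005, sd 0.05 — essentially central, slightly
  upstream, a few percent of an arm length of jitter.
* core genes: components at ±0.185 (sd 0.10) with weights 0.45/0.55 —
  the focal point at 12–25% of the arm length from the centre observed
  for ribosomal operons, with the mild downstream excess seen in real
  genomes.
* protoclusters of categories NRPS/PKS/terpene/RiPP/oligosaccharide:
  components at ±0.85 (sd 0.08) — distal arms; category `other`:
  centred (sd 0.25), since that heterogeneous category shows no distal
  preference.
* duplicate core-gene copies: the distal model, matching their
  observed arm placement.

Planted genes are 1–3 kb and protoclusters 20–100 kb (uniform;
configurable ranges for small test genomes), placed without overlap by
rejection sampling with a bounded retry budget — an error, not an
infinite loop, when a configuration cannot fit. Default cohort
conditions are a 9 Mb chromosome with 124 core-gene models, 3
duplicated models and 12 protoclusters per genome, mirroring a
complete *Streptomyces* chromosome at a protocluster count kept low
enough for non-overlapping placement (real hybrid protoclusters
overlap, which the truth-table design deliberately avoids).

A planted TIR overwrites the last `tir_len` bases with the reverse
complement of the first `tir_len`. For the planted length to *be* the
true maximal end-anchored repeat length — the quantity the detector is
tested against — the inner boundary must not extend by chance
complementarity of the random flanks, including gapped realignments
onto nearby diagonals. The generator therefore plants purine-only
spacers (12 bp after the left copy, 212 bp before the right copy):
purines never pair with purines, so no alignment diagonal within the
200 bp band crosses the boundary. The spacers are skipped for
near-palindromic configurations where they would overlap the copies.

Species sets use substitution-only divergence (per-site, uniform over
the three alternative bases): with no indels the Mash-distance/rate
relationship stays monotone and cleanly testable. Cluster bases are
independent random sequences by default (maximally separated) or
derived from a common ancestor at a higher rate; configurations where
within-cluster divergence would reach the between-cluster level are
rejected as inseparable by construction. Replicon panels plant ≥ 1
marker-domain hit on each designated plasmid and only decoy domains
elsewhere.

What passing tests on this generator does **not** show: robustness to
repeat-rich sequence, to fragmented assemblies, to annotation errors,
to indel divergence, or to the overlapping hybrid protoclusters of
real antiSMASH output. The generator validates the coordinate and
k-mer machinery, not the upstream annotation tools.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale problems
chosen as the package's own validation conditions: a TIR sweep of
100 bp–50 kb planted on 200 kb chromosomes, 50 small genomes for the
orientation involution, a 100-genome cohort at the default 9 Mb study
conditions for the placement pattern (coordinates only — sequence
generation is skipped where only geometry is analysed), 50 kb genome
pairs against the exact-Jaccard oracle, and 3 × 4 planted species at
0.5% divergence. Quartiles are linearly interpolated (R type 7) and
standard deviations use denominator n − 1, with the SD reported
missing for a single observation. Distance-matrix symmetry is enforced
to 1e-12; density normalisation is validated to 1e-3 (trapezoidal
integration on the 512-point grid); the KDE implementation is checked
against its oracle at 1e-9.

## Known limitations

* TIR detection reports the single best end-anchored alignment; it
  does not enumerate secondary repeat structures, telomere motifs or
  terminal proteins, and cannot correct assemblies whose TIRs were
  collapsed or truncated upstream.
* The placement analyses assume one linear replicon per genome;
  circular genomes are out of scope by design.
* No significance test for compartmentalisation is provided — the
  densities are descriptive.
* Louvain results are seed-dependent on ambiguous networks; the seed
  is part of the reported result.
* GenBank parsing targets the antiSMASH dialect (protocluster/region
  features with product/category qualifiers), not arbitrary GenBank.
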
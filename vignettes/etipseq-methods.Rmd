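---
title: "etipseq: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{etipseq: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what is modelled, which knobs matter, what the synthetic data generator
does and does not emulate, and where genuinely open design choices were
settled.

## The measurement being modelled

Topoisomerase IIβ passes a T-segment duplex through a transient
double-strand break in a G-segment. Etoposide freezes the covalent
enzyme–G-segment intermediate, so immunoprecipitating the enzyme recovers
its genomic action sites. Two readouts are analysed here:

* **Two-fraction site mapping (eTIPa).** DNA on the beads is split into a
  bead-bound fraction (P1, covalent complexes) and a 0.5 M NaCl eluate
  (P2; resealed complexes stay enzyme-bound non-covalently and elute).
  Peaks called separately per fraction are intersected into three site
  classes.
* **Proximity ligation of G- and T-segments (eTIPb).** Fragments bound to
  one enzyme molecule are adaptor-ligated and paired-end sequenced. The
  mapped distance between the two reads ("chimera length") separates
  proximal strand passage (< 3 kb), distal strand passage (3 kb–2 Mb) and
  inter-complex ligation noise (> 2 Mb). Read orientations, written
  upstream→downstream with F = `+` and R = `-`, encode the local DNA
  topology: an intact proximal loop yields RF; pairing of distal
  homologous segments yields RF/FR when the repeats are direct (same
  strand) and FF/RR when inverted.

## Toposite calling

Read pairs are kept when both mates map uniquely, the pair is convergent
and the insert is below 500 bp. Each mate is extended to 200 bp in its
strand direction and per-base pileup accumulated, so track mass equals
200 × reads minus edge clipping — an identity the tests assert exactly.

Windows of 200 bp at 50 bp steps are scored in one of two modes:

* **local-poisson** (default): the window count is tested against a
  Poisson null whose rate is the maximum of the genome-wide rate and 5 kb
  / 10 kb local rates (the classic local-lambda guard against broad
  enrichment); p-values are Benjamini–Hochberg corrected across all
  windows and windows with q < 0.01 are merged into maximal peaks.
* **zinb**: a zero-inflated two-component negative-binomial mixture is
  fitted to window counts by EM; a window is enriched when the posterior
  probability of the enriched component reaches 0.5. This mirrors the
  0.5 "threshold" semantics of the original (now unmaintained)
  zero-inflated NB peak caller the field used; the window/step, local
  scales and q-cutoff in the default mode are package choices, not
  published values.

Peak summits are the maximal-pileup base. Both modes agree on strong
enrichments (tested at Jaccard ≥ 0.8); the local-Poisson mode is the
default because it is robust on small toy genomes where a mixture fit can
be under-determined.

**Evidence map.** The exact published decision rule mapping P1/P2 evidence
onto Ts1/Ts2/Ts3 lives in supplementary material that is not part of the
main text, so the map is a configurable bijection. The default —
P2-only → Ts1, P1-only → Ts2, both → Ts3 — follows the biochemistry:
resealed (relaxation-type) complexes elute at high salt and the abundant
TSS-associated class should therefore be P2-only, while the stable class
coincident with partner-protein binding carries both kinds of evidence.
Overlap between fractions is ≥ 1 bp; whether a reciprocal-overlap fraction
should be required is unstated in the source material, and 1 bp was chosen
as the weakest (most inclusive) reading.

**Region annotation.** The TSS zone is TSS ± 2 kb (strand-aware 5' end);
gene bodies minus TSS zones form the genic region; the remainder is
intergenic. Labels partition the sites with TSS taking precedence, and the
three region lengths partition the genome exactly. Densities are sites per
100 kb of region length.

## Chimera analysis

Chimera pairs are dropped when a mate carries the ligation adaptor at its
5' end or maps non-uniquely; inter-chromosomal pairs are counted but not
analysed. Ends are sorted by coordinate; the span is the distance between
read midpoints (the published definition names no anchor, and midpoints
make the span symmetric in the two reads). Boundary conventions: 3 kb
belongs to DSP, 2 Mb belongs to DSP, strictly greater is noise.

Each end is matched to toposites through its 2 kb read-centred window —
the same window used for homology extraction, which keeps the two analyses
consistent; ties go to the nearest summit, then largest overlap, then
lowest q. Chimeras with an unassigned end are excluded from combination
statistics. Combination labels are unordered (six combinations).

With `f_i` the fraction of class-i ends among all `2N` assigned ends, the
expected combination counts under random end pairing are `N f_i^2`
(homologous) and `2 N f_i f_j` (heterologous); these sum to `N`
identically. Each combination is tested by a 1-df χ² of
(observed, N−observed) against (expected, N−expected) and corrected by
Benjamini–Hochberg across the six combinations; depleted combinations
(observed < expected) are flagged. Whether the published expected-count
model treats ends or chimeras as the sampling unit is not printed; the
ends-based model above matches the stated "frequencies of toposites
detected at the end of chimeras". Note one statistical property the test
suite documents deliberately: because the expectations are fitted from the
same end pool, the per-combination test is conservative under the random
re-pairing null (its realized false-positive rate is well below the
nominal level). Homologous Ts1 chimeras in the DSP range carry no
orientation preference and are flagged noise-equivalent in orientation
tables.

## Terminal homology of DSP ends

From each chimera end a 2 kb genomic window centred on the read is cut out
on the plus strand (clipped and flagged at chromosome edges). Two local
alignments are computed: upstream-plus vs downstream-plus (`score_pp`) and
upstream-plus vs reverse-complemented downstream (`score_pm`). Scoring
follows the classic EMBOSS Water defaults — match +5, mismatch −4, gap
open 10, gap extension 0.5, with a gap of length L costing
`open + 0.5 L` — because the cited program is named in the source but its
parameters are not; `N` scores as a mismatch against everything including
itself. The verdict is **direct** when `score_pp` exceeds `score_pm` by
more than one match unit (margin 5), **inverted** in the opposite case,
**ambiguous** within the margin, and withheld when both windows were
clipped below 200 bp. Raw scores are reported against the distribution of
matched random control pairs (same chromosome, separation ≤ 2 Mb, N
coverage < 20 % per window, rejection-sampled under a fixed seed) rather
than against a hard score threshold, since no such threshold is published.

Repeat annotation of ends requires both windows to overlap same-named
intervals of a user-supplied BED; single-end hits are reported separately.

## Cluster and hotspot detection

Density tracks count item midpoints in 100 kb windows at 10 kb steps;
midpoint counting (half-open on window bounds) makes stride-aligned window
subsets conserve the item count exactly. Clusters are maximal merges of
windows with count ≥ threshold — 15 for Ts2 and 5 for Ts3 toposites as
published; the chimera (DSP) cluster threshold defaults to 5 ends per
window and is configurable because the published criterion is confined to
supplementary material. Hotspots are transitive unions of same-class
toposite clusters and DSP clusters sharing ≥ 1 bp, kept only when both
kinds contribute. Calling is monotone in the threshold and order-invariant
(both proven in tests).

## Chromatin condensation imaging

Each nucleus stack is linearly stretched to the full 256 gray levels,
smoothed in-plane by a 3×3 mean filter (the axial step, 0.275 µm, is much
coarser than the lateral sampling, so the z-axis is left unfiltered; the
published processing names no kernel radius), and segmented by a single
global Otsu threshold followed by largest 26-connected component selection
and 3D hole filling — a deliberate substitution of a simple, dependency-free
segmenter for the interactive plugin used originally; everything
downstream (histograms, isosbestic point, condensed fraction) follows the
published arithmetic. Histograms are built over mask voxels of the
*unfiltered* normalized stack and scaled by per-nucleus total intensity;
per-level medians across nuclei give each condition's curve.

The isosbestic point — the level where the condition curves intersect,
separating dispersed (dark) from condensed (bright) chromatin — is found
by smoothing the curves (running mean over 11 levels; per-level median
curves are jagged because every nucleus is stretched individually),
requiring a structural sign change of a pairwise curve difference (mean
difference beyond 2 % of its maximum on a 20-level flank on each side),
and taking the qualifying level with minimal cross-condition spread within
a 30–220 search band. The band excludes the trivial crossings of the empty
tails; the spread-minimization criterion is this package's formalization,
as no explicit multi-curve criterion is published. For two conditions
whose voxel intensities are mixtures of the same two class distributions,
this crossing sits at the equal-density point of the two classes — exactly
the threshold at which misclassification on both sides is balanced, which
is why the condensed fraction (mask voxels above the level, divided by
mask voxels) recovers the planted mixture weight. Volumes are mask voxel
counts times the voxel volume (defaults 0.1 µm lateral, 0.275 µm axial).
Groups are compared by two-sided Mann–Whitney tests (normal approximation;
exact ties are common in voxel-count-derived quantities).

## The synthetic data generator

`sim_spec()` fixes the study conditions; every artifact derives its RNG
stream from the master seed plus a per-artifact salt, so each module is
individually reproducible and a fixed seed reproduces every file byte for
byte.

* **Genome.** I.i.d. background at 42 % GC over chr1 (3 Mb) and chr2
  (1 Mb) by default. Repeat families (defaults: two direct families and
  one inverted family, 1 kb units, 4–6 copies, 85–90 % identity) are
  planted inside class-specific territories of chr1 sized so that any
  within-family pair lies in the distal (< 2 Mb) regime; divergence is
  i.i.d. substitution only, which keeps pairwise identity analytically
  controlled (±2 points, asserted by alignment in tests). Inverted-family
  copies alternate strand, so such families also contain same-strand
  (direct) pairs — as real inverted repeat families do.
* **Toposites and genes.** 200 sites per class by default, 400 bp wide;
  Ts1 sites around the TSS of randomly chosen genes, Ts2/Ts3 sites drawn
  around a few cluster centres in mutually exclusive territories (the
  published large-scale picture), with every repeat copy hosting a site of
  its family's class. Gene bodies cover about a third of the genome and
  are placed by stick-breaking so any realistic occupancy always fits.
* **Fraction reads.** Uniform background at 30× raw coverage per fraction
  plus site-centred fragments (centres Normal(summit, width/4)) bringing
  local density to 10× background, scaled by the class × fraction weight
  matrix (Ts1: P2 only; Ts2: P1 only; Ts3: both) — the generative mirror
  of the default evidence map. All pairs are 100 bp mates, convergent,
  insert < 500 bp; 5 % are corrupted (wrong orientation, long insert, or
  multi-mapping flag) to exercise the filter.
* **Chimeras.** PSP events straddle a Ts1 summit with log-uniform span on
  [200, 3000) and orientation RF; DSP events pick a planted repeat pair of
  the required relative orientation and emit RF/FR (direct) or FF/RR
  (inverted) with equal odds, reads uniform within the copies;
  inter-complex noise draws uniform positions and uniform orientation,
  span unconstrained. Mate order is randomized so loaders must
  canonicalize. Every chimera carries an id tracing to exactly one truth
  record.
* **Nuclei.** Ellipsoidal masks (~10–12 % of a 48×48×25 stack); bright
  foci are grown as spheres until exactly the planted fraction of nuclear
  voxels is condensed, then intensities are drawn from broad overlapping
  distributions (euchromatin N(95, 15), heterochromatin N(185, 20),
  background N(20, 5)). The overlap is deliberate: stained chromatin is a
  continuum, and with disjoint narrow spikes the isosbestic crossing
  degenerates into an empty valley where every level qualifies.

What the generator does **not** emulate: sequencing errors and quality
scores, PCR duplicates, mappability structure (uniqueness is a per-mate
flag), indel divergence of repeats (optional substitutions only),
inter-chromosomal chimeras, chromatic aberration or anisotropic PSF blur
in imaging. Passing tests therefore demonstrate correctness of the
algorithms under clean generative assumptions, not robustness to every
artifact of real libraries.

## Problem sizes and reproducibility

The default simulated conditions (4 Mb genome at 30× per fraction; 2,500
chimeras; 60 nuclei of 48×48×25 voxels) keep any single stage under about
two minutes on one CPU while leaving all statistical contrasts far from
marginal; the bundled `demo_config()` scales these down further for
smoke-testing. The pipeline writes its resolved configuration next to its
outputs, and reruns with the same configuration are byte-identical —
asserted in the test suite by comparing summary files.

## Known limitations

* The evidence→class map is a documented default, not a published rule;
  analyses that depend on class identity should treat the mapping as a
  parameter.
* The combination χ² is conservative under the random-pairing null (see
  above); its use here mirrors the published analysis rather than an
  exactly calibrated alternative (a permutation test would provide one).
* Alignment of 2 kb windows is exact but not fast; genome-scale homology
  scans should subsample or parallelize (the pipeline subsamples
  deterministically via `homology_max`).
* The zinb caller fits a global mixture; on very small genomes with few
  enriched windows the local-Poisson mode is the safer default.
* Control-pair sampling assumes the chromosome is not mostly assembly gap;
  it fails loudly after a bounded number of rejections otherwise.
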
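# etipseq

Analysis of topoisomerase IIβ action sites from eTIP-seq experiments.

Type II DNA topoisomerases pass one DNA duplex (the T-segment) through a
transient break in another (the G-segment). Etoposide-mediated topoisomerase
immunoprecipitation sequencing (eTIP-seq) arrests the enzyme covalently on
the G-segment and reads out its genomic action sites in two arms:

* **eTIPa** — the immunoprecipitated DNA is split into a bead-bound (P1) and
  a high-salt-eluted (P2) fraction; peaks called per fraction classify
  "toposites" into three classes (Ts1 = P2-only, Ts2 = P1-only,
  Ts3 = both, by the configurable default evidence map).
* **eTIPb** — G- and T-segments bound to one enzyme molecule are ligated via
  an adaptor and paired-end sequenced; each "chimera" measures the genomic
  distance between the two segments. Spans below 3 kb are proximal strand
  passage (PSP), spans of 3 kb–2 Mb are distal strand passage (DSP), longer
  ones are inter-complex noise. Read orientations, ordered upstream →
  downstream (F = forward, R = reverse), carry mechanistic signal: PSP is
  RF-dominated, DSP on direct repeats gives RF/FR, DSP on inverted repeats
  gives FF/RR.

The package implements the full computational pipeline around these ideas:

* read-pair filtering (unique, convergent, insert < 500 bp), 200 bp
  strand-extension pileup, and peak calling (local-Poisson default, or a
  zero-inflated negative-binomial mixture with a 0.5 posterior threshold);
* toposite classification, GC/region annotation (TSS zone = TSS ± 2 kb,
  genic, intergenic; densities per 100 kb);
* chimera loading, toposite-combination statistics (expected counts
  `N·fᵢ²` and `2N·fᵢ·fⱼ` from end frequencies, per-combination χ² with
  Benjamini–Hochberg correction), span and orientation tables;
* terminal homology of DSP chimera ends: 2 kb read-centred windows aligned
  U+ vs D+ and U+ vs D− by Smith–Waterman (match +5, mismatch −4, gap open
  10, extension 0.5); the larger score calls a **direct** or **inverted**
  repeat, and matched random control pairs (≤ 2 Mb apart, < 20 % gap
  coverage) calibrate the score scale;
* sliding-window density maps (100 kb window, 10 kb step), toposite clusters
  (count thresholds 15 for Ts2, 5 for Ts3), DSP-chimera clusters, and their
  same-class integration into **hotspots**;
* chromatin-condensation quantification from 3D nucleus stacks: 256-level
  stretch, mean filter, Otsu segmentation, per-nucleus intensity histograms,
  the cross-condition isosbestic point, condensed fraction and volume, with
  Mann–Whitney group comparison;
* a fully ground-truthed synthetic data generator (`sim_spec()`,
  `simulate_genome()`, `simulate_etipa_reads()`, `simulate_chimeras()`,
  `simulate_nuclei()`) that emulates all of the above — planted homologous
  repeat families drive the chimera orientation rules.

## Worked example

```r
library(etipseq)
cfg <- demo_config(seed = 5)          # scaled-down study conditions
cfg$stages[["imaging"]] <- TRUE
summary <- run_etip_pipeline(cfg, "run1")
```

The run directory contains per-stage outputs (FASTA, read tables, bedGraph
pileups, toposite BED/TSV, annotated chimera BEDPE, homology and control
score tables, cluster/hotspot BEDs, per-nucleus TSV) plus `summary.json`.
For seed 5 the summary reads, in part:

```json
"call":    {"n_toposites": {"Ts1": 67, "Ts2": 50, "Ts3": 71},
            "class_recovery": 0.98936170213, "summit_within_100bp": 0.98404255319}
"chimera": {"n_by_span_class": {"DSP": 488, "PSP": 401}, "n_assigned": 789}
"homology":{"concordance": 1, "median_dsp_score": 4085.75,
            "median_control_score": 1607}
"clusters":{"n_hotspots": {"Ts2": 1, "Ts3": 1}}
"imaging": {"isosbestic_level": 149,
            "mean_fraction_by_condition": {"D1": 0.456288, "D5": 0.295185}}
```

Reading: ~99 % of called toposites carry their true planted class and ~98 %
of summits land within 100 bp of the planted site centre; chimera spans
split into proximal and distal regimes; the read-orientation ↔ repeat-
directionality concordance is 100 % and distal ends score ~2.5× above
matched random controls; same-class toposite and chimera clusters integrate
into one Ts2 and one Ts3 hotspot; and the two imaging conditions (planted
condensed fractions 0.45 / 0.30) are recovered as 0.456 / 0.295 with the
isosbestic boundary at gray level 149.

Reruns with the same configuration are byte-identical. A thin command-line
wrapper is available at `inst/scripts/etipseq.R`.

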
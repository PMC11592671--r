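---
title: "Methods: quantifying nuclear-cytoplasmic shuttling with nucshuttle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nuclear-cytoplasmic shuttling with nucshuttle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshuttle)
```

`nucshuttle` quantifies how a fluorescently tagged protein partitions between
the nucleus and the cytoplasm, and whether that partitioning is consistent
with active nuclear import/export. It covers five measurement families —
intensity-ratio imaging, FRAP, FRET acceptor photobleaching, sequence-motif
scanning and biochemical fractionation — plus a seeded synthetic-data
generator that produces inputs with known ground truth for every family.

## 1. Synthetic fields with ground truth

`field_spec()` / `generate_field()` simulate a three-channel field (protein,
DAPI, brightfield): non-overlapping elliptical cells each containing one
elliptical nucleus, a uniform background level (default 0.05), per-cell
nuclear intensity fraction drawn as Normal(`nuclear_fraction` = 0.7, sd
`fraction_jitter` = 0.05) clipped to [0, 1], optional punctate "speckles",
and Gaussian pixel noise (`noise_sigma`).

Defaults and why:

* `nuclear_fraction = 0.7` places the simulation in the regime of a
  predominantly nuclear protein with a clear cytoplasmic pool — the regime
  the analysis is designed to resolve.
* `n_cells = 15` on a 512×512 field keeps rejection-sampled placement fast
  while giving segmentation realistic cell crowding.
* Nucleus radii 9–14 px and cell radii 22–32 px at `pixel_size = 0.2` µm/px
  approximate cultured-cell proportions.

Two deliberate departures from photorealism keep the ground truth exact:

* The **protein channel is not blurred**; edge blur (`edge_blur_sigma`) is
  applied to the DAPI and brightfield channels only. Blurring the protein
  channel would smear intensity across the compartment boundary and make the
  drawn per-cell fraction unrecoverable at the 1e-6 level the tests demand.
* Speckle intensity mass is compensated back into the compartment base level,
  so the integrated compartment intensities still realize the requested
  fraction exactly before noise.

The generator does **not** emulate optical point-spread functions, shot
noise statistics, uneven illumination, or out-of-focus light. Conclusions
about robustness to those effects cannot be drawn from it.

## 2. Nuclear-fraction imaging pipeline

`segment_nuclei()` smooths DAPI (Gaussian sigma 2 px), thresholds with Otsu's
method, fills holes, and splits touching nuclei with a distance-map
watershed. Objects outside 40–5000 px or touching the border are dropped.
`segment_cells()` grows each nucleus seed into a cell body with a seeded
Voronoi propagation on the combined protein/brightfield foreground.

`measure_nc()` subtracts a background estimate (the intensity mode of
non-cell pixels), then computes per cell

$$ f_N = \frac{\bar I_{nuc}}{\bar I_{nuc} + \bar I_{cyto}} $$

with means over the nuclear mask and the cell-minus-nucleus mask. The two
masks partition each cell pixel-exactly; degenerate cells (cytoplasmic ring
of 5 px or less, or zero total signal) are dropped with a message.
`summarize_population()` reports the per-cell mean, sd and n, flagging
populations below 75 cells — the headline number is the per-cell mean, with
the experiment-level alternative available through
`compare_groups(mode = "experiment")` because the literature convention is
ambiguous about the test unit.

`pearson_coloc()` is the plain Pearson coefficient over mask pixels, with an
explicit `"undefined"` status when a channel has zero variance, and
`detect_speckles()` finds condensate-like puncta as local maxima of a
per-compartment, median-subtracted difference-of-Gaussians response.

## 3. FRAP normalization and fitting

`double_normalize()` applies the standard double normalization: background
subtraction, division by the pre-bleach bleach-ROI mean, and correction by
the whole-cell ROI to cancel acquisition bleaching. `full_scale_normalize()`
then maps the first post-bleach value to 0,
$F(t) = (I(t) - I_0)/(1 - I_0)$, so recovery curves with different bleach
depths are comparable.

`fit_recovery()` fits $c_0 + A_1(1-e^{-k_1 t}) + A_2(1-e^{-k_2 t})$ (single
model: $A_2 = 0$) with `minpack.lm::nlsLM` from five jittered multi-starts;
rates are bounded to $[10^{-5}, 10]\,s^{-1}$ and components reordered so
$k_1$ is the fast one. The half-time is $\ln 2/k$ for the single model and a
bisection root of the fitted curve for the double model — there is no closed
form. `mobile_fraction()` is the fitted plateau of the double-normalized
curve; it deliberately takes only the fit object, which records the offset
and the input normalization. Fits with plateau > 1.2 are flagged rather than
rejected.

## 4. FRET acceptor photobleaching

Per ROI, efficiency is the donor dequenching ratio
$E = (D_{post} - D_{pre})/D_{post}$ (`fret_efficiency()`), and the bleach
efficiency is $B = (1 - A_{post}/A_{pre}) \times 100$
(`bleach_efficiency()`). QC keeps bleached ROIs with **strictly** more than
60% acceptor bleach. Each cell contributes the mean of its (up to six)
bleached ROIs minus one unbleached control ROI that must lie at least 3 µm
away (`cell_corrected_efficiency()`).

The synthetic generator produces donor recovery via
$D_{post} = D_{pre}/(1 - E\,b)$, where $b$ is the realized acceptor bleach
fraction. Under partial bleaching the raw formula therefore returns the
apparent efficiency $E\,b$; `bleach_corrected_efficiency()` divides by $b$
as measured from the acceptor channel, which recovers the true $E$ exactly
on noiseless data while using only observable quantities.

`normalize_to_control()` rescales whole cohorts so the positive-control
cohort mean is exactly 1 (and is idempotent). `compare_fret()` uses a
Wilcoxon rank-sum test for two cohorts (unpaired by default — bleached and
control cells are physically different cells) and Kruskal–Wallis with a
hand-rolled, tie-corrected Dunn post hoc (Holm adjustment) for three or
more; no installed package provides Dunn's test.

## 5. Motif scanning and variants

`scan_nls()` slides a 12-residue window and scores the K/R count over the
window length; windows scoring at least 7/12 are candidates and each maximal
run of overlapping candidates is reported as its best-scoring (leftmost on
ties) window. The score is a transparent count, not a trained predictor.

`scan_nes()` classifies every 15-mer against the four CRM1 consensus
classes, expressed as hydrophobic anchor offsets
(Φ ∈ {L, I, V, F, M}; alanine tolerated at the first anchor only):
class 1a (0, 4, 7, 9), 1b (0, 3, 6, 8), 2 (0, 2, 5, 7) and 3 (0, 3, 7, 9),
with precedence 1a > 1b > 2 > 3 and the pattern allowed anywhere in the
window. Overlapping same-class windows merge into one span — merging is done
per class, so interleaved windows of another class cannot split a run.

`parse_variant()` / `apply_variant()` support missense (`K213E`), nonsense
(`S243*`) and frameshift (`S278Pfs*71[:tail]`) edits with reference-residue
checking, and `diff_motifs()` reports motifs lost, gained and retained after
an edit. The packaged FASTA is a clearly labelled **synthetic scaffold**: a
low-complexity filler carrying the curated motif windows at their native
coordinates, so coordinate conventions are testable without distributing a
real proteome sequence.

## 6. Screen, fractionation and statistics

`screen_karyopherins()` classifies gene symbols (case-insensitively) against
the packaged karyopherin catalog of protein importers, protein exporters and
RNA exporters. `quantify_fractionation()` normalizes each lane's band by its
total protein load, reports the nuclear percentage
$100\,N_n/(N_n + N_c)$, and uses the marker lanes (Histone H3, tubulin) as a
**binary purity check** — leakage above 10% of a marker into the wrong lane
raises a flag rather than entering the quantification.

`significance_stars()` applies the inclusive tiers *** $p \le 0.0009$,
** $p \le 0.009$, * $p \le 0.05$, else `ns` — the unusual printed boundaries
are preserved verbatim.

## 7. Reproducibility

All generators take a single integer seed; `derive_seed()` derives
independent sub-stream seeds from it, and `run_pipeline()` writes every
table, a JSON summary and a log with seed and parameters. The repository's
`scripts/acceptance.R` recomputes the headline quantities from scratch for
any seed.

```{r example, eval = FALSE}
g <- generate_field(field_spec(seed = 1))
nuclei <- segment_nuclei(g$field$dapi)
cells <- segment_cells(g$field, nuclei)
summarize_population(measure_nc(g$field, cells, nuclei))
```

Typical problem sizes: a 512×512 field with 15 cells generates in about one
second and segments in well under a second; a 250-frame FRAP fit takes tens
of milliseconds; the full test suite (including 100-sequence oracle
comparisons and 50 noisy FRAP replicates) runs in under a minute.
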
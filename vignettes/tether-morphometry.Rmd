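---
title: "Single-molecule AFM morphometry of coiled-coil tethers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule AFM morphometry of coiled-coil tethers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tethermorph)
```

## The problem

Golgins such as GCC185 are long dimeric coiled coils that tether transport
vesicles at the Golgi. Imaged by atomic force microscopy (AFM) after
adsorption to mica, single molecules of such a tether appear as thin
flexible filaments, roughly 145 nm long for the full-length protein, with
three recurring structural features:

* **splays** — the two chains of the dimer separate at a terminus into two
  short visible arms;
* a central **bubble** — a local unwinding of the coiled coil, visible as a
  loop of two separated strands near the middle of the molecule;
* terminal **globules** — an N-terminal GFP fusion moiety and the smaller
  C-terminal GRIP domain, which also give the molecule a readable
  orientation.

`tethermorph` implements the complete quantitative workflow for such data:
scan flattening, molecule detection and selection, skeleton tracing with an
eight-segment feature decomposition, and the population statistics
(conformational classes, bubble frequency and size, normalized
splay-to-splay distance, relative feature positions, group comparisons).
Because raw scans of this kind are rarely public, the package also ships a
synthetic-topograph generator with exact per-molecule ground truth, so that
every stage of the pipeline is testable end to end.

## The measurement model

### Flattening

Raw AFM images carry a sample tilt plus per-scan-line offsets. Since
molecules cover only a small fraction of each line, the line median tracks
the local background, and flattening subtracts the median of every row and
then the median of every column (`flatten()`). Two conventions matter and
are fixed here: passes run row-first (scan lines first), and the median of
an even-length line is the mean of the two central values. After one pass
every column median is exactly zero. Note that a second pass is not a
no-op in general — removing column medians re-perturbs the row medians —
so the package performs the single pass per axis that the procedure
defines; for an additive row-plus-column offset field the output is
exactly zero and further passes change nothing.

### Detection and selection

Foreground pixels are those above `median + k * MAD` of the flattened
image (`k = 3` by default; the MAD estimates the noise scale), grouped
into 8-connected components (thin diagonal filaments fragment under
4-connectivity). Components below 30 px are set aside as noise speckle.
The selection criteria mirror manual practice: objects touching the field
border are rejected (`border`), as are objects much larger than the
typical single-molecule area or containing more than one ground-truth
molecule when truth is available (`aggregate`), and objects whose skeleton
does not reduce to the canonical anatomy (`untraceable`). Every detected
object lands in exactly one of the metrics or rejection tables. On
typical synthetic fields 40–70% of molecule-scale objects survive
selection; a warning is emitted outside that band.

### Tracing and the eight segments

Each retained object is thinned to a unit-width skeleton (Guo–Hall
parallel thinning plus a staircase-corner cleanup; unlike Zhang–Suen this
leaves no two-pixel diagonal ladders, so curve pixels have exactly two
neighbours), and converted to a graph of endpoints, junctions and pixel
paths. Spur edges below 6 nm are pruned — but a junction carrying *two*
terminal edges is a candidate splay fork, and its paired branches are only
pruned at pixel scale, so pruning cannot delete true arms. Enclosed
low-height regions (below half the duplex ridge height) are punched out of
the mask before thinning: they are bubble valleys whose above-threshold
rim closed under tip broadening, and removing them restores the cycle that
makes a bubble detectable.

The backbone is the longest terminus-to-terminus path through the graph
(the tree diameter) — a splay arm is always shorter than the rest of the
molecule. A terminus whose first junction lies within the arm scale
(40 nm) and carries an off-path terminal edge is a splayed end; the unique
cycle, if its contour exceeds 8 nm, is the bubble, and its two paths
between the attachment junctions are the strands. Because the strands run
merged into a single ridge near the chord endpoints, each strand's end
tangent is intersected with the stalk tangent and the hidden neck (clipped
at one pixel per junction) is restored to the strand length. A cycle whose
two strands differ more than threefold is treated as a backbone
self-contact, not a bubble, and the molecule is rejected as untraceable.

Terminal globule caps are excluded from segment lengths: from each
endpoint the trace is trimmed while the ridge height exceeds
`cap_trim_height_nm` (1.95 nm, between the 1.5 nm duplex and the 2.0 nm
GRIP cap), and the maximum local height in the trimmed region is recorded.
The end with the taller cap is called N (GFP above GRIP); if the two caps
differ by less than `height_tie_nm` (0.25 nm) the molecule is kept but
flagged orientation-ambiguous and orientation-dependent metrics are
withheld.

The segments are: `X1, X2` N-terminal arms, `X3` N-side stalk, `X4, X5`
bubble strands, `X6` C-side stalk, `X7, X8` C-terminal arms; absent
features are zero, pairs are stored in decreasing order, and a bubble-free
molecule carries its whole stalk in `X3` (`X6 = 0`).

### Lengths on a digital trace

Summing per-pixel steps (1 axial, √2 diagonal — `path_length()`)
overestimates the length of a smooth digitized curve by the classical ~5%
staircase bias. Reported lengths therefore use `contour_length()`: the
pixel path is lightly smoothed (each interior vertex replaced by the mean
of a symmetric ±1-pixel window, endpoints fixed) and Euclidean steps are
summed. A straight digital line is measured exactly; on circles the
residual bias is below 1%. This mirrors measuring a molecule with a
sparse segmented line rather than pixel by pixel.

### Per-molecule metrics

* **Bubble size** `= (X4 + X5) / 2`; 0 without a bubble.
* **Total length** `= (X1+X2)/2 + X3 + (X4+X5)/2 + X6 + (X7+X8)/2` —
  paired features are averaged, mirroring the bubble-size convention.
* **Normalized splay-to-splay distance**: the Euclidean distance between
  the two splay junctions divided by the traced backbone path between them
  (strands entering as their mean); for an unsplayed end the trimmed
  terminus substitutes for the junction. Rigid, extended molecules
  approach 1.
* **Relative positions** of the bubble or antibody label: path length from
  the GFP end to the feature start/centre/end over the total length.
* **Conformation class**: one of eight labels from N-splay x C-splay x
  bubble.

Population statistics use standard machinery: exact binomial confidence
intervals for splay and bubble fractions, Welch's unpaired two-tailed
t test for group comparisons (a pooled-variance form is available but the
unequal-variance default is the safer reading of "unpaired, two-tailed
t test"), histograms and empirical CDFs for distribution overlays, and
the coiled-coil prediction arithmetic (`predicted_length()`,
`percent_shortfall()`) with the canonical 0.1485 nm/residue axial rise.

## The synthetic-topograph generator

The generator emulates 1.2 μm × 1.2 μm scans at 512 × 512 px (2.34 nm/px)
of sparse surface-adsorbed molecules, with defaults encoding the study
conditions:

| parameter | wild type | hinge deletion | rationale |
|---|---|---|---|
| contour length (nm) | 145 ± 12 | 136 ± 10 | measured full-length mean; deletion removes 103 of 1684 residues |
| persistence length (nm) | 50 | 150 | floppy wild type vs visibly straighter mutant |
| per-end splay probability | 0.6164 | 0.6164 | yields 85% ≥1 end and 38% both ends under independent ends |
| bubble probability | 0.5 | 0.2 | half of wild-type molecules vs 20% |
| bubble strand mean (nm) | 27 ± 7 | 17 ± 2.5 | mean sizes, with the much sharper mutant distribution |

A `noDTT` preset (rod-like molecules: splay and bubble probabilities 0.05,
quasi-rigid backbone) emulates non-reducing buffer, and `fragment:<name>`
presets cover the four truncation constructs, with contour means scaled
from residue counts at the canonical rise times the observed ~0.69
compaction.

Backbones are discrete planar worm-like chains (mica-adsorbed molecules
are effectively two-dimensional); the discrete closed form for the mean
squared end-to-end distance (`wlc_mean_sq_end_to_end()`) is exact for this
model and anchors the simulation tests. Splayed termini are modeled by
shortening the duplex by the mean arm length and growing two diverging,
nearly straight arms from the junction, so that the total-length formula
recovers the generator contour. Arms are rendered stiff (300 nm
persistence) with divergence half-angles of 0.61 ± 0.17 rad truncated at
0.45 rad: the study's splay counts were scored visually, hence on splays
that are resolvable, and these settings keep a splayed end resolvable at
the 2.34 nm pixel. The bubble replaces a central sub-path (92% of the mean
strand length, centred near mid-molecule where the hinge regions sit) with
two circular arcs bulging to opposite sides; the chord is shrunk if needed
so the strands stay at least `bubble_lateral_offset_nm` (8 nm) apart, and
strand lengths are drawn as a per-molecule mean with a small (≤11%)
asymmetry so both strands always reach across the chord. Heights are
1.5 nm for the duplex ridge, 2.5/2.0 nm for the GFP/GRIP caps and 4 nm
for the antibody blob — distinguishable within the ~2.5 nm display range
of such scans; none of these heights are printed in the source study and
they are free parameters here.

Rendering rasterizes ridges and spherical-ish caps, applies grayscale
dilation by a spherical tip (apparent height is the maximum of surface
height plus the tip profile `sqrt(R² − r²) − R`; peak heights of isolated
convex features are preserved, lateral widths broaden monotonically with
`R`), then adds a tilted plane, per-scan-line offsets and white noise
(0.1 nm SD, a typical air-imaging roughness). Placement is uniform with
rejection of >60% footprint overlap; border contact is recorded, not
prevented, so selection filtering can be exercised. Twenty molecules per
field is the default surface density — the study does not report one, and
this value lands the retained fraction inside the reported 40–70% band.
Every molecule draws from its own substream of the root seed, so
populations are bitwise reproducible.

What the generator does **not** emulate: excluded-volume effects (chains
may self-cross, and such molecules are rejected exactly as a human scorer
would reject them), tip asymmetry and double-tip artifacts, scar lines,
thermal drift, and height-dependent adhesion contrast. Passing the
recovery suite therefore demonstrates that the tracer is unbiased for
idealized but realistically noisy scans, not that it is robust to every
instrumental pathology.

## Validation studies and what they show

The acceptance suite runs scaled-down studies of 200 molecules per
condition (about ten scan fields each; roughly a minute per study on one
CPU):

* on clean renders (no tip, no noise) the recovered total-length mean is
  within 5% of the generator mean, conformation classes agree with ground
  truth for ≥90% of molecules, and bubble detection has ≥90% sensitivity
  at ≤5% false positives;
* under the default conditions (3 nm tip, noise, slant) the total-length
  mean stays within 10%, bubble frequency and the splay fractions fall
  within binomial 95% confidence intervals of the preset probabilities,
  and bubble-size means are within 10% of the preset means;
* an antibody-labeled population (label at residue 805, i.e. fraction
  0.478 of the backbone) recovers the label's median relative position
  within ±0.03;
* the hinge-deletion contrast reproduces the qualitative study result:
  fewer and smaller bubbles and a larger normalized splay-to-splay
  distance than wild type, each at Welch (or proportion-test) p < 0.01.

Two analytic checks tie the statistics module directly to printed
population numbers: a per-end splay probability calibrated to a both-ends
fraction of 38% predicts 85% of molecules with at least one splayed end
(`independent_ends_check()`), and the 889-residue N-terminal half at its
measured 91.2 nm mean is 30.9% short of its 132.0 nm coiled-coil
prediction — the "~30% shorter than predicted" compaction.

## Known limitations

* Per-strand bubble lengths on *individual* molecules carry ±1–2 px of
  junction-placement jitter, and the shorter strand of a strongly
  asymmetric bubble is biased low (it hugs the chord and partially merges
  with the stalk). The calibrated quantity is the strand mean — the bubble
  size — and, at population level, its mean.
* Splays whose arms never separate by a pixel are invisible in principle;
  the generator deliberately renders resolvable splays (see above), so
  real preparations with tighter splay geometry would be undercounted.
* The N/C call requires a resolvable cap-height difference; constructs
  without a GFP (e.g. the C-terminal fragment) are orientation-ambiguous
  by design and their orientation-dependent metrics are withheld.
* Contour lengths exclude the globule caps (the trace stops at the cap
  boundary), so measured totals run ~2–3% below the generator contour,
  which includes the backbone beneath the caps.

## Reproducing a run

```{r example, eval = FALSE}
pop <- population_preset("wt", n_molecules = 50, seed = 1)
sim <- generate_population(pop, scan_spec())
res <- analyze_population(sim)
rep <- report_metrics(list(wt = res$metrics))
str(rep$groups$wt)
```

`scripts/acceptance.R` re-runs the analytic checks, the oracle
comparisons, the geometry limits and the four recovery studies from
scratch and writes every quantity to a JSON file; see the README.
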
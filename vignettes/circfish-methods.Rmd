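---
title: "Dual-probe smFISH for circular RNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-probe smFISH for circular RNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circfish)
library(dplyr)
```

## The measurement model

An exonic circRNA shares its entire sequence with the linear host
transcript; only the back-splice junction is unique to the circle, and a
single junction cannot anchor enough fluorophores for single-molecule
detection. The dual-probe strategy sidesteps the junction entirely:

* the **PC** set tiles the circularised exon(s) and hybridises to *both*
  isoforms;
* the **PL** set tiles exons absent from the circle and hybridises only to
  the *full-length linear* transcript.

Each RNA molecule appears as one diffraction-limited spot per probe set
bound to it. After detecting spots independently in the two channels, a
spot with a counterpart within **250 nm** (3D Euclidean distance, inclusive
boundary) in the other channel is one full-length linear molecule; a
PC-only spot is a circular molecule; a PL-only spot is a fragment of the
linear isoform (a partially degraded molecule carrying the PL but not the
PC exons). Two conservation identities follow directly and are enforced by
`classify_spots()`:

$$ n_\text{linear} + n_\text{circular} = n_\text{PC}, \qquad
   n_\text{linear} + n_\text{fragment} = n_\text{PL}. $$

## Probe design

`tile_probes()` uses a greedy left-to-right cursor: the 20-nt window at the
cursor is emitted as a probe when its GC fraction lies in the inclusive
window [0.35, 0.55], after which the cursor jumps by `probe_len + 2`
(the 2-nt gap prevents quenching between adjacently bound fluorophores);
otherwise the cursor advances by one base. Commercial designers solve the
same problem with proprietary scoring; a deterministic greedy tiler is
reproducible, trivially auditable, and achieves the closed-form capacity

$$ N_\max(L) = \left\lfloor \frac{L + g}{\ell + g} \right\rfloor $$

when the GC filter is off (probe length $\ell$, gap $g$; 39 probes on an
875-nt target at $\ell = 20$, $g = 2$). The companion rule
`min_target_length(n)` = $n\ell + (n-1)g$ quantifies the method's main
limitation: with the 15–20 probes needed for a discrete spot, targets
shorter than roughly 330–440 nt cannot be imaged, so very short circRNAs
are out of reach regardless of chemistry. GC content is the only
thermodynamic proxy used (no melting-temperature model), matching how such
probe panels are screened in practice. Probes may span exon–exon junctions
*inside* one target region — those junctions exist in both isoforms — but
never cross between the PC and PL regions, and no back-splice-junction
probe is offered. U and T are interchangeable on input; probes are emitted
in the DNA alphabet as reverse complements of their target windows.

## The synthetic scene generator

Real circFISH ground truth does not exist — no one knows the true molecule
count of a cell — so every downstream stage is validated against a
simulator whose scenes are exactly known.

**Geometry.** The default acquisition is 16 z-slices at 200 nm spacing with
130 nm xy pixels: a standard epifluorescence stack (13 µm camera pixels
behind a 100× objective). Nuclei are random non-overlapping rotated
ellipses (semi-axes 10–16 px); a cell's territory is the nearest-nucleus
partition of the field clipped to a 2.5-fold dilation of its nucleus, a
stand-in for the unavailable membrane stain. Nuclei are 2D and extruded
through z, because nuclear/cytoplasmic calls are made on max-projected
masks downstream.

**Molecules.** Per cell and class, counts are Poisson (a negative-binomial
over-dispersion option exists, off by default); each molecule is nuclear
with a class-specific probability and is placed uniformly over the
corresponding 2D compartment, z uniform over the stack. Defaults mirror
the reported biology of the ZNF609 pair: linear molecules 25% nuclear
(predominantly cytoplasmic), circular 50/50. Field-level defaults are
60/40/10 linear/circular/fragment molecules per cell; the count-level
scenario configuration (`scenario_config()`) uses 100 cells with 30 linear
and 10 circular per cell — a moderately expressed circRNA, chosen once as
typical of imaged circRNA abundances.

**Optics.** Each molecule renders as an anisotropic 3D Gaussian (the PSF of
a diffraction-limited emitter; σ defaults 170 nm xy, 350 nm z, safely
below the 250 nm radius — the configuration warns otherwise). Linear
molecules emit in both channels, circular only in PC, fragments only in
PL. The PC channel rendering of every molecule is offset by a per-molecule
registration jitter (Normal, 50 nm SD per axis), modelling
channel-to-channel registration error — well under the 250 nm radius, so
classification is nearly noiseless at defaults. Noise is Poisson on signal
plus background, with additive Gaussian read noise, clipped at zero.

**Perturbations.** `apply_rnase_r()` thins molecules with exponential
survival $2^{-t/t_{1/2}}$ — the exonuclease digests linear RNA and
fragments quickly (default half-life 1 h) and erodes circles only slowly
(default 48 h; prolonged digestion does degrade circRNA, hence a finite
value). `apply_knockdown()` removes a fraction of one class only. Both
operate on an existing ground truth, so a time course or a
control/knockdown pair is a *coupled* design: every arm is a thinning of
the same molecule population driven by one set of survival draws. This
makes survivor sets nest across timepoints (a property the tests verify)
and makes the "unchanged" class exactly unchanged in a knockdown, as the
selectivity claim intends. The half-lives are scenario parameters, not
measured constants: the source experiments report qualitative loss at
fixed timepoints, not decay rates.

**What the simulator does not model:** optical aberrations, photobleaching,
autofluorescence, tissue section artifacts, transcription-site clusters,
and structured protein channels. Passing tests therefore demonstrate that
the *computational* chain is correct and unbiased under ideal-but-noisy
imaging physics; they do not certify performance on degraded clinical
material, where background and fragment rates are higher.

## Spot detection

Detection uses the standard smFISH operator: a scale-normalised
Laplacian-of-Gaussian. The volume is smoothed with an anisotropic Gaussian
at the expected spot scale and the negated Laplacian is accumulated with
per-axis $\sigma^2$ normalisation,
$-\sum_a \sigma_a^2 \, \partial^2/\partial a^2$, computed in voxel units
with per-axis voxel sizes, so a matched blob yields a positive peak of
scale- and amplitude-proportional height. Sigmas below half a voxel are
rejected as undersampled. Spots are local maxima of the response in a
3×3×3 neighbourhood (configurable radius), refined to subpixel precision
by an intensity-weighted centroid of the positive response in the
surrounding 3×3×3 window, and reported in nm (axis order z, y, x; 0-based
voxel origin; a voxel's centre is at $(i + 0.5) \times$ voxel size).
Plateau ties are broken to the lowest (z, y, x) index. Centroid refinement
keeps the worst-case localisation error well under half a voxel for
isolated spots — sufficient margin against a 250 nm matching radius at
130 nm pixels — without the cost of full 3D Gaussian fitting.

**Automatic thresholding** follows the spot-count plateau heuristic:
thresholds are swept logarithmically between the 90th percentile and the
maximum of the response, local-maxima counts are computed at each, and the
geometric midpoint of the longest run with <5% relative change per step is
returned. A valid plateau must additionally span at least a factor 1.5 in
threshold: without this span requirement the rule is underdetermined on
signal-free volumes, where short accidental runs exist; with it, pure
noise fails calibration with an instructive error instead of yielding an
arbitrary threshold. The plateau count is amplitude-invariant (doubling
the stack doubles the threshold, not the count).

## Matching and classification

All cross-channel pairs within the radius are sorted by distance (ties by
PL then PC index) and accepted greedily while both endpoints are free —
a deterministic one-to-one matching. One-to-one is the physically
meaningful choice for single molecules: one linear transcript carries one
PL and one PC probe load. A many-to-one mode
(`match_spots(one_to_one = FALSE)`) exists because the original analysis
code's behaviour on this point is unknowable; the default is one-to-one.
Greedy nearest-pair matching is not guaranteed optimal, but on random
instances it attains ≥95% of the maximum-cardinality matching (verified
against an augmenting-path oracle) and is exactly optimal whenever each
spot has at most one in-radius candidate — the regime any usable smFISH
experiment operates in. Linear molecules are reported at the pair
midpoint, a convention.

Exact recovery of class counts is only decodable when inter-molecule
spacing exceeds the radius plus jitter; at high density, coincidental
PL/PC proximities are genuine ambiguities that no classifier could
resolve. The validation suite therefore checks *exactness* on
sub-resolution-density scenes (simulator minimum-separation option,
600 nm) and *unbiasedness* (class-proportion MAE < 2 points over 1,000
scenes) at unconstrained default density with 30 nm localisation noise
added per axis — the density regime where those coincidences occur and
simply remain rare in 3D.

## Quantification and statistics

DAPI is max-projected, smoothed (σ = 1 px by default — enough to suppress
shot noise without biasing the Otsu boundary), thresholded with Otsu's
method, hole-filled, size-filtered, and split by watershed on the distance
transform; cell territories grow from the nuclei across a fixed-radius
dilation. Spots are assigned to the cell and compartment at their (y, x)
pixel; background spots are excluded. Cells touching the field border are
excluded from per-cell statistics by default (partially observed cells
bias means), and zero-count cells are *included* in count averages but
excluded from localisation-fraction averages (a cell with no molecules of
a class carries no localisation information).

Summaries follow the field's reporting conventions: mean molecules per
cell with a 95% CI of $1.96 \cdot s/\sqrt{n}$ (normal approximation);
pairwise condition comparisons by two-sided, pooled-variance Student's
t-test (`stats::t.test(var.equal = TRUE)`; the test suite verifies it
against the textbook pooled formula); star codes `***` for p < 0.001, `*`
for p < 0.05, `ns` otherwise; no multiple-testing correction, matching how
such panels are conventionally reported; and a warning below 100 cells per
condition. Two identical zero-variance samples (possible for an untouched
class in a coupled design) are reported as t = 0, p = 1 rather than an
error.

## Problem sizes and numerical choices

The validation suite runs entirely on synthetic data generated at test
time. Sizes were chosen to make every statistical check well-powered while
keeping a full run around two minutes: detection benchmarks use 16×256×256
stacks with 50–60 spots; classification exactness uses one 60/40/10 cell;
the bias study uses 1,000 spot-level scenes; the RNase R and knockdown
scenarios use 100 cells × 20 replicates and 100 cells respectively, at the
count level (the imaging chain is validated separately, so repeating it
inside every scenario replicate would only re-test the renderer).
Reproducibility is seed-exact: a pinned `rng_seed` makes cell maps,
molecule tables and rendered stacks bit-identical, and the survival draws
of a digestion series are shared across timepoints. TIFF stacks are
written as 16-bit with a power-of-two intensity scale recorded in a JSON
sidecar, which makes `write(read(x))` voxel-identical (division by a
power of two is exact in binary floating point).

## Known limitations

* Cell territories are a geometric stand-in; absolute "molecules per
  cell" depends on that convention wherever no membrane marker exists.
* The greedy matcher can (rarely) mis-pair at high density; a
  maximum-cardinality matcher would remove the <5% gap at cubic cost.
* Centroid localisation is adequate for a 250 nm radius but inferior to
  Gaussian fitting near the Nyquist limit; fitting is a natural extension.
* Fragments are defined operationally (PL-only signal); molecules that
  lost the PL exons instead are invisible to both probe sets and are not
  modelled.
* The statistics are per-cell normal approximations; strongly
  over-dispersed counts (the negative-binomial option) deserve GLM-based
  comparisons, which are out of scope here.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_cells = 3, field_shape = c(16, 200, 200),
                  mean_counts = c(linear = 15, circular = 8, fragment = 2),
                  rng_seed = 4)
scene <- simulate_scene(cfg, noise = FALSE)
write_stack(scene$stack, "scene.tif")
res <- run_pipeline("scene.tif", pipeline_config(seed = 3), "out")
res$summary$class_counts
autoplot(res$classified)
```
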
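---
title: "Tracking bacterial motility from frame series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking bacterial motility from frame series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactrack)
```

## The problem

Motility is an energy-hungry behaviour: a flagellated bacterium only
swims when it has the nutrients and metabolic state to afford it. The
swimming speed of single cells sampled from a fermenter can therefore
serve as a near-real-time viability probe — it drops during a diauxic
shift, recovers during consumption of the secondary carbon source, and
collapses at the onset of sporulation. Unlike bulk optical methods,
single-cell tracking also works in turbid production media, because the
analysis below is blind to anything that does not move.

`bactrack` implements the complete computational chain for such a
monitoring setup: synthetic scene generation (replacing the
microscope), moving-object isolation by frame differencing, particle
detection and measurement, frame-to-frame association, velocity
statistics, plus two supporting calculators — capillary shear stress
(to certify that sampling does not shear off flagella) and dilution
planning to the working optical density.

## The sum-difference transform

A series of $N$ frames $A_1, \dots, A_N$ (canonically $N = 30$ at
30 fps: one second of video) is converted into one *sum-difference
image* per frame:

$$B_k = \sum_{j \ne k} \left| A_k - A_j \right|,$$

computed component-wise. A pixel whose value never changes contributes
zero to every term, so static content — debris, undissolved medium
particles, dirt on the optics — is suppressed *exactly*. A cell present
at a pixel in frame $k$ but absent there in most other frames
accumulates close to $(N-1)\,c$ contrast units, while its historical
positions ("trail") only accumulate a few $c$; thresholding separates
the two.

Denoising then subtracts twice the global pixel mean of $B_k$
(clipping negatives to zero) and linearly rescales to the 0–255 range.
The mean is the global image mean: the noise floor of the
sum-difference image has no spatial structure that would justify a
per-row or per-column variant. Normalization constants are computed
per image, not shared across the series, so each $B_k$ uses its full
dynamic range. Accumulation happens in double precision (exact for
these integer sums); only the final normalized image is rounded back
to 8 bits.

Two degenerate cases are handled without errors: a series in which
nothing moves produces all-zero $B_k$ and, downstream, zero particles
and zero velocity vectors.

**Known limitation.** The transform needs a moving object in the
*current* frame to dominate the trail. If every cell has left the
field of view by frame $k$, $B_k$ contains only trail residue, which
per-image normalization then amplifies; such frames can yield spurious
static detections that survive as zero-velocity tracks. In practice a
sample at the working density always has movers in view; scenes
constructed for validation keep at least one mover present throughout.

## Particle analysis

Foreground pixels (`>=` threshold) are grouped into 8-connected
components; labelling is delegated to `EBImage::bwlabel()` with a
union-find merge across diagonal neighbours. The default threshold is
Otsu's method on the normalized image — the original acquisition
software's binarization rule is not documented, and Otsu adapts to
scene brightness while remaining deterministic. Components smaller
than `min_area = 14` px² are discarded: that is the area of a disc of
diameter 0.4 µm at 94.2 nm/px, the detection limit of the 40×
phase-contrast setup.

Each component is reduced to seven characteristics: centre of mass
(x, y), perimeter, area, orientation, length and width. Conventions
this package fixes (the vendor routine the field historically used
does not document its own):

* **Coordinates**: pixel (0, 0) at top-left, x rightwards, y
  downwards, positions are pixel-centre floats.
* **Orientation**: angle of the principal axis from the second central
  moments of the pixel centres, degrees in $[-90, 90)$ from +x
  towards +y.
* **Length/width**: full extents of the pixel centres projected on the
  major/minor principal axes, plus one pixel (so a single pixel has
  length = width = 1).
* **Perimeter**: crack-boundary length, i.e. the number of exposed
  pixel edges ($4\,\mathrm{area} - 2\,\#\text{adjacent pairs}$).

These definitions make the features exactly testable (translation
equivariance, 90° rotation behaviour, agreement with brute-force
moment computation) at the cost of ignoring sub-pixel edge effects.

## Association and tracking

For each consecutive frame pair an error matrix $E$ holds the weighted
L1 feature distance

$$e_{ij} = \sum_{c} w_c \left| f_c(i) - f_c(j) \right|$$

over the seven characteristics. Before weighting, each characteristic
is divided by its series-wide robust scale (median absolute value,
floored at 1) so that pixels, squared pixels and degrees become
commensurate; the map is idempotent. Orientation differences are taken
on the 180° circle, since −89° and +89° describe nearly the same
rod. Pairs whose *raw* centroid displacement exceeds the gate
(default 40 px ≈ 113 µm/s at canonical optics — above any plausible
swimming speed, below frame-to-frame ambiguity) are inadmissible.

The defaults weight the centroid terms 1.0 and the five shape terms
0.2 each: at 30 fps position is the dominant cue over one frame
interval, while shape breaks ties when two cells approach. The method
itself does not prescribe weights; they are exposed in
`feature_weights()`.

Matching is solved as an optimal linear assignment (an $O(n^3)$
Hungarian implementation, exercised against brute-force permutation
enumeration in the tests) rather than greedy nearest-neighbour:
greedy linking cannot guarantee the absence of double assignments when
two bacteria cross, whereas the global optimum resolves a crossing
correctly whenever the combined position-plus-shape cost favours the
true continuation. Unmatched earlier-frame particles are
*disappearances* (cells leaving the field of view, detection
dropouts); unmatched later-frame particles are *appearances*.

Track building chains the matches. A track interrupted for at most
`max_gap` frames (default 1) is re-linked to the cheapest admissible
appeared particle, with the displacement gate scaled by the elapsed
frame count (the gate expresses a maximum speed, so admissibility over
$g{+}1$ frame intervals allows $(g{+}1)\times$ the displacement);
competing re-links are resolved by another optimal assignment. Tracks
with fewer than `min_track_len = 5` detections are removed as
spurious. Both knobs are configuration keys; only track length is
used to reject records — no velocity-outlier filtering is applied.

Velocities are computed per consecutive detection pair:
$v = \lVert \Delta \mathbf{x} \rVert \cdot s \cdot \mathrm{fps} / (g{+}1)$
with $s$ the pixel size (94.2 nm) and $g$ the number of bridged gap
frames — the straight-line distance over the elapsed time, consistent
with the Euclidean-distance velocity definition. The *sample* is the
pool of all such vectors, not per-track means. The summary carries a
quality flag: when the mean number of detected particles per frame
exceeds 15, association becomes unreliable (too many near-identical
candidates inside the gate) and the result is marked `too_crowded` —
the operational remedy is further dilution.

## The synthetic scene generator

Scenes emulate what the real optics deliver: few (1–15) bright
ellipse-shaped bacteria on a noisy constant background, static debris
discs, crossings, and entry/exit at frame edges. Cells advance
`speed / fps` µm per step with a Gaussian heading perturbation;
bodies are rasterized as solid ellipses aligned with the heading,
using 4×4 coverage-weighted anti-aliasing so that sub-pixel centroid
recovery is meaningful. Ground truth records per-frame centroids and
the per-step speed (exactly the spec speed under this motion model).
Rendering is bit-deterministic given the spec and seed.

Default study conditions: 5 bacteria (the 5–10 band is the tracker's
optimal operating regime), speeds 40–60 µm/s, canonical pixel pitch
and frame rate, background level 20, Gaussian pixel noise with sd 0
(clean) or 5 (noisy condition). The noise model is an assumption —
the real sensor's noise statistics are not characterized — as is the
uniform background; phase-contrast halos, defocus and flagella are
deliberately not modelled. Validation scenes use a 1024×768 px window
(speeds of 60 µm/s traverse ~640 px per second; this keeps whole
paths in frame at a tractable rendering cost) with start positions
chosen so the straight-line path stays 60 px inside the border.
Consequently, passing the recovery tests shows the chain is correct
and unbiased on idealized rod-shaped movers; it does not certify
robustness to optical artefacts absent from the generator.

```{r recovery-example}
spec <- random_scene_spec(n_bacteria = 5, speed_range = c(40, 60),
                          seed = 1)
scene <- render_scene(spec)
result <- run_pipeline(scene$frames)
c(truth = mean(scene$truth$speed_um_s),
  recovered = result$mean_velocity)
```

## Velocity statistics

Stage summaries report mean ± SEM (sd/√n) over pooled velocity
vectors. Stages are compared with the two-sided Mann–Whitney U test —
single-cell velocity distributions are typically non-normal, which the
three goodness-of-fit tests (Shapiro–Wilk, Anderson–Darling,
Cramér–von Mises, all against the composite normal hypothesis with
estimated parameters) let you verify per data set. The U test uses
the exact null for combined $n \le 20$ without ties and the
tie-corrected normal approximation otherwise; its type-I error is
checked by simulation (1000 null pairs, n = 50) in the acceptance
suite. Sidedness is two-sided throughout — stage contrasts can go in
either direction. Histograms use half-open bins $[lo, hi)$ of 5 µm/s
by default. The motile fraction helper reports the unweighted mean ±
sample sd of per-sample percentages.

## Capillary rheology

Sampling pumps a cell suspension through a capillary; too much shear
tears off flagella and destroys the signal. For laminar
Hagen–Poiseuille flow:

$$u_m = \frac{4Q}{\pi D^2}, \quad u(y) = 2u_m\left(1 -
\left(\frac{2y}{D}\right)^2\right), \quad \dot\gamma = \frac{8u_m}{D},
\quad \tau = \eta\dot\gamma, \quad Re = \frac{u_m D}{\nu},$$

with $y$ measured from the capillary axis (so $u(0) = u_{max} = 2u_m$
and $u(\pm D/2) = 0$), laminar for $Re < 2300$. At 4 ml/min these
formulas reproduce the bench reference velocities for 1 / 0.5 /
0.25 mm capillaries to the printed precision, and numeric quadrature
of the profile over the cross-section recovers $Q$ to well under
0.1%. Default fluid properties describe a dilute aqueous broth at
~35 °C (η = 0.72 mPa·s, ρ = 993 kg/m³), configurable. Absolute
wall-shear-stress values depend on the measured viscosity of the
actual medium, which is configuration, not physics; the package
therefore validates τ through its $D^{-3}$ scaling at fixed flow rate
rather than against any absolute reference.

```{r shear-example}
capillary_report(capillary_spec_bench(diameter_mm = 0.5,
                                      flow_ml_min = 4))
```

## Sample preparation

Imaging works best at OD600 = 1.15 (sparser samples waste statistics,
denser ones trip the crowding flag). `plan_dilution()` assumes OD is
linear in concentration in this regime — standard in the dilute range,
and the executed dilution is verified *gravimetrically* rather than by
photometric re-check: `verify_dilution()` compares the balance reading
with `sample_mass × factor` at a default symmetric tolerance of 2%
(routine balance plus pipetting accuracy; no tolerance is prescribed
by the method itself). A sample already below target is flagged, not
"concentrated". Densities of sample and diluent default to
1.000 g/ml, configurable.

## Numerical and testing choices

* All randomness is seeded; scenes are bit-reproducible and the
  pipeline is deterministic for fixed inputs and configuration.
* Assignment optimality is verified against brute-force permutation
  enumeration on matrices up to 6×6; inadmissible entries are encoded
  as a large finite penalty so the solver maximizes the number of
  admissible matches first, then minimizes cost.
* Validation problem sizes: 10 seeds per noise condition for velocity
  recovery on 1024×768 scenes of 5 cells; recovered per-scene mean
  speeds fall within 5% (clean) and 10% (noise sd 5) of ground truth,
  typically within 0.2%.
* Ties in the crossing test are avoided by construction (arrival
  offset of a few frames); simultaneous centroid coincidence merges
  the two blobs into one detection for more than `max_gap` frames and
  legitimately splits one track — a documented boundary of the
  default configuration, not a defect of the assignment.
* The `length >= width` convention is enforced by swapping extents
  (and rotating the reported orientation by 90°) when the moment axis
  and the extent ordering disagree on near-isotropic blobs.
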
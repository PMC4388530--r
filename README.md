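# bactrack

Single-cell motility tracking for flagellated bacteria in microscopy
frame series — with a synthetic scene generator, capillary
shear-stress calculations and dilution planning.

## What it is for

Swimming costs a bacterium a lot of energy, so single-cell swimming
speed is a sensitive, near-real-time proxy for culture viability: it
drops during a diauxic shift, recovers while the secondary carbon
source is consumed, and collapses when sporulation starts. `bactrack`
is aimed at fermentation monitoring and motility assays where a camera
on a phase-contrast microscope records short frame series (canonically
30 frames at 30 fps, 1280 × 960 px, 94.2 nm/px — a 120.6 × 90.4 µm
field of view) and the question is: *how fast are the cells moving
right now?* Because the method only ever sees what moves, it works in
turbid production media where bulk optical techniques fail.

## The method

For an *N*-frame series *A₁ … A_N*, each frame gets a **sum-difference
image**

> B_k = Σ_{j≠k} |A_k − A_j| (component-wise),

which cancels static content exactly and concentrates contrast at the
current position of every moving object. After subtracting twice the
global mean and normalizing to 0–255, bright 8-connected components
are measured for seven characteristics (centre of mass x/y, perimeter,
area, orientation, length, width). Consecutive frames are linked by
**optimal linear assignment** on the error matrix of weighted L1
feature differences,

> e_ij = Σ_c w_c |f_c(i) − f_c(j)|,

with a displacement gate, gap closing across single-frame dropouts,
and removal of short spurious tracks. Each step of a track yields one
velocity vector `v = ‖Δx‖ · pixel_size · fps`; a sample is summarized
as mean ± SEM over all vectors and compared across process stages with
the two-sided Mann–Whitney U test (velocity distributions are
routinely non-normal, which the bundled Shapiro–Wilk,
Anderson–Darling and Cramér–von Mises tests verify). A sample whose
mean detected count exceeds 15 particles per frame is flagged
`too_crowded` — tracking accuracy degrades beyond that density, and
the sample-preparation module computes the dilution (to OD600 1.15,
verified gravimetrically) that avoids it.

A Hagen–Poiseuille module (u_m = 4Q/πD², u_max = 2u_m, γ̇ = 8u_m/D,
τ = ηγ̇, Re = u_m·D/ν) bounds the shear stress a sample experiences in
the capillaries of the sampling line, certifying that sampling does
not tear off flagella.

## Worked example

No microscope needed — the scene generator renders moving ellipses
with known kinematics and hands you the ground truth:

```r
library(bactrack)

spec  <- random_scene_spec(n_bacteria = 5, speed_range = c(40, 60),
                           seed = 1)
scene <- render_scene(spec)
result <- run_pipeline(scene$frames)
#> loaded 30 frames (1024 x 768 px)
#> detected 150 particles (mean 5.0 per frame)
#> built 5 tracks (0 gap frames closed)
#> 145 velocity vectors, mean 53.23 um/s [ok]

result
#> <sample_result> mean 53.23 um/s (SEM 0.32), n = 145 vectors,
#>                 5.0 bacteria/image [ok]
round(c(truth = mean(scene$truth$speed_um_s),
        recovered = result$mean_velocity), 3)
#>     truth recovered
#>    53.230    53.228
```

All five cells were found, tracked through all 30 frames (5 tracks ×
29 steps = 145 vectors), and the recovered mean speed agrees with the
generator's ground truth to 0.002 µm/s. The capillary report for the
0.5 mm sampling line at 4 ml/min:

```r
capillary_report(capillary_spec_bench(diameter_mm = 0.5,
                                      flow_ml_min = 4))
#> <flow_field>
#>   u_m    0.3395 m/s (339.5 mm/s)
#>   u_max  0.6791 m/s (679.1 mm/s)
#>   wall shear rate   5432 1/s
#>   wall shear stress 3.911 Pa
#>   Re 234.1 (laminar)
```

A command-line front end wrapping the same functions lives in
`inst/cli/bactrack.R` (`scene generate`, `track run`, `stats compare`,
`shear report`, `prep plan`).

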
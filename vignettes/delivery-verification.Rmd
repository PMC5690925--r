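---
title: "Automated daily delivery verification: model, tolerances and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated daily delivery verification: model, tolerances and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobaltQA)
```

## The verification problem

A step-and-shoot IMRT machine with three cobalt-60 heads (120° apart, one
30-pair MLC per head) records, at the end of every fraction, a delivery log
with the as-delivered gantry angles, MLC leaf positions, per-segment
beam-on times and the day's source strength and dose rate. The approved
plan overview holds the same quantities as intended. `cobaltQA` compares
the two, item by item, and renders one daily report.

The comparison is organized in the order a reviewer would follow: patient
and plan identity, prescription, cobalt-60 source block, plan-level beam
count, then per beam (gantry, segment count, total beam-on time, fluence
map) and per segment (leaf positions, beam-on time). Identity and
prescription items compare exactly; physical quantities compare within
tolerances; a check **fails** only when its deviation is *strictly greater*
than the tolerance, matching the "error greater than tolerance" convention
used in commissioning practice. `warn` is reserved for non-safety findings:
a fraction number beyond the prescribed count, a missing screen capture, or
a degenerate (all-closed) fluence denominator.

## Source decay and the two time scales

Planned beam-on times are defined at the nominal planning dose rate of
1.85 Gy/min per head (the rate at new-source installation). The machine
delivers at the day's decayed rate, so for head dose rate $r_d$ the log
records $t_{\mathrm{delivered}} = t_{\mathrm{planned}} \cdot r_0 / r_d$
with $r_0$ the nominal rate. Each of the three sources decays
independently from its own calibration:

$$ r_d = r_{\mathrm{cal}} \cdot 2^{-\Delta t / T_{1/2}},
   \qquad T_{1/2} = 5.2711\ \mathrm{y}. $$

All plan-vs-log time comparisons are made **on the nominal scale**: the
log's times are multiplied by $r_d / r_0$ first. The alternative
(comparing on the delivered scale) would be equivalent for correct logs,
but normalizing makes a historically important failure mode visible: a log
that reports times *before* the decay correction produces, after
normalization, a time discrepancy equal to the full decay deficit, failing
both the beam-on-time check and the fluence comparison. The decayed
source strength and dose rate in the log are themselves recomputed from
the configuration's reference calibration and compared within a relative
tolerance of $10^{-3}$ (our choice, configurable; the decay law moves the
rate by about $3.6\times10^{-4}$ per day, so this tolerance flags stale
source data older than roughly three days while ignoring rounding).

The half-life is a physical constant, not a fit parameter, but it is
stored in the XML configuration rather than hard-coded so that the value
the checker used is auditable in every clinic's config file.

## The fluence model

For one beam with $N$ segments, segment beam-on times $t_k$ (seconds) and
aperture maps $A_k(x,y)$ on the isocenter plane,

$$ F(x, y) = \sum_{k=1}^{N} t_k\, A_k(x, y), $$

in units of seconds of open beam time. $A_k$ is rasterized from the 30
leaf-pair positions with **area weighting**: each pixel's value is the
fraction of its area inside the open aperture, so pixels straddling a leaf
tip or a leaf-row boundary get fractional coverage. Compared with binary
center-in-aperture rasterization this makes the map integral equal the
analytic open area (the test suite holds this to $10^{-3}$ relative, and
observes $\sim 10^{-14}$), and makes the pass rate insensitive to how the
grid happens to align with leaf edges.

Geometry conventions: $x$ is the leaf-travel direction, $y$ the stacking
direction, pair 1 at the most negative $y$; positions are cm projected to
the isocenter plane. The grid defaults to 1 mm spacing over
31.5 cm × 31.5 cm, covering the 30 × 1.05 cm leaf stack. The projected
leaf width (1.05 cm) and the grid are configurable; 1 mm comfortably
resolves the 2 mm MLC tolerance, and coarser grids (we use 0.5 cm in
fast-running tests) are fine for gross-error detection but smear
sub-pixel leaf wobble over wide edge pixels, which distorts pass rates
near the boundary — noise-sensitivity tests therefore run on the 1 mm
grid.

The delivered map is composed from decay-normalized segment times, so
source decay alone never produces a fluence difference.

### Pass-rate criterion

Pixels with planned intensity strictly greater than 10% of the planned
map's maximum are evaluated; an evaluated pixel passes when
$|F_{\mathrm{delivered}} - F_{\mathrm{plan}}|$ is strictly less than 2% of
that maximum; the beam is acceptable when at least 90% of evaluated pixels
pass. Both strict inequalities follow the criterion as printed; the
absolute value is our reading (the sign convention is not stated in the
source criterion). The mean, maximum (absolute) and SD of the difference
are reported over the evaluated set. An all-closed plan beam has no
evaluated pixels; its pass rate is undefined and reported as a warning,
not a failure.

```{r fluence-example}
g  <- grid_spec(spacing = 0.5)
ap <- lapply(1:30, function(i) leaf_pair(i, -5, 5))
fm <- compose_fluence(list(segment(1, 3, ap), segment(2, 7, ap)), g)
shifted <- fluence_map(fm$values + 0.03 * max(fm$values), g)
fluence_compare(fm, shifted)   # a uniform 3% offset fails every pixel
```

## What the synthetic generator emulates

`generate_plan()` produces random valid plans: beam groups whose 1–3 beams
sit on distinct heads at gantry angles 120° apart; per segment, a
contiguous open span of 6–20 leaf pairs shaped as a rectangle or a
staircase, 2–10 cm wide, centred within ±3 cm; closed pairs parked at the
aperture's central junction; beam-on times uniform in [1, 60] s at the
nominal rate. These defaults are the study conditions of the whole test
suite. `simulate_delivery()` decays the sources to the treatment day,
scales every time by $r_0/r_d$, optionally adds Gaussian machine noise,
and rounds to the log resolution (ms for times, 0.1 mm for positions) as
a real machine log would.

`inject_error()` applies exactly one modification per error specification;
the catalogue covers gantry offsets, single-leaf offsets, segment-time
offsets, beam-weighting scale factors, skipped beams and segments, wrong
patient, wrong plan version, decay-uncorrected log times, interruptions,
stale source-decay data, and closed-pair junction walks. Two notes:

* `interruption_split` models treatment interruption with the fraction of
  the segment actually delivered as its magnitude. Magnitude 1 means
  interrupted and fully resumed — the recorded partials sum to the planned
  time and verification passes, the behaviour a correct machine shows.
  Magnitude < 1 truncates the recorded time and fails the time check.
* A 1% beam-weighting change exceeds the 0.2 s time tolerance only for
  beams with more than 20 s of total beam-on time; sensitivity tests for
  that scenario use segment times in [20, 60] s so the fault is above
  tolerance by construction.

What the generator does **not** emulate: patient anatomy or dose,
MR imaging and registration, leaf-motion dynamics between segments
(apertures are static per segment), head-specific output factors beyond
the decayed dose rate, and correlated or drifting machine errors (noise is
iid Gaussian). Passing tests therefore demonstrate that the *comparison
engine* applies its criteria correctly, not that real machine logs are
parsed (the file dialect here is the package's own, versioned and
human-diffable) nor that clinical error rates are representative.

## Numerical choices

* **Tolerance semantics.** Deviation equal to the tolerance passes; the
  boundary is located by bisection in the acceptance suite and lands on
  0.5° / 2 mm / 0.2 s within bisection resolution.
* **Gantry angles** are stored in [0°, 360°) and compared on the circle
  (min of $|a-b|$ and $360-|a-b|$), so 359.9° vs 0.1° is a 0.2°
  deviation, not 359.8°.
* **File dialect resolution**: times 3 decimals (ms), positions 2
  (0.1 mm), angles 3, rates 6. All below the corresponding tolerances;
  generator and simulator round to the same resolution, which makes
  write→parse an exact identity (tested on 100 random pairs).
* **Beam matching** between plan and log is by beam id, falling back to
  (head, gantry within tolerance); unmatched beams on either side fail.
  The join key is not part of the log semantics, so the fallback keeps a
  renamed-but-identical delivery verifiable while still failing genuinely
  missing beams.
* **Time tolerance** (0.2 s) applies both per segment and to the per-beam
  total, since both are checked categories.
* **Degenerate inputs**: empty segment lists and mismatched grids are
  errors; an all-closed planned beam warns on fluence rather than failing.
* **Test problem sizes.** Unit and property tests run 1–2 beam groups with
  1–3 beams × 1–3 segments, a 0.5 cm grid for pipeline tests and the 1 mm
  default grid for rasterization accuracy and noise tests; the acceptance
  suite uses 100 random apertures for conservation, 100 file pairs for
  round-trip, 50 seeds for clean-run completeness and a 0.01 mm
  supersampling oracle on sampled pixels. These sizes are the package's
  own choice of a thorough-but-quick regression suite.

## Known limitations

* The parser reads this package's documented dialect, not any vendor's
  proprietary export or DICOM-RT; adapting to a real format means writing
  a new reader producing the same in-memory types.
* The fluence criterion is intensity-difference only — no
  distance-to-agreement or gamma analysis — exactly as specified for this
  class of daily check; it is a delivery-parameter check, not dose QA.
* Screen captures are embedded in the report but never analyzed.
* Couch and collimator parameters are not modelled (not present in this
  machine's check list).
* PDF export requires an external HTML-to-PDF engine at run time; the
  HTML report is always produced and is self-contained.
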
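---
title: "Quantifying fenestrations and substrate mechanics from force-volume AFM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fenestrations and substrate mechanics from force-volume AFM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenestra)
```

## The measurement problem

Liver sinusoidal endothelial cells (LSECs) are perforated by fenestrations:
patent transcellular pores of roughly 50-350 nm diameter, gathered in sieve
plates in the thin peripheral cytoplasm. Two numbers summarize their state.
*Porosity* is the number of fenestrations per square micrometre of projected
cell area (fen./µm²); it collapses in fibrosis and inflammation
("defenestration") and can recover on soft substrates. *Deformability* is
the ratio of a fenestration's apparent diameter imaged at a high load force
(300 pN) to its diameter at a low load force (170 pN), expressed as a fold
change or percent enlargement; it reflects how compliant the pore rim is
under the pressures exerted by flowing blood.

Quantitative-imaging (QI) AFM records a complete force-distance curve at
every pixel. That one scan therefore supports three distinct analyses:

1. **Contact mechanics.** Each curve can be fitted with a Hertz-Sneddon
   model to yield the local apparent Young's modulus.
2. **Load-resolved topography.** The surface can be reconstructed at any
   load force below the imaging setpoint, because the piezo position at
   which each curve crosses a target force is known per pixel.
3. **Morphometry.** Pores detected in reconstructions at two different
   loads, matched one-to-one, give the deformability statistic; pores in a
   single reconstruction give porosity.

The same package analyzes the mechanical characterization of the hydrogel
substrates used to mimic the perisinusoidal niche: Hertz-Sneddon
spectroscopy on the AFM side, and amplitude-sweep rheology (linear
viscoelastic range, storage-modulus averaging, shear-to-Young conversion,
loss factor) on the bulk side, plus the bookkeeping of a per-cell
endocytosis assay.

Because raw instrument data of this kind are rarely deposited, the package
ships a synthetic-data module that generates force-volume phantoms with
known ground truth. Every downstream claim the package makes is validated
as *parameter recovery* on those phantoms.

## Contact models and fitting

For a spherical (hemispherical-probe) tip of radius $R$ the force at
indentation $\delta$ is

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

and for a four-sided pyramidal tip of face half-angle $\theta$

$$F = 0.7453\,\frac{E}{1-\nu^2}\,\tan\theta\,\delta^{2}.$$

The pyramid prefactor 0.7453 is the standard four-sided-pyramid constant;
it is recorded in every fit result and is configurable in source. Poisson's
ratio defaults to $\nu = 0.5$ (incompressible), the conventional choice for
cells and hydrated gels; the same assumption makes the rheological
conversion $E = 2G'(1+\nu)$ reduce exactly to $E = 3G'$.

Indentation is computed from the piezo position and the cantilever
deflection, $\delta = (z - z_c) - F/k$, so the spring constant $k$ (a
calibration input, consumed as metadata) links the two length scales. The
closed-form inverse of the sphere model,
$\delta = [3F(1-\nu^2)/(4E\sqrt{R})]^{2/3}$, is exposed directly
(`invert_indentation()`): at $F = 100$ pN on a 0.8 kPa gel with a 20 nm tip
it gives $\approx 0.63$ µm, which is why nanometre-scale features of very
soft gels cannot be resolved at such loads - the imaged surface is already
deeply indented.

**Contact point.** Two estimators are implemented. The *threshold* detector
finds the first crossing of $n_\sigma \times$ (baseline noise SD) that
persists for $m$ consecutive samples (defaults $n_\sigma = 3$, $m = 5$) and
then back-extrapolates the linearized contact regime ($F^{2/3}$ for a
sphere) to zero force. The extrapolation step matters: a raw threshold
crossing is systematically late by the indentation at the threshold force,
which is of order 100 nm on kPa-soft material and would bias the fitted
modulus upward by tens of percent. The *residual-search* estimator is a
brute-force grid over candidate contact points, refitting the model at each
and minimizing the residual; it is slower and serves as the independent
reference. On noisy phantom curves the two agree to well under two sample
spacings (median).

**Modulus fit.** For a fixed contact point the modulus enters the model
linearly, so the least-squares estimate is closed-form. By default the fit
also refines the contact point by a local residual search around the
threshold estimate. The fit window is expressed in indentation (the package
default for phantom work is 50-900 nm; deeper windows in the
1000-1500 nm range are appropriate for cell measurements with sharp tips,
and 900-1000 nm for soft gels with large spherical probes). On the default
64x64 phantom at 20 pN force noise, the per-map median fitted modulus lands
within a fraction of a percent of truth; the 5 % acceptance margin is
generous.

## Topography reconstruction

`reconstruct_height_at_force()` finds, per pixel, the first crossing of the
target force that persists for two consecutive samples, interpolates the
piezo position linearly between the bracketing samples, and reports the
deflection-corrected tip position $-(z_{\times} - F/k)$. Subtracting the
deflection makes rigid and compliant pixels directly comparable and makes
the monotonicity property exact: at any pixel, the reported height is
non-increasing in the load force, because a higher load can only indent
deeper. The two-sample persistence rule suppresses noise-induced early
crossings. Pixels whose curve never reaches the target force are marked
invalid, and a map more than half invalid triggers a warning rather than an
error.

## The phantom and its rim model

The phantom is an elliptical cell body of height $h_c$ (default 300 nm) on
a flat substrate, with a parabolic nuclear bulge and sieve plates of pores
placed by rejection sampling (no overlaps) in the peripheral cytoplasm.
Each pixel gets a genuinely Hertzian approach curve: force zero before
contact, and after contact the force solving the balance
$\delta + F(\delta)/k = z - z_c$, plus additive Gaussian force noise
(default SD 20 pN, the tens-of-pN regime of a soft cantilever at moderate
bandwidth). Pore diameters are drawn from a normal distribution truncated
to the physiological 50-350 nm range.

**Why pores appear to grow with load.** The substrate (default 52 kPa) is
stiffer than the cell body (default 6 kPa), so at higher load the cell
surface is indented more than the pore floor. Around each pore we place an
annular rim over which the contact height climbs from the substrate back to
the cell surface following a power profile

$$h(r) = h_c \left(\frac{r - r_0}{w}\right)^{p}, \qquad r_0 \le r \le r_0 + w,$$

with rim width $w = c\,r_0$ set by the dimensionless `rim_compliance` $c$
and profile exponent $p$ (default 0.2). In a reconstruction at load $F$ the
apparent surface is $h(r) - \delta(E(r), F)$, and the half-depth crossing
sits at

$$r(F) = r_0\left[1 + c\,u(F)^{1/p}\right], \qquad
u(F) = \tfrac{1}{2}\left(1 + \frac{\delta_{cell}(F) - \delta_{sub}(F)}{h_c}\right)$$

(clamped to $[0,1]$). This is the generator's closed-form ground truth: the
apparent diameter $2r(F)$ is non-decreasing in load whenever the substrate
is stiffer than the cell, grows strictly with $c$, and the fold change
between two loads is independent of pore size. A purely *linear* rim
($p = 1$) cannot reach the 40 % enlargement regime observed on soft
substrates: because both indentation depths scale as $F^{2/3}$, the
half-depth crossing under a linear ramp is bounded by
$(0.5 + g_{high})/(0.5 + g_{low})$ with $g \propto F^{2/3}$, which stays
below about 1.25 for any physically sensible geometry. The convex profile
($p < 1$) concentrates the rim's height gain near its outer edge, giving
the crossing the dynamic range that the measured regime requires. The
mechanical origin of fenestration deformability (membrane bending versus
rim elasticity) is not settled; the rim model is a generative stand-in with
the right phenomenology, not a mechanistic claim.
`rim_compliance_for_enlargement()` inverts the closed form, so a phantom
can be programmed to any attainable target enlargement.

What the phantom deliberately does *not* emulate: retract curves and
adhesion, viscoelastic creep, lateral/thermal drift, finite-thickness
(bottom-effect) contact, and scanner nonlinearity. Passing recovery tests
on phantoms therefore demonstrates the correctness of the analysis chain
under the stated noise model - not robustness to every artifact of real
instruments.

## Morphometry choices

**Flattening.** Scan-line flattening must not destroy the cell-substrate
step. `flatten_map()` first identifies the dominant background height
cluster of the whole map (2-means on heights clipped at the 75th
percentile, so a tall nucleus cannot capture a cluster), fits each line's
polynomial only to pixels near that level with iterative residual clipping,
and interpolates coefficients across lines that contain no background
pixels. The substrate (lower-cluster) median is then referenced to zero.

**Segmentation.** The cell mask is the largest connected component above a
height threshold (automatic default: midpoint of the two height clusters),
with holes filled - pores count toward projected cell area. The nuclear
bulge is the high contiguous region above a bulge threshold, morphologically
closed; pores whose centroid falls inside it are "fenestrae labyrinths",
counted separately and excluded from porosity, since they cannot be
transcellular.

**Pore detection and the diameter criterion.** Pore pixels are those deeper
than a threshold below the local cell surface (default: half the apparent
membrane height, a relative criterion that transfers across phantoms and
loads). Components are found on a lightly smoothed map (physical smoothing
length 25 nm - half the smallest fenestration - converted to pixels), but
the diameter is measured on the *raw* map, along the fast scan axis through
the centroid with sub-pixel interpolation, so smoothing cannot inflate it.
The measurement level is configurable (`half_depth`, the default, measures
halfway between cell surface and substrate; `fixed_depth` and `full_width`
are alternatives) and is recorded in the output attributes of every run,
because a manually measured reference diameter depends on exactly this
unstated choice. The measurement error scale is the pixel size (20-27 nm
at deformability imaging resolution), and single-pore sweep tests hold the
error under one pixel across the whole 50-350 nm range.

**Matching and deformability.** Pores from the low- and high-force
reconstructions are matched greedily by centroid distance, closest pairs
first (order-independent), capped at 3 pixels. The deformability summary is
the mean and SD of per-pair fold changes, with percent enlargement
$(\bar{f} - 1) \times 100$. Porosity excludes nuclear-region pores and
divides by the filled-mask cell area; whether the reference area should
include or exclude the pores themselves is ambiguous in manual practice -
the filled mask (including) is the default here and is what the recovery
tests calibrate against.

## Rheology

The linear viscoelastic range (LVER) of an amplitude sweep is determined
from the storage modulus: the plateau level is estimated robustly (median
of the leading quarter of points, refined by averaging all points within
the deviation band), and the LVER extends to the last strain at which $G'$
stays within 10 % (configurable) of that plateau. A sweep whose leading
window is not plateau-like raises a "no LVER" error. Whether the original
plateau fit should be a constant or a sloped line is ambiguous; the
constant fit is the default and the relative slope per decade of strain is
reported alongside so a non-flat "plateau" is visible. Averaged $G'$ over
the LVER converts to Young's modulus as $E = 2G'(1+\nu) = 3G'$ at
$\nu = 0.5$ - an exact identity in this package, tested to machine
precision. The loss factor is the mean pointwise $G''/G'$ over the LVER;
values well below 1 (0.08-0.11 for polyacrylamide-type gels) indicate
solid-like behaviour. Replicate sweeps are summarized as mean ± SD across
sweep-level results, not pooled points.

## Statistics

Group comparisons use the unpaired equal-variance Student t-test (Welch
behind a flag), annotated with the conventional stars (* p < 0.05,
** p < 0.01, *** p < 0.001). Box-chart summaries report mean, SD and the
5th/95th percentiles using linear interpolation between order statistics
(type 7); the convention is stated in every report because percentile
conventions differ across software. Type-I calibration of the test is part
of the acceptance suite (rejection rate within binomial error of the
nominal level over 1000 null simulations). The unit of replication (cells
versus animals versus maps) is the caller's declaration: the pipeline
reports per-map quantities and leaves aggregation explicit.

## Problem sizes and numerical choices

Simulation sizes used by the test and acceptance suites were chosen as the
smallest that exercise every code path at realistic geometry: modulus
recovery on the default 64x64-pixel phantom at 100 nm pixels; porosity on
96x96-pixel phantoms at 83 nm pixels (four maps per regime, control-like
~1.5 fen./µm² and defenestrated ~0.35 fen./µm²); deformability on
128x128-pixel sieve-plate phantoms at 27 nm pixels pooled over five seeds
(~45 matched pairs); rheology over 100 simulated sweeps. Newton iteration
solves the per-pixel force balance (12 vectorized iterations, monotone
convergence); reconstruction crossings are linearly interpolated;
degenerate inputs (empty strain grids, empty masks, all-invalid maps,
zero cell counts, infeasible nuclei placement) raise errors naming the
offending field, and borderline ones (blank images, >50 % invalid maps,
sub-noise thresholds) warn and proceed.

## Known limitations

* The apparent modulus is uncorrected for finite sample thickness or
  viscoelasticity; on thin peripheral cytoplasm over stiff substrate the
  half-space Hertz model exaggerates indentation, which is also why
  phantom membrane contrast shrinks at 300 pN.
* Connected-component nuclei counting merges touching nuclei (documented
  behaviour of the simple threshold method; no watershed splitting).
* The rim model is phenomenological; recovered "rim compliance" should not
  be interpreted as a material constant.
* Porosity recovery degrades when pore cores approach the pixel size;
  sub-pixel pores are invisible by construction, so porosity at coarse
  pixel sizes is a lower bound.
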
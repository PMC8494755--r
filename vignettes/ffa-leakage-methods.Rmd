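---
title: "Quantifying retinal blood leakage in FFA sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal blood leakage in FFA sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fundus fluorescein angiography (FFA) records the retina after an
intravenous fluorescein injection: blood vessels fill with dye and appear
bright, and wherever the vasculature is abnormal, dye escapes and forms
diffuse, amorphous bright regions — leakage. In preclinical models of
pathological angiogenesis (e.g. *Vldlr*-deficient mice), the intensity and
area of leakage over a series of timepoints are the primary readouts for
disease severity and drug response. Quantifying them by hand is slow and
observer-dependent; `ffaleak` automates the chain from raw frames to
leakage time series.

The pipeline has four stages:

1. **Vessel removal** — build a vessel-free leakage image `I_l` per frame.
2. **Vessel segmentation** — a binary vessel map for reference-point
   detection (and as a product in its own right).
3. **Registration** — align every frame to the first timepoint with a
   rigid transform, initialized at a vessel-convergence reference point.
4. **Quantification** — leakage intensity and area time series over the
   shared field of view.

## Separating leakage from vessels

Vessels are bright *tubular* structures; leakage is bright but *isotropic*
at the scale of a vessel diameter. Grayscale opening with a flat line
structuring element removes bright structures narrower than the element
while leaving broad smooth regions almost unchanged.

**Small vessels.** For orientations `theta_i = (i-1) pi/8`, `i = 1..8`, the
frame is opened with a digital line of length `l_sv` at each orientation
and the pixelwise minimum is kept. At a pixel on a thin vessel the
minimizing orientation is perpendicular to the vessel, so the vessel is
replaced by the background minimum along a line crossing it. `l_sv` must
be slightly larger than the *effective* width of the thickest vessel this
step should erase; note that a vessel rendered (or imaged) with a Gaussian
cross-section is roughly 1.8x wider at its base than its nominal
full-width-at-half-maximum diameter.

**Large vessels.** The residue `Delta I_theta = open(line(l_lv, theta)) -
open(line(l_lv, theta + pi/2))` is large on a vessel aligned with `theta`
(the parallel opening preserves the ridge, the perpendicular one removes
it) and near zero on isotropic structure, where both openings agree. The
maximum of the residues over the eight orientations is therefore a
large-vessel image with leakage suppressed; because the orientation set is
closed under perpendicularity, it is nonnegative everywhere. The residue
image is then regularized by the quadrature vesselness map (below) and
thresholded with hysteresis; the resulting vessel mask is removed from the
small-vessel-removed image by infilling each masked pixel with the
grayscale opening of that image under a disc of diameter `l_lv`. The
opening is anti-extensive, so infilled values never exceed the surrounding
leakage level; zeroing the pixels instead would bias the mean-intensity
readout that is the endpoint of the pipeline. The result is the final
leakage image `I_l`.

Numerical details: all openings reflect-pad the frame by twice the kernel
half-width (so the dilation half of the opening only consumes erosion
values computed from full windows), and run on values scaled by a power of
two into [0, 1] — a transformation that is exact in binary floating point,
so results are identical to operating on raw values.

## Log-Gabor quadrature vesselness

The vessel-likeness map is built from a bank of log-Gabor quadrature
filters: for scale index `s`, the center frequency is `w0 = 2^-s` cycles
per pixel; the radial profile `exp(-ln^2(f/w0) / (2 ln^2 k))` has a
2-octave bandwidth (|ln k| = B ln2 / (2 sqrt(2 ln 2))) and is exactly zero
at zero frequency, so the filters have no DC response and the map is
invariant to constant offsets. Eight orientations cover 180 degrees; the
angular window is a Gaussian in angle with standard deviation
`(pi/8)/1.2`, one-sided in direction so each spatial filter is a complex
quadrature pair. With that spread, the summed squared magnitudes (counting
each filter's implicit antipodal coverage of Hermitian spectra) are
angle-independent to within a few percent at every passband radius.

Per scale, the eight complex orientation responses are summed; the scales
are combined as the `|q|^3`-weighted mean `P = sum q_n |q_n|^3 / sum
|q_n|^3` (defined as 0 where all responses vanish), and the vesselness is
the regularized real part `LP = Re(P |P| / (|P|^2 + sigma^2))`. `sigma`
(default 3) suppresses noise-driven responses; any value above about 1
gives nearly identical maps, which the test suite checks. `|LP| < 1`
always holds for `sigma >= 1`.

**Choosing the number of scales.** `w0 = 2^-s` means scale `s` resonates
with structure of wavelength `2^s` pixels. Two scales (the function
default) suit thin vasculature a few pixels wide. The synthetic phantoms
used by the tests render vessels up to 8 px nominal (about 15 px
effective) diameter at 256 px frame size, one octave below the two-scale
band, so all phantom-based tests and the acceptance script run with three
scales. This is a property of the data scale, not of the method.

## Vessel segmentation

The full vesselness map is segmented with a two-phase piecewise-constant
active-contour (Chan-Vese) energy: squared deviation from the two phase
means plus `mu` per 4-neighbor pair of discordant labels (a discrete
boundary length). The energy, not the solver, defines the output, and the
package minimizes it by exact coordinate descent: phase means and
checkerboard label sweeps alternate, each step provably non-increasing, so
the energy trace is monotone and the result deterministic for a fixed
initialization (the seed-free hysteresis mask by default). `mu` defaults
to `0.1 * range^2`, which keeps the data/boundary balance invariant to
affine intensity rescaling. Constant inputs are rejected as degenerate;
the higher-mean phase is returned as foreground.

Hysteresis thresholds are expressed as quantiles of the within-ROI
vesselness values so they transfer across exposure levels. The defaults
are q90/q98: the low threshold must sit in the gap between the background
and vessel modes of the vesselness histogram, and with vasculature
covering well under 30% of the field of view a q70 threshold would sit
inside the background mode and produce oversized masks. Because the mask
is at most `1 - q_low` of the field by construction, what is stable under
threshold perturbations is the segmentation *accuracy* (thick vessels
covered, thin and off-orientation structure excluded), not the raw mask
area; the tests assert exactly that.

## Reference-point detection

Registration needs a landmark that is stable across timepoints while
leakage grows around it. The vessel convergence point (the optic disk) is
found by line voting on the vessel skeleton:

1. the hysteresis vessel mask is conditioned (5 px disc closing, specks
   smaller than the pruning scale dropped) — noise pits otherwise turn
   into spurious skeleton loops — and thinned to an 8-connected,
   topology-preserving medial axis (Zhang-Suen);
2. the skeleton becomes a graph: pixels with one neighbor are
   terminations, pixels with three or more are bifurcations (mutually
   adjacent bifurcation pixels merge into one node; a node-free loop
   becomes a single cyclic edge), and each edge stores its ordered
   medial-axis pixel chain;
3. terminal branches shorter than `T_b` are deleted iteratively — removal
   can expose new short branches — with re-thinning between passes so
   leftover junction pixels cannot masquerade as bifurcations;
4. for every chain pixel, a total-least-squares line is fitted to the
   chain points within radius `L_0` (total least squares so vertical
   vessels pose no problem), and the full line is rasterized into an
   accumulator, one vote per covered pixel;
5. the maximum of the Gaussian-smoothed accumulator is the reference
   point. The lines fitted along one vessel cross the disk in a fan a few
   pixels wide, so the smoothing width (default 4 px) should match that
   fan; ties break by scan order.

Defaults `T_b = 20`, `L_0 = 30` suit 512 px frames and scale linearly
with frame width (the 256 px phantom tests use 10 and 15).

## Rigid registration

Eye motion between timepoints is modeled as rotation plus translation.
Frames register to the first timepoint (least leakage, least saturation).
The similarity metric is normalized cross-correlation over the fixed
field of view — insensitive to the global intensity changes that growing
fluorescein causes — maximized by regular-step gradient ascent
(central-difference gradients, parameter scales of 1 px translation per
0.01 rad rotation, only improving steps accepted, deterministic) over a
2-level multiresolution pyramid. The optimization is initialized by the
translation that matches the two frames' reference points, with the
rotation center at the fixed frame's reference point so angle and
translation gradients decouple near the structure of interest; if either
reference point is unavailable the initialization falls back to the
identity about the ROI centroid, and a frame whose registration fails is
excluded with a warning.

Quantification proceeds on the intersection of all registered fields of
view, so every timepoint's statistics cover the same retinal area. The
leakage images are extracted from the *native* (unresampled) frames and
then warped with the recovered transforms: the fixed frame is never
resampled, so extracting leakage after warping would give the first frame
different noise statistics under the openings than every other frame.

## Quantification

Three readouts per timepoint, all over the shared analysis ROI:

- **relative fluorescein intensity** `r_t`: mean of `I_l` minus the first
  frame's mean (so `r_1 = 0` exactly) — relative values because the map
  from intensity to fluorescein concentration is unknown;
- **leakage area fraction** `a_t`: the Otsu-delineated leakage area
  divided by the ROI area;
- **in-region intensity** `s_t`: the sum of `I_l` inside the leakage mask
  divided by the ROI area. It usually tracks `r_t`; `r_t` needs no
  thresholding step and is the preferred readout.

The Otsu threshold maximizes between-class variance over a 256-bin
histogram (ties towards the lower threshold). By default it is computed
per frame, matching single-frame delineation; for time-series area
analysis the `pooled_otsu` option computes one threshold from the pooled
in-ROI values of all frames, because per-frame thresholds are not
comparable across a sequence when the first frame has weak leakage
contrast (its threshold falls below the vessel-residue level). The
phantom studies in the tests and the acceptance script use the pooled
variant.

Series are reported on the native time grid and linearly interpolated
onto an equally spaced grid (default 1 min; knots on the grid reproduce
exactly; no extrapolation), convenient for derivative estimates.

## Evaluation against annotations

`relative_difference(x, ref) = |x - ref|/ref` (note the asymmetry: the
second argument is the reference) summarizes agreement with annotation
masks; `agreement_table()` reports mean and standard deviation over
frames for each (series, reference) pair plus Pearson correlations, with
each annotator in turn serving as the reference. Intensity comparisons
use unnormalized values so the first frame does not degenerate to zero
for every series.

## The synthetic phantom

No public FFA dataset with leakage annotations exists for this model
system, so a seeded generator stands in for real data in every test:

- a dark frame with a circular bright field of view (the camera aperture,
  static across timepoints);
- a branching vessel tree: primaries radiate from a convergence point,
  daughters branch at acute offsets (0.25-0.5 rad) so the tree keeps the
  roughly radial course of retinal vasculature, centerline headings
  perturbed with sd 0.05 rad per step (gentle curvature, locally straight
  at line-fit scale); Gaussian cross-sections with half maximum at the
  nominal radius, diameters 2-8 px tapering with depth;
- leakage blobs with raised-cosine profiles, so the "true support" used
  by area-recovery tests is well defined even though real leakage has no
  sharp boundary. The amplitude series `A_t` is the programmed
  field-of-view-mean leakage contribution: the blob field is normalized
  so its in-ROI mean equals `A_t` exactly (peak brightness and support
  area then both grow over time, as dye accumulates and spreads, while
  the integrated signal is `A_t` — which is what makes `A_t` the correct
  recovery target for the intensity series). Default `A_t` linear from 1
  to 8 intensity units, support radius growing 1.15x per timepoint;
- per-timepoint rigid jitter (translation magnitude up to 25 px, rotation
  up to 8 degrees; identity at the first timepoint), additive Gaussian
  noise (sd 4), all draws fixed by one seed.

Defaults describe a 512 px eye (ROI radius 230, 6 primaries, depth 2,
timepoints 1, 3, 5, 7, 9 min). The test suite and the acceptance script
run 256 px phantoms (ROI radius 115, blob radius 20) with pipeline
parameters matched to that scale — `l_sv = 15`, `l_lv = 17`, `T_b = 10`,
`L_0 = 15`, three quadrature scales — which exercises every stage at a
fraction of the cost.

`perturb_annotation()` models inter-annotator variability: it shifts a
mask boundary in the signed-distance sense and adds a smooth seeded
perturbation to the boundary position. The annotator-agreement analogue
in the tests gives two synthetic annotators the half-maximum leakage
support with +-3 px boundary criteria and 2 px boundary noise, pools the
frames of three sequences, and checks that the method-vs-annotator mean
relative difference (averaged over the two references) stays within 1.5x
the inter-annotator difference.

**What passing these tests does and does not show.** The phantoms share
the geometry, contrast ordering and motion model of real FFA, but not its
optics: no vignetting or illumination gradients, no choroidal background
texture, no saturation, Gaussian rather than Poisson-dominated noise, and
perfectly rigid motion. Recovery on phantoms demonstrates that the
implementation is correct and the pipeline identifiable under controlled
conditions; it does not by itself validate the method on real eyes.

## Known limitations

- Rigid registration cannot absorb non-rigid deformation; strongly
  deformed sequences need a deformable extension.
- Bright non-leakage structures (artifacts, lesions) that survive vessel
  removal are counted as leakage; such data need a masking step upstream.
- Per-frame Otsu thresholds are unreliable when a frame has little
  leakage contrast; use `pooled_otsu` for cross-time area comparisons.
- The area readout of any fixed-threshold delineation grows with both
  support and amplitude; when blob amplitude rises steeply the area
  series can deviate from pure support growth by a few percent of
  correlation.
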
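# ffaleak

Quantification of retinal blood leakage in fundus fluorescein angiography
(FFA) time series.

In FFA, fluorescein-filled vessels and dye leaking from abnormal vessels
both appear bright. For preclinical retinal-angiogenesis models (such as
the *Vldlr*-deficient mouse), the intensity and area of the diffuse
leakage regions over a series of timepoints are the primary disease
readouts — but leakage is amorphous, entangled with the vasculature, and
the eye moves between acquisitions, so manual quantification is slow and
observer-dependent. `ffaleak` implements an automated pipeline:

1. **Vessel removal.** Small vessels are erased by oriented grayscale
   openings: with line structuring elements at angles
   `theta_i = (i-1) pi/8`, the vessel-free image is the pixelwise minimum
   `min_i open(I, line(l_sv, theta_i))`. Large vessels are enhanced by
   perpendicular-opening residues
   `I_v~ = max_i [ open(I, line(l_lv, theta_i)) - open(I, line(l_lv, theta_i + pi/2)) ]`,
   which suppresses isotropic leakage, then segmented (quadrature
   vesselness + hysteresis) and infilled, giving the leakage image `I_l`.
2. **Log-Gabor quadrature vesselness.** A multi-scale bank with center
   frequencies `w0 = 2^-s` cycles/px and 2-octave bandwidth; per-scale
   orientation sums `q_n`, the combined response
   `P = sum q_n |q_n|^3 / sum |q_n|^3`, and the regularized map
   `LP = Re( P|P| / (|P|^2 + sigma^2) )`.
3. **Reference point.** The vessel skeleton becomes a graph
   (bifurcations/terminations as nodes, medial-axis chains as edges);
   short branches are pruned iteratively; a total-least-squares line is
   fitted around every chain pixel and drawn into an accumulator; the
   smoothed accumulator maximum marks the vessel convergence point (the
   optic disk), a landmark stable while leakage grows.
4. **Rigid registration.** Every frame is registered to the first
   timepoint by maximizing normalized cross-correlation over the field of
   view with regular-step gradient ascent, initialized by matching
   reference points.
5. **Quantification.** Over the intersection of all registered fields of
   view: relative fluorescein intensity (mean `I_l` minus the first
   frame's mean), Otsu-delineated leakage area over ROI area, and
   in-region intensity, on the native and an equally spaced time grid.

A seeded synthetic phantom generator (`generate_sequence()`) renders
FFA-like eyes — circular field of view, branching vessel tree converging
on an optic-disk point, growing raised-cosine leakage blobs, rigid jitter,
noise — with full ground truth, and backs every test.

## Worked example

```r
library(ffaleak)

# a synthetic eye: 256 px frames, 5 timepoints, growing leakage,
# rigid jitter up to 25 px / 8 degrees, full ground truth
spec <- phantom_spec(size = 256, roi_radius = 115, blob_radius0 = 20)
ph   <- generate_sequence(spec, seed = 42)

res <- run_pipeline(ph$sequence, params = opening_params(15, 17),
                    T_b = 10, L_0 = 15, n_s = 3, pooled_otsu = TRUE)
tidy(res)
#> # A tibble: 5 × 5
#>   time_min rel_intensity area_fraction in_region_intensity otsu_T
#>      <dbl>         <dbl>         <dbl>               <dbl>  <dbl>
#> 1        1          0           0.0181                1.33   49.4
#> 2        3          1.58        0.0404                2.98   49.4
#> 3        5          3.99        0.0668                5.33   49.4
#> 4        7          7.12        0.0972                8.15   49.4
#> 5        9         10.2         0.153                12.3    49.4
```

`rel_intensity` is the mean leakage-image intensity relative to the first
timepoint (0 by construction there): leakage brightness grows steadily
with time. `area_fraction` is the fraction of the shared field of view
delineated as leakage at the sequence-wide Otsu threshold (49.4 intensity
units), growing from 1.8% to 15.3%. `in_region_intensity` sums leakage
intensity inside the delineated region per unit ROI area and tracks
`rel_intensity`, as expected when the background of the leakage image is
low.

Against this phantom's ground truth, the recovered registration maps
points to within 0.08 px and 0.01 degrees of the programmed jitter, and
the intensity and area series correlate with the programmed dynamics at
Pearson r = 0.992 and 0.995. `autoplot(res)` draws the three series;
`glance(res)` gives one-row summaries (final values, intensity slope).

Real data enter through `load_sequence("manifest.csv")` (columns `path`,
`time_min`; single-channel TIFF or PNG frames, intensities kept in native
code values). A thin command-line front end with `synth`, `leakage`,
`vessels`, `vesselness`, `refpoint`, `register` and `quantify`
subcommands is installed at `inst/scripts/ffaleak.R`.

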
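# osteem

Quantification of osteogenic matrix mineralization from 2D fluorescence
(excitation–emission) spectra of Alizarin Red S (ARS) staining — built for
cell-biology and biomaterials labs that need an *in-situ* mineralization
readout on substrates where the classical absorbance assay fails, opaque
graphene-oxide (GO) coatings in particular.

## The method

ARS chelates calcium in the mineralized extracellular matrix. On a 2D
fluorescence spectrum (excitation 400–580 nm, emission from
λ<sub>exc</sub> + 40 nm to 700 nm), mineralization changes the surface
shape: undifferentiated cells show a single broad emission band near
500 nm; the ARS–calcium complex adds a 670 nm band, and a **saddle point**
appears near 560 nm emission where the two bands meet. The package detects
and classifies this fingerprint (discrete Hessian on the smoothed, masked
surface, cross-checked against a 1-D emission-profile signature), and
quantifies mineralization with the normalized ratiometric index

> R = I(λ<sub>exc</sub> = 420, λ<sub>em</sub> = 670) / I(λ<sub>exc</sub> = 420, λ<sub>em</sub> = 560)

Because R is a ratio of two cells of the same spectrum, a scalar attenuation
— an opaque substrate dimming all fluorescence — cancels exactly; normalized
to an undifferentiated control, R gives a fold induction directly comparable
to optical-density (OD 515 nm) quantification. The package also provides the
linear concentration calibrations of both channels (OD@515 and F670 at
420 nm excitation, plus their cross-fit), the four-method comparison
(OD/fluorescence × surface/liquid) with the symmetric pairwise agreement
statistic, and a seeded synthetic spectra generator with known ground truth
(component amplitudes, substrate optics, target folds) that stands in for
the assay's raw data in every test.

## Worked example

```r
library(osteem)

# a seeded five-condition experiment (control, 7/14 d osteogenic medium on
# glass, GO alone, GO + medium), three replicates, 2 % noise
ex <- generate_experiment(noise = noise_model(seed = 42))

# shape fingerprint of a GO sample measured in situ
e <- subtract_background(ex$eems[["go_7d_r1_surface"]],
                         ex$eems[["blank_go"]])
classify_spectrum(e)
#> Shape report [go_7d_r1_surface]: mineralized_double_peak
#>   primary peak at exc 430 nm / em 660 nm (0.9844 a.u.)
#>   saddle at exc 440 nm / em 560 nm (0.5779 a.u.)

ratio_index(e)
#> I(420, 670) / I(420, 560) = 0.999 / 0.5431 = 1.839

# four quantification methods on the glass 7-day condition
quantify_four_methods(ex, "om_7d")
#> Fold induction by method:
#>   od_surface     1.97
#>   od_liquid      2.064
#>   fluor_surface  1.95
#>   fluor_liquid   2.111
#> max pairwise relative difference: 0.07921

# fluorescence calibration over the 0.00125-4 mM free-dye ladder
ser <- generate_dilution_series(noise = noise_model(seed = 42))
calibrate_fluorescence(ser)
#> Linear calibration: f670_exc420 = 0.98181 * concentration_mM + 0.00315422
#>   n = 12, R-squared = 0.999884
```

The classification says the GO sample formed mineralized matrix (the saddle
sits at 560 nm). The four folds agree within 8 % — all four methods see the
same ~2× induction — and the calibration is linear with R² ≈ 0.9999. On GO,
`od_surface` is automatically excluded as unusable (the substrate's
broadband absorbance dominates); the ratio index is unaffected because the
attenuation cancels.

A command-line pipeline wraps the same functions
(`simulate` / `analyze` / `calibrate` / `quantify` / `report`):

```sh
Rscript inst/cli/osteem simulate --seed 42 --out run1
Rscript inst/cli/osteem analyze --manifest run1 --out run1/reports
```

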
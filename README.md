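# mpdeep

Signal-to-background modelling and z-stack analysis for two- and
three-photon (2P/3P) deep fluorescence microscopy of densely fluorescent
samples — the regime of bacterial mycelium, biofilms and plant tissue,
where ~10% of the volume fluoresces and out-of-focus background, not signal
strength, sets the depth limit.

`mpdeep` is aimed at microscopists planning deep multiphoton imaging
(choosing excitation order, predicting attainable depth for a given sample
turbidity) and at analysts quantifying z-stacks (depth profiles of signal
and background, excitation-order exponents, effective attenuation lengths,
PSF radii from bead stacks). Because raw deep-imaging stacks are rarely
shareable, the package also ships a synthetic phantom generator that
renders filament scenes and bead volumes through the same optics model, so
the whole analysis chain can be exercised and validated end to end.

## The model

A beam of wavelength λ focused to a minimal 1/e² waist w₀ at z = 0 in a
medium of refractive index n and scattering length lₑ has relative
intensity

    I(x, y, z) = (w₀² / w(z)²) · exp(−2 (x² + y²) / w(z)²) · exp(z / lₑ)

with

    w(z) = w₀ √(1 + (z / (n·z_R))²),   z_R = π w₀² / λ .

z is measured from the focus, positive toward the sample surface; the
final factor is the loss of ballistic photons on the way to the focus. An
m-photon process (m = 2 or 3) generates fluorescence ∝ Iᵐ, so:

* **signal** = ∭ Iᵐ over the focal volume (|z| ≤ 5.8 µm, full lateral
  plane), boosted by 1/fill_fraction because the focus sits on a
  fluorescent structure rather than the volume-averaged medium;
* **background** = ∭ Iᵐ from 5.8 µm above the focus up to the sample
  surface, with each slab's emission attenuated over its escape path
  (absorption length L_a, default 0.5 mm).

The lateral integral has the closed form π w(z)²/(2m) per slab, so the 3D
integrals reduce to fast 1D quadratures. The signal-to-background ratio
(SBR) falls with depth, and the depth where it reaches 1:1 is the
practical imaging depth limit; `depth_at_sbr()` solves for it by
bisection.

The analysis side implements histogram-based stack metrics: the per-slice
background is the histogram mode (most abundant pixel value), the signal
is read off a histogram threshold (count or brighter-fraction strategy),
the top-slice background defines the zero-value convention, nonlinearity
exponents come from log–log least squares of signal vs. power, and
attenuation lengths from ln(power)-vs-depth schedules at constant focal
brightness.

## Worked example

```r
library(mpdeep)
library(dplyr)

beam <- beam_parameters(wavelength_um = 1.040, waist_um = 0.55)
psf_lateral_radius(beam, order = 3)   # 0.318 µm (3P)
psf_lateral_radius(beam, order = 2)   # 0.389 µm (2P)

medium <- medium_properties(scattering_length_um = 120,
                            absorption_length_um = 500,
                            fill_fraction = 1)
sbr(c(200, 400, 600, 800), beam, medium, order = 3)
#>   depth_um order   signal background  ratio
#> 1      200     3 1.36e- 3   3.26e- 6 418.
#> 2      400     3 6.15e- 6   1.55e- 8 395.
#> 3      600     3 2.78e- 8   2.02e-10 137.
#> 4      800     3 1.25e-10   3.92e-11   3.20

depth_at_sbr(1, beam, medium, order = 3)
#> [1] 853.3551
```

Three-photon contrast in a 120 µm scattering-length medium stays usable
for hundreds of micrometres and crosses 1:1 near 850 µm — around seven
attenuation lengths deep.

Synthetic power series recover the excitation order of each detection
channel:

```r
series <- generate_power_series(noise_cv = 0.05, seed = 7)
series |> group_by(channel) |> group_map(~ glance(fit_power_exponent(.x)))
#> blue:  exponent 3.05 (se 0.020)   -- three-photon
#> green: exponent 2.82 (se 0.018)   -- mixed 2P/3P
#> red:   exponent 1.95 (se 0.016)   -- two-photon

sched <- generate_power_schedule(le_um = 170, noise_cv = 0.05, seed = 3)
glance(estimate_attenuation_length(sched))
#>   le_um std.error r.squared  nobs
#> 1  168.      2.04     0.999     6
```

And a rendered phantom closes the loop from scene to analysed profile:

```r
scene <- generate_filament_scene(volume_um = c(32, 32, 120), seed = 1)
#> <filament_scene> 32 x 32 x 120 um, 234 filaments, fill 0.100 (target 0.100)
stack <- render_stack(scene, beam,
                      medium_properties(80, 500,
                                        fill_fraction = scene$realized_fill),
                      channel = "blue", z_step_um = 20, seed = 2)
sbr_profile(stack)
#>   channel slice depth_um background signal ratio
#> 1 blue        1        0          1     59    59
#> 2 blue        2       20          1     26    26
#> ...                                      (constant surface power, so the
#>                                           in-focus signal decays with depth)
```

Each result type has an `autoplot()` method (`sbr_profile`, `sbr_map`,
`power_fit`, `attenuation_fit`), and the fit objects support broom-style
`tidy()`/`glance()`.

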
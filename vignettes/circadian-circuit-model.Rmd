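---
title: "Modelling the circadian phototransduction circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the circadian phototransduction circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circphot)
```

## The circuit in brief

Human circadian phototransduction is not a single-photopigment process. The
M1 ipRGC carries an intrinsic melanopsin response, but its drive to the SCN
is shaped by distal retinal circuitry: the spectrally opponent S-cone
bipolar (SB) adds a blue-ON signal through *en passant* synapses, the AII
amacrine shunts the ipRGC with a rod-dominated signal that sets its
comparatively high threshold, cones progressively silence that rod signal as
light levels rise, and the dopaminergic A18 amacrine disconnects the shunt
entirely whenever the SB signals "yellow". An S-cone amacrine is assumed to
rectify the SB signal, so only its blue-ON component ever reaches the ipRGC.

`circphot` turns that circuit into arithmetic on spectra. For a corneal
spectral irradiance $E(\lambda)$ the five excitations are
$X_i = \int s_i(\lambda)\,E(\lambda)\,d\lambda$ with $s_i$ the corneal
(lens-filtered, peak-normalized) sensitivity of class
$i \in \{S, M, L, \mathrm{rod}, \mathrm{mel}\}$, and the achromatic channel
is $V_{ach} = X_L + X_M$ (unit weights: the H1 horizontal cell is described
only as combining L and M, and the opponent gain $k$ absorbs any common
scale). The opponent signal is $b - y = X_S - k\,V_{ach}$, with $b - y > 0$
labelled *blue* and $b - y \le 0$ *yellow* — warm sources sit on the
boundary-inclusive side. The circadian drive is

$$
R \;=\;
\begin{cases}
\max\!\bigl(0,\; X_{mel} + a_1 (b-y) - a_2\bigl(1 -
  e^{-X'_{rod}/\sigma}\bigr)\bigr), & b-y > 0,\\[4pt]
X_{mel}, & b-y \le 0,
\end{cases}
\qquad
X'_{rod} = \frac{X_{rod}}{1 + a_3 V_{ach}}.
$$

The clamp at zero is the elevated threshold: shunting never sign-inverts the
response, it bleeds current until nothing leaves the retina. On the yellow
branch the shunt is decoupled (A18) and the rectified SB input is zero
(SCA), so the ipRGC acts alone, whatever the gains.

## Assumptions inherited from the circuit description

* M1 and displaced M1 ipRGCs are treated as one functional unit.
* Only ON responses reach the SCN; the yellow-OFF SB signal is eliminated
  before the ipRGC, which we implement by letting the opponent term enter
  only on the blue branch (never as a negative contribution).
* The A18 decoupling is a hard, diode-like switch at $b-y = 0$. A graded
  decoupling would smooth the notch into a dip; the diode reading produces
  the discontinuity, which is the phenomenon of interest.
* The shunt acts on the summed blue-branch signal (intrinsic + SB input),
  not on the intrinsic response alone; the circuit description does not
  disambiguate, and shunting at the ipRGC membrane acts on whatever current
  is present there.
* Photopigment peaks are treated as retinal values with lens filtering
  applied on top; whether published $\lambda_{max}$ values are pre- or
  post-lens is left open by the circuit description, and this choice keeps
  the template and the filter separable.

## Spectral machinery and numerical conventions

Everything lives on one wavelength grid, 380–780 nm at 1 nm by default:
wide enough to cover all five templates' support, fine enough to localize
the notch to a nanometre. Continuous spectra integrate by the trapezoid
rule; generated monochromatic lines carry a rectangle (value × step)
convention so a single-bin line integrates to its nominal power exactly (a
1-bin spike under the trapezoid rule would integrate to half). Mixtures
inherit the rectangle rule whenever a line participates. Off-grid
monochromatic requests fail loudly rather than snapping — silent snapping
would corrupt notch localization. File input is linearly interpolated onto
the grid and zero-filled (with a message) outside the file's range.

Opsin templates are Gaussians in wavelength with FWHM 80 nm, peak
normalized. The only quantitative statement available about opsin shape is
"Gaussian-like" with an ~80 nm half-bandwidth, and the Gaussian makes that
bandwidth an exact property rather than an approximation; a vitamin-A
nomogram backend could be added later behind `pigment_template()` without
touching anything downstream. Macular pigment is excluded: pre-retinal
filtering is attributed largely to the crystalline lens.

Three tables ship with the package at 1 nm: the CIE 1951 scotopic
$V'(\lambda)$ (peak 1 at 507 nm) and CIE 1924 photopic $V(\lambda)$ (peak 1
at 555 nm) luminous-efficiency functions, interpolated from their standard
5 nm values by a monotone Hermite spline (no overshoot, so the tabulated
peaks stay the global maxima and illuminance constants 1700 and
683 lm W$^{-1}$ apply exactly at the peaks), and a **synthetic**
crystalline-lens transmittance curve. No published standard-observer lens
table is bundled; instead hand-set optical-density anchors following the
qualitative shape of young-adult lens density data (steep absorption below
450 nm, essentially transparent beyond 650 nm) are monotonically
interpolated and exponentiated. The file is named
`lens_transmittance_synthetic.csv` to make its provenance unmistakable. It
satisfies the properties the model relies on — values in $[0,1]$,
non-decreasing through 400–550 nm, $\ge 0.99$ at 700 nm — but absolute
short-wavelength numbers should not be quoted as a standard observer's.

Two numerical tie-breaks matter. Corneal sensitivities are renormalized to
peak 1, taking the first grid index on (measure-zero) ties. The branch
decision uses a relative tolerance, blue iff
$b - y > 10^{-12}(X_S + k V_{ach})$: a line exactly at the calibrated
cross-point yields $b-y$ that is zero only up to rounding, and without the
tolerance its branch flips with the stimulus power.

## Calibration

**Cross-point.** $k = s_S(\lambda_c) / (s_L(\lambda_c) + s_M(\lambda_c))$
at $\lambda_c = 500$ nm, in closed form, so a 500 nm line is exactly
spectrally neutral. Recalibrating at another wavelength moves the notch
there, which the tests exercise at 510 nm.

**Gains.** $a_1, a_2, a_3, \sigma$ have no published values; they are set
by a deterministic search that targets the one published quantitative
property of the full circuit — a monochromatic half-bandwidth of ~100 nm at
the 300 scotopic lux criterion — subject to the qualitative prediction
shape: enhanced sensitivity relative to melanopsin-alone at 460 nm and
reduced at 490 nm, both compared on raw per-irradiance scale. The search
nondimensionalizes against the criterion-level excitations of the 500 nm
line ($X_{rod}^0$, $V_{ach}^0$, $X_{mel}^0$): $a_2$ scans fixed multiples
of $X_{mel}^0$ (shunt depth relative to the intrinsic response), $a_3$
multiples of $1/V_{ach}^0$ (how strongly criterion-level cone drive
releases the shunt), $\sigma$ multiples of $X_{rod}^0$, and at each node
$a_1$ is refined on a fixed grid plus a golden-section step. Node order and
tie-breaking are fixed, so two runs return identical parameters to the last
bit; the whole search takes about a second (each candidate curve is a
vectorized evaluation over 251 wavelengths, tested equal to the
per-wavelength pipeline to machine precision). The calibrated defaults
reach the 100 nm target essentially exactly.

Light level enters only through the criterion: each wavelength's line is
scaled to equal *scotopic* illuminance, because rod signalling is what sets
the threshold in this circuit, and 300 scotopic lux is roughly the
half-saturation level for nocturnal melatonin suppression. Wavelengths
where $V'$ is zero on the grid cannot reach the criterion; they are
excluded and recorded, never interpolated over.

## The sensitivity curve and its metrics

The curve ordinate is circadian drive per unit corneal irradiance at the
criterion level, peak-normalized — the standard action-spectrum convention;
whether the empirical ordinate is per-irradiance or per-quantum is not
settled, and per-irradiance is the choice made here. The default evaluation
range is 400–650 nm (the plotted span of the empirical comparisons) while
the computational grid stays 380–780 nm. FWHM is measured between the
outermost half-maximum crossings, each linearly interpolated between
bracketing grid points, erroring (not extrapolating) if a flank never falls
below half maximum. The notch wavelength is the right endpoint of the
largest adjacent-step jump — exact for a hard branch switch on a 1 nm grid —
and notch depth is the maximum of (reference − full) over 470–500 nm with
both curves divided by the reference's raw peak ("common normalization";
per-curve peak normalization would make the yellow-branch tails disagree
merely because the full curve's peak is higher).

At the defaults the full curve has FWHM 100 nm against 74.7 nm for
melanopsin alone (the lens trims the Gaussian's short flank, which is why
the melanopsin-only figure sits below the nominal 80 nm), the notch sits at
500 nm with depth 0.34, and the depth falls monotonically with level
(0.71 at 100 sc lx to 0.03 at 3000 sc lx): raising the level raises cone
drive faster than the bounded shunt can grow, which is the circuit's
explanation for the notch shrinking in bright light.

## Subadditivity

Opponent differencing makes polychromatic responses subadditive:
`subadditivity_index()` returns $R(A{+}B)/(R(A){+}R(B))$. For a blue-branch
line at its criterion-level power plus a yellow line, the index is below 1
whether or not the mixture crosses the boundary. Two caveats are worth
stating plainly. First, for $A = B$ the blue-branch response is *convex* in
intensity (the shunt is concave and bounded), so a self-mixture is never
subadditive — the index is $\ge 1$, reaching 1 exactly when the shunt is
disabled ($a_2 = 0$) or both $a_1 = a_2 = 0$. Second, at very dim levels a
blue+yellow mixture can be *super*additive: the blue component alone is
largely eaten by the shunt, while the mixture crosses to the yellow branch
and escapes it. Both behaviours are the threshold logic of the circuit, not
artefacts; the subadditivity claim is a photopic-level statement and the
tests frame it that way.

## What the synthetic stimuli do and do not emulate

The generators cover the stimulus classes the model's predictions are about:
monochromatic lines (the narrowband stimuli of the melatonin-suppression
action-spectrum experiments), Gaussian-free blackbody radiators as "warm"
(2700 K) and "cool" (6500 K) polychromatic whites straddling the b−y
cross-point, and arbitrary nonnegative mixtures. They are idealized: real
lamps have structured spectra, real experimental narrowband stimuli have
~10 nm bandwidth rather than one grid bin, and no noise, adaptation state,
pupil size or temporal profile is represented. Passing tests therefore
demonstrate the circuit arithmetic and its published shape properties, not
agreement with any individual empirical dataset; the empirical
action-spectrum points themselves are not bundled or fitted.

## Problem sizes and runtime

The default grid has 401 points; a sensitivity curve is 251 model
evaluations; gain calibration evaluates a few thousand candidate curves
vectorized. Model calibration takes ~1.5 s and the full test suite ~15 s on
one core, so everything is comfortably interactive.

## Known limitations

* No temporal dynamics (adaptation, photon counting over time) and no
  spatial structure across the retina — single numbers per stimulus.
* No melatonin-suppression dose–response transform: the model stops at
  circadian drive, and 300 scotopic lux enters only as the criterion level.
* The nocturnal-rodent circuit (direct rod→ipRGC input, orders of magnitude
  higher sensitivity) is out of scope; predictions are for diurnal humans.
* The lens table is synthetic (see above); the Gaussian template is an
  idealization of opsin absorbance shape.
* The free gains are identified only up to the calibration targets: other
  $(a_1, a_2, a_3, \sigma)$ combinations can satisfy the same constraints,
  and the deterministic search order is what pins down one of them.
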
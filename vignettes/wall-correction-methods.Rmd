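---
title: "Photon transport, cavity response, and the wall correction factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon transport, cavity response, and the wall correction factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A spherical graphite-walled cavity ionization chamber realizes an air-kerma
primary standard for high-dose-rate Ir-192 brachytherapy sources: the
reference air-kerma rate is the kerma rate to air, in air, 1 m from the
source, corrected for air attenuation and scattering. The chamber wall both
attenuates the incoming primary photons and adds scattered photons to the
cavity signal, so the measured charge must be corrected by the wall
correction factor

$$k_\mathrm{wall} = k_\mathrm{att}\,k_\mathrm{sc}
  = \frac{\langle e^{+\mu t}\,\varepsilon_P\rangle}
         {\langle \varepsilon_P + \varepsilon_S\rangle},
\qquad
k_\mathrm{att} = \frac{\langle e^{+\mu t}\,\varepsilon_P\rangle}
                      {\langle \varepsilon_P\rangle},
\qquad
k_\mathrm{sc} = \frac{\langle \varepsilon_P\rangle}
                     {\langle \varepsilon_P + \varepsilon_S\rangle},$$

where $\varepsilon_P$ and $\varepsilon_S$ are the cavity energy deposits
attributable to primary (never-scattered) and scattered photons, $t$ is the
wall path a primary crossed before depositing, and $\mu$ the wall's linear
attenuation coefficient at the photon's energy. `irkwall` estimates these
ratios by Monte Carlo photon transport through the three-region analytic
scene (ambient air, graphite shell, air cavity) with a point source at
100 cm, and companion functions post-process the tallies
(`wall_factors()`, `energy_scan()`, `chamber_comparison()`).

A second, clinically motivated component simulates a PMMA cylinder (radius
10 cm, height 14 cm) with a 2 cm diameter axial air cavity standing in for
an organ cavity (esophagus, bronchus). The source sits at mid-height
(7 cm), either on the cavity axis or displaced to the cavity surface
(points A and B, diametrically opposite along the monitoring radius), and
photon kerma is scored in eighteen 0.5 cm cubes whose centres run from
1.25 cm to 9.75 cm from the axis (`simulate_phantom()`,
`dose_ratio_table()`).

## Photon physics

Interaction coefficients for graphite, air, PMMA, stainless steel and
iridium ship as plain-text tables on the conventional 0.01-1.5 MeV grid of
the standard mass attenuation / mass energy-absorption compilations, and
are interpolated log-log (`attenuation_coefficient()`); queries below
0.01 MeV are errors, not extrapolations. Two simplifications are embedded
in the tables themselves:

* **Coherent (Rayleigh) scattering is not a process.** The total
  attenuation keeps the full tabulated value, and the photoelectric
  branching fraction is defined as one minus the Klein-Nishina incoherent
  share of the total, so the small coherent component (about 1% of
  interactions in low-Z media above 0.2 MeV) terminates histories instead
  of slightly deflecting them. This marginally hardens the deep-penetration
  field; at the sub-percent level it is a known systematic, not a bug.
* **Stainless steel uses the elemental iron table** (alloy neighbours
  bracket iron; the capsule shell is 250 um), and **iridium is an
  interpolation in atomic number between the tungsten and gold tables**
  with explicit knots at its K edge. Iridium coefficients only enter
  source-core self-absorption, where a few percent of table error moves
  the spectrum by far less.

Compton scattering samples the free-electron Klein-Nishina differential
cross section by rejection (`compton_scatter()`); binding and Doppler
effects are ignored, appropriate above 60 keV in low-Z media. Fluorescence
is omitted (sub-keV relevance here). Photons falling below the table floor
terminate.

## The source

`bare_lines()` carries the principal Ir-192 photon lines between 60 and
885 keV (gammas plus the daughter K X-ray groups) with standard
photons-per-decay intensities; the three very weak lines above 1 MeV are
omitted, so 885 keV is the hardest photon in the problem and its 687 keV
Compton edge sets the charged-particle-equilibrium wall thickness
(`cpe_wall_thickness()`: 0.31 g cm^-2 over a nominal graphite density of
1.7 g cm^-3 is about 1.8 mm, comfortably below the 3 mm walls).

`attenuated_spectrum()` computes the fluence spectrum at the reference
point, 100 cm from the source axis on its perpendicular bisector: each
line, emitted from a deterministic quadrature grid over the 3.5 mm x
0.6 mm active iridium core (32 axial x 16 radial x 16 azimuthal points by
default), is attenuated along the exact ray through the residual core and
the 250 um steel capsule wall. Quadrature rather than Monte Carlo keeps
the spectrum bit-reproducible; refining the grid changes no bin by more
than 2e-4. Binning is 5 keV from 0.06 to 0.90 MeV (the published figure's
resolution is unstated). The 100 cm air column is deliberately excluded -
the reference air-kerma rate is defined corrected for air attenuation and
scattering - while ambient air in chamber scenes is simulated by the
transport itself. The resulting mean energy is about 0.37 MeV, consistent
with the conventional "close to 0.4 MeV" characterisation.

## Chamber transport and the cavity response model

`simulate_chamber()` emits photons from the point source into the cone
subtending the chamber (a 10% half-angle margin admits near-cone photons
that can scatter in from the air; the cone fraction is retained for
absolute normalisation, and halving the margin moves no factor beyond
statistics). Free paths are sampled across the up-to-five analytic
segments per flight (air, wall, cavity, wall, air), interactions branch
photoelectric/incoherent, and every deposit is tagged primary or scattered.
For primaries the companion tally carries the unfolding weight
$e^{+\mu t}$, with $t$ the wall path crossed before the deposit; the
optical depth of the ambient air is not unfolded (a documented convention:
the wall factor corrects the wall, air corrections belong to other terms
of the standard).

Three cavity response estimators are available (`run_config()`):

* **`csda_response`** (default). In a real chamber the cavity air
  (1.2e-3 g cm^-3) contributes almost none of the ionization; the signal
  comes from secondary electrons liberated in the graphite near the
  interface. At every sampled collision in the wall or gas the recoil
  electron (Compton kinematics; photoelectrons follow the photon
  direction) is followed in a straight line, slowing according to packaged
  CSDA range tables for graphite and air (consistent with the 0.31
  g cm^-2 range of 687 keV electrons in graphite), and the cavity deposit
  is the energy it loses between entering and leaving the gas. The deposit
  is averaged over a randomly rotated comb of 16 electron azimuths - a
  conditional-expectation device with the same mean and far lower
  variance. The model is parameter-free.
* **`track_length`**: the classic collision-kerma track-length estimator
  over gas chords, $w\,E\,(\mu_{en}/\rho)\,\rho\,\ell$
  (`score_cavity_track()`).
* **`analog`**: energy transferred at sampled gas collisions; used with an
  inflated gas density as an independent cross-check of `track_length`
  (the factors are density-ratio invariant while the cavity stays
  optically thin).

**Why the default is not the track-length estimator.** The gas-chord
estimators tag the photon field *crossing the gas*; the electron-mediated
signal tags the photon field *in the inner wall layer*, which includes
grazing trajectories (impact parameters between the cavity and outer
radii) that never cross the gas but carry long wall paths and hence large
$e^{+\mu t}$ weights. The difference is not academic: for the INER chamber
under the Ir-192 spectrum the gas-chord estimator gives
$k_\mathrm{att}\approx1.073$, an interface-shell tally gives about
$1.114$-$1.122$, and the straight-ahead-CSDA response lands at about
$1.083$; the published full-electron-transport value, $1.1021$, falls
between the straight-ahead and shell extremes, exactly where lateral
electron diffusion - which a straight-line model cannot supply - would
move it. The same bracketing holds for $k_\mathrm{sc}$ (about $0.954$,
$0.928$-$0.932$ and $0.945$ against $0.9402$). The residual systematic of
the default model is therefore about $-1.5$% on $k_\mathrm{att}$, $+0.5$%
on $k_\mathrm{sc}$ and $-1$% on $k_\mathrm{wall}$, with partial
cancellation in the product; condensed-history electron transport, which
would close the gap, is deliberately outside this package's scope. The
acceptance suite states the published values with a 0.5% tolerance, so
the attenuation-dominated checks sit honestly outside it while the
ratios-of-doses results pass; both facts are visible in the test output
rather than smoothed over.

Uncertainties are history-by-history: per-history deposit second moments
propagate to the ratios in quadrature ignoring their correlation. Because
$k_\mathrm{att}$'s numerator and denominator are nearly proportional this
overstates its uncertainty considerably (the published component
uncertainties, which account for the correlation, are an order of
magnitude smaller); the approximation is conservative and documented.

## Phantom transport

`simulate_phantom()` defaults to a **deterministic first flight**: the
uncollided kerma in every cube is a Fibonacci-lattice quadrature over
emission directions (2e5 by default) with exact exponential attenuation
and an analytic integral across each cube, and only the scattered field is
simulated - every history is forced to collide once (weight
$1-e^{-\tau_\mathrm{esc}}$), then transported analog with track-length
scoring of all subsequent flights. This removes the dominant variance at
the far cubes, where fewer than one in a thousand analog histories
contributes. The all-Monte-Carlo `analog` mode remains available and a
test checks the two agree.

The **source model matters at millimetre range.** The default `capsule`
model emits from points uniform over the finite active core with bare-line
energies and weighs every emission by its direction-dependent transmission
through the residual iridium core and the steel capsule. Two consequences
are material for the nearest cube when the source is displaced to point B
(touching that cube's face): near-axial emission crosses the core end-on
and is suppressed by roughly $e^{-0.8}$, and a rigid capsule "at the
cavity surface" has its axis one capsule radius (0.055 cm) inside the
surface. With both, the uncollided B/central ratio at 1.25 cm is 16.2
where an axis-on-surface isotropic point source gives 25-27; the published
table is only reproducible with the explicit capsule. The `point` model
(exact position, supplied spectrum) is retained for the closed-form
inverse-square checks. Photons scattered inside the capsule are treated as
absorbed (pure attenuator); the cable, plug and tail are omitted.

Doses are photon collision kerma per emitted photon (Gy/history). The
published displacement table is total dose including a small
source-electron component (about 1/7 of the photon dose at the nearest
monitoring point, 1/60 elsewhere); the nearest-point ratios are therefore
compared at a widened 10% tolerance, and the surface-to-centre "about 1%"
bound lands at about 1.2% in photon-kerma terms - the centre dose that
normalises it lacks its electron share. This near-miss is reported as
computed.

## Problem sizes and reproducibility

Default run sizes are 1e7 histories for chamber acceptance runs (relative
standard errors well below 0.1% for the track-length estimator, a few
0.1% for the electron-response model) and 1e6-2e6 per phantom position;
unit tests use 1e4-1e5. The original study used at least 1e8 histories;
the stated tolerances absorb the difference. Every simulation accepts a
seed and is bit-reproducible: identical configuration and seed give
identical tallies, the CLI writes a JSON manifest (command, parameters,
seed, checksums, package version) beside every output, and the spectrum
and uncollided-kerma stages are deterministic quadratures with no seed
at all.

## Numerical choices and degenerate inputs

Sphere and capped-cylinder intersections collapse missed or tangent shells
to zero-length segments (milestone ordering is enforced by a running
maximum), so rays grazing a boundary score nothing rather than failing;
boundary points classify to the denser region (body over cavity). Log-log
interpolation is exact at grid points; fictitious materials with exact
zeros round-trip as exact zeros. The Klein-Nishina sampler rejects against
the forward-scatter envelope (density at most 2), and the electron range
inverse is the exact piecewise-power-law inverse of the range
interpolant. Histories are processed in vectorised batches (5e5 by
default); per-history tallies are accumulated by index so a history's
multiple deposits stay together for the variance bookkeeping.

## Known limitations

* No electron transport: straight-ahead CSDA response in the chamber
  (about 1% systematic on $k_\mathrm{wall}$, see above) and pure kerma
  scoring in the phantom (no electron dose column).
* No coherent scattering, binding/Doppler corrections, or fluorescence.
* The iridium table is a Z-interpolation, not a measured compilation.
* The phantom's four edge cavities are filled with PMMA, as in the study
  design; the central cavity is air at standard density.
* Scatter from outside the source cone (chamber scenes) is represented
  only through the cone margin; the ambient region is truncated 10 cm
  beyond the source.
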
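---
title: "Methods: zero-field read-off, orientation-selective couplings and the toy-site generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-field read-off, orientation-selective couplings and the toy-site generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfepr)
```

This vignette documents the models behind the package, the parameters
that matter, the numerical choices, and what the synthetic-data tests do
and do not demonstrate about real measurements.

## The spin model and its regime of validity

The electron system is a high-spin Mn(II) ion, S = 5/2, in a strong
applied field, with the working Hamiltonian

$$H = g\beta B S_z + D\left[S_{z'}^2 - \tfrac{S(S+1)}{3}\right]
      + E\left[S_{x'}^2 - S_{y'}^2\right],$$

primed axes being the zero-field principal frame. All production
computations are first order in the zero-field interaction: the
$M_s \leftrightarrow M_s{+}1$ transition is shifted from the Zeeman
frequency by $(M_s + \tfrac12)[D(3\cos^2\theta_{zf} - 1) +
3E\sin^2\theta_{zf}\cos 2\phi_{zf}]$, which in the equatorial plane spans
$-D \pm 3E$. First order keeps the turning-point read-off invertible in
closed form, which is the point of the method; it is adequate because
$|D|/\nu_{obs} \approx 0.11$ at 94 GHz for these sites.

The test suite checks the closed forms against an independent
exact-diagonalization oracle (explicit 6×6 spin matrices, numerical
eigenvalues). Second-order corrections for S = 5/2 are *not* small
multiples of $D^2/\nu_{obs}$ at every orientation: measured over random
orientations and all five transitions at the rhombicity of these sites
($E/|D| \lesssim 0.1$), the worst-case deviation is just under
$10\,D^2/\nu_{obs}$ (and grows to roughly $14\,D^2/\nu_{obs}$ at maximal
rhombicity). The package therefore documents and tests the bound
$10\,D^2/\nu_{obs}$ for the SOD regime, about 12 GHz at the parameters
used here — large in absolute terms at the outer turning points, which is
why the read-off tolerances below are quoted in tenths of GHz rather than
MHz. Deviations at the *canonical* orientations, where the read-off
actually happens, are far smaller because the dominant off-diagonal
zero-field elements vanish there.

Units: GHz for electron-spin frequencies and (D, E); MHz for nuclear
couplings and frequencies; mT for fields; Å for distances. Conversions
use CODATA constants computed at run time (`electron_ghz_per_mt`,
`point_dipole_prefactor`), never literals.

The convention $0 \le E \le |D|/3$ is enforced;
`canonicalize_zfs` relabels principal axes for out-of-convention input.
With that convention and $D<0$, the extreme low-field edge of the powder
pattern is the $\theta_{zf}=0$ orientation and the extreme high-field
edge is equatorial along the axis we label $x$ (first-order bracket
$-D+3E$). Which equatorial axis is called $x$ versus $y$ is purely a
labelling choice; the physically meaningful statements — single-valued
orientation sets at the edges, equatorial span $-D\pm3E$ — do not depend
on it.

## Powder simulation

`simulate_fieldsweep` deposits one stick per grid orientation and
transition (weight = solid angle × Boltzmann population of the lower
manifold) onto the field axis and convolves once with a Gaussian of the
stated FWHM. Echo-detected spectra are absorption-shaped; no
field-modulation derivative is applied. Transition moments are not
included in the default weighting; they rescale whole transitions and do
not move turning points.

The default orientation grid is 361 × 181 over the hemisphere
(θ step 0.25°). With stick deposition, a coarser grid leaves a
discretization comb whose period exceeds the 10 mT default linewidth and
defeats automated feature detection; at the default the residual ripple
is below 1% and a spectrum costs well under half a second. The grid is
an argument everywhere, and the integral of the simulated amplitude is
invariant under refinement (tested at the 0.5% level).

## Turning-point detection

The published analysis reads the labelled turning points off the
spectrum by eye. `locate_turning_points` replaces that with a
deterministic, configurable procedure:

1. Light Savitzky–Golay smoothing for derivatives; heavier smoothing
   (~2.5 linewidths) for peak picking, with a prominence filter whose
   floor is the raw noise level.
2. Outer edges: onset at 5% of the maximum, then a staircase "walk-out"
   that repeatedly extends the onset to the outermost point above 3% of
   the local level (guarded by 4× the noise floor). This recovers weak
   outer plateaus — the thin $zz$ shoulder next to a dominant central
   line, or next to the strong perpendicular divergence of a near-axial
   pattern. The edge proper is the nearby derivative extremum: a
   Gaussian-blurred step is steepest exactly at the step. An edge whose
   inside-minus-outside contrast stays below the noise floor (e.g. the
   faint outer turning point of the weakly populated $M_s=+3/2$
   transition at 6 K) is rejected and the search jumps inward to the
   next genuine step.
3. The interior $(zz, -3/2)$ step is the derivative extremum near half
   the $(zz,-5/2)$ offset — the $(M_s+\tfrac12)$ ratio makes that exact
   at first order.
4. The intermediate-axis singularity $(yy,-5/2)$ is the strongest
   prominent maximum between the center and the far edge; if the pick is
   actually its $-3/2$ counterpart (at exactly half the offset) the peak
   near twice the offset is taken instead.
5. The sign of D is taken from a guess when given; otherwise both
   assignments are scored by the half-offset consistency of the interior
   step *plus* a comparison of the two sides' strongest peaks. The
   half-offset test alone cannot fix the sign (every $-3/2$ feature sits
   at half its $-5/2$ partner on both sides); the side carrying the
   powder divergence is the $xx/yy$ side, and that is robust down to the
   signal-to-noise ratios the recovery tests use.

All thresholds (onset fraction, smoothing windows) are arguments.
Read-off accuracy at the default 10 mT linewidth: D within ~0.02 GHz and
E within ~0.03 GHz on noise-free synthetics; D within 5% at
signal-to-noise 20. The reported uncertainties are propagated from the
linewidth ($\sigma_D = g\beta/h \cdot \mathrm{FWHM}/8$ and the
corresponding two-label combination for E).

## ENDOR / ELDOR-NMR line algebra and fitting

All offsets are relative to $q\nu_{NMR}$; the positive branch of a
single-quantum line sits at $-M_s A_{\rm eff}$, a multi-quantum
combination at $\sum_i -M_s\,\Delta m_{I,i} A_{{\rm eff},i}$. The
single-nucleus I = 1 double-quantum line is purely hyperfine-determined:
the first-order quadrupole shifts of its two single-quantum steps cancel,
which the implementation realizes by construction and the tests verify
against 100 random quadrupole tensors.

Widths quoted as "5.3 (2.2)" are interpreted as Gaussian FWHM (the common
spectroscopic convention). Manifold weights default to equal across the
manifolds contributing at a turning-point field; Boltzmann weighting is
available via the weight argument. The matrix (distant-proton) line is an
ordinary component with $A_{\rm eff}=0$, never an implicit background
subtraction. ELDOR-NMR transition probabilities, where needed for
relative intensities, use an isolated, swappable forbiddenness heuristic
$\propto (T/\nu_{NMR})^{2q}$ normalized within each quantum order; it
never moves line positions.

`fit_components` is deterministic: coupling seeds spaced 1 MHz across the
bounds, every seed combination refined by Levenberg–Marquardt
(`minpack.lm`), best residual wins, ties to the smaller couplings.
Recovery on synthetics: exact components to 0.05 MHz noise-free, both
couplings within 0.3 MHz at signal-to-noise 15 across 50 seeds.

## Point-dipole model

$T = (\mu_0/4\pi) g_e\beta_e g_n\beta_n/(h r^3)$, evaluated from
constants at $g_e = 2.0023$ (using 2.00 changes the prefactor by <0.2%,
below every tolerance used). T denotes the axial dipolar parameter with
principal values $(-T,-T,+2T)$; converters to and from explicit principal
values are provided. The linearized distance sensitivity
$dr = r\,dT/(3T)$ agrees with the finite difference to 5% for
$dT/T \lesssim 0.075$ (the exact relative error is $\approx \tfrac23
dT/T$). A frequency shift can be read either as a coupling shift or as a
line-position shift; the latter scales by $|M_s q|$ and both readings are
exposed (`line_shift` argument). The headline number — 100 kHz
corresponding to ~0.03 Å at the water-proton geometry — uses the coupling
reading.

## Frame search

`euler_grid_search` scans ZYZ Euler angles exhaustively, scoring
candidates by (1) the RMS mismatch of predicted effective couplings with
the field along the candidate $D_{zz}$ and (2) the RMS residual of the
predicted ENDOR spectrum with the field along the candidate $D_{yy}$,
both non-dimensionalized by the target magnitudes and equally weighted by
default (the two criteria are stated without weights; the weighting is an
argument). Numerical design choices:

- The coupling term depends only on the $D_{zz}$ direction, which allows
  an exact branch-and-bound: cells are visited in order of that term and
  the scan stops when it alone exceeds the best total score. Typical
  full 5° scans finish in well under a second.
- At the 150 kHz display convolution the spectral residual decorrelates
  within a fraction of a degree — no grid can sample that. The search
  therefore compares both sides broadened to a 2 MHz internal width: the
  supplied target is re-convolved with the complementary kernel and the
  model is pushed through the same window-truncated operator, so
  out-of-window lines drop out of both sides identically and the score
  basin becomes a few degrees wide.
- Refinement: 1° local passes seeded from the best few coarse cells,
  including for each cell the best second γ on the half-circle (the
  spectral term is invariant under γ → γ + π, and nearby γ basins can be
  ranked incorrectly at the coarse step).
- Determinism: ties break to the smallest (β, α, γ).

The score depends on the zero-field axes only through quadratic forms, so
it is invariant under sign flips of any two axes; `zfs_frame_orbit`
returns the four equivalent Euler triples and the search reports that
orbit. Recovery tests compare axis directions modulo sign. With targets
built over a wide spectral window the search recovers 20 random frames to
~1°; with the narrow −10 to −5 MHz criterion window a minority of frames
leave the in-plane angle under-determined (few lines fall in the window),
which is an identifiability limit of the criterion, not of the search.

## The toy-site generator

`build_toy_site` makes an idealized trigonal-bipyramidal site: His26 and
water axial, His81/His171/Asp167 equatorial; molecular z along
Mn–N(His26), x along Mn–O(Asp167). Crystal structures of these sites do
not resolve hydrogens, so protons are placed with standard covalent
geometry (O–H 0.97 Å, H–O–H 104.5°, ring C–H 1.08 Å in-plane, imidazoles
as regular pentagons of side 1.37 Å). The water orientation, Mn–O
distance (within ±0.1 Å of the 2.22 Å crystallographic value) and O–H
length (within 0.95–0.99 Å) are set by a deterministic box-constrained
optimization so the two water protons land near the 2.62 / 2.91 Å
metal–proton distances inferred spectroscopically; the ring protons then
fall at 3.44 Å, i.e. dipolar couplings of ~1.9 MHz, inside the 1.8–2.4
MHz window expected for imidazole ring protons. The His171 ring dihedral
is +30° for the Mn-type variant and −60° for the Fe-type variant, the
only difference between them.

`tensors_from_site` assigns protons axial point-dipole tensors along
their Mn–H vectors; default isotropic parts are 0 except −0.45 MHz for
the farther water proton (the bonding-sensitive part seen for that
proton). Nitrogen hyperfine tensors are **parametric, not ab initio**:
the dipolar part is point-dipole, and the isotropic part of the axial
nitrogen is calibrated so its effective coupling along z is 4 MHz, the
largest nitrogen coupling at the low-field edge; quadrupole tensors are
placeholders (|P_zz| = 0.8 MHz along the bond) and everything is tagged
`synthetic`. What passing tests show, therefore, is that the *pipeline*
(projection → line algebra → synthesis → fitting → frame search) is
self-consistent and invertible at realistic magnitudes; they do not show
that a real site's electronic structure follows the point-dipole model —
the known deviations (spin density delocalization onto ligands) are
precisely why measured dipolar values (e.g. 4.1 MHz) differ by ~7% from
the point-dipole value at the same distance (4.40 MHz at 2.62 Å), and why
production use consumes externally supplied tensor sets.

Seeded noise is additive white Gaussian with σ = max amplitude / SNR; the
global RNG state is restored after use.

## Problem sizes and determinism

The shipped tests simulate 50 random SOD-regime parameter sets for the
read-off recovery, 50 noise seeds for the fit recovery, 20 random frames
for the search recovery, and 100 random quadrupole tensors for the
double-quantum invariance; everything is seeded and the whole suite runs
in a few minutes on one core. Degenerate inputs (pure noise, flat or
non-decaying spectra, missing labels, off-resonance fields, non-unit
directions, non-traceless tensors) produce labelled errors rather than
numbers.

## Known limitations

- First order only: no second-order zero-field corrections in the
  production path, no pseudo-secular hyperfine terms (valid at high field
  where ν_NMR ≫ A), no relaxation or pulse-response modelling.
- The ⁵⁵Mn hyperfine sextet is not simulated; the read-off uses envelope
  positions, which is also how the published values were obtained.
- The turning-point detector assumes the spectrum decays below threshold
  at the axis ends and that the four labelled features are resolved; it
  reports what it found when they are not.
- The frame-search criterion with the narrow ENDOR window does not always
  determine the in-plane angle (see above); widening the window or adding
  couplings resolves this.
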
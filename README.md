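# hfepr

High-field EPR, ENDOR and ELDOR-detected NMR analysis of high-spin Mn(II)
(S = 5/2) active sites in metalloproteins — in particular the
manganese/iron superoxide dismutase (SOD) family, where the Mn(II)
zero-field interaction and the hyperfine couplings of nearby protons and
nitrogens report on the ligand-sphere structure at a resolution beyond
crystallography.

## What it does

**Zero-field splitting from powder spectra.** At W-band (94 GHz) the
field-swept echo spectrum of Mn(II) is spread by the zero-field
interaction, characterized by the axial and rhombic parameters D and E.
To first order, the M<sub>s</sub> ↔ M<sub>s</sub>+1 transition resonates
at

B<sub>res</sub> = h\[ν<sub>obs</sub> − (M<sub>s</sub> + ½)(D(3cos²θ<sub>zf</sub> − 1) + 3E sin²θ<sub>zf</sub> cos 2φ<sub>zf</sub>)\]/(gβ)

where (θ<sub>zf</sub>, φ<sub>zf</sub>) orient the field in the zero-field
principal frame. The package simulates the powder pattern
(`simulate_fieldsweep`), finds the labelled turning points
D<sub>zz,−5/2</sub>, D<sub>zz,−3/2</sub>, D<sub>xx,−5/2</sub>,
D<sub>yy,−5/2</sub> with a deterministic feature detector
(`locate_turning_points`), and inverts them to (D, E)
(`extract_zfs`): D = (gβ/h)ΔB<sub>zz,−5/2</sub>/4,
E = (gβ/h)(ΔB<sub>xx,−5/2</sub> − ΔB<sub>yy,−5/2</sub>)/12.

**Orientation-selective double resonance.** At a chosen field only
specific molecular orientations resonate (`resonant_orientations`); the
hyperfine tensor projected onto that direction gives the effective
coupling A<sub>eff</sub> = A<sub>iso</sub> + n̂ᵀT n̂
(`effective_coupling`). ENDOR and single-/multiple-quantum ELDOR-NMR line
positions follow the offset convention ν′ − qν<sub>NMR</sub> =
−M<sub>s</sub> q A<sub>eff</sub> (`sq_frequencies`, `mq_frequencies`,
`offset_to_aeff`); spectra are Gaussian component mixtures
(`synthesize_spectrum`) fitted by deterministic multi-start least squares
(`fit_components`). Single-nucleus ¹⁴N double-quantum lines are free of
first-order quadrupole shifts, which the line algebra reproduces.

**Point-dipole geometry.** The dipolar part of a proton coupling follows
T = (μ₀/4π) g<sub>e</sub>β<sub>e</sub>g<sub>n</sub>β<sub>n</sub>/(h r³) ≈
79.06/r³ MHz (r in Å), with A<sub>eff</sub> = A<sub>iso</sub> +
T(3cos²θ<sub>n</sub> − 1). `point_dipole_T`, `distance_from_T` and
`distance_sensitivity` convert couplings to metal–proton distances and
quantify how far a frequency shift moves a distance (dr = r·dT/(3T)).

**Frame search.** `euler_grid_search` orients the zero-field tensor in
the molecular frame by brute force over ZYZ Euler angles, scoring each
candidate against measured effective couplings at the low-field edge and
the ENDOR spectrum at the D<sub>yy</sub> position, with the axis-sign
symmetry orbit reported (`zfs_frame_orbit`).

**Synthetic data.** `build_toy_site` constructs an idealized
trigonal-bipyramidal Mn(His)₃(Asp)(H₂O) site (His171 ring dihedral +30°
or −60° to emulate the active/inactive contrast), `tensors_from_site`
derives point-dipole tensor sets from it, and `add_noise` provides seeded
noise — so every stage is testable without downloads.

## Worked example

```r
library(hfepr)

s <- spectrometer_settings(nu_obs_ghz = 94, g = 2.0023, temperature_k = 6)
z <- zfs_parameters(-10.60, 0.63)          # Mn-specific SOD site

sp <- simulate_fieldsweep(s, z, linewidth_mt = 10,
                          transitions = c(-5/2, -3/2))
extract_zfs(sp, s)
#> ZFS: D = -10.59 GHz, E = 0.635 GHz (E/|D| = 0.060, |D|+E = 11.22 GHz)

# ELDOR-NMR: the observed -12 MHz edge at the low-field position
offset_to_aeff(-12.0, ms = -5/2, q = 1)
#> [1] -4.8

# water-proton distance from its dipolar coupling, and its sensitivity
distance_from_T(3.3)                       # 2.883 A
distance_sensitivity(2.91, 3.3, 0.100)     # 0.029 A per 100 kHz
```

The recovered D = −10.59 GHz and E = 0.635 GHz agree with the generator
values within the read-off resolution (about a quarter linewidth, here
0.07 GHz on D); −4.8 MHz is the coupling at the edge of the
single-quantum proton spectrum; and the last two lines show that a
100 kHz coupling shift corresponds to ~0.03 Å at the water-proton
geometry — the scale that makes these measurements a sub-0.1 Å structural
probe.

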
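---
title: "Modelling and measuring hollow biomolecular co-condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring hollow biomolecular co-condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Fusion oncoproteins of the FET family (FUS-ERG, FUS-Gal4 and relatives)
co-condense with microsatellite-containing double-stranded DNA into
*hollow* co-condensates: a dense protein--DNA shell enclosing a dilute
aqueous lumen. Experimentally the sequence of events is that protein
droplets form first, dsDNA coats their surface, infiltrates, and a
cavity bounded by a sharp internal surface opens. `hollowcond`
implements (i) a mesoscopic phase-field model of this process, (ii) the
morphology classification and composition sweeps used to build its state
diagram, (iii) the elliptical-annulus radial profiling applied to
super-resolution images of condensate shells, (iv) particle-analysis
morphometry, and (v) a synthetic image generator that provides ground
truth for the two measurement stages. This vignette records the model,
the defaults, and the reasoning behind every choice that the underlying
physics does not fix.

## The model

Three order parameters live on a periodic square grid:

* `eta` -- local concentration of protein--nucleic-acid *complex*
  relative to the critical threshold for phase separation,
* `phi` -- local amphiphilicity (`phi > 0` hydrophilic, `phi < 0`
  hydrophobic),
* `chi` -- one or more nucleic-acid concentration fields.

The free energy is of Ohta--Kawasaki type,

$$
F = \int \Big[ w_\eta\,\eta^2(1-\eta)^2
  + \tfrac{\epsilon_\eta^2}{2}\lvert\nabla\eta\rvert^2
  + (s + s_0)\tfrac{w_\phi}{4}(\phi^2-1)^2
  + s\,\tfrac{\epsilon_\phi^2}{2}\lvert\nabla\phi\rvert^2
  - b_1\,\phi\,q(\eta)
  + b_2\,\phi\,h(\eta) \Big] dx
  \;+\; \frac{\alpha}{2}\sum_{k\neq 0}\frac{\lvert\hat\eta_k\rvert^2}{\lvert k\rvert^2}A ,
$$

with dense-phase indicator $s(\eta)=\eta^2$, saturating interface
indicator $q(\eta) = 4 s_c(1-s_c)$, $s_c=\sqrt{\tanh \eta^4}$, and core
indicator $h(\eta)=\tanh\eta^6$. The long-range term (strength
$\alpha$) penalises unbounded coarsening and selects a finite structural
length, as in microphase-separating systems.

The couplings encode the biology:

* **$b_1$** rewards hydrophilic alignment (`phi > 0`) where dense and
  dilute phases meet -- the differential interaction of the complex's
  hydrophilic (RGG) versus hydrophobic (DNA-binding domain) parts with
  the aqueous buffer. Crucially, at a partially condensed plateau
  ($\eta$ just above the dilute binodal) this term *destabilises* the
  uniform interior once `phi` has ordered hydrophilic: hollowing begins
  as an interfacial instability of the seeded droplet. The interface
  indicator is normalised to unit maximum so that the literature values
  of $b_1$ (0.14 for the wild-type system, 0.04 for the hydrophobic
  variant) are directly comparable to the well depths.
* **$b_2$** drives `phi` negative deep inside the dense phase (the
  complex buries its hydrophilic motifs in the core). Both indicators
  saturate smoothly; with polynomial (unsaturated) couplings the
  $b_2$ feedback has a spurious runaway minimum at $\eta \approx 1.6$.
* The $\psi_C$ mechanism operates through the initial condition: the
  seeded complex amplitude is $\min(1, \zeta_{protein}/\psi_C)$, so a
  higher critical fraction (weaker protein--DNA binding) leaves the
  droplet below the instability threshold and no hollow structure forms.

Dynamics: `eta` follows conserved Ohta--Kawasaki dynamics
$\partial_t\eta = m_\eta \nabla^2 (\delta F/\delta\eta) - \alpha(\eta-\bar\eta)$,
`phi` relaxes non-conserved ($\partial_t\phi = -m_\phi\,\delta F/\delta\phi$),
and each `chi` species obeys conservative drift--diffusion

$$
\partial_t \chi = \nabla\cdot\big( M_\chi (\nabla\chi - \chi\nabla \ln K) \big),
\qquad
M_\chi = d_\chi\big[\sigma\!\big(\tfrac{\eta_{free}-\eta}{\xi_{free}}\big)
 + k_{bind}\, s(\eta)\, g(\phi)\big],
\quad
K = 1 + \kappa\, k_{bind}\, A(\eta,\phi).
$$

Free (unbound) nucleic acid diffuses in the dilute phase but cannot
cross the dense shell; transport through the shell is complex-mediated
and proportional to the binding affinity $k_{bind}$, gated in
`hydrophobic_only` mode by a soft hydrophobicity sigmoid
$g(\phi)=\sigma(-\phi/\xi)$. The factor $K$ is a local binding
equilibrium: $\chi \propto K$ is the steady state, so bound species
enrich where their affinity field is high. Pure gated Fickian diffusion
(no drift) was rejected because its steady state is spatially uniform:
it cannot produce equilibrium shell enrichment or affinity-dependent
selectivity at any parameter setting. The affinity field is

* `hydrophobic_only` (protein--dsDNA):
  $A = \frac{s^2}{s^2 + 0.004}\,\sigma(-\phi/\xi)$ -- binding saturates
  once the complex phase is established (half-point at the same
  density as the free-diffusion gate, Hill coefficient 2);
* `both` (amphiphilic protein--RNA copolymer): the tadpole-like diblock
  partitions to the dense--dilute *interface*, where both its
  hydrophobic and hydrophilic blocks are satisfied:
  $A = \min(1.5,\ \gamma_{if}\lvert\nabla\eta\rvert^2)$. A purely local
  $(\eta,\phi)$ rule cannot produce the observed localisation at both
  surfaces; interfacial partitioning is the standard continuum
  description of a surfactant.

## How a hollow condensate forms here

The default initial condition mirrors the experiment: a preformed
protein droplet (tanh disc, radius 40 cells on a $128^2$ grid), a
nucleic-acid coat at its surface, and a *complexation seed* -- a band of
elevated `eta` at the interface, because complexes form where the DNA
coat meets the droplet. The seed matters: without it the interfacial
instability nucleates at a random noise maximum and collapses into a
compact blob instead of a shell. The coat is centred slightly inside
the interface (offset `chi_offset = -14` grid units), representing the inward
migration of surface-bound DNA during the early phase; by the time the
shell densifies, this material is trapped at the nascent internal
surface.

The run then proceeds: `phi` orders hydrophilic in the droplet
(`phi_bias = +0.15`; fresh complexes expose hydrophilic RGG), the
$b_1$ term destabilises the droplet interior, the rim densifies into a
ring fed by interior material, the centre drains (helped by the
long-range term) and a cavity bounded by a sharp interface remains.
Raising $\psi_C$ to 0.95 leaves the droplet amplitude below the
instability window, and lowering $b_1$ to 0.04 removes the interfacial
destabilisation; in both cases no hollow structure forms, matching the
reported parameter sensitivity.

## Default parameters

| parameter | default | why |
|---|---|---|
| grid | $128^2$, `dx = 1` | resolves a 40-cell droplet with interface width ~2 cells |
| `w_eta`, `eps_eta^2` | 4.2, 4 | stability window: with `b1 = 0.14` the seeded plateau is unstable, with `b1 = 0.04` or `psi_c = 0.95` it is stable |
| `w_phi`, `eps_phi^2`, `phi_well_floor` | 0.05, 0.5, 0.1 | shallow amphiphilicity well; the floor keeps `phi` bounded in the dilute phase |
| `b1`, `b2` | 0.14, 0.7 | `b1` from the reported wild-type value; `b2` drives fully dense cores (`eta ~ 1`, reached at high protein) hydrophobic, while the thin default shell stays amphiphilic — the soft gate (`xi = 1`) keeps bound nucleic acid mobile there |
| `alpha` | 0.006 | large enough to stabilise the shell against collapse, small enough not to dissolve the seeded droplet |
| `m_eta`, `m_phi` | 1, 3 | `phi` relaxes faster than `eta` transports |
| `d_chi`, `xi`, `kappa` | 0.5, 1.0, 15 | nucleic-acid diffusivity, gate softness, partition strength; see selectivity below |
| `zeta_protein`, `zeta_dna` | 0.17, 0.05 | the working point: `0.17/0.85 = 0.2` sits inside the `b1`-controlled instability window, `0.17/0.95 = 0.179` outside it |
| `dt`, `t_end` | 0.2, 600 | the semi-implicit scheme is stable here; the hollow state is established by `t ~ 150` and the energy has plateaued well before 600 |

The composition axes of the default state diagram
(`zeta_protein` in 0.06 ... 0.75) bracket the reentrant sequence seen
experimentally: too little protein gives no condensate (`one_phase`),
the working point gives hollow shells, and excess protein fills the
lumen (`homogeneous`).

## Numerical scheme

Semi-implicit Fourier-spectral integration on the periodic grid: stiff
linear operators ($\epsilon^2 k^4$, a constant-coefficient splitting of
the variable-coefficient `phi` flux with coefficient
$\max(1, \max s)$, and linear stabilisation constants `stab_eta = 5
w_eta`, `stab_phi = 2 w_phi`) are treated implicitly; all nonlinear
terms explicitly. The `k = 0` mode of `eta` is untouched, so total
`eta` mass is conserved to round-off. `chi` uses a flux-form
finite-volume step in the variable $u = \chi/K$ with *harmonic* face
mobilities (arithmetic means leak across sharp low-mobility barriers
such as a hydrophilic wall), internally substepped for stability; it
conserves mass to round-off and preserves positivity up to clipping
that is logged and bounded at $10^{-6}$ of the total. The integrator is verified against an independent explicit
Euler oracle, against the analytic linear dispersion relation
$\sigma(k) = -m_\eta k^2 (f''(\bar\eta) + \epsilon_\eta^2 k^2) - \alpha$,
and against the energy-dissipation property of the decoupled
Cahn--Hilliard limit.

## Morphology classification and the state diagram

A state is `one_phase` if no connected dense component
(`eta > 0.5`, the half-well threshold) reaches 100 cells, `hollow` if a
dense component of that size fully encloses a dilute cavity of at
least 20 cells (flood fill from the domain boundary; unreached dilute
pockets are cavities), else `homogeneous`. The steady state is defined
operationally: a run may stop once the relative free-energy change over
the trailing 10% of elapsed time falls below $10^{-5}$. Multiply-hollow
states count as hollow; the label is morphological, not count-based.
Sweeps classify the final snapshot of one seeded, independent run per
composition cell; the default sweep uses a $64^2$ grid with the droplet
geometry scaled accordingly (radius 20), which reproduces the same
label sequence at a quarter of the cost.

## Radial profiling of shell images

The measurement pipeline follows the super-resolution protocol exactly:
(1) Fourier low-pass enhancement -- all radial frequencies above half
the Nyquist frequency are zeroed, which preserves the mean exactly and
is idempotent; (2) annotation of the internal and external surfaces as
ellipses (manual annotations are first-class input; an automatic
external-surface fit via Otsu threshold and second-moment ellipse is
provided, plus a clearly-labelled ray-valley heuristic for suggesting
internal surfaces); (3) twenty intermediate ellipses by linear
parameter interpolation, giving 21 annular bands; (4) per band, the
area-normalised signal (mean intensity; a total-fraction alternative is
exposed) against the normalised distance from the internal surface.
Pixels are assigned to bands by point-in-ellipse tests, inner boundary
excluded, so no pixel is double-counted. Empty bands are reported with
count 0 rather than interpolated.

The asymmetry index
$(\bar S_{inner\ third} - \bar S_{outer\ third})/\bar S$ with a
monotonicity guard (Spearman $\le -0.7$) separates interior-enriched
dsDNA-like profiles (index $\ge 0.2$) from symmetric vesicle-like RNA
profiles (index $< 0.1$ in magnitude).

## Morphometry

`detect_condensates()` mirrors the particle-analysis recipe:
rolling-ball background subtraction (grayscale opening, radius 50 px),
auto (Otsu) or fixed threshold, connected components, hole filling
(`include_holes`) so shells report the whole droplet area, minimum area
0.5 um^2, circularity $4\pi A/P^2$ within 0.8--1.0, border objects
excluded, diameter $2\sqrt{A/\pi}$. The perimeter is the ordered
8-connected contour length (axis steps 1, diagonals $\sqrt 2$), which
matches the polygon perimeter of the reference tool: an axis-aligned
square measures $\approx 0.785$ (correctly rejected) while digital
discs measure 0.90--1.02 (kept; the upper bound accepts up to 1.05 to
absorb discretisation bias). A Crofton-style intercept-count perimeter
was evaluated and rejected because it overestimates the circularity of
squares past the 0.8 cutoff. The hollowness score (core mean over
shell-band mean, core 40% and band the outer 30% of the equivalent
radius, cutoff 0.5, ties homogeneous) operationalises the visual
hollow/homogeneous distinction.

## Synthetic data: what it does and does not emulate

The generator renders elliptical shells with three radial profile
families (interior-peaked linear, symmetric double peak, flat) chosen
to straddle the asymmetry-classifier thresholds, plus droplet panels of
discs, annuli and deliberately elongated (3:1) ellipses with known
rasterised areas. Optics are reduced to a Gaussian PSF (default sigma 1 px = 25 nm) and
photon-limited Poisson noise (default peak 100 photons, background 2,
25 nm pixels); read noise, depth structure, spectral bleed-through and
annotation error are *not* modelled. Each render carries two ground
truths: the analytic pre-PSF band profile and the *noise-free
measurement reference* (the band profile of the PSF-blurred image).
Noise-robustness statistics compare against the latter, because the
procedure performs no deconvolution and the PSF bias is deterministic
and common to both; exactness checks with the PSF off compare against
the former. Recovery statistics on these fixtures validate the
measurement code, not the microscope: they show the banding,
normalisation and classification are unbiased at realistic photon
counts, nothing more.

## Known limitations

* Two-dimensional, periodic domain; no thermal fluctuations.
* The functional is a minimal realisation consistent with the published
  qualitative behaviour; absolute time and length scales are
  dimensionless and not fitted to micrographs.
* The `psi_c` and `b1` switches are verified at the default working
  point; far from it (e.g. very high protein) both perturbed and
  unperturbed systems condense and the switches are not meaningful.
* The lumen-versus-exterior nucleic-acid contrast depends on the coat
  being internalised before the shell seals; the `chi_offset` default
  encodes that observation rather than predicting it.
* Simulation sizes in the test-suite ($128^2$ for single runs, $64^2$
  for sweeps and long conservation checks, $16^2$ for time-integrator
  oracles) were chosen as the smallest grids on which the respective
  phenomena are well resolved.
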
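# hollowcond

Phase-field simulation and quantitative imaging of **hollow biomolecular
co-condensates** — the vesicle-like droplets that FET fusion
oncoproteins (e.g. FUS-ERG) form with microsatellite-containing dsDNA:
a dense protein–DNA shell enclosing a dilute aqueous lumen.

The package is for researchers studying condensate architecture who
need, in one place:

* a **mesoscopic model** of hollow co-condensate formation — three
  coupled order parameters (complex concentration η, amphiphilicity φ,
  nucleic-acid concentration χ) evolving under an Ohta–Kawasaki-type
  free energy,

  F = ∫ [ w_η η²(1−η)² + (ε_η²/2)|∇η|² + (s+s₀)(w_φ/4)(φ²−1)²
        + s (ε_φ²/2)|∇φ|² − b₁ φ q(η) + b₂ φ h(η) ] dx
        + (α/2) Σ_{k≠0} |η̂_k|²/|k|²,

  with conserved Ohta–Kawasaki dynamics for η, non-conserved relaxation
  for φ and gated drift–diffusion for χ (∂χ/∂t = ∇·(M(∇χ − χ∇ln K))),
  integrated by a semi-implicit Fourier-spectral scheme;
* **morphology classification** (one-phase / homogeneous / hollow, via
  flood-fill cavity detection) and composition **state-diagram sweeps**
  that reproduce the reentrant protein dependence of hollow formation;
* the **super-resolution radial-profiling procedure** for condensate
  shells: Fourier low-pass enhancement, elliptical annulus annotation,
  twenty interpolated ellipses, area-normalised band signal against the
  normalised distance from the internal surface;
* ImageJ-style **condensate morphometry**: rolling-ball background
  subtraction (radius 50 px), auto threshold, minimum particle size
  0.5 µm², circularity filter 0.8–1.0, hole filling for shell images,
  diameter from area (d = 2√(A/π)), plus a hollowness score;
* a **synthetic microscopy generator** (elliptical shells with known
  radial profiles, Gaussian PSF, Poisson noise; droplet panels with
  known per-object truth) so every stage is testable without external
  data.

## Worked example

Simulate the default protein–dsDNA system (ψ_C = 0.85, b₁ = 0.14, a
preformed droplet with a DNA-coated surface on a 128² grid), classify
the final state, and measure the radial dsDNA distribution across the
shell:

```r
library(hollowcond)

grid <- grid_spec(128, 128)
params <- model_params()           # psi_c = 0.85, b1 = 0.14, ...
ic <- initial_condition(zeta_protein = 0.17, zeta_dna = 0.05, seed = 1)

traj <- run_simulation(grid, ic, params, t_end = 600, save_every = 100)
final <- final_state(traj)

classify_field_state(final)
#> [1] "hollow"

profile <- radial_chi_distribution(final)
round(profile$signal[c(1, 6, 11, 16, 21)], 3)
#> [1] 0.258 0.249 0.229 0.199 0.170
cor(profile$x, profile$signal, method = "spearman")
#> [1] -1
```

The condensate is hollow, and the dsDNA signal is highest at the
internal surface, decaying monotonically toward the external surface
(Spearman correlation −1 across the 21 bands) — the nested
asymmetric organisation seen in super-resolution images. Re-running
with `model_params(psi_c = 0.95)` (weaker protein–DNA binding) or
`model_params(b1 = 0.04)` (a more hydrophobic protein variant) yields
no hollow condensate; `coupling_mode = "both"` (an amphiphilic
protein–RNA copolymer) yields a symmetric, double-peaked RNA profile
instead.

The imaging side works on any single-channel TIFF:

```r
img <- read_image_tiff("shell.tif")
enhanced <- lowpass_enhance(img)              # half-Nyquist cutoff
outer <- fit_external_ellipse(enhanced)       # automatic calibration
ann <- annulus_annotation(inner = my_inner_ellipse, outer = outer)
band_profile(enhanced, ann, n_bands = 21)

panel <- read_image_tiff("droplets.tif")
objects <- detect_condensates(subtract_background(panel, 50),
                              detection_params(pixel_size_um = 0.05))
```

A thin command-line wrapper with subcommands `simulate`, `sweep`,
`analyze-sted`, `morphometry` and `synthesize` is installed at
`system.file("cli", "hollowcond.R", package = "hollowcond")`.

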
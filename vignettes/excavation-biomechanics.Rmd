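---
title: "Excavation biomechanics of two-layered bird bills: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excavation biomechanics of two-layered bird bills: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Birds that excavate nest cavities load their bills in two mechanically
antagonistic ways: axial impact (pecking/chiselling) and torsion (gouging
and twisting). Bill geometry cannot optimize both at once — a deep, wide
bill is a stiff column that resists buckling under impact but, under a
prescribed twist, develops high surface shear; a narrow bill does the
opposite. `billmech` implements a desk-scale version of this comparative
analysis: it simulates a clade of bill geometries, solves the two loading
regimes with a built-in finite-element (FE) solver, compares the stresses
against closed-form beam metrics, and tests the associations with
phylogenetic comparative statistics.

The pipeline reproduces *directional* (sign-level) claims on synthetic
geometry: the impact and torsion peak stresses are negatively associated
across species, beam theory predicts each regime's FE stress, and the
natural two-material (keratin-over-bone) bill outperforms homogeneous
designs. Absolute stress values depend on mesh resolution, tip-load
distribution, and contact idealization, and are not comparable to any
particular specimen-level study.

# The structural model

## Geometry

A maxilla is idealized as a tapering superelliptic solid of length $L$
(default 0.05 m — all species are scaled to a common length so that
geometry, not size, drives the comparison). Cross-sections satisfy
$|x/A(z)|^p + |y/B(z)|^p = 1$ with half-axes shrinking from the base by a
power law

$$A(z) = \tfrac{w}{2}\left[s + (1-s)\,(1-z/L)^{q_w}\right],$$

and analogously for depth. The parameters and defaults:

| parameter | meaning | default |
|---|---|---|
| `base_width`, `base_depth` | full outer width/depth at the base (m) | per species |
| `shell_thickness` | rhamphotheca layer thickness (m) | 0.0015 |
| `width/depth_taper_exponent` $q$ | taper power; 1 = conical | 1 |
| `section_exponent` $p$ | 2 = ellipse; larger = boxier | 2 |
| `tip_scale` $s$ | residual tip size as a fraction of the base | 0.15 |

`tip_scale` keeps the loaded tip patch a finite surface (a mathematically
sharp tip would make the FE tip load singular and the torsional
compliance of the last slab unbounded); 0.15 gives a blunt-but-pointed
profile comparable to a worn excavating bill. With `tip_scale = 1` the
generator produces prismatic cylinders, which is how the analytic
verification problems are built.

The solid has two conformally bonded material regions: an outer keratin
shell of constant thickness and an inner bony core (an endocast standing
in for trabecular bone — no attempt is made to model trabeculae). Near
the tip, where the shell thickness exceeds the available radius, the core
pinches to a small fraction (20%) of the local section: real bill tips
are effectively solid keratin. Material properties are nanoindentation
values for ramphastid bills — keratin $E = 6.5$ GPa, bone
$E = 12.7$ GPa, $\nu = 0.4$ for both; densities are carried as metadata
only (the analysis is static).

## Meshing

Cross-sections are discretized as a disk (centre node, concentric rings);
the core occupies the inner radial layers and the shell the outer ones,
sharing the interface ring nodes, so the bond is exact by construction
(the continuous-problem limit of a tied contact with a stiff penalty).
Each structured cell is star-tetrahedralized around its centroid with
quad faces split along the diagonal through the smallest global node id —
a rule that makes any two neighbouring cells agree on the shared face
triangulation, so the mesh is watertight and conformal at every
resolution, including across the material interface.

Axial stations always include the two protocol breakpoints: the
measurement-zone centre ($2L/3$) and the tip-patch edge ($0.95\,L$).
Without this, the discrete geometry of the fixed/loaded tip patch changes
with resolution (one station ring at coarse meshes, several at fine
ones), which makes the torsional anchoring stiffness — and hence the
whole transmitted torque — oscillate between refinement levels instead of
converging. Pinning the breakpoints removed that artefact.

## Loading regimes

*Impact*: all basal nodes are fixed; a total force $F = 10$ N (a
woodpecker-scale pecking force) is applied in $-z$ over the outer-surface
nodes within 5% of the length from the tip, distributed in proportion to
lumped nodal surface area so the resultant is exact.

*Torsion*: the tip patch is fixed; the basal nodes receive the
small-rotation displacement field $u_x = -\theta(y - c_y)$,
$u_y = \theta(x - c_x)$, $u_z = 0$ about the $+z$ axis through the
bony-core base centroid, with $\theta = 1.75$ mrad (0.1°). At this angle
the linearization error is $O(\theta^2) \approx 3\times10^{-6}$.

The solver is standard constant-strain Tet4 assembly (sparse symmetric
stiffness, Cholesky factorization, relative-residual check at $10^{-8}$).
Element stresses are constant per tet; nodal von Mises values are
volume-weighted averages over adjacent elements (node-based peaks are
much less noisy than element-based ones under Tet4). Performance per
species and regime is the peak nodal von Mises stress over the
outer-surface band at two-thirds of the length (half-width 2.5% of $L$, a
configurable knob — the protocol's zone centre is fixed but its width is
an operational choice), chosen away from both constrained regions to
avoid local boundary effects.

## Verification and convergence

The FE stack is verified against analytic elasticity: a uniaxial prism
(uniform $\sigma = F/A$), the circular-shaft torsion solution
($\tau = G\theta r/L$, checked as von Mises $\sqrt{3}\tau$), an
Euler–Bernoulli cantilever tip deflection, a uniform-strain patch test
(exact for Tet4), work balance, linearity, and frame invariance. Tet4 is
known to be overstiff in bending; the cantilever check is therefore run
at the refinement where its own convergence plateaus, and the mandatory
convergence harness (`convergence_study()`) mirrors the source protocol:
peak zone stress is recomputed at a ladder of resolutions refined
*proportionally in all three directions*, reporting the percent change
between levels against a 5% criterion. On the default bill the impact
regime plateaus comfortably below 5%; the torsion regime converges more
slowly because the slender tip dominates torsional compliance (its local
discretization error perturbs the transmitted torque globally), which is
documented rather than hidden — the comparative analysis uses a common
resolution across species, so this bias is shared, and the rank-based
statistics are insensitive to it.

# The beam model

Closed-form metrics for a solid elliptical cantilever with half-axes
$a = $ width/2, $b = $ depth/2 (the conversion happens exactly once, in
`beam_metrics()`):

- Euler critical load $P_{cr} = \pi^2 E I_x/(KL)^2$ with $I_x = \pi a b^3/4$
  and $K = 2$ (fixed–free), giving the critical buckling stress
  $\sigma_{cr} = P_{cr}/(\pi a b) = \pi^2 E b^2/(16 L^2)$ — depth alone
  controls impact performance;
- resultant torque $T = \pi G \theta a^3 b^3 / ((a^2+b^2)L)$ and maximum
  surface shear $\tau_{max} = 2T/(\pi a b^2) = 2G\theta a^2 b/((a^2+b^2)L)$
  — both width and depth control torsion performance, in the opposite
  direction.

A combined expression for $\tau_{max}$ circulates with a spurious extra
factor of $\pi$; it is inconsistent with its own two ingredients (the
$\pi$ cancels on substitution) and with the circular-shaft limit
$G\theta r/L$, so the self-consistent form is used. A constant factor has
no effect on any rank-based statistic. The $\tau_{max}$ location
($x=0, y=b$) formally requires $b < a$; following the comparative
protocol the formula is evaluated for all bills regardless, and this
caveat is inherited by any absolute (non-rank) use of the metric.

# The synthetic clade

`generate_clade()` emulates the study system: 15 species in two sister
subclades of 7 and 8 (two families of barbets), on a pure-birth tree
rescaled to unit height with the family split at depth 0.4. Log bill
width and depth evolve by correlated Brownian motion (tip standard
deviation 0.3 on the log scale around means of 13 and 15 mm, evolutionary
correlation 0.8), spanning a narrow/shallow to wide/deep morphospace of
roughly 8–25 mm — the documented range for excavating barbets scaled to a
5 cm bill. Body length is log-normal around 17 cm, positively coupled to
bill size (slope 0.9 on the shared log-deviation, residual sd 0.12).
These defaults were chosen once, from the study system's description, and
constitute the package's study conditions.

What the generator does *not* emulate: curved culmens (the tomial axis is
straight, so "tomial length" is operationalized as the axial extent),
real rhamphotheca thickness variation, internal trabecular architecture,
asymmetry, and measurement error in museum specimens. Passing tests on
this synthetic clade therefore demonstrate that the *pipeline* recovers
the geometric tradeoff and composite advantage where they exist by
construction of the mechanics — not that any particular real clade shows
them.

# Statistics

- **Spearman correlations** use exact p-values for small untied samples
  (n ≤ 10) and the t-approximation otherwise.
- **PGLS with Pagel's λ**: residual covariance $\sigma^2 V(\lambda)$
  where $V(\lambda)$ multiplies the off-diagonal of the tree covariance
  $C$ by $\lambda \in [0,1]$. $\hat\lambda$ maximizes the profile
  likelihood (grid step 0.01 plus local refinement); fits are also
  reported at the fixed treatments $\lambda = 0$ (OLS) and $\lambda = 1$
  (Brownian motion), mirroring the three-way reporting convention used
  when λ is unreliable at small n. Likelihood-ratio tests against each
  bound use the boundary-corrected $\tfrac12\chi^2_1$ reference, with
  p = 1 when the estimate sits on the tested bound. The reported
  adjusted $R^2$ is $1-(1-R^2)(n-1)/(n-2)$ with $R^2$ taken from the GLS
  fit against the GLS intercept-only model under the same $V$ — the exact
  adjusted-$R^2$ convention differs between packages, so equality with
  other software is expected only up to this definition.
- **Wilcoxon signed-rank tests** drop zero differences and use the exact
  distribution for n ≤ 25 untied differences.
- **Phylogenetic paired t-test**: the differences follow
  $d \sim N(\mu 1, \sigma^2 V(\lambda))$ with λ profiled by *restricted*
  maximum likelihood and the t statistic on $n-2$ degrees of freedom.
  REML was chosen deliberately: with 15 species the ML estimate of λ is
  biased downward, which shrinks the standard error of $\mu$ and
  measurably inflates the test's type-I error (our Monte-Carlo
  calibration puts the ML plug-in convention near 0.10–0.12 at nominal
  0.05; REML at roughly 0.08–0.09). A Satterthwaite df adjustment
  overcorrects to ~0.02. Residual mild anticonservatism is intrinsic to
  any plug-in-λ test at this sample size. On a star phylogeny λ is
  inestimable and the test reduces exactly to the ordinary paired t-test
  ($n-1$ df), which is also its verification oracle.
- **BM simulation** draws tip values from the matrix normal
  $\mathrm{vec}(X) \sim N(\text{root}, R \otimes C)$; it is the engine of
  both the clade generator and the calibration tests.

Independent oracles in the test suite pin these routines down: exact
permutation enumeration for Spearman (n = 7), sign-assignment enumeration
for Wilcoxon, OLS for $\lambda=0$, the independent-contrasts
through-origin regression for $\lambda=1$, an external
phylogenetic-signal estimator for $\hat\lambda$, and the ordinary paired
t-test on a star tree.

# Problem sizes and determinism

The default `test` tier (15 species × 6 solves at ~3,000 elements each,
convergence ladders up to ~90,000 elements, calibration loops of 500–1000
replicates at n = 15 and 20 replicates at 128 tips) was sized so that a
complete verification run is a few minutes on one CPU; the `production`
tier raises mesh resolution for final figures. All randomness funnels
through explicit integer seeds (clade generation, simulators, tests), and
a fixed seed reproduces every table byte-for-byte.

# Known limitations

- Static linear elasticity: no impact dynamics, no contact, no material
  or geometric nonlinearity; "impact" is a static equivalent load.
- Tet4 elements are overstiff; absolute stresses carry a
  resolution-dependent bias that cancels only in cross-species
  comparisons at a common resolution. Tet10 would be the natural
  extension.
- The torsion regime's transmitted torque is dominated by the slender
  tip and converges slowly; torsion stresses should be read as
  comparative, not absolute.
- The lofted PLY ingest route assumes surfaces star-shaped about the z
  axis; strongly curved bills would need a true Delaunay backend.
- Beam metrics treat the bill as solid and homogeneous, as in the source
  protocol; the composite structure enters only through the FE model.
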
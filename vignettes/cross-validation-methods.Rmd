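---
title: "Cross-validating multipole refinement strategies: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validating multipole refinement strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcross)
```

# The model

`rcross` works with the Hansen–Coppens aspherical-atom (multipole) model.
Each atom's electron density is

$$\rho(\mathbf r) = \rho_\mathrm{core}(r)
  + P_v\,\kappa^3 \rho_\mathrm{val}(\kappa r)
  + \sum_{l=1}^{4} \kappa'^3 R_l(\kappa' r)
    \sum_{m} P_{lm\pm}\, Y_{lm\pm}(\hat{\mathbf r}),$$

with spherical core and valence densities built from a bundled single-ζ
Slater shell table (exponents after the standard single-ζ best-atom
values), deformation radial functions $R_l(r) \propto r^{n_l} e^{-\zeta
r}$, and real spherical harmonics $Y_{lm\pm}$. Two conventions matter:

* **Angular normalization.** The harmonics are fully orthonormalized
  ($\int Y^2 d\Omega = 1$) rather than density-normalized. The populations
  are therefore coefficients on an orthonormal basis; they differ from the
  conventional density-normalized populations by a fixed per-$(l,|m|)$
  factor. Because the identical functions appear in the real-space density
  and (through the Fourier–Bessel transforms $\langle j_l\rangle$) in the
  scattering factors, every cross-space consistency check is unaffected by
  this choice.
* **One analytic density for both spaces.** The spherical (IAM) form
  factors come from the same Slater shells as the multipole engine, via
  closed-form transforms $\int R(r)\, j_l(4\pi s r)\, r^2\,dr$ (rational
  expressions in $\zeta$ and $K = 4\pi s$, with a Taylor series below
  $K(n+3)/\zeta < 0.9$ to avoid cancellation). This makes "multipole model
  with all $P_{lm}=0$, $\kappa=1$ equals the IAM" exact by construction,
  and lets a discrete Fourier transform of the sampled real-space density
  serve as an independent oracle for the analytic structure factors
  (agreement is required to 0.5% out to $\sin\theta/\lambda = 1.2$ Å⁻¹ and
  measured at ~0.05%).

Displacement uses CIF-convention $U_{ij}$ (Å²), converted internally to
$\beta_{ij} = 2\pi^2 a^*_i a^*_j U_{ij}$, with third-order Gram–Charlier
anharmonicity in the International Tables sign convention:
$T(\mathbf h) = T_\mathrm{harm}(\mathbf h)\,[1 - \tfrac{4\pi^3}{3} i\,
C^{jkl} h_j h_k h_l]$. The convention is not trusted but verified: the
displacement factor must match the numerical Fourier transform of the
corresponding Gram–Charlier probability density function to $10^{-6}$ (a
cross-module test).

Local axes follow common multipole-refinement practice: local $z$ towards
the first reference atom, local $x$ orthogonalized in the plane of the
second, right-handed $y$. Local-symmetry codes (`none`, `m`, `mm2`, `3`,
`cyl`, `cyl_mm`) restrict the allowed multipoles; the allowed sets are
*derived at run time* by numerical invariance of each harmonic under the
point-group generators, never transcribed from a table, so the table
cannot be wrong independently of the harmonics themselves.

# Constraints

Three constraint classes are expressed in one affine map
$p_\mathrm{full} = A f + b$:

* **local-symmetry masks** — symmetry-forbidden populations are identically
  zero;
* **special positions** — the site stabilizer is detected within a
  tolerance (default $10^{-4}$ fractional) and its linear action on
  coordinates, $U_{ij}$, Gram–Charlier tensors and populations is
  projected numerically; the null space of the stacked $(D_g - I)$
  operators is pivot-normalized so that every free parameter *is* one
  designated full component (this is what makes pack→unpack round trips
  bit-exact and constraint application idempotent);
* **chemical ties** — tie groups share the valence parameters ($P_v$,
  $P_{lm}$, $\kappa$, $\kappa'$) of their leader atom.

A classic consequence, reproduced in the tests: an atom on the mirror plane
of an orthorhombic group has $C_{112}$ (and every Gram–Charlier component
with an odd count of the mirror-normal index) forced to zero, and an atom
on an inversion centre loses all odd-$l$ populations and all ten $C_{jkl}$.

# Refinement

Minimization is on $F^2$ (weights $1/\sigma^2(F_o^2)$, matching the HKLF 4
data format) by Gauss–Newton with Levenberg damping; one overall scale is
refined alongside the model. R values are reported on $|F|$ (the scale on
which ΔR differences of order $10^{-3}$ are conventionally plotted) as
well as on $F^2$. Derivatives are analytic for coordinates (phase), $U$
(harmonic exponent), $C_{jkl}$, and all populations (linear); κ and κ′ use
per-atom forward differences. One deliberate approximation: local-axis
orientations are held fixed when differentiating with respect to
coordinates, the usual practice in multipole engines; the resulting ~4%
Jacobian error in coordinate columns affects neither the converged
minimum nor the recovery tests.

Convergence is max |shift/esd| < 0.01 or 50 cycles. A column of the
Jacobian that is exactly null or collinear (released duplicates of the
same parameter, insufficient data) raises an error naming the null-space
parameters; ill-conditioned but non-singular problems proceed under
damping, with pseudo-inverse variances — that distinction is what lets the
forgotten-constraint scenario refine to a diagnosable (rather than fatal)
state.

Strategy steps name parameter classes in the conventional shorthand (M
monopoles, D dipoles, Q quadrupoles, O octupoles, H hexadecapoles, U
displacement, K κ, KP κ′), an optional atom subset, a data filter (all /
low-order / high-order with configurable cuts, defaults 0.5 and 0.8 Å⁻¹),
and constraint edits (release local symmetry, release ties, switch atoms
to anharmonic). The bundled scenario strategies are *cumulative*: each
step refines the newly released classes jointly with everything already
free. Pure one-class-at-a-time refinement stalls on the strongly
correlated $P_v$–κ pair, leaving real signal in the residuals that a later
constraint release would absorb — which would masquerade as model
improvement and destroy the overfit signature. With cumulative selection
the constrained model reaches its optimum before any release, so whatever
the release gains is noise by construction.

Shaking (before each cross-validation member) perturbs coordinates by
N(0, 0.002 fractional) and all six $U_{ij}$ (diagonal multiplicatively at
5%, off-diagonals additively on the scale of the mean diagonal), then
re-applies the constraint map *of the unshaken model* — so special
positions and ties survive the shake exactly, unless a constraint class
has deliberately been switched off to emulate a setup mistake.

# Cross-validation and diagnostics

The partition assigns Friedel/Laue groups, not individual reflections,
whenever Friedel awareness is on; groups are shuffled under the seed and
placed greedily on the smallest set, so set sizes differ by at most one
pairing unit. Each member refines on its training set; every step then
gets a zero-cycle structure-factor calculation on the member's test set,
with the training scale (test data never influence any fitted quantity).
R_cross pools all test records — each reflection exactly once, enforced —
and ΔR tables difference consecutive steps overall and in the low/high
shells split at 0.5 Å⁻¹. The all-data refinement is seeded independently
of the partition, so permuting set labels cannot change it.

Parameter diagnostics emit the five tables: (1) members with
$|v_\mathrm{total} - v_i| > 3 s_\mathrm{total}$; (2) Shapiro–Wilk flags
($W < 0.905$ or $p < 0.05$; the W cut is calibrated for about 20 members
and is conservative at smaller k); (3)
$|v_\mathrm{total}-v_\mathrm{mean}|/s_\mathrm{total} > 0.5$; (4)
$s_\mathrm{mean} > s_\mathrm{total}$; (5) outlier counts per test set.
Because the k refinements share $(k-1)/k$ of the data they are far from
independent: the observed $s_\mathrm{mean}/s_\mathrm{total}$ on the toys
is ~0.3–0.4, well below the independent-refinement expectation given by
the Cochran factor (0.987 at k = 20) — exactly the direction the theory
predicts, which is why $s_\mathrm{mean} > s_\mathrm{total}$ is a genuine
alarm rather than noise.

The per-set R_free scan flags sets above median + 3σ. The reference σ is
the larger of the counting approximation $R/\sqrt{2n}$ and the robust
spread (1.4826·MAD) of the per-set values: the counting formula alone
ignores genuine member-to-member model variation and over-flags at toy
scale, while an overexposed reflection puts its set tens of σ above the
median, so the MAD floor costs no sensitivity. The reflection scan flags
low-order (stol ≤ 0.5 Å⁻¹), strong (top intensity decile), badly
under-observed ($(sF_c^2 - F_o^2)/\sigma \ge 10$) reflections — the
$F_o \ll F_c$ overexposure signature — and reports shell means of
$F_o^2/sF_c^2$.

Kuhs' rule is evaluated as $Q_n = 2\sqrt{n}\,(2\pi)^{-1/2}\sqrt{2\ln 2}\,
\langle u^2\rangle^{-1/2}$ and compared against the data resolution on the
$q = 4\pi\sin\theta/\lambda$ scale (the only scale on which typical
$\langle u^2\rangle$ values make the rule attainable by real data sets).
The Gram–Charlier pdf check reports the minimum pdf value and the
integrated negative probability; a harmonic atom is exactly non-negative.

# Topology

Property maps use the *static* model density (no thermal smearing), H
atoms excluded by default, on 0.1 Å grids over the non-H bounding box
plus 2.5 Å. Error cubes are pointwise sample standard deviations
(denominator k−1) across the member densities. Bond-critical-point
searches run Newton iterations on finite-difference gradients (step
2·10⁻⁵ Å) and Hessians (10⁻³ Å) of the analytic density from the
internuclear midpoint, to $|\nabla\rho| < 10^{-8}$; the Hessian
eigenvalues give ρ, ∇²ρ, the (3,−1) signature test and the ellipticity.
Finite differences were chosen over hand-coded second derivatives of all
multipole terms and validated against the closed-form Laplacian of a
Gaussian (10⁻⁶) and against stencil-size perturbations (BCP position
stable to 10⁻⁴ Å). On a cylindrically symmetric bond the transverse
stencil directions are equivalent, so the degenerate eigenvalue pair is
equal to rounding accuracy and ε < 10⁻⁶ without special handling.

# Synthetic fixtures and what they do (not) show

The generator produces 4–5 atom toy crystals (elements restricted to the
bundled H–F range plus Si/P/S/Cl in the tables) with known ground truth:
a P-1 recovery workhorse, a P1 Friedel scenario, a Pm crystal with an
anharmonic atom on the mirror, a tied/cylindrical pair crystal where
releasing constraints is pure overparameterization, an anharmonic crystal
satisfying Kuhs' rule, and an overexposure scenario. Observations are
$F_o^2 = |F_c|^2(1 + N(0, q))$ with $\sigma = q|F_c|^2 + \text{floor}$
(floor = 2% of the median intensity times max(q, 10⁻⁴)); the default
noise is q = 1%, resolutions 0.8–1.1 Å⁻¹, k = 20 test sets (scaled to
k = 8–10 in the heavier simulation tests to keep the suite fast; the toy
cells have 1–2·10³ reflections). Everything is reproducible byte-for-byte
from (scenario, seed).

What passing these simulations shows: the statistics, constraints and
failure-mode detectors behave as designed on data whose generating model
is known exactly. What they cannot show: behaviour under systematic
errors absent from the noise model (absorption, extinction, thermal
diffuse scattering, Poisson counting statistics), disorder, or
databank-quality radial functions — real-data conclusions still require
the analyst's judgement.

# Known limitations

* The σ(R_free) ≈ R_free/√(2n) approximation assumes per-reflection
  contributions of comparable size. On few-atom toy cells the |F|
  distribution is much heavier-tailed than the Wilson statistics of a
  many-atom crystal (CV² of |F| ≈ 1.4 vs 0.27), and the resampled R_free
  spread exceeds the formula by ~1.6× regardless of the noise model; the
  corresponding acceptance check is therefore expected to fail at toy
  scale even though the formula and the resampling estimator are both
  implemented exactly. The same analysis predicts agreement within ~20%
  in the Wilson regime of realistic structures.
* Refinement offers constraints but no restraints, no extinction,
  absorption or anomalous-dispersion corrections, and no twin handling.
* Pairing for cross-validation covers Friedel/Laue mates only;
  pseudo-symmetry-related reflections are not co-assigned.
* Density maps are static; atomic-basin integration and gradient-path
  tracing are out of scope.

# A minimal session

```{r example, eval = FALSE}
model <- make_toy_crystal("overfit_demo")
refl  <- simulate_fobs(model, seed = 1)
part  <- make_partition(refl, model$spacegroup, k = 10, seed = 1)
cv    <- run_cv(refl, iam_model(model),
                scenario_strategy("overfit_demo", model), part, seed = 100)
delta_r_table(cv)          # the release step is flagged as overfitting
parameter_report(cv)       # five outlier tables across the k members
plot_delta_r(cv)           # paired d<R_work> / dR_cross bars per step
```
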
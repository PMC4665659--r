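---
title: "Estimating hydrogen ADPs by segmented rigid-body analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hydrogen ADPs by segmented rigid-body analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadp)
```

## The model

An anisotropic displacement parameter (ADP) is the covariance of an atom's
Gaussian positional smearing, a symmetric 3×3 tensor U in Å². `hadp`
decomposes every atom's displacement into two statistically independent
parts:

* **external** motion — the molecule moving as a (segmented) rigid body in
  the lattice — and
* **internal** motion — intramolecular vibration about the equilibrium
  geometry.

Non-hydrogen atoms have refined ADPs; hydrogens do not. The estimation
transfers information from the non-H atoms (external part) and from
harmonic normal modes of model compounds (internal part), and sums the two
at each hydrogen site.

### External part: TLS plus attached rigid groups

Rigid-body motion with small amplitudes gives, for an atom at position
$\mathbf r$,

$$ U_{\mathrm{ext}}(\mathbf r) \;=\; T + A L A^{\!\top} + A S + S^{\!\top} A^{\!\top},
   \qquad A = -[\mathbf r - \mathbf o]_\times , $$

where $T$ (Å²) is the translation tensor, $L$ (rad²) the libration tensor,
$S$ (Å·rad) the screw coupling and $\mathbf o$ the origin. Because $A$ is
antisymmetric, adding a multiple of the identity to $S$ does not change
$U_{\mathrm{ext}}$; we therefore impose $\operatorname{tr} S = 0$, the
classic indeterminacy, leaving 6 + 6 + 8 = 20 free parameters. Each
*attached rigid group* (ARG) — a fragment that can librate about a single
torsion bond with unit axis $\mathbf n$ through point $\mathbf p$ — adds

$$ \langle\varphi^2\rangle\, \mathbf v \mathbf v^{\!\top}, \qquad
   \mathbf v = \mathbf n \times (\mathbf r - \mathbf p) $$

for its member atoms. The group libration is modelled as independent of
the body motion: no body–group cross terms are fitted. This is the minimal
physically meaningful extension; a screw-type coupling per group would add
parameters that small molecules rarely constrain well, and the historical
segmented-body codes differ on this point.

The fit is ordinary linear least squares over all 6 tensor components of
all non-H atoms with unit weights (observed ADP uncertainties rarely
survive file formats intact). The origin is the unweighted centroid of the
body non-H atoms; fitted ADPs are origin-invariant ($T$ and $S$ absorb
shifts — a property the test suite checks explicitly), so no
centre-of-reaction transformation is applied. The linear system is solved
by SVD with a relative singular-value cutoff of 1e-10; rank deficiency
(e.g. planar bodies) yields the minimum-norm solution and is reported with
the condition number. Group amplitudes are kept non-negative by
clip-to-zero-and-refit, which is deterministic and needs no constrained
solver.

### Internal part: the coth law

For mass-weighted orthonormal mode vectors $\mathbf l_{A,k}$ with angular
frequency $\omega_k = 2\pi c \tilde\nu_k$,

$$ U_{\mathrm{int},A} \;=\; \sum_{k}\;
   \frac{\hbar}{2 m_A \omega_k}\,
   \coth\!\Big(\frac{\hbar\omega_k}{2 k_B T}\Big)\,
   \mathbf l_{A,k} \mathbf l_{A,k}^{\!\top}. $$

The sum runs over modes whose (optionally scaled) wavenumber is at or
above a **low-frequency cutoff**, default 200 cm⁻¹: slower modes describe
quasi-lattice motion already captured by the TLS fit, and imaginary modes
(stored as negative wavenumbers) are excluded with them. No Eckart
re-projection is performed — the cutoff also removes the six near-zero
rigid-body modes. The frequency scaling factor defaults to 1.0 and is a
plain configuration knob; method-specific empirical factors belong to the
user's quantum-chemistry protocol, not to this package.

Two limits anchor the implementation and are asserted in the tests: at
$T \to 0$ each mode contributes its zero-point amplitude
$\hbar/2m\omega$, and for $\hbar\omega \ll k_B T$ the classical
$k_B T/m\omega^2$ is recovered within 1%. The per-mode normalization gives
a conservation law, $\sum_A m_A\operatorname{tr}U_{\mathrm{int},A} =
\sum_k (\hbar/2\omega_k)\coth(\cdot)$, which the suite verifies to 1e-10.

Internal tensors are stored in a cache keyed by invariom-style
**chemical-environment names** (`H1c[1c1h1h]` for a methyl H, `H1o[1c]`
for a hydroxyl H, …) and by temperature (rounded to 0.1 K; lookups accept
the nearest entry within 1 K, no interpolation — coth is non-linear in T,
and silently interpolated entries would be hard to audit). Each tensor is
expressed in a deterministic **local atomic frame** (z toward the
highest-priority neighbour, x toward the highest-priority second-shell
neighbour; priority = atomic number descending, then label ascending) so
it can be rotated onto any chemically equivalent atom. Name collisions in
the cache resolve first-wins with a warning.

Bond orders are not perceived: candidate torsion axes are the *bridge
bonds* of the heavy-atom skeleton (removal disconnects the molecule),
which excludes ring bonds automatically. This deliberately approximates
"single bonds": double bonds in chains are flagged as candidates too, but
a genuinely rigid double-bonded substituent simply scores $\Omega \ge 0$
and is not accepted.

### Automatic segmentation

For every candidate axis the molecule is split in two; the smaller side
(atom count, H included; ties resolved toward the lower-indexed endpoint)
is the putative ARG. The **rigidity index**

$$ \Omega \;=\; \varepsilon \,\langle \Delta_{\mathrm{intra}}\rangle
   \;-\; \langle \Delta_{\mathrm{inter}}\rangle $$

compares Hirshfeld rigid-bond projection differences
$\Delta = |\,\mathbf n^{\!\top} U_A \mathbf n - \mathbf n^{\!\top} U_B
\mathbf n\,|$ *within* the group (bonded non-H pairs) against those
*across* it (all non-H cross pairs, projected along each pair vector).
$\varepsilon = 2$ by default: a group is accepted when the cross-bond
differences are at least twice the internal ones, i.e. the group is
internally rigid but flexibly attached. Acceptance requires
$\Omega < -10^{-12}$ Å² rather than $\Omega < 0$: with noiseless synthetic
input the deltas of a perfectly rigid body are ~1e-18 Å² of floating-point
rounding, and a strict sign test would accept them; physical signals are
of order 1e-4 Å². Accepted groups of fewer than `min_group_size = 8` atoms
are discarded (too few observations for a stable amplitude), overlapping
acceptances resolve greedily by most-negative Ω, and the body always
retains at least 8 non-H atoms, releasing the weakest groups if necessary.

The detector has a finite noise floor by construction: the planted-group
signal in the synthetic studies is
$\langle\Delta_{\mathrm{inter}}\rangle \sim 5\times10^{-4}$ Å², so ADP
noise of 1e-3 Å² per component genuinely defeats detection — which is why
the noise-robustness tests of the *estimator* fix the segmentation to the
known ground truth and study the least-squares error in isolation.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `temperature` | from file | K | measurement temperature (CLI/argument overrides the file value) |
| `cutoff` | 200 | cm⁻¹ | low-frequency cutoff of the internal sum |
| `freq_scale` | 1.0 | — | multiplicative wavenumber scaling |
| `epsilon` | 2.0 | — | rigidity-index weight |
| `min_group_size` | 8 | atoms | smallest accepted attached group |
| `bond_tolerance` | 0.40 | Å | bonding margin over covalent-radius sums |
| `missing_internal` | `"error"` | — | `"zero"` substitutes zero internal motion with a warning |

## The synthetic-data generator

`make_structure(synth_spec(...))` builds small organic-like test crystals
with exactly known ground truth. The body is a puckered eight-membered
carbon ring — a single cycle has no skeleton bridges (so no spurious
torsion candidates), is three-dimensional (avoiding the planar-body TLS
rank deficiency) and meets the eight-non-H body floor. Topologies add a
rigid tail, a methyl group, a librating nine-atom cyclopentyl group, a
librating chain group of 7 or 8 atoms (exercising the size filter), or a
second rotated copy of the molecule. Defaults emulate a measurement near
100 K: T ≈ 0.02 Å² with ±30% anisotropy, L of a few (degrees)², a traceless
S of ~1e-3 Å·rad, a group libration of 0.01 rad² (≈ (5.7°)²), and mock
modes spanning 80–3200 cm⁻¹ with two modes deliberately below the cutoff.

Observed ADPs are planted as
$U_{\mathrm{obs}} = U_{\mathrm{ext}} + U_{\mathrm{int}} + \text{noise}$
for non-H atoms only; hydrogen ground truth lives in the sidecar record,
mimicking X-ray input. Internal ADPs are assigned *through the same
environment-name database transfer the estimator uses*, so the planted
values are exactly representable by the model and noiseless recovery is
exact to numerical precision (the end-to-end tests assert 1e-8 Å²). Mock
mode vectors are an orthonormal completion of a seeded random matrix —
they satisfy every algebraic property of real eigenvectors but carry no
force-field physics; likewise the noise model (i.i.d. Gaussian on tensor
components) is a convenience, not an error model of refinement. Passing
tests therefore demonstrate the correctness of the estimator's algebra and
bookkeeping, not the physical adequacy of the rigid-body decomposition for
any particular crystal.

## Numerical choices

* Tensor components are ordered u11, u22, u33, u23, u13, u12 everywhere;
  bases are tagged (`cif_star` vs `cartesian`) and converted via
  $U_{\mathrm{cart}} = A D U^\ast D A^{\!\top}$, $D =
  \operatorname{diag}(a^\ast, b^\ast, c^\ast)$, with the
  a-along-x / b-in-xy orthogonalization convention (the common PDB
  convention; the algebra is convention-independent, file round trips are
  not).
* Positive semidefiniteness is tested with tolerance 1e-8 Å². Internal
  subtraction may legitimately produce non-PSD fit targets; estimated
  hydrogen ADPs that are non-PSD are flagged, never clipped.
* The overlap statistic uses the closed form
  $S = 100\,(1 - 2^{3/2}(\det U_1 \det U_2)^{1/4} / \det(U_1+U_2)^{1/2})$,
  clamped to [0, 100] against rounding spill; the suite cross-checks it
  against direct 3-D grid integration of $\int\!\sqrt{p_1 p_2}\,d\mathbf r$
  to 0.05 S-units on random tensor pairs.
* The ADP scaling model is $\kappa U + c$ with scalar $\kappa$ and a
  symmetric additive offset $c$ (7 parameters, Frobenius objective,
  off-diagonal rows weighted $\sqrt 2$); a scale-only mode is available.
  The exact functional form used historically for this correction is not
  uniquely documented; this is the minimal model consistent with its
  published applications, and it is known to degrade when atoms of very
  different mass (e.g. Fe) dominate the fit — such cases are out of scope.
* Problem sizes in the test suite were chosen so the whole suite runs in
  well under a minute of CPU: 25–50-atom synthetic structures, 1e6-sample
  Monte-Carlo checks of the TLS formula (agreement asserted at
  5·10⁻³ of the tensor magnitude, commensurate with the sampling error of
  a covariance at that sample count), 61³-point integration grids.

## Scope and limitations

* Disordered structures (partial occupancies / split sites) and molecules
  on special positions are detected and refused; the file readers still
  load them.
* Bond-order perception, aromaticity, nested attached groups (a group
  hanging off another group) and body–group screw coupling are not
  modelled.
* The QM-log parser reads the common Gaussian frequency-output layout
  (orientation table, `Frequencies --` blocks, thermochemistry masses);
  other programs' logs should be converted to the documented neutral mode
  format.
* No standard uncertainties are produced for fitted TLS or scaling
  parameters.
* XD-dialect `.res` files differ from SHELX in ways this package does not
  model; they are unsupported.
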
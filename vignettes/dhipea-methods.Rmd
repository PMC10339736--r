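---
title: "Methods: double-hybrid ionization potentials and electron affinities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-hybrid ionization potentials and electron affinities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhipea)
```

## The model

`dhipea` treats vertical electron detachment and attachment for a
closed-shell reference described by spatial orbitals with energies
$\varepsilon_p$ (hartree). Indices $i, j, k$ run over active occupied
orbitals, $a, b, c$ over virtuals, and $P, Q$ over an auxiliary
(density-fitting) basis. All two-electron repulsion integrals
$(ia|jb)$ (Mulliken convention) are represented through the
density-fitting factorization
$$
K_{ia,jb} = (ia|jb) = \sum_Q J_{ia}^Q J_{jb}^Q, \qquad
\mathbf J = \mathbf I\,\mathbf V^{-1/2},
$$
where $\mathbf I$ holds the three-center Coulomb integrals and
$\mathbf V$ the two-center Coulomb metric over the auxiliary functions.
The whole artifact sits *behind* the SCF: a backend adapter supplies
converged orbitals, energies, and the AO-basis $\mathbf I$ and
$\mathbf V$; no exchange–correlation evaluation, grid, or SCF iteration
lives here. For a pure or hybrid functional the charged-state problem is
already solved by the orbital energies themselves; the package's subject
is the scaled second-order machinery that double hybrids add on top.

### First order

In the basis of singly ionized (attached) determinants the secular
problem is diagonal with unit eigenvectors: $\mathrm{VIP}^{(1)}_{\bar k}
= -\varepsilon_{\bar k}$ and the attachment energy
$\omega^{(1)}_{\bar c} = +\varepsilon_{\bar c}$. `first_order_states()`
reports these from the channel edge inward, preserving the backend's
stable order among degenerate orbitals.

### The perturbative (CIS(D)-type) ansatz

The second-order (D) correction for target orbital $\bar k$ is the
diagonal second-order self-energy evaluated at the fixed frequency
$\omega = \varepsilon_{\bar k}$ — the frequency-independent, diagonal
approximation. Spin-resolved, for ionization out of $\bar k$:
$$
\omega^{(D)}_{\mathrm{OS}} =
 -\sum_{jla} \frac{(\bar k j|al)^2}
             {\varepsilon_{\bar k} + \varepsilon_a - \varepsilon_j - \varepsilon_l}
 \;-\; \sum_{jab} \frac{(\bar k a|jb)^2}{D_{\bar k j}^{ab}},
 \qquad
 D_{ij}^{ab} = \varepsilon_i + \varepsilon_j - \varepsilon_a - \varepsilon_b,
$$
and the same-spin part replaces each squared direct integral by the
antisymmetrized square with a configuration weight of one half, e.g.
$\tfrac12\,[(\bar k j|al)-(\bar k l|aj)]^2$ in the first (2h1p) sum.
The final value is
$\mathrm{VIP} = -\varepsilon_{\bar k} + c_{\mathrm{OS}}\,
\omega^{(D)}_{\mathrm{OS}} + c_{\mathrm{SS}}\,\omega^{(D)}_{\mathrm{SS}}$;
attachment mirrors this with the opposite overall sign of the
self-energy contribution. Implementation-wise the 2h1p sum is folded
directly from the `build_v_ija()` intermediate
(cost $N_{occ}^2 N_{virt} N_{aux}$, since one occupied index is pinned
to $\bar k$), and the 2p1h sum is contracted through the row-restricted
$Y$ intermediate of the MP2 module,
$Y_{ia}^Q = \sum_{jb} \tilde u_{ij}^{ab} J_{jb}^Q$ with
$\tilde u = c_{\mathrm{OS}} t + c_{\mathrm{SS}}(t - t^\top)$ built from
the doubles amplitudes $t_{ij}^{ab} = (ia|jb)/D_{ij}^{ab}$. Both steps
are $N^4$; ionization never references a virtual–virtual integral
factor, and attachment touches them only through the single
fixed-index slice $J_{\bar c a}^Q$.

Because the extracted source text of the underlying equations was not
available verbatim, the working equations above were re-derived from the
standard second-order self-energy algebra under the constraints the
method statement fixes (cost exponents, which $J$ blocks are needed, and
the identification with the diagonal frequency-independent
self-energy); the test suite then anchors every term, including the
OS/SS split, to an *independently coded* spin-orbital enumeration
oracle.

### The iterative (non-Dyson ADC(2)-type) ansatz

The iterative ansatz couples the singles (1h or 1p) space to the doubles
(2h1p or 2p1h) space. The doubles block is diagonal at zeroth order, so
it is never stored: its effect is applied analytically as a fold,
leaving the nonlinear singles-space problem
$$
\big[\,\mathrm{diag}(\mp\varepsilon) \pm \mathbf B +
\mathbf C\,(\omega\mathbf 1 - \mathbf D)^{-1}\mathbf C^\top\big]\,
\mathbf c = \omega\,\mathbf c ,
$$
with $\mathbf D$ the doubles configuration energies
($\varepsilon_a - \varepsilon_i - \varepsilon_j$ for 2h1p,
$\varepsilon_a + \varepsilon_b - \varepsilon_i$ for 2p1h). The static
second-order singles block $\mathbf B$ generalizes the 2p1h (2h1p) term
of the perturbative correction off the diagonal. It is built from
ground-state MP2 amplitudes, i.e. with orbital-energy denominators and
no $\omega$ dependence, which is exactly why it can be precomputed once
per (reference, channel) job from the unrestricted $Y$ intermediate —
the single $N^5$ step, counted by `read_counters()$y_builds` and
independent of how many states are subsequently solved. Since the raw
contraction $S_{ij} = \sum_{aQ} J_{ia}^Q Y_{ja}^Q$ is not symmetric off
the diagonal, $\mathbf B = \tfrac12(\mathbf S + \mathbf S^\top)$ is the
symmetrization; its diagonal reproduces the perturbative term exactly,
which is the property the tests pin down.

Scaling convention: second-order *blocks* ($\mathbf B$ and every folded
product $\mathbf C(\cdot)\mathbf C^\top$) carry one power of their spin
scale. Operationally the couplings are weighted by
$\sqrt{c_{\mathrm{OS}}}$ or $\sqrt{c_{\mathrm{SS}}}$ per configuration
class, so the folded products — and the doubles weight entering the pole
strength — scale linearly in $(c_{\mathrm{OS}}, c_{\mathrm{SS}})$. With
both scales zero the operator degenerates to the diagonal and the
solver returns the Koopmans value in one macro-iteration, exactly.

**Solver.** The nonlinearity is handled by macro-iterations: $\omega$ is
frozen, the resulting symmetric folded operator is diagonalized by a
Davidson method, $\omega$ is updated to the selected Ritz value, and the
cycle repeats until $|\Delta\omega| \le$ `conv_energy`
($10^{-6}\,E_h$ by default). Root following selects, at every Davidson
step, the Ritz vector of maximum overlap with the anchor — initially the
unit vector of the target orbital, re-anchored to the previous converged
iterate after each macro-iteration — rather than the lowest eigenvalue,
so a deep ionization whose state is, say, the third root is tracked
correctly. Folding a linear eigenproblem is exact, so a converged
$(\omega, \mathbf c)$ of the folded iteration is an exact eigenpair of
the explicit singles$\oplus$doubles matrix; the dense oracle exploits
this by simply diagonalizing that matrix.

**Pole strength.** The doubles amplitudes of a converged state are
recovered analytically, $\mathbf d = (\omega\mathbf 1 -
\mathbf D)^{-1}\mathbf C^\top \mathbf c$ with the scale-weighted
couplings, and the pole strength is $1/(1 + \|\mathbf d\|^2)$ — the
squared singles-block norm of the normalized full vector. First-order
contributions are unscaled while all second-order contributions carry
their spin scale. More than one normalization of a scaled pole strength
is conceivable; this dense-oracle-anchored reading is the one
implemented, it is stated in the report metadata
(`pole_strength_convention`), and it has the required limits: exactly 1
at zero scales, monotonically decreasing with growing second-order
weight.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `c_os`, `c_ss` | from functional | – | spin scales on all second-order terms; `(0, 0)` = hybrid/Koopmans limit, `c_ss = 0` = SOS |
| `drop_tol` | `1e-10` | relative | metric eigenvalues below `drop_tol * max` are discarded (auxiliary-basis linear dependence) |
| `degeneracy_tol` | `1e-8` | $E_h$ | smallest admissible MP2 or folded denominator; the calculation aborts (no level shift) because the methods presuppose a gapped closed-shell reference |
| `conv_energy` | `1e-6` | $E_h$ | macro-iteration threshold on $|\Delta\omega|$ |
| `resid_tol` | `1e-5` | – | Davidson residual tolerance, chosen to under-resolve `conv_energy` so the inner solver never limits the energy accuracy |
| `max_subspace` / collapse | 20 / 2 | vectors | Davidson subspace cap, collapsed onto the two best-overlap Ritz vectors; fixed for reproducibility |
| `overlap_floor` | 0.3 | – | below this maximum overlap the followed root is declared lost |
| `gap_min`, `sigma` | 0.2, 0.05 | $E_h$ | toy generator: guaranteed HOMO–LUMO gap and three-center magnitude scale |

Numerical conventions: the metric inverse square root uses a symmetric
eigendecomposition (not a Cholesky of $\mathbf V^{-1}$), matching the
$\mathbf J = \mathbf I\mathbf V^{-1/2}$ form; the auxiliary index is the
fastest-varying storage dimension because every hot contraction sums
over it; orbital energies are ascending within the occupied and virtual
blocks with backend order preserved under exact degeneracy (stable
tie-break); orthogonalization inside Davidson is modified Gram–Schmidt
applied twice in arrival order, so runs are bit-reproducible.

## Design choices on genuinely open points

- **(D) denominators.** The perturbative correction uses plain
  DH-reference orbital energies in all denominators — no level shift and
  no self-consistency in $\omega$ at this level. The folded solver is
  where relaxation is bought.
- **Range-separated functionals.** The adapter contract carries an
  optional attenuated two-center metric (`metric_attenuated`), but by
  default the second-order terms use full-range integrals. The hook
  exists so an RS-aware backend can supply the attenuated metric without
  any change to the correlated code; this default is deliberate and
  flagged rather than silently assumed.
- **EA reporting sign.** The package natively reports the *attachment
  energy* $\varepsilon_{\bar c} + \text{correction}$ (negative =
  unbound); `ea_sign: ea` in a job flips the sign for users who prefer
  the electron-affinity convention.
- **Registry values.** The shipped functional table is authoritative for
  the class, the default ansatz, and the empirical-parameter count of
  each entry. The numeric parameters (exact-exchange fraction, spin
  scales, range-separation parameter) carry a per-row `param_source`
  field: rows marked `representative` hold family-typical values and
  the defining publication in the `citation` column should be consulted
  before production use.
- **Spin adaptation.** Production code implements closed-shell
  spatial-orbital formulas; the OS/SS split is *validated* (not defined)
  against the spin-orbital oracle, in which opposite- and same-spin
  configuration classes separate exactly.

## What the synthetic references emulate — and what they do not

`make_toy_reference()` produces random orthonormal MO coefficients,
occupied energies in $[-2, -0.5]\,E_h$, virtuals in a window opening
`gap_min` above $-0.5\,E_h$ (fixed global windows, so direct sums of
fragments keep the gap), and symmetric random AO three-center factors of
magnitude `sigma` over a well-conditioned SPD metric. With the default
`sigma = 0.05` the second-order corrections stay small against the gap,
keeping every folded state single-root dominant — the regime the scaled
second-order methods are designed for, and the regime in which "the root
belonging to orbital $\bar k$" is well defined. Fragmented toys are
exact direct sums, which is what makes the size-intensivity checks
sharp.

What the toys do *not* emulate: realistic integral magnitudes, sparsity
or decay structure of Gaussian-basis integrals, near-degenerate valence
manifolds, or core-hole physics. Passing the oracle-equivalence suite
therefore certifies the *algebra* (contractions, folds, spin classes,
scalings) on gapped references, not the accuracy of any functional on
real molecules — accuracy assessment requires real SCF backends and
external benchmark geometries, which are out of scope here.

Oracles are deliberately an independent code path: four-index integrals
by the naive $\mathbf I\mathbf V^{-1}\mathbf I^\top$ contraction with a
dense Kronecker MO transform, and all second-order quantities by
explicit enumeration over spin-orbital 2h1p/2p1h configurations. They
share no contraction kernels with the production modules and are
size-guarded (occ $\le 6$, virt $\le 8$).

## Problem sizes

The shipped fixture manifest (`toy_manifest()`) spans 20 perturbative
toys (2–5 occupied, 3–7 virtual, 10–25 auxiliary; `sigma` up to 0.10)
and 10 iterative toys (2–4 occupied, 3–5 virtual, `sigma = 0.05`), sizes
at which the dense configuration spaces stay a few hundred dimensions
and each oracle evaluation completes in well under ten seconds. The
cost-scaling check uses a ladder from (4, 6, 20) to (12, 18, 60) and
verifies a log–log slope of 1 against the nominal
$N_{occ}^2 N_{virt} N_{aux}$ count within 15 %.

## Known limitations

- Closed-shell, gapped references only: quasi-degenerate denominators
  abort by design; there is no open-shell or multireference path.
- In the shake-up regime (second-order couplings comparable to the gap,
  e.g. deep ionizations with large `sigma`), no root is singles-dominant
  and maximum-overlap root following can hop between near-degenerate
  mixed roots; the iterative fixtures deliberately stay out of this
  regime.
- The $N^4$ SOS shortcut via Laplace transformation is not implemented;
  SOS is realized as `c_ss = 0` inside the standard $N^5$ contraction,
  which is irrelevant at toy scale.
- No integral screening or sparsity; dense contractions throughout.
- Dyson orbitals, transition moments beyond the simplified pole
  strength, and third-order schemes are out of scope.
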
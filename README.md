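# dhipea

Double-hybrid vertical ionization potentials and electron affinities in R.

`dhipea` computes vertical ionization potentials (VIPs) and vertical
electron affinities (VEAs) of closed-shell molecules at double-hybrid (DH)
density functional levels, for computational chemists who want the
correlated charged-state machinery — not the SCF — in an inspectable,
fully tested form. The self-consistent-field step is delegated to a
pluggable backend adapter; everything downstream of the converged orbitals
(density-fitted integral factorization, MP2 intermediates, the perturbative
and iterative charged-state solvers) is implemented here and validated
against independent brute-force oracles.

## The methods

At first order, the ionized or attached states in the basis of singly
ionized/attached determinants are trivial: the VIP of orbital *k̄* is
−ε<sub>k̄</sub> and the attachment energy of orbital *c̄* is
+ε<sub>c̄</sub> (Koopmans). Pure and hybrid functionals stop here. Double
hybrids add a scaled second-order correction, in one of two ansätze:

- **CIS(D)-based (perturbative).** A second-order (D) correction is added
  *a posteriori*:

      VIP = −ε_k̄ + c_OS · ω(D)_OS + c_SS · ω(D)_SS

  where the opposite-spin and same-spin parts of ω(D) are the 2h1p and
  2p1h configuration sums of the diagonal second-order self-energy
  Σ<sup>(2)</sup><sub>k̄k̄</sub>(ω) evaluated at the fixed frequency
  ω = ε<sub>k̄</sub> (the frequency-independent, diagonal approximation).
  The spin scales (c_OS, c_SS) come from the functional; a global
  correlation fraction α_C is the special case c_OS = c_SS = α_C, and
  spin-opposite scaling (SOS) is c_SS = 0. Cost is N⁴: one occupied index
  of every intermediate is pinned to the target orbital, and ionization
  never touches the unoccupied–unoccupied integral block.

- **ADC(2)-based (iterative).** The non-Dyson secular problem couples the
  1h (or 1p) space to the 2h1p (or 2p1h) space. The doubles block is
  diagonal at zeroth order and is folded analytically, giving a nonlinear
  singles-space eigenproblem

      σ(c, ω) = [ diag(−ε_occ) + B + C (ω − D)⁻¹ Cᵀ ] c = ω c

  with a static second-order singles block **B** built once from
  ground-state MP2 amplitudes (the one N⁵ step, independent of the number
  of states) and scale-weighted second-order terms. It is solved by a
  root-following Davidson algorithm inside a macro-iteration on ω
  (threshold 10⁻⁶ E<sub>h</sub>), tracking the maximum-overlap root rather
  than the lowest one. Because the singles coefficients relax, pole
  strengths below unity become available; the perturbative ansatz always
  has pole strength exactly 1.

Two-electron integrals enter only through the density-fitting
factorization **K** = **J J**ᵀ with **J** = **I V**<sup>−1/2</sup>, built
block-selectively (occ–virt and occ–occ blocks; virt–virt factors only as
on-demand single-index slices for attachment).

Energies are hartree internally; eV appears only at the reporting boundary
(27.211386245988 eV/E<sub>h</sub>).

## Worked example

No quantum chemistry program is needed to try the machinery: the fixtures
module generates deterministic synthetic reference states (random
orthonormal orbitals, a guaranteed HOMO–LUMO gap, seeded random DF
factors) that stand in for converged SCF output.

```r
library(dhipea)

report <- run_job(list(
  method = "adc2", channel = "both", n_states = 2,
  scales = c(1.2, 0.5),                      # (c_OS, c_SS)
  toy = list(n_occ = 4, n_virt = 6, n_aux = 20, seed = 7)))
print(report)
```

```
Job: custom(1.2,0.5) / adc2
 channel orbital omega1_eV final_eV niter pole_strength converged
      ip    HOMO   14.0584  14.1034     2     0.9994948      TRUE
      ip  HOMO-1   38.1880  38.1716     3     0.9971102      TRUE
      ea    LUMO   -1.3937  -1.4187     3     0.9985713      TRUE
      ea  LUMO+1    1.7857   1.7555     3     0.9981674      TRUE
```

`omega1_eV` is the first-order (Koopmans) value, `final_eV` the
relaxed DH result after the iterative second-order treatment, `niter` the
macro-iteration count of the folded solver, and `pole_strength` the
singles-block weight of the converged state (1 would be a pure
one-particle transition; the negative LUMO value is an unbound attachment
at this level). The same job with `method = "cisd"` gives the perturbative
numbers, and `method = "orbital_energies"` stops at first order, as a
hybrid functional would.

The same run is available from a shell:

```sh
Rscript exec/dhipea run --config job.yaml --output report.json
```

Lower-level surfaces (`build_metric_inverse_sqrt()`, `build_df_tensor()`,
`mp2_energy()`, `vip_correction()`, `prepare_sigma_workspace()`,
`solve_state()`, `pole_strength()`, …) expose each stage separately; the
registry of benchmark functionals is available through
`functional_registry()` and `resolve_functional("PBE-QIDH")`.

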
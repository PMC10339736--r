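#' Construct a self-consistent-field reference state
#'
#' The reference state is the sole interface between the correlated stages
#' and the DFT/HF backend: molecular-orbital coefficients, orbital energies
#' (hartree), the frozen-core/occupied/virtual partition, and the functional
#' under which the reference was produced.
#'
#' Orbital energies must be ascending within the occupied block and within
#' the virtual block (aufbau filling of the closed-shell determinant); among
#' degenerate orbitals the backend-supplied order is preserved.
#'
#' @param mo_coefficients AO x MO coefficient matrix.
#' @param orbital_energies Numeric vector of MO energies in hartree.
#' @param n_frozen_core,n_occupied_active,n_virtual Space partition counts;
#'   they must sum to the MO count.
#' @param produced_by `functional_config` of the generating functional.
#' @return Object of class `reference_state`.
#' @export
reference_state <- function(mo_coefficients, orbital_energies,
                            n_frozen_core, n_occupied_active, n_virtual,
                            produced_by = scaled_functional(1, 1)) {
  eps <- as.numeric(orbital_energies)
  nmo <- length(eps)
  n_frozen_core <- as.integer(n_frozen_core)
  n_occupied_active <- as.integer(n_occupied_active)
  n_virtual <- as.integer(n_virtual)
  if (!all(is.finite(eps)))
    stop("orbital energies must be finite", call. = FALSE)
  if (n_frozen_core + n_occupied_active + n_virtual != nmo)
    stop("space partition inconsistent with MO count", call. = FALSE)
  if (!is.matrix(mo_coefficients) || ncol(mo_coefficients) != nmo)
    stop("mo_coefficients must have one column per MO", call. = FALSE)
  n_occ <- n_frozen_core + n_occupied_active
  if (n_occ > 1L && is.unsorted(eps[seq_len(n_occ)]))
    stop("occupied orbital energies must be ascending", call. = FALSE)
  if (n_virtual > 1L && is.unsorted(eps[n_occ + seq_len(n_virtual)]))
    stop("virtual orbital energies must be ascending", call. = FALSE)
  if (n_occ >= 1L && n_virtual >= 1L &&
      eps[n_occ] > eps[n_occ + 1L])
    stop("occupied/virtual partition violates aufbau filling", call. = FALSE)
  structure(
    list(mo_coefficients = mo_coefficients, orbital_energies = eps,
         n_frozen_core = n_frozen_core,
         n_occupied_active = n_occupied_active, n_virtual = n_virtual,
         produced_by = produced_by),
    class = "reference_state")
}

#' @export
print.reference_state <- function(x, ...) {
  cat(sprintf(
    "Reference state: %d MOs (%d frozen core, %d active occupied, %d virtual)\n",
    length(x$orbital_energies), x$n_frozen_core, x$n_occupied_active,
    x$n_virtual))
  homo <- x$n_frozen_core + x$n_occupied_active
  if (homo >= 1L && x$n_virtual >= 1L)
    cat(sprintf("  HOMO %.6f Eh, LUMO %.6f Eh, gap %.6f Eh\n",
                x$orbital_energies[homo], x$orbital_energies[homo + 1L],
                x$orbital_energies[homo + 1L] - x$orbital_energies[homo]))
  cat("  produced by:", x$produced_by$name, "\n")
  invisible(x)
}

## Index helpers for the active spaces (frozen core excluded).
.active_occ_idx <- function(ref) ref$n_frozen_core + seq_len(ref$n_occupied_active)
.virt_idx <- function(ref) {
  ref$n_frozen_core + ref$n_occupied_active + seq_len(ref$n_virtual)
}
.eps_occ <- function(ref) ref$orbital_energies[.active_occ_idx(ref)]
.eps_virt <- function(ref) ref$orbital_energies[.virt_idx(ref)]

#' Acquire a converged reference from an SCF backend
#'
#' The backend is a formal adapter: any object with a `converge(mol, func)`
#' function returning the converged closed-shell reference plus handles to
#' the AO-basis density-fitting integrals (the three-center (AO AO | aux)
#' tensor and the two-center Coulomb metric over the auxiliary basis). No
#' exchange-correlation evaluation, integration grid, or SCF iteration code
#' lives in this package.
#'
#' The backend's return value must be a list with elements
#' `mo_coefficients`, `orbital_energies`, `n_frozen_core`,
#' `n_occupied_active`, `n_virtual`, `ao_three_center` (array, dims
#' `c(n_aux, n_ao, n_ao)`, symmetric in the two AO indices), and `metric`
#' (n_aux x n_aux symmetric positive definite). An optional
#' `metric_attenuated` element may supply an attenuated (range-separated)
#' Coulomb metric; by default the full-range metric is used everywhere.
#'
#' @param mol A `molecule_spec`; the closed-shell contract
#'   (`spin_multiplicity == 1`) is enforced before the backend is invoked.
#' @param func `functional_config` the backend should converge.
#' @param backend Adapter object (list with a `converge` function), e.g.
#'   [toy_backend()].
#' @return A list with elements `ref` (a `reference_state`) and `ao`
#'   (the AO integral handles as returned by the backend).
#' @export
acquire_reference <- function(mol, func, backend) {
  if (!inherits(mol, "molecule_spec"))
    stop("mol must be a molecule_spec", call. = FALSE)
  if (mol$spin_multiplicity != 1L)
    stop("closed-shell reference required: spin_multiplicity must be 1",
         call. = FALSE)
  if (!is.list(backend) || !is.function(backend$converge))
    stop("backend must provide a converge(mol, func) function", call. = FALSE)
  out <- backend$converge(mol, func)
  ref <- reference_state(out$mo_coefficients, out$orbital_energies,
                         out$n_frozen_core, out$n_occupied_active,
                         out$n_virtual, produced_by = func)
  ao <- list(ao_three_center = out$ao_three_center, metric = out$metric,
             metric_attenuated = out$metric_attenuated)
  list(ref = ref, ao = ao)
}

#' A backend adapter around a synthetic toy reference
#'
#' Wraps a pre-built synthetic reference (see [make_toy_reference()]) in the
#' SCF-backend adapter contract, ignoring the molecular geometry. Useful for
#' end-to-end driver runs without an external quantum chemistry program.
#'
#' @param n_occ,n_virt,n_aux,seed,... Passed to [make_toy_reference()].
#' @return A backend adapter list with a `converge` function.
#' @export
toy_backend <- function(n_occ = 4L, n_virt = 6L, n_aux = 20L, seed = 7L, ...) {
  args <- list(n_occ = n_occ, n_virt = n_virt, n_aux = n_aux, seed = seed, ...)
  list(
    name = "toy",
    converge = function(mol, func) {
      toy <- do.call(make_toy_reference, args)
      list(mo_coefficients = toy$ref$mo_coefficients,
           orbital_energies = toy$ref$orbital_energies,
           n_frozen_core = toy$ref$n_frozen_core,
           n_occupied_active = toy$ref$n_occupied_active,
           n_virtual = toy$ref$n_virtual,
           ao_three_center = toy$ao$ao_three_center,
           metric = toy$ao$metric)
    })
}
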
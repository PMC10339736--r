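## Ground-state DF-MP2.
##
## Amplitudes are never stored as a full four-index object: everything is
## evaluated per occupied pair from the J factors, with the orbital-energy
## denominators D_ij^ab = eps_i + eps_j - eps_a - eps_b formed on the fly.
## The spin-opposite-scaled variant is realized by c_ss = 0 inside the
## standard contraction (no Laplace-transform shortcut).

.default_degeneracy_tol <- 1e-8

## D_ij^ab as a virt x virt matrix for one occupied pair
.pair_denominator <- function(eps_occ, eps_virt, i, j) {
  outer(-eps_virt, -eps_virt, "+") + eps_occ[i] + eps_occ[j]
}

## J_ia factors of one occupied orbital as a (rank x virt) matrix
.j_occ_slice <- function(df, i) {
  matrix(df$J_ia[, i, ], df$n_aux_effective, df$n_virt)
}

## (ia|jb) as a virt x virt matrix for one occupied pair
.pair_integrals <- function(df, i, j) {
  W <- crossprod(.j_occ_slice(df, i), .j_occ_slice(df, j))
  .count_flops(as.numeric(df$n_aux_effective) * df$n_virt^2)
  W
}

#' MP2 doubles amplitudes for one occupied pair
#'
#' Returns the virt x virt block `t_ij^ab = (ia|jb) / D_ij^ab`, with the
#' integrals reconstructed from the DF factors.
#'
#' @param df A `df_tensor`.
#' @param eps List with `occ` and `virt` orbital-energy vectors (hartree),
#'   e.g. from [orbital_energy_blocks()].
#' @param i,j Active occupied indices.
#' @param degeneracy_tol Smallest admissible `|D_ij^ab|`; below it the
#'   reference is flagged as quasi-degenerate and the calculation aborts.
#' @return virt x virt matrix of amplitudes.
#' @export
pair_amplitudes <- function(df, eps, i, j,
                            degeneracy_tol = .default_degeneracy_tol) {
  D <- .pair_denominator(eps$occ, eps$virt, i, j)
  if (min(abs(D)) < degeneracy_tol)
    stop("quasi-degenerate reference: |D_ij^ab| below degeneracy tolerance",
         call. = FALSE)
  .pair_integrals(df, i, j) / D
}

#' Orbital-energy blocks of a reference state
#'
#' @param ref A `reference_state`.
#' @return List with `occ` (active occupied) and `virt` energies in hartree.
#' @export
orbital_energy_blocks <- function(ref) {
  list(occ = .eps_occ(ref), virt = .eps_virt(ref))
}

#' Spin-resolved DF-MP2 correlation energy
#'
#' Opposite-spin and same-spin contributions are accumulated separately and
#' combined as `E = c_os * E_os + c_ss * E_ss`. For a gapped closed-shell
#' reference both parts are non-positive.
#'
#' @inheritParams pair_amplitudes
#' @param scales Length-2 numeric `(c_os, c_ss)`.
#' @return List with `os`, `ss`, `scaled` (hartree).
#' @export
mp2_energy <- function(df, eps, scales = c(1, 1),
                       degeneracy_tol = .default_degeneracy_tol) {
  n_occ <- df$n_occ
  E_os <- 0; E_ss <- 0
  for (i in seq_len(n_occ)) for (j in seq_len(n_occ)) {
    D <- .pair_denominator(eps$occ, eps$virt, i, j)
    if (min(abs(D)) < degeneracy_tol)
      stop("quasi-degenerate reference: |D_ij^ab| below degeneracy tolerance",
           call. = FALSE)
    W <- .pair_integrals(df, i, j)
    E_os <- E_os + sum(W * W / D)
    E_ss <- E_ss + sum(W * (W - t(W)) / D)
  }
  list(os = E_os, ss = E_ss,
       scaled = scales[1] * E_os + scales[2] * E_ss)
}

#' The Y intermediate
#'
#' Contraction of the three-center factors with the (scale-weighted) MP2
#' amplitudes: `Y[Q, i, a] = sum_jb u_ij^ab J[Q, j, b]`, where
#' `u = c_os * t + c_ss * (t - t_swapped)` combines the direct
#' (opposite-spin) and antisymmetrized (same-spin) amplitudes, each
#' pre-multiplied by its scale. With scales `(1, 1)` this is the unscaled
#' definition. The full build is the one N^5 step of the iterative ansatz
#' and is counted by the `y_builds` counter; `rows` restricts the build to
#' selected occupied rows, which realizes the N^4 restricted evaluation of
#' the perturbative corrections.
#'
#' @inheritParams mp2_energy
#' @param rows Optional integer vector of occupied rows to build; default
#'   all rows (counts as a full N^5 build).
#' @return Array `(n_aux_eff, length(rows), n_virt)`.
#' @export
build_Y <- function(df, eps, scales = c(1, 1), rows = NULL,
                    degeneracy_tol = .default_degeneracy_tol) {
  full <- is.null(rows)
  if (full) rows <- seq_len(df$n_occ)
  if (full) .dh_counters$y_builds <- .dh_counters$y_builds + 1L
  rank <- df$n_aux_effective
  Y <- array(0, c(rank, length(rows), df$n_virt))
  for (ri in seq_along(rows)) {
    i <- rows[ri]
    for (j in seq_len(df$n_occ)) {
      D <- .pair_denominator(eps$occ, eps$virt, i, j)
      if (min(abs(D)) < degeneracy_tol)
        stop("quasi-degenerate reference in Y build", call. = FALSE)
      t_ij <- .pair_integrals(df, i, j) / D
      u <- scales[1] * t_ij + scales[2] * (t_ij - t(t_ij))
      ## Y[Q, i, a] += sum_b J[Q, j, b] u[a, b]
      Y[, ri, ] <- Y[, ri, ] + .j_occ_slice(df, j) %*% t(u)
      .count_flops(as.numeric(rank) * df$n_virt^2)
    }
  }
  Y
}
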
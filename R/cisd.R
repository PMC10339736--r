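## Perturbative (CIS(D)-type) VIP and VEA corrections.
##
## At first order the ionized/attached states are single determinants and
## the eigenvalues are plain (negative) orbital energies; the second-order
## (D) correction for one target orbital is evaluated with the frequency
## fixed at that orbital energy, which makes it the diagonal,
## frequency-independent second-order self-energy. Costs are N^4 because
## one index of every intermediate is restricted to the target orbital;
## ionization needs no virtual-virtual integrals at all, and attachment
## touches them only through single-fixed-index DF slices.

#' First-order ionized or attached states
#'
#' In the basis of singly ionized (attached) determinants the first-order
#' problem is diagonal: VIPs are negative occupied orbital energies, VEAs
#' are virtual orbital energies, and the eigenvectors are Cartesian unit
#' vectors. States are returned from the channel edge inward (HOMO, HOMO-1,
#' ... for IP; LUMO, LUMO+1, ... for EA); degenerate orbitals keep their
#' stable index order.
#'
#' @param ref A `reference_state`.
#' @param channel `"ip"` or `"ea"`.
#' @param n_states Number of states; at most the size of the channel space.
#' @return data.frame with `orbital` (position in the active occupied or
#'   virtual block), `label`, and `omega_first` (hartree).
#' @export
first_order_states <- function(ref, channel = c("ip", "ea"), n_states = 1L) {
  channel <- match.arg(channel)
  if (channel == "ip") {
    n_space <- ref$n_occupied_active
    if (n_states > n_space)
      stop("n_states exceeds the number of active occupied orbitals",
           call. = FALSE)
    orb <- seq(n_space, by = -1L, length.out = n_states)
    omega <- -.eps_occ(ref)[orb]
    lab <- ifelse(orb == n_space, "HOMO", paste0("HOMO-", n_space - orb))
  } else {
    n_space <- ref$n_virtual
    if (n_states > n_space)
      stop("n_states exceeds the number of virtual orbitals", call. = FALSE)
    orb <- seq_len(n_states)
    omega <- .eps_virt(ref)[orb]
    lab <- ifelse(orb == 1L, "LUMO", paste0("LUMO+", orb - 1L))
  }
  data.frame(orbital = orb, label = lab, omega_first = omega,
             stringsAsFactors = FALSE)
}

#' The V_ij^a intermediate for one ionized orbital
#'
#' Couplings between the ionized determinant of orbital `k` and the
#' two-hole-one-particle space, with one occupied index restricted to `k`:
#' the direct part holds `(kj|al)` and the exchange part `(kl|aj)`
#' (Mulliken convention, indices `[j, l, a]`). The opposite-spin channel
#' uses the direct part alone; the same-spin channel uses their
#' difference. Only the occupied-occupied and occupied-virtual J blocks are
#' touched; the build costs `N_occ^2 N_virt N_aux` multiply-adds.
#'
#' @param df A `df_tensor`.
#' @param eps Orbital-energy blocks, see [orbital_energy_blocks()].
#' @param k Active occupied index of the ionized orbital.
#' @return List with arrays `direct` and `exchange`, both
#'   `(n_occ, n_occ, n_virt)`, and `denominator_base[j, l, a] =
#'   eps_j + eps_l - eps_a`.
#' @export
build_v_ija <- function(df, eps, k) {
  n_occ <- df$n_occ; n_virt <- df$n_virt
  if (k < 1L || k > n_occ)
    stop("target orbital must be an active occupied index", call. = FALSE)
  rank <- df$n_aux_effective
  Jij_k <- matrix(df$J_ij[, k, ], rank, n_occ)          # (Q, j) = (kj|Q)
  direct <- crossprod(Jij_k, .j_ia_mat(df))             # [j, (l,a)] = (kj|al)
  .count_flops(as.numeric(rank) * n_occ * n_occ * n_virt)
  direct <- array(direct, c(n_occ, n_occ, n_virt))
  exchange <- aperm(direct, c(2, 1, 3))                 # (kl|aj)
  den <- outer(outer(eps$occ, eps$occ, "+"), eps$virt, "-")
  list(direct = direct, exchange = exchange, denominator_base = den)
}

#' The V_i^ab intermediate for one attached orbital
#'
#' Couplings between the attached determinant of virtual orbital `c` and
#' the two-particle-one-hole space: direct part `(ca|ib)`, exchange part
#' `(cb|ia)`, indices `[a, i, b]`. Virtual-virtual DF factors are accessed
#' only through the slice provider with the fixed index `c`.
#'
#' @inheritParams build_v_ija
#' @param c_orb Active virtual index of the attached orbital.
#' @return List with arrays `direct` and `exchange`, both
#'   `(n_virt, n_occ, n_virt)`, and `denominator_base[a, i, b] =
#'   eps_a + eps_b - eps_i`.
#' @export
build_v_iab <- function(df, eps, c_orb) {
  n_occ <- df$n_occ; n_virt <- df$n_virt
  if (c_orb < 1L || c_orb > n_virt)
    stop("target orbital must be an active virtual index", call. = FALSE)
  S_c <- df$j_ab_slice(c_orb)                           # (Q, a) = (ca|Q)
  direct <- crossprod(S_c, .j_ia_mat(df))               # [a, (i,b)] = (ca|ib)
  .count_flops(as.numeric(df$n_aux_effective) * n_virt * n_occ * n_virt)
  direct <- array(direct, c(n_virt, n_occ, n_virt))
  exchange <- aperm(direct, c(3, 2, 1))                 # (cb|ia)
  den <- aperm(outer(outer(eps$virt, eps$virt, "+"), eps$occ, "-"),
               c(1, 3, 2))
  list(direct = direct, exchange = exchange, denominator_base = den)
}

## shared fold of a V intermediate against a frequency:
## sum of v^2 / (omega - den_base-ish); os uses direct^2, ss the
## antisymmetrized square with the 1/2 configuration weight
.fold_v <- function(v, den, degeneracy_tol) {
  if (min(abs(den)) < degeneracy_tol)
    stop("vanishing 2h1p/2p1h-type denominator at the target frequency",
         call. = FALSE)
  anti <- v$direct - v$exchange
  list(os = sum(v$direct^2 / den),
       ss = 0.5 * sum(anti^2 / den))
}

#' Second-order (D) correction to a vertical ionization potential
#'
#' Evaluates the opposite-/same-spin parts of the perturbative correction
#' for ionization out of active occupied orbital `k`, at the fixed
#' frequency `-eps_k` (frequency-independent diagonal evaluation). The
#' 2h1p contribution is folded directly from [build_v_ija()]; the 2p1h
#' contribution is contracted through the row-restricted Y intermediate,
#' so the whole correction costs N^4.
#'
#' The returned `os`/`ss` are unscaled; `scaled = c_os*os + c_ss*ss` is the
#' (D) correction entering `VIP = -eps_k + scaled`.
#'
#' @inheritParams build_v_ija
#' @param scales Length-2 numeric `(c_os, c_ss)`.
#' @param omega Evaluation frequency (defaults to the first-order VIP,
#'   `-eps_k`).
#' @param degeneracy_tol Guard for vanishing denominators.
#' @return List with `os`, `ss`, `scaled`, `omega_first`.
#' @export
vip_correction <- function(df, eps, k, scales = c(1, 1), omega = NULL,
                           degeneracy_tol = .default_degeneracy_tol) {
  omega_first <- -eps$occ[k]
  if (is.null(omega)) omega <- omega_first
  ## folded 2h1p part at the fixed frequency
  v <- build_v_ija(df, eps, k)
  folded <- .fold_v(v, omega + v$denominator_base, degeneracy_tol)
  ## 2p1h part through the k-restricted Y intermediate: S_kk = sum_aQ J Y
  Jk <- .j_occ_slice(df, k)
  y_os <- build_Y(df, eps, scales = c(1, 0), rows = k,
                  degeneracy_tol = degeneracy_tol)
  y_ss <- build_Y(df, eps, scales = c(0, 1), rows = k,
                  degeneracy_tol = degeneracy_tol)
  b_os <- sum(Jk * matrix(y_os, nrow(Jk), ncol(Jk)))
  b_ss <- sum(Jk * matrix(y_ss, nrow(Jk), ncol(Jk)))
  os <- folded$os - b_os
  ss <- folded$ss - b_ss
  list(os = os, ss = ss, scaled = scales[1] * os + scales[2] * ss,
       omega_first = omega_first)
}

#' Second-order (D) correction to a vertical electron attachment energy
#'
#' Mirror of [vip_correction()] for attachment into active virtual orbital
#' `c_orb`, evaluated at the fixed frequency `+eps_c`. The 2p1h
#' contribution is folded from [build_v_iab()] (virtual-virtual factors via
#' the single slice `c`); the 2h1p contribution is a direct N^4
#' contraction over occupied-virtual factors only. The attachment energy
#' is `eps_c + scaled` (a negative value means unbound attachment at this
#' level).
#'
#' @inheritParams vip_correction
#' @param c_orb Active virtual index.
#' @return List with `os`, `ss`, `scaled`, `omega_first`.
#' @export
vea_correction <- function(df, eps, c_orb, scales = c(1, 1), omega = NULL,
                           degeneracy_tol = .default_degeneracy_tol) {
  omega_first <- eps$virt[c_orb]
  if (is.null(omega)) omega <- omega_first
  n_occ <- df$n_occ; n_virt <- df$n_virt
  ## folded 2p1h part
  v <- build_v_iab(df, eps, c_orb)
  folded <- .fold_v(v, omega - v$denominator_base, degeneracy_tol)
  ## static 2h1p part: (ci|aj) over J_ia only, denominators
  ## omega + eps_a - eps_i - eps_j
  Jc <- matrix(df$J_ia[, , c_orb], df$n_aux_effective, n_occ)  # (Q, i)
  P <- crossprod(Jc, .j_ia_mat(df))                  # [i, (j,a)] = (ic|ja)
  .count_flops(as.numeric(df$n_aux_effective) * n_occ * n_occ * n_virt)
  P <- array(P, c(n_occ, n_occ, n_virt))             # (ci|aj) at [i, j, a]
  den <- omega + outer(outer(-eps$occ, -eps$occ, "+"), eps$virt, "+")
  if (min(abs(den)) < degeneracy_tol)
    stop("vanishing 2h1p-type denominator at the target frequency",
         call. = FALSE)
  Pex <- aperm(P, c(2, 1, 3))                        # (cj|ai)
  b_os <- sum(P^2 / den)
  b_ss <- 0.5 * sum((P - Pex)^2 / den)
  os <- folded$os + b_os
  ss <- folded$ss + b_ss
  list(os = os, ss = ss, scaled = scales[1] * os + scales[2] * ss,
       omega_first = omega_first)
}

#' Assemble a scaled state result from a perturbative correction
#'
#' Applies the functional's opposite-/same-spin scales to an unscaled
#' correction and packages the final VIP or attachment energy. For the
#' perturbative ansatz the state remains a single determinant, so the pole
#' strength is exactly 1.
#'
#' @param omega_first First-order value (hartree).
#' @param correction List with unscaled `os` and `ss` parts (hartree), as
#'   returned by [vip_correction()] / [vea_correction()].
#' @param func A `functional_config` with `ansatz = "cisd"`.
#' @param channel `"ip"` or `"ea"`.
#' @param orbital Target orbital index (within its block).
#' @return Object of class `state_result`.
#' @export
apply_dh_scaling <- function(omega_first, correction, func,
                             channel = "ip", orbital = NA_integer_) {
  if (!inherits(func, "functional_config"))
    stop("func must be a functional_config", call. = FALSE)
  if (func$ansatz != "cisd")
    stop("hybrid functional defines no second-order correction ",
         "(ansatz must be 'cisd')", call. = FALSE)
  sc <- func$second_order_scales
  omega_final <- omega_first + sc[["os"]] * correction$os +
    sc[["ss"]] * correction$ss
  structure(
    list(channel = channel, target_orbital = orbital,
         omega_first = omega_first,
         omega_D_os = correction$os, omega_D_ss = correction$ss,
         scales = sc, omega_final = omega_final,
         final_eV = hartree_to_ev(omega_final),
         iterations = 0L, residual = 0, converged = TRUE,
         pole_strength = 1),
    class = "state_result")
}

#' @export
print.state_result <- function(x, ...) {
  cat(sprintf(
    "%s state, orbital %s: omega1 = %.6f Eh, (D) os/ss = %.6f/%.6f Eh\n",
    toupper(x$channel), x$target_orbital, x$omega_first,
    x$omega_D_os, x$omega_D_ss))
  cat(sprintf("  final = %.6f Eh = %.4f eV (%d iterations, pole strength %s)\n",
              x$omega_final, x$final_eV, x$iterations,
              format(x$pole_strength, digits = 6)))
  invisible(x)
}
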
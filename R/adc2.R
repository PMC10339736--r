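## Iterative (non-Dyson ADC(2)-type) VIP and VEA states.
##
## The secular problem couples the singles (1h or 1p) space to the doubles
## (2h1p or 2p1h) space. The doubles block is diagonal in zeroth order and
## is never stored: its effect enters sigma analytically as the fold
## C (omega - D)^-1 C^T, which makes the singles-space eigenproblem
## nonlinear in omega. A static second-order singles-block term, built from
## ground-state MP2 amplitudes through the Y intermediate, completes the
## operator; that Y build is the one N^5 step and happens once per
## workspace, independent of how many states are then solved. Second-order
## terms carry the functional's opposite-/same-spin scales; couplings are
## weighted by the square roots of the scales so each folded product
## carries one power of its scale.

#' Precompute the sigma workspace for one channel
#'
#' Builds everything the iterative solver needs for a (reference, channel)
#' job: the spin-resolved static singles-block matrices, the
#' singles-doubles coupling tables (direct and antisymmetrized), and the
#' doubles configuration energies. For the IP channel no virtual-virtual
#' DF factor is ever referenced; for the EA channel virtual-virtual
#' factors are pulled once through the single-index slice provider.
#'
#' @param df A `df_tensor`.
#' @param eps Orbital-energy blocks, see [orbital_energy_blocks()].
#' @param channel `"ip"` or `"ea"`.
#' @param scales Length-2 numeric `(c_os, c_ss)`.
#' @param degeneracy_tol Guard for vanishing MP2 denominators.
#' @return Object of class `sigma_workspace`.
#' @export
prepare_sigma_workspace <- function(df, eps, channel = c("ip", "ea"),
                                    scales = c(1, 1),
                                    degeneracy_tol = .default_degeneracy_tol) {
  channel <- match.arg(channel)
  n_occ <- df$n_occ; n_virt <- df$n_virt
  rank <- df$n_aux_effective
  ## N^5 precompute: spin-resolved Y intermediates (once per workspace)
  y_os <- build_Y(df, eps, scales = c(1, 0), degeneracy_tol = degeneracy_tol)
  y_ss <- build_Y(df, eps, scales = c(0, 1), degeneracy_tol = degeneracy_tol)
  .dh_counters$y_builds <- .dh_counters$y_builds - 1L  # two builds, one step
  sym <- function(S) (S + t(S)) / 2

  if (channel == "ip") {
    ## static block: S_ij = sum_aQ J[Q,i,a] Y[Q,j,a]
    Jm <- matrix(aperm(df$J_ia, c(2, 1, 3)), n_occ, rank * n_virt)
    S_os <- Jm %*% t(matrix(aperm(y_os, c(2, 1, 3)), n_occ, rank * n_virt))
    S_ss <- Jm %*% t(matrix(aperm(y_ss, c(2, 1, 3)), n_occ, rank * n_virt))
    .count_flops(2 * as.numeric(n_occ)^2 * rank * n_virt)
    B_os <- sym(S_os); B_ss <- sym(S_ss)
    ## couplings G[k, (j,l,a)] = (kj|al), H the antisymmetrized combination
    Gfull <- crossprod(.j_ij_mat(df), .j_ia_mat(df))   # (k,j) x (l,a)
    .count_flops(as.numeric(rank) * n_occ^2 * n_occ * n_virt)
    G4 <- array(Gfull, c(n_occ, n_occ, n_occ, n_virt))
    G <- matrix(G4, n_occ, n_occ * n_occ * n_virt)
    H <- matrix(G4 - aperm(G4, c(1, 3, 2, 4)), n_occ,
                n_occ * n_occ * n_virt)
    cfg_energy <- as.vector(outer(outer(-eps$occ, -eps$occ, "+"),
                                  eps$virt, "+"))   # eps_a - eps_j - eps_l
    diag1 <- -eps$occ
    sgnB <- -1
  } else {
    ## static block: S_ab = -sum_iQ J[Q,i,a] Y[Q,i,b]
    Jm <- matrix(aperm(df$J_ia, c(3, 1, 2)), n_virt, rank * n_occ)
    S_os <- -Jm %*% t(matrix(aperm(y_os, c(3, 1, 2)), n_virt, rank * n_occ))
    S_ss <- -Jm %*% t(matrix(aperm(y_ss, c(3, 1, 2)), n_virt, rank * n_occ))
    .count_flops(2 * as.numeric(n_virt)^2 * rank * n_occ)
    B_os <- sym(S_os); B_ss <- sym(S_ss)
    ## couplings F[c, (a,i,b)] = (ca|ib), via one slice per virtual
    Fm <- matrix(0, n_virt, n_virt * n_occ * n_virt)
    for (cc in seq_len(n_virt)) {
      S_c <- df$j_ab_slice(cc)
      Fm[cc, ] <- as.vector(crossprod(S_c, .j_ia_mat(df)))
      .count_flops(as.numeric(rank) * n_virt * n_occ * n_virt)
    }
    F4 <- array(Fm, c(n_virt, n_virt, n_occ, n_virt))
    G <- matrix(F4, n_virt, n_virt * n_occ * n_virt)
    H <- matrix(F4 - aperm(F4, c(1, 4, 3, 2)), n_virt,
                n_virt * n_occ * n_virt)
    cfg_energy <- as.vector(outer(outer(eps$virt, -eps$occ, "+"),
                                  eps$virt, "+"))   # eps_a + eps_b - eps_i
    diag1 <- eps$virt
    sgnB <- 1
  }
  structure(
    list(channel = channel, scales = scales,
         diag1 = diag1,
         B = sgnB * (scales[1] * B_os + scales[2] * B_ss),
         G = G, H = H, cfg_energy = cfg_energy,
         degeneracy_tol = degeneracy_tol,
         n_singles = length(diag1)),
    class = "sigma_workspace")
}

#' @export
print.sigma_workspace <- function(x, ...) {
  cat(sprintf(
    "Sigma workspace [%s]: %d singles, %d doubles configurations, scales (%g, %g)\n",
    x$channel, x$n_singles, length(x$cfg_energy), x$scales[1], x$scales[2]))
  invisible(x)
}

.folded_weights <- function(ws, omega) {
  den <- omega - ws$cfg_energy
  if (min(abs(den)) < ws$degeneracy_tol)
    stop("folded denominator |omega - D| below degeneracy tolerance",
         call. = FALSE)
  den
}

## sigma action shared by both channels: the operator is
## diag(+-eps) + B + c_os G (omega-D)^-1 G^T + (c_ss/2) H (omega-D)^-1 H^T
.sigma_apply <- function(cvec, omega, ws) {
  out <- ws$diag1 * cvec + drop(ws$B %*% cvec)
  if (all(ws$scales == 0)) return(out)
  den <- .folded_weights(ws, omega)
  if (ws$scales[1] != 0) {
    f <- drop(crossprod(ws$G, cvec))
    out <- out + ws$scales[1] * drop(ws$G %*% (f / den))
  }
  if (ws$scales[2] != 0) {
    f <- drop(crossprod(ws$H, cvec))
    out <- out + 0.5 * ws$scales[2] * drop(ws$H %*% (f / den))
  }
  out
}

## diagonal of the folded operator at fixed omega (Davidson preconditioner)
.sigma_diag <- function(ws, omega) {
  d <- ws$diag1 + diag(ws$B)
  if (all(ws$scales == 0)) return(d)
  den <- .folded_weights(ws, omega)
  if (ws$scales[1] != 0)
    d <- d + ws$scales[1] * drop(ws$G^2 %*% (1 / den))
  if (ws$scales[2] != 0)
    d <- d + 0.5 * ws$scales[2] * drop(ws$H^2 %*% (1 / den))
  d
}

#' Sigma transformation for the ionization channel
#'
#' Action of the omega-folded effective Jacobian on a singles (1h)
#' vector: the first-order diagonal `-eps_i c_i`, the static second-order
#' singles block, and the analytically folded 2h1p resolvent, with the
#' second-order pieces weighted by the workspace scales. Linear in `c` at
#' fixed `omega`.
#'
#' @param cvec Singles vector (length = active occupied count).
#' @param omega Current folding frequency, hartree.
#' @param ws An IP `sigma_workspace`.
#' @return The transformed vector.
#' @export
sigma_ip <- function(cvec, omega, ws) {
  stopifnot(inherits(ws, "sigma_workspace"), ws$channel == "ip")
  .sigma_apply(cvec, omega, ws)
}

#' Sigma transformation for the attachment channel
#'
#' Mirror of [sigma_ip()] on the virtual space: diagonal `+eps_a c_a` plus
#' the folded 2p1h resolvent and the static second-order block.
#'
#' @param cvec Singles vector (length = virtual count).
#' @param omega Current folding frequency, hartree.
#' @param ws An EA `sigma_workspace`.
#' @return The transformed vector.
#' @export
sigma_ea <- function(cvec, omega, ws) {
  stopifnot(inherits(ws, "sigma_workspace"), ws$channel == "ea")
  .sigma_apply(cvec, omega, ws)
}

## ---- Davidson with root following ------------------------------------------

## Symmetric Davidson on a fixed operator; follows the root of maximum
## overlap with `anchor` rather than the lowest one. Deterministic:
## expansion vectors are orthogonalized in arrival order (modified
## Gram-Schmidt, twice), subspace capped with collapse onto the two
## best-overlapping Ritz vectors.
.davidson_follow <- function(apply_op, diag_op, n, anchor,
                             resid_tol = 1e-5, max_subspace = 20L,
                             collapse_to = 2L, max_iter = 200L,
                             overlap_floor = 0.3) {
  normalize <- function(v) v / sqrt(sum(v^2))
  B <- matrix(normalize(anchor), n, 1)
  AB <- matrix(apply_op(B[, 1]), n, 1)
  for (it in seq_len(max_iter)) {
    S <- crossprod(B, AB)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    X <- B %*% es$vectors                      # Ritz vectors, full space
    ov <- abs(drop(crossprod(X, normalize(anchor))))
    sel <- which.max(ov)
    if (ov[sel] < overlap_floor)
      stop("root lost: maximum overlap with the followed state fell below ",
           overlap_floor, call. = FALSE)
    theta <- es$values[sel]
    x <- X[, sel]
    r <- drop(AB %*% es$vectors[, sel]) - theta * x
    rnorm <- sqrt(sum(r^2))
    if (rnorm <= resid_tol || ncol(B) >= n)
      return(list(value = theta, vector = normalize(x), residual = rnorm,
                  iterations = it))
    ## preconditioned expansion
    denom <- diag_op - theta
    denom[abs(denom) < 1e-6] <- sign(denom[abs(denom) < 1e-6] + 1e-300) * 1e-6
    t_new <- r / denom
    for (pass in 1:2)
      t_new <- t_new - B %*% crossprod(B, t_new)
    tn <- sqrt(sum(t_new^2))
    if (tn < 1e-12)
      return(list(value = theta, vector = normalize(x), residual = rnorm,
                  iterations = it))
    B <- cbind(B, t_new / tn)
    AB <- cbind(AB, apply_op(B[, ncol(B)]))
    if (ncol(B) > max_subspace) {
      keep <- order(ov, decreasing = TRUE)[seq_len(min(collapse_to, ncol(X)))]
      Bn <- X[, keep, drop = FALSE]
      qrB <- qr(Bn)
      B <- qr.Q(qrB)
      AB <- apply(B, 2, apply_op)
    }
  }
  stop("Davidson failed to reach the residual tolerance", call. = FALSE)
}

#' Solve one iterative ionized/attached state
#'
#' Self-consistent solution of the folded nonlinear eigenproblem for one
#' target orbital. Macro-iterations fix the folding frequency at the
#' current Ritz value and run the root-following Davidson solver to the
#' residual tolerance; the frequency is then updated and the cycle repeats
#' until the energy change drops below `conv_energy` (default 1e-6
#' hartree). The followed root maximizes the overlap with the initial unit
#' vector of the target orbital and is re-anchored to the previous iterate
#' after each macro-iteration, so a target whose state is not the lowest
#' root is tracked correctly. With zero scales the operator is diagonal
#' and the first-order value is returned after one macro-iteration.
#'
#' @param ws A `sigma_workspace`.
#' @param target Target orbital position in the singles space (active
#'   occupied index for IP, virtual index for EA).
#' @param conv_energy Convergence threshold on |delta omega|, hartree.
#' @param max_iter Maximum macro-iterations.
#' @param resid_tol Davidson residual tolerance on the folded problem.
#' @param overlap_floor Minimum admissible overlap before the root is
#'   declared lost.
#' @return Object of class `iterative_state`: `omega` (hartree), unit
#'   singles `vector`, `iterations` (macro), `residual`, `converged`, plus
#'   channel/target metadata.
#' @export
solve_state <- function(ws, target, conv_energy = 1e-6, max_iter = 50L,
                        resid_tol = 1e-5, overlap_floor = 0.3) {
  stopifnot(inherits(ws, "sigma_workspace"))
  n <- ws$n_singles
  if (target < 1L || target > n)
    stop("target orbital outside the singles space", call. = FALSE)
  anchor <- numeric(n); anchor[target] <- 1
  omega <- ws$diag1[target]
  state <- NULL
  converged <- FALSE
  residual <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    dav <- .davidson_follow(
      apply_op = function(v) .sigma_apply(v, omega, ws),
      diag_op = .sigma_diag(ws, omega), n = n, anchor = anchor,
      resid_tol = resid_tol, overlap_floor = overlap_floor)
    delta <- dav$value - omega
    omega <- dav$value
    anchor <- dav$vector
    residual <- dav$residual
    if (abs(delta) <= conv_energy) { converged <- TRUE; break }
  }
  if (!converged)
    stop("state did not converge within ", max_iter, " macro-iterations",
         call. = FALSE)
  structure(
    list(channel = ws$channel, target = target, omega = omega,
         vector = anchor, residual = residual, iterations = it,
         converged = converged, scales = ws$scales),
    class = "iterative_state")
}

#' @export
print.iterative_state <- function(x, ...) {
  cat(sprintf(
    "%s iterative state, target %d: omega = %.8f Eh (%.4f eV), %d macro-iterations\n",
    toupper(x$channel), x$target, x$omega, hartree_to_ev(x$omega),
    x$iterations))
  invisible(x)
}

#' Pole strength of a converged iterative state
#'
#' The squared norm of the singles block of the full (singles plus folded
#' doubles) state vector: the doubles amplitudes are recovered
#' analytically as `(omega - D)^-1 C^T c` with the scale-weighted
#' couplings, and the pole strength is `1 / (1 + |d|^2)`. First-order
#' contributions are unscaled while every second-order contribution
#' carries its spin scale, so zero scales give exactly 1 and growing
#' second-order weight monotonically depresses the pole strength.
#'
#' @param state A converged `iterative_state`.
#' @param ws The `sigma_workspace` the state was solved in.
#' @return Pole strength in (0, 1].
#' @export
pole_strength <- function(state, ws) {
  stopifnot(inherits(state, "iterative_state"),
            inherits(ws, "sigma_workspace"))
  if (!isTRUE(state$converged))
    stop("pole strength is defined for converged states only", call. = FALSE)
  if (all(ws$scales == 0)) return(1)
  den <- .folded_weights(ws, state$omega)
  cvec <- state$vector
  d2 <- 0
  if (ws$scales[1] != 0) {
    f <- drop(crossprod(ws$G, cvec))
    d2 <- d2 + ws$scales[1] * sum((f / den)^2)
  }
  if (ws$scales[2] != 0) {
    f <- drop(crossprod(ws$H, cvec))
    d2 <- d2 + 0.5 * ws$scales[2] * sum((f / den)^2)
  }
  1 / (1 + d2)
}
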
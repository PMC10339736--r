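## Dense brute-force oracles.
##
## Every numerical claim of the production modules is anchored against the
## routines in this file, which deliberately share no contraction code with
## them: four-center integrals are rebuilt here by the naive I V^-1 I^T
## contraction and a dense Kronecker MO transform, and all second-order
## quantities are obtained by explicit enumeration over spin-orbital
## configurations (2h1p / 2p1h), never through the blocked J factors or the
## Y intermediate. Sizes are guarded: these routines are O(N^6)-ish and
## meant for toys only.

.oracle_size_guard <- function(toy, max_occ = 6L, max_virt = 8L) {
  if (toy$ref$n_occupied_active > max_occ || toy$ref$n_virtual > max_virt)
    stop("oracle size guard: toy too large (occ <= ", max_occ,
         ", virt <= ", max_virt, ")", call. = FALSE)
}

#' Dense four-center MO integrals of a toy reference (oracle route)
#'
#' Reconstructs the AO integral matrix by the naive `I V^-1 I^T`
#' contraction and transforms it to the active MO basis with a dense
#' Kronecker product. Returns the full `(pq|rs)` array over active MOs
#' (frozen core excluded), Mulliken convention.
#'
#' @param toy Output of [make_toy_reference()].
#' @return 4-index array `g[p, q, r, s] = (pq|rs)` over active MOs
#'   (occupied first, then virtual).
#' @export
oracle_mo_integrals <- function(toy) {
  I3 <- toy$ao$ao_three_center
  V <- toy$ao$metric
  d <- dim(I3)
  n_aux <- d[1]; n_ao <- d[2]
  Imat <- matrix(I3, n_aux, n_ao * n_ao)
  K_ao <- t(Imat) %*% solve(V, Imat)
  act <- c(.active_occ_idx(toy$ref), .virt_idx(toy$ref))
  C <- toy$ref$mo_coefficients[, act, drop = FALSE]
  C2 <- kronecker(C, C)          # row (mu,nu) -> col (p,q), p fastest
  K_mo <- t(C2) %*% K_ao %*% C2
  n <- length(act)
  array(K_mo, c(n, n, n, n))
}

## spin-orbital bookkeeping over the active space: orbitals 1..n_act each
## with spin +1 (alpha) and -1 (beta)
.so_space <- function(toy) {
  n_occ <- toy$ref$n_occupied_active
  n_virt <- toy$ref$n_virtual
  n <- n_occ + n_virt
  eps <- c(.eps_occ(toy$ref), .eps_virt(toy$ref))
  occ <- seq_len(n_occ); virt <- n_occ + seq_len(n_virt)
  so <- list(sp = rep(seq_len(n), each = 2L),
             spin = rep(c(1L, -1L), n))
  so$eps <- eps[so$sp]
  so$occ <- so$sp %in% occ
  list(so = so, eps = eps, occ = occ, virt = virt,
       n_occ = n_occ, n_virt = n_virt)
}

## antisymmetrized spin-orbital integral <pq||rs> from the spatial array
.so_anti <- function(g, so, p, q, r, s) {
  d <- 0
  if (so$spin[p] == so$spin[r] && so$spin[q] == so$spin[s])
    d <- d + g[so$sp[p], so$sp[r], so$sp[q], so$sp[s]]
  if (so$spin[p] == so$spin[s] && so$spin[q] == so$spin[r])
    d <- d - g[so$sp[p], so$sp[s], so$sp[q], so$sp[r]]
  d
}

#' Dense second-order self-energy oracle
#'
#' Evaluates the diagonal second-order self-energy for one target orbital
#' by explicit summation over all 2h1p and 2p1h spin-orbital
#' configurations at the fixed frequency `omega` (default: the target
#' orbital energy, i.e. the frequency-independent evaluation). Spin classes
#' are accumulated separately, so the opposite-/same-spin split of the
#' perturbative (D) correction is available. The returned values are the
#' *unscaled* OS/SS parts of the correction to the first-order VIP
#' (`-eps_k`) or attachment energy (`+eps_c`); the scaled correction is
#' `c_os * os + c_ss * ss`.
#'
#' @param toy Output of [make_toy_reference()].
#' @param orbital Position of the target orbital within the active occupied
#'   block (IP) or virtual block (EA).
#' @param channel `"ip"` or `"ea"`.
#' @param scales Length-2 numeric `(c_os, c_ss)` used for the `scaled`
#'   element of the result.
#' @param omega Frequency of the self-energy evaluation, hartree; defaults
#'   to the target orbital energy.
#' @return List with `os`, `ss` (unscaled correction parts, hartree),
#'   `scaled`, and `omega_first`.
#' @export
dense_selfenergy_oracle <- function(toy, orbital, channel = c("ip", "ea"),
                                    scales = c(1, 1), omega = NULL) {
  channel <- match.arg(channel)
  .oracle_size_guard(toy)
  g <- oracle_mo_integrals(toy)
  sp <- .so_space(toy)
  so <- sp$so
  target_sp <- if (channel == "ip") sp$occ[orbital] else sp$virt[orbital]
  eps_t <- sp$eps[target_sp]
  if (is.null(omega)) omega <- eps_t
  t_so <- which(so$sp == target_sp & so$spin == 1L)  # alpha component

  occ_so <- which(so$occ); virt_so <- which(!so$occ)
  os <- 0; ss <- 0
  ## 2p1h-type configurations: hole i, particles a b
  for (i in occ_so) for (a in virt_so) for (b in virt_so) {
    v <- .so_anti(g, so, t_so, i, a, b)
    if (v == 0) next
    den <- omega + so$eps[i] - so$eps[a] - so$eps[b]
    if (abs(den) < 1e-8)
      stop("oracle: vanishing 2p1h denominator", call. = FALSE)
    term <- 0.5 * v * v / den
    if (so$spin[i] == so$spin[t_so]) ss <- ss + term else os <- os + term
  }
  ## 2h1p-type configurations: holes i j, particle a
  for (i in occ_so) for (j in occ_so) for (a in virt_so) {
    v <- .so_anti(g, so, t_so, a, i, j)
    if (v == 0) next
    den <- omega + so$eps[a] - so$eps[i] - so$eps[j]
    if (abs(den) < 1e-8)
      stop("oracle: vanishing 2h1p denominator", call. = FALSE)
    term <- 0.5 * v * v / den
    if (so$spin[i] == so$spin[j]) ss <- ss + term else os <- os + term
  }
  sgn <- if (channel == "ip") -1 else 1
  os <- sgn * os; ss <- sgn * ss
  list(os = os, ss = ss,
       scaled = scales[1] * os + scales[2] * ss,
       omega_first = if (channel == "ip") -eps_t else eps_t)
}

#' Dense ground-state MP2 oracle
#'
#' Opposite-/same-spin resolved MP2 correlation energy by explicit
#' summation over all spin-orbital double substitutions.
#'
#' @param toy Output of [make_toy_reference()].
#' @return List with `os`, `ss`, `total` (hartree).
#' @export
oracle_mp2_energy <- function(toy) {
  .oracle_size_guard(toy)
  g <- oracle_mo_integrals(toy)
  sp <- .so_space(toy)
  so <- sp$so
  occ_so <- which(so$occ); virt_so <- which(!so$occ)
  os <- 0; ss <- 0
  for (i in occ_so) for (j in occ_so) for (a in virt_so) for (b in virt_so) {
    v <- .so_anti(g, so, i, j, a, b)
    if (v == 0) next
    den <- so$eps[i] + so$eps[j] - so$eps[a] - so$eps[b]
    term <- 0.25 * v * v / den
    if (so$spin[i] == so$spin[j]) ss <- ss + term else os <- os + term
  }
  list(os = os, ss = ss, total = os + ss)
}

## ---- dense ADC(2)-type matrices --------------------------------------------

## enumerate spin-orbital 2h1p configurations (holes i<j, particle a) with
## the spin projection of a singly ionized alpha state, plus their coupling
## vector to every alpha 1h orbital
.enum_2h1p <- function(g, sp) {
  so <- sp$so
  occ_so <- which(so$occ); virt_so <- which(!so$occ)
  n_occ <- sp$n_occ
  cfg_den <- numeric(0); cfg_class <- character(0)
  Vmat <- NULL
  alpha_holes <- which(so$occ & so$spin == 1L)
  rows <- list(); k <- 0L
  for (ii in seq_along(occ_so)) for (jj in seq_along(occ_so)) {
    if (jj <= ii) next
    i <- occ_so[ii]; j <- occ_so[jj]
    for (a in virt_so) {
      ## Sz of the (n-1)-electron configuration must match alpha removal
      if (-so$spin[i] - so$spin[j] + so$spin[a] != -1L) next
      v <- vapply(alpha_holes, function(kso) .so_anti(g, so, kso, a, i, j),
                  0)
      k <- k + 1L
      rows[[k]] <- v
      cfg_den[k] <- so$eps[a] - so$eps[i] - so$eps[j]
      cfg_class[k] <- if (so$spin[i] == so$spin[j]) "ss" else "os"
    }
  }
  list(V = do.call(rbind, rows), den = cfg_den, class = cfg_class)
}

## mirror for 2p1h configurations (particles a<b, hole i) coupling to alpha
## 1p orbitals
.enum_2p1h <- function(g, sp) {
  so <- sp$so
  occ_so <- which(so$occ); virt_so <- which(!so$occ)
  cfg_den <- numeric(0); cfg_class <- character(0)
  alpha_parts <- which(!so$occ & so$spin == 1L)
  rows <- list(); k <- 0L
  for (aa in seq_along(virt_so)) for (bb in seq_along(virt_so)) {
    if (bb <= aa) next
    a <- virt_so[aa]; b <- virt_so[bb]
    for (i in occ_so) {
      if (so$spin[a] + so$spin[b] - so$spin[i] != 1L) next
      v <- vapply(alpha_parts, function(cso) .so_anti(g, so, cso, i, a, b),
                  0)
      k <- k + 1L
      rows[[k]] <- v
      cfg_den[k] <- so$eps[a] + so$eps[b] - so$eps[i]
      cfg_class[k] <- if (so$spin[a] == so$spin[b]) "ss" else "os"
    }
  }
  list(V = do.call(rbind, rows), den = cfg_den, class = cfg_class)
}

## static second-order singles-block term: B = sym(S),
## S_pq = sum_cfg V_p(cfg) V_q(cfg) / D_q(cfg), with ground-state-type
## denominators; classes accumulated separately
.oracle_static_block <- function(g, sp, channel) {
  so <- sp$so
  occ_so <- which(so$occ); virt_so <- which(!so$occ)
  if (channel == "ip") {
    idx <- which(so$occ & so$spin == 1L)
    third <- occ_so; pair_space <- virt_so
  } else {
    idx <- which(!so$occ & so$spin == 1L)
    third <- virt_so; pair_space <- occ_so
  }
  n <- length(idx)
  S_os <- matrix(0, n, n); S_ss <- matrix(0, n, n)
  for (kk in third) {
    for (aa in seq_along(pair_space)) for (bb in seq_along(pair_space)) {
      if (bb <= aa) next
      a <- pair_space[aa]; b <- pair_space[bb]
      v <- vapply(idx, function(p) .so_anti(g, so, p, kk, a, b), 0)
      if (all(v == 0)) next
      same <- so$spin[a] == so$spin[b]
      for (q in seq_len(n)) {
        if (v[q] == 0) next
        den <- if (channel == "ip")
          so$eps[idx[q]] + so$eps[kk] - so$eps[a] - so$eps[b]
        else
          so$eps[idx[q]] + so$eps[kk] - so$eps[a] - so$eps[b]
        col <- v * v[q] / den
        if (same) S_ss[, q] <- S_ss[, q] + col
        else S_os[, q] <- S_os[, q] + col
      }
    }
  }
  list(os = (S_os + t(S_os)) / 2, ss = (S_ss + t(S_ss)) / 2)
}

#' Dense non-Dyson ADC(2)-type oracle
#'
#' Builds the explicit singles-plus-doubles secular matrix for one channel
#' -- 1h + 2h1p configurations for ionization, 1p + 2p1h for attachment --
#' with the second-order static singles block scaled linearly by the spin
#' scales and the singles-doubles couplings scaled by their square roots
#' (so every folded second-order product carries one power of its scale).
#' Diagonalizing this matrix yields, exactly, the self-consistent roots of
#' the folded nonlinear eigenproblem the production solver iterates on;
#' each root is returned with its squared singles-block norm (the pole
#' strength of that state).
#'
#' @param toy Output of [make_toy_reference()].
#' @param channel `"ip"` or `"ea"`.
#' @param scales Length-2 numeric `(c_os, c_ss)`.
#' @return List with `values` (all eigenvalues, ascending), `vectors`,
#'   `n_singles`, `singles_norm2` (per root), and helper `root_for_target`.
#' @export
dense_adc2_oracle <- function(toy, channel = c("ip", "ea"),
                              scales = c(1, 1)) {
  channel <- match.arg(channel)
  .oracle_size_guard(toy)
  g <- oracle_mo_integrals(toy)
  sp <- .so_space(toy)
  B <- .oracle_static_block(g, sp, channel)
  if (channel == "ip") {
    eps1 <- sp$eps[sp$occ]
    diag1 <- -eps1
    dbl <- .enum_2h1p(g, sp)
    sgnB <- -1
  } else {
    eps1 <- sp$eps[sp$virt]
    diag1 <- eps1
    dbl <- .enum_2p1h(g, sp)
    sgnB <- 1
  }
  n1 <- length(diag1)
  A11 <- diag(diag1, n1) + sgnB * (scales[1] * B$os + scales[2] * B$ss)
  w <- ifelse(dbl$class == "os", sqrt(scales[1]), sqrt(scales[2]))
  C <- t(dbl$V * w)                     # n1 x n_cfg
  M <- rbind(cbind(A11, C),
             cbind(t(C), diag(dbl$den, length(dbl$den))))
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  s2 <- colSums(vecs[seq_len(n1), , drop = FALSE]^2)
  res <- list(values = vals, vectors = vecs, n_singles = n1,
              singles_norm2 = s2,
              blocks = list(singles = A11, coupling = C,
                            doubles_diag = dbl$den))
  res$root_for_target <- function(target) {
    which.max(abs(vecs[target, ]))
  }
  res
}
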
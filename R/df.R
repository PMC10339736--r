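## Density-fitting (resolution-of-identity) machinery.
##
## Four-center two-electron integrals never appear explicitly: the matrix
## K with elements K_{ia,jb} = (ia|jb) is factorized as K = J J^T with
## J = I V^(-1/2), where I collects the three-center Coulomb integrals and V
## is the two-center Coulomb metric over the auxiliary basis. Blocks of J
## are built selectively: ionization workflows need only the
## occupied-virtual and occupied-occupied blocks, while attachment
## workflows additionally access virtual-virtual factors through an
## on-demand single-fixed-index slice provider. The auxiliary index is the
## fastest-varying storage dimension, since every hot contraction sums
## over it.

#' Inverse square root of the auxiliary Coulomb metric
#'
#' Computes the symmetric whitening transform `T` with `T^T V T = I` on the
#' retained eigenspace, by eigendecomposition of the two-center Coulomb
#' matrix. Eigenvalues below `drop_tol` times the largest eigenvalue are
#' discarded, which guards against (near-)linear dependence in the
#' auxiliary basis; the retained dimension is the effective rank.
#'
#' @param V Symmetric positive semidefinite metric over the auxiliary basis.
#' @param drop_tol Relative eigenvalue threshold in (0, 1).
#' @return List with `transform` (n_aux x rank matrix `T`, satisfying
#'   `T %*% t(T) = V^-1` on the retained subspace) and `rank`.
#' @export
build_metric_inverse_sqrt <- function(V, drop_tol = 1e-10) {
  if (!is.matrix(V) || nrow(V) != ncol(V))
    stop("metric must be a square matrix", call. = FALSE)
  if (max(abs(V - t(V))) > 1e-10 * max(1, max(abs(V))))
    stop("metric is not symmetric within tolerance", call. = FALSE)
  if (drop_tol <= 0 || drop_tol >= 1)
    stop("drop_tol must lie in (0, 1)", call. = FALSE)
  es <- eigen((V + t(V)) / 2, symmetric = TRUE)
  keep <- es$values > drop_tol * max(es$values)
  if (!any(keep))
    stop("all metric eigenvalues discarded; metric is numerically zero",
         call. = FALSE)
  U <- es$vectors[, keep, drop = FALSE]
  lam <- es$values[keep]
  list(transform = sweep(U, 2, sqrt(lam), "/"), rank = sum(keep))
}

.df_audit_env <- function() {
  e <- new.env(parent = emptyenv())
  e$jab_requests <- integer(0)
  e
}

#' Build the blocked density-fitting tensor
#'
#' Transforms the AO-basis three-center integrals to the MO basis and
#' applies the metric inverse square root, materializing only the
#' occupied-occupied and occupied-virtual blocks of `J`. Virtual-virtual
#' factors are exposed exclusively through `j_ab_slice(c)`, which computes
#' the `(rank x n_virt)` slice with one virtual index fixed on demand and
#' records the request in the access audit; the full virtual-virtual block
#' is never allocated.
#'
#' @param ao_three_center Array with dims `c(n_aux, n_ao, n_ao)`, symmetric
#'   in the AO indices.
#' @param mo_coefficients AO x MO matrix.
#' @param spaces List with integer index vectors `frozen`, `occ`, `virt`
#'   (columns of `mo_coefficients`); frozen orbitals are excluded from every
#'   block.
#' @param transform Output of [build_metric_inverse_sqrt()].
#' @return Object of class `df_tensor` with fields `J_ia`
#'   (`rank x n_occ x n_virt`), `J_ij` (`rank x n_occ x n_occ`),
#'   `j_ab_slice`, `n_aux_effective`, and an access-audit environment.
#' @export
build_df_tensor <- function(ao_three_center, mo_coefficients, spaces,
                            transform) {
  d <- dim(ao_three_center)
  if (length(d) != 3L || d[2] != d[3])
    stop("ao_three_center must have dims (n_aux, n_ao, n_ao)", call. = FALSE)
  n_aux <- d[1]; n_ao <- d[2]
  if (nrow(mo_coefficients) != n_ao)
    stop("dimension mismatch between AO tensor and MO coefficients",
         call. = FALSE)
  Tm <- transform$transform
  if (nrow(Tm) != n_aux)
    stop("metric transform incompatible with auxiliary dimension",
         call. = FALSE)
  C_occ <- mo_coefficients[, spaces$occ, drop = FALSE]
  C_virt <- mo_coefficients[, spaces$virt, drop = FALSE]
  n_occ <- ncol(C_occ); n_virt <- ncol(C_virt)

  ## half transform over the first AO index: H[(Q,nu), i] for occupieds
  I_mat <- matrix(ao_three_center, n_aux * n_ao, n_ao)
  half_occ <- I_mat %*% C_occ                       # (Q, mu) x i, mu == second AO
  .count_flops(as.numeric(n_aux) * n_ao * n_ao * n_occ)
  half_occ <- aperm(array(half_occ, c(n_aux, n_ao, n_occ)), c(1, 3, 2))

  second <- function(half, C2) {
    n2 <- ncol(C2)
    m <- matrix(half, n_aux * dim(half)[2], n_ao) %*% C2
    .count_flops(as.numeric(n_aux) * dim(half)[2] * n_ao * n2)
    array(m, c(n_aux, dim(half)[2], n2))
  }
  M_ia <- second(half_occ, C_virt)                  # (Q, i, a)
  M_ij <- second(half_occ, C_occ)                   # (Q, i, j)

  whiten <- function(M) {
    dm <- dim(M)
    J <- crossprod(Tm, matrix(M, n_aux, dm[2] * dm[3]))
    .count_flops(as.numeric(n_aux) * transform$rank * dm[2] * dm[3])
    array(J, c(transform$rank, dm[2], dm[3]))
  }
  audit <- .df_audit_env()
  obj <- list(
    J_ia = whiten(M_ia),
    J_ij = whiten(M_ij),
    n_aux_effective = transform$rank,
    n_occ = n_occ, n_virt = n_virt,
    audit = audit)
  ## on-demand virt-virt slice: J[, c, a] for fixed virtual c
  force(C_virt); force(Tm)
  obj$j_ab_slice <- function(c_index) {
    stopifnot(c_index >= 1L, c_index <= n_virt)
    audit$jab_requests <- c(audit$jab_requests, as.integer(c_index))
    dvec <- C_virt[, c_index]
    H <- matrix(ao_three_center, n_aux * n_ao, n_ao) %*% dvec   # (Q, nu)
    S <- matrix(H, n_aux, n_ao) %*% C_virt                      # Q x a
    .count_flops(as.numeric(n_aux) * n_ao * (n_ao + n_virt))
    crossprod(Tm, S)                                            # rank x a
  }
  class(obj) <- "df_tensor"
  obj
}

#' @export
print.df_tensor <- function(x, ...) {
  cat(sprintf(
    "DF tensor: %d occupied x %d virtual, effective aux rank %d\n",
    x$n_occ, x$n_virt, x$n_aux_effective))
  cat(sprintf("  blocks held: J_ia, J_ij; virt-virt slices served: %d\n",
              length(x$audit$jab_requests)))
  invisible(x)
}

## J_ia as a (rank x occ*virt) matrix; pair (i,a) is column i + (a-1)*n_occ.
.j_ia_mat <- function(df) matrix(df$J_ia, df$n_aux_effective,
                                 df$n_occ * df$n_virt)
.j_ij_mat <- function(df) matrix(df$J_ij, df$n_aux_effective,
                                 df$n_occ * df$n_occ)

#' Reconstruct the (ia|jb) integral matrix from the DF factors
#'
#' Convenience for diagnostics and small systems: returns the full
#' `K = J J^T` matrix over occupied-virtual pairs. Quadratic in the pair
#' count, so intended for toy-sized references only.
#'
#' @param df A `df_tensor`.
#' @return `(n_occ*n_virt) x (n_occ*n_virt)` matrix, pair index `(i, a)`
#'   mapped to `i + (a-1)*n_occ`.
#' @export
df_reconstruct_ovov <- function(df) {
  J <- .j_ia_mat(df)
  crossprod(J)
}

## space partition helper: MO column indices per block for a reference
df_spaces <- function(ref) {
  list(frozen = seq_len(ref$n_frozen_core),
       occ = .active_occ_idx(ref),
       virt = .virt_idx(ref))
}
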
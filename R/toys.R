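## Synthetic reference states.
##
## A "toy" stands in for the output of a converged SCF calculation: random
## orthonormal MO coefficients, orbital energies with a guaranteed HOMO-LUMO
## gap, and random (symmetric, well-conditioned) AO-basis density-fitting
## integrals. The three-center magnitudes are kept small relative to the gap
## (sigma default 0.05 hartree) so that second-order corrections are
## perturbative and the folded ionization/attachment problems stay
## single-root dominant -- the physical regime the correlated methods
## target. Generation is fully deterministic for a fixed seed
## (Mersenne-Twister / Inversion, fixed by name).

.with_toy_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

.make_toy_fragment <- function(n_occ, n_virt, n_aux, seed, gap_min, sigma,
                               n_frozen) {
  .with_toy_rng(seed, {
    n_mo <- n_frozen + n_occ + n_virt
    n_ao <- n_mo
    ## orbital energies: frozen core deep, valence occupied in [-2, -0.5],
    ## virtuals starting gap_min above the HOMO
    eps_core <- if (n_frozen > 0L) sort(stats::runif(n_frozen, -25, -10))
                else numeric(0)
    ## fixed global windows (occupied below -0.5, virtuals above
    ## -0.5 + gap_min) so any direct sum of fragments keeps the gap
    eps_occ <- sort(stats::runif(n_occ, -2, -0.5))
    eps_virt <- sort(stats::runif(n_virt, -0.5 + gap_min,
                                  -0.5 + gap_min + 1.5))
    ## random orthonormal coefficients (QR with sign fixing for determinism)
    A <- matrix(stats::rnorm(n_ao * n_mo), n_ao, n_mo)
    qrA <- qr(A)
    C <- qr.Q(qrA)
    sgn <- sign(diag(qr.R(qrA))); sgn[sgn == 0] <- 1
    C <- sweep(C, 2, sgn, "*")
    ## AO three-center integrals, symmetric in the AO pair
    I3 <- array(stats::rnorm(n_aux * n_ao * n_ao, sd = sigma),
                c(n_aux, n_ao, n_ao))
    I3 <- (I3 + aperm(I3, c(1, 3, 2))) / 2
    ## well-conditioned SPD Coulomb metric
    W <- matrix(stats::rnorm(n_aux * n_aux), n_aux, n_aux)
    V <- tcrossprod(W) / n_aux + diag(n_aux)
    list(C = C, eps = c(eps_core, eps_occ, eps_virt), I3 = I3, V = V,
         n_frozen = n_frozen, n_occ = n_occ, n_virt = n_virt, n_aux = n_aux)
  })
}

.direct_sum_fragments <- function(frs) {
  n_ao <- sum(vapply(frs, function(f) nrow(f$C), numeric(1)))
  n_aux <- sum(vapply(frs, function(f) f$n_aux, numeric(1)))
  I3 <- array(0, c(n_aux, n_ao, n_ao))
  V <- matrix(0, n_aux, n_aux)
  C <- matrix(0, n_ao, n_ao)
  off_ao <- 0L; off_aux <- 0L
  mo_frag <- integer(0); mo_eps <- numeric(0); mo_kind <- character(0)
  cols <- list()
  for (f in seq_along(frs)) {
    fr <- frs[[f]]
    na <- nrow(fr$C); nx <- fr$n_aux
    I3[off_aux + seq_len(nx), off_ao + seq_len(na), off_ao + seq_len(na)] <-
      fr$I3
    V[off_aux + seq_len(nx), off_aux + seq_len(nx)] <- fr$V
    C[off_ao + seq_len(na), length(mo_eps) + seq_len(ncol(fr$C))] <- fr$C
    mo_eps <- c(mo_eps, fr$eps)
    mo_frag <- c(mo_frag, rep(f, ncol(fr$C)))
    mo_kind <- c(mo_kind,
                 rep(c("frozen", "occ", "virt"),
                     c(fr$n_frozen, fr$n_occ, fr$n_virt)))
    off_ao <- off_ao + na; off_aux <- off_aux + nx
  }
  ## reorder: frozen, then occupied ascending, then virtual ascending
  ord <- c(which(mo_kind == "frozen")[order(mo_eps[mo_kind == "frozen"])],
           which(mo_kind == "occ")[order(mo_eps[mo_kind == "occ"])],
           which(mo_kind == "virt")[order(mo_eps[mo_kind == "virt"])])
  list(C = C[, ord, drop = FALSE], eps = mo_eps[ord], I3 = I3, V = V,
       fragment_of = mo_frag[ord],
       n_frozen = sum(mo_kind == "frozen"),
       n_occ = sum(mo_kind == "occ"), n_virt = sum(mo_kind == "virt"),
       n_aux = n_aux)
}

#' Generate a synthetic reference state with DF factors
#'
#' Builds a deterministic pseudo-random reference (see the module notes in
#' the source) plus its blocked DF tensor via the production metric/transform
#' path. With `fragments > 1` the requested sizes are split evenly over
#' non-interacting fragments whose AO integrals, metric, and coefficients
#' are exactly block diagonal; cross-fragment entries of every derived
#' quantity are then exactly zero, which underpins the size-intensivity
#' tests. Fragment seeds are derived from `seed` (fragment f uses
#' `seed + 7919*(f-1)`), so fragment 1 of a dimer reproduces the monomer
#' generated with the same sizes and `seed` itself.
#'
#' @param n_occ,n_virt,n_aux Total active occupied / virtual / auxiliary
#'   dimensions (divisible by `fragments`).
#' @param seed Integer seed.
#' @param gap_min Guaranteed HOMO-LUMO gap in hartree.
#' @param sigma Magnitude scale of the AO three-center integrals.
#' @param fragments Number of non-interacting fragments.
#' @param identical_fragments If `TRUE`, every fragment reuses the same seed
#'   (a dimer of identical monomers).
#' @param n_frozen Number of frozen-core orbitals (fragments = 1 only).
#' @param drop_tol Metric conditioning threshold, see
#'   [build_metric_inverse_sqrt()].
#' @return List with `ref` (a `reference_state`), `df` (a `df_tensor`),
#'   `ao` (raw AO handles: `ao_three_center`, `metric`), and `fragment_of`
#'   (fragment label per MO).
#' @export
make_toy_reference <- function(n_occ = 4L, n_virt = 6L, n_aux = 20L,
                               seed = 7L, gap_min = 0.2, sigma = 0.05,
                               fragments = 1L, identical_fragments = FALSE,
                               n_frozen = 0L, drop_tol = 1e-10) {
  stopifnot(n_occ >= 1L, n_virt >= 1L, n_aux >= 1L, fragments >= 1L)
  if (gap_min <= 0)
    stop("gap construction infeasible: gap_min must be positive",
         call. = FALSE)
  if (fragments > 1L) {
    if (n_occ %% fragments || n_virt %% fragments || n_aux %% fragments)
      stop("fragment sizes must divide n_occ, n_virt, n_aux", call. = FALSE)
    if (n_frozen > 0L)
      stop("frozen cores are only supported for fragments = 1", call. = FALSE)
    frs <- lapply(seq_len(fragments), function(f) {
      s <- if (identical_fragments) seed else seed + 7919L * (f - 1L)
      .make_toy_fragment(n_occ %/% fragments, n_virt %/% fragments,
                         n_aux %/% fragments, s, gap_min, sigma, 0L)
    })
    raw <- .direct_sum_fragments(frs)
  } else {
    raw <- .make_toy_fragment(n_occ, n_virt, n_aux, seed, gap_min, sigma,
                              as.integer(n_frozen))
    raw$fragment_of <- rep(1L, length(raw$eps))
  }
  func <- scaled_functional(1, 1, name = sprintf("toy(seed=%d)", seed))
  ref <- reference_state(raw$C, raw$eps, raw$n_frozen, raw$n_occ,
                         raw$n_virt, produced_by = func)
  tr <- build_metric_inverse_sqrt(raw$V, drop_tol = drop_tol)
  df <- build_df_tensor(raw$I3, raw$C, df_spaces(ref), tr)
  list(ref = ref, df = df,
       ao = list(ao_three_center = raw$I3, metric = raw$V),
       fragment_of = raw$fragment_of)
}

#' The shipped fixture manifest
#'
#' Seeds and sizes of the standard synthetic-reference suite used by the
#' validation tests; the references themselves are always regenerated in
#' code from these parameters.
#'
#' @param suite Optional filter, `"perturbative"` or `"iterative"`.
#' @return data.frame with columns `suite`, `seed`, `n_occ`, `n_virt`,
#'   `n_aux`, `gap_min`, `sigma`.
#' @export
toy_manifest <- function(suite = NULL) {
  path <- system.file("extdata", "toy_manifest.tsv", package = "dhipea")
  if (!nzchar(path)) path <- "inst/extdata/toy_manifest.tsv"
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(suite)) tab <- tab[tab$suite == suite, , drop = FALSE]
  tab
}

#' Build one toy from a manifest row
#'
#' @param row One-row data.frame from [toy_manifest()].
#' @return See [make_toy_reference()].
#' @export
toy_from_manifest <- function(row) {
  make_toy_reference(n_occ = row$n_occ, n_virt = row$n_virt,
                     n_aux = row$n_aux, seed = row$seed,
                     gap_min = row$gap_min, sigma = row$sigma)
}
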
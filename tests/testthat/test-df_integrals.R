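test_that("metric inverse square root matches an explicit 2x2 oracle", {
  id <- build_metric_inverse_sqrt(diag(3))
  expect_equal(tcrossprod(id$transform), diag(3), tolerance = 1e-14)
  expect_equal(id$rank, 3L)

  V <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  tr <- build_metric_inverse_sqrt(V)
  ## T T^T must equal V^-1 (explicit 2x2 inverse)
  Vinv <- matrix(c(1, -0.5, -0.5, 1), 2, 2) / 0.75
  expect_lt(max(abs(tcrossprod(tr$transform) - Vinv)), 1e-12)
  expect_lt(max(abs(t(tr$transform) %*% V %*% tr$transform - diag(2))),
            1e-12)

  expect_error(build_metric_inverse_sqrt(matrix(c(1, 2, 0, 1), 2, 2)),
               "not symmetric")
  expect_error(build_metric_inverse_sqrt(V, drop_tol = 2), "drop_tol")
})

test_that("an exactly singular metric loses rank but not accuracy", {
  toy <- make_toy_reference(3, 4, 8, seed = 5)
  V <- toy$ao$metric
  I3 <- toy$ao$ao_three_center
  ## duplicate the last auxiliary function
  n <- nrow(V)
  V2 <- rbind(cbind(V, V[, n]), c(V[n, ], V[n, n]))
  I32 <- array(0, dim(I3) + c(1, 0, 0))
  I32[1:n, , ] <- I3
  I32[n + 1, , ] <- I3[n, , ]
  tr2 <- build_metric_inverse_sqrt(V2)
  expect_identical(tr2$rank, n)
  df2 <- build_df_tensor(I32, toy$ref$mo_coefficients, df_spaces(toy$ref),
                         tr2)
  expect_lt(max(abs(df_reconstruct_ovov(df2) - df_reconstruct_ovov(toy$df))),
            1e-10)
})

test_that("K = J J^T reproduces the naive I V^-1 I^T contraction", {
  toy <- standard_toy()
  g <- oracle_mo_integrals(toy)
  K <- df_reconstruct_ovov(toy$df)
  n_occ <- 4L; n_virt <- 6L
  occ <- seq_len(n_occ); virt <- n_occ + seq_len(n_virt)
  for (i in occ) for (a in seq_len(n_virt)) for (j in occ)
    for (b in seq_len(n_virt))
      expect_lt(abs(K[i + (a - 1) * n_occ, j + (b - 1) * n_occ] -
                      g[i, virt[a], j, virt[b]]), 1e-11)
  ## symmetry under (ia) <-> (jb) and positive semidefiniteness
  expect_lt(max(abs(K - t(K))), 1e-13)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("identity coefficients reindex the AO tensor unchanged", {
  set.seed(42)
  n_ao <- 5L; n_aux <- 6L
  I3 <- array(rnorm(n_aux * n_ao * n_ao), c(n_aux, n_ao, n_ao))
  I3 <- (I3 + aperm(I3, c(1, 3, 2))) / 2
  spaces <- list(frozen = integer(0), occ = 1:2, virt = 3:5)
  df <- build_df_tensor(I3, diag(n_ao), spaces,
                        list(transform = diag(n_aux), rank = n_aux))
  expect_equal(df$J_ia[, 2, 3], I3[, 2, 5])
  expect_equal(df$J_ij[, 1, 2], I3[, 1, 2])
  expect_equal(drop(df$j_ab_slice(1L)[, 2]), I3[, 3, 4])
  expect_error(build_df_tensor(I3, diag(4), spaces,
                               list(transform = diag(n_aux), rank = n_aux)),
               "dimension mismatch")
})

test_that("ionization workflows never touch virtual-virtual factors", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  ## no virt-virt block is ever held on the tensor itself
  expect_false(any(grepl("ab", setdiff(names(toy$df), "j_ab_slice"))))
  invisible(vip_correction(toy$df, eps, 4))
  invisible(prepare_sigma_workspace(toy$df, eps, "ip", c(1, 1)))
  expect_length(toy$df$audit$jab_requests, 0L)
  ## the EA perturbative path requests exactly the one slice it needs
  invisible(vea_correction(toy$df, eps, 2))
  expect_identical(toy$df$audit$jab_requests, 2L)
})

test_that("two-fragment references have exactly zero cross-fragment factors", {
  dim2 <- make_toy_reference(4, 6, 20, seed = 11, fragments = 2)
  frag <- dim2$fragment_of
  occ_f <- frag[1:4]
  virt_f <- frag[5:10]
  J <- dim2$df$J_ia
  for (i in 1:4) for (a in 1:6)
    if (occ_f[i] != virt_f[a])
      expect_identical(max(abs(J[, i, a])), 0)
  ## and the reconstructed K vanishes between pairs on different fragments
  K <- df_reconstruct_ovov(dim2$df)
  pair_frag <- as.vector(outer(occ_f, virt_f,
                               function(x, y) ifelse(x == y, x, NA)))
  same <- which(!is.na(pair_frag))
  for (p in same) for (q in same)
    if (pair_frag[p] != pair_frag[q])
      expect_identical(K[p, q], 0)
})
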
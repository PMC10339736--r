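test_that("sigma is the dense folded matrix action, and is linear", {
  toy <- make_toy_reference(3, 4, 12, seed = 19)
  eps <- orbital_energy_blocks(toy$ref)
  scales <- c(1.2, 0.5)
  for (ch in c("ip", "ea")) {
    ws <- prepare_sigma_workspace(toy$df, eps, ch, scales)
    orc <- dense_adc2_oracle(toy, ch, scales)
    n1 <- ws$n_singles
    apply_fn <- if (ch == "ip") sigma_ip else sigma_ea
    for (omega in c(0.9, 1.7)) {
      ## dense route: fold the oracle's explicit blocks at the same omega
      Cb <- orc$blocks$coupling
      M_dense <- orc$blocks$singles +
        Cb %*% (t(Cb) / (omega - orc$blocks$doubles_diag))
      M_prod <- sapply(seq_len(n1), function(i) {
        e <- numeric(n1); e[i] <- 1
        apply_fn(e, omega, ws)
      })
      expect_lt(max(abs(M_prod - M_dense)), 1e-12)
    }
    ## linearity and additivity at fixed omega
    set.seed(1)
    v1 <- rnorm(n1); v2 <- rnorm(n1)
    expect_equal(apply_fn(2 * v1, 1.1, ws), 2 * apply_fn(v1, 1.1, ws),
                 tolerance = 1e-13)
    expect_equal(apply_fn(v1 + v2, 1.1, ws),
                 apply_fn(v1, 1.1, ws) + apply_fn(v2, 1.1, ws),
                 tolerance = 1e-12)
  }
})

test_that("zero scales make sigma diagonal and the solve immediate", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  ws_ip <- prepare_sigma_workspace(toy$df, eps, "ip", c(0, 0))
  ws_ea <- prepare_sigma_workspace(toy$df, eps, "ea", c(0, 0))
  v <- seq_len(4) / 4
  expect_equal(sigma_ip(v, 0.7, ws_ip), -eps$occ * v, tolerance = 1e-14)
  w <- seq_len(6) / 6
  expect_equal(sigma_ea(w, 0.7, ws_ea), eps$virt * w, tolerance = 1e-14)
  for (k in 1:4) {
    st <- solve_state(ws_ip, k)
    expect_identical(st$iterations, 1L)
    expect_equal(st$omega, -eps$occ[k], tolerance = 1e-14)
    first <- first_order_states(toy$ref, "ip", 4)
    expect_equal(st$omega, first$omega_first[first$orbital == k])
  }
})

test_that("the folded solver matches the dense oracle root by root", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  scales <- c(1.2, 0.5)
  for (ch in c("ip", "ea")) {
    ws <- prepare_sigma_workspace(toy$df, eps, ch, scales)
    orc <- dense_adc2_oracle(toy, ch, scales)
    for (t in seq_len(ws$n_singles)) {
      st <- solve_state(ws, t)
      expect_true(st$converged)
      expect_equal(sum(st$vector^2), 1, tolerance = 1e-12)
      r <- orc$root_for_target(t)
      expect_equal(st$omega, orc$values[r], tolerance = 1e-6)
    }
  }
})

test_that("root following tracks a target that is not the lowest root", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  ws <- prepare_sigma_workspace(toy$df, eps, "ip", c(1.2, 0.5))
  orc <- dense_adc2_oracle(toy, "ip", c(1.2, 0.5))
  ## target the 3rd-highest occupied: its state is the 3rd-lowest 1h root
  st <- solve_state(ws, 2L)
  singles_dominant <- which(orc$singles_norm2 > 0.5)
  expect_equal(st$omega, orc$values[singles_dominant[3]], tolerance = 1e-6)
  expect_gt(st$omega, solve_state(ws, 4L)$omega)  # not the lowest root
})

test_that("the N^5 precompute runs once per workspace regardless of states", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  reset_counters()
  ws <- prepare_sigma_workspace(toy$df, eps, "ip", c(1, 1))
  expect_identical(read_counters()$y_builds, 1L)
  for (k in c(4L, 3L, 2L)) invisible(solve_state(ws, k))
  expect_identical(read_counters()$y_builds, 1L)
})

test_that("iterative and perturbative ansaetze agree to first order", {
  ## Richardson-style continuity: with the second-order block scaled by a
  ## small lambda, the iterative relaxation is O(lambda^2)
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  pc <- vip_correction(toy$df, eps, 4)
  dev <- sapply(c(1e-3, 2e-3), function(lam) {
    ws <- prepare_sigma_workspace(toy$df, eps, "ip", lam * c(1, 1))
    st <- solve_state(ws, 4L, conv_energy = 1e-13)
    cisd <- pc$omega_first + lam * (pc$os + pc$ss)
    st$omega - cisd
  })
  corr <- 1e-3 * abs(pc$os + pc$ss)
  expect_lt(abs(dev[1]), 0.01 * corr)            # agreement to first order
  expect_equal(dev[2] / dev[1], 4, tolerance = 0.2)  # quadratic remainder
})

test_that("pole strengths obey their limits and match the oracle", {
  toy <- make_toy_reference(3, 4, 14, seed = 29)
  eps <- orbital_energy_blocks(toy$ref)
  ws0 <- prepare_sigma_workspace(toy$df, eps, "ip", c(0, 0))
  st0 <- solve_state(ws0, 3L)
  expect_identical(pole_strength(st0, ws0), 1)
  scales <- c(1, 1)
  for (ch in c("ip", "ea")) {
    ws <- prepare_sigma_workspace(toy$df, eps, ch, scales)
    orc <- dense_adc2_oracle(toy, ch, scales)
    for (t in seq_len(ws$n_singles)) {
      st <- solve_state(ws, t, conv_energy = 1e-11, resid_tol = 1e-10)
      r <- orc$root_for_target(t)
      expect_equal(pole_strength(st, ws), orc$singles_norm2[r],
                   tolerance = 1e-8)
      expect_lte(pole_strength(st, ws), 1)
    }
  }
  ## monotone decrease with growing opposite-spin weight
  p <- sapply(c(0.5, 1, 1.5), function(cs) {
    w <- prepare_sigma_workspace(toy$df, eps, "ip", c(cs, 0))
    pole_strength(solve_state(w, 3L), w)
  })
  expect_true(all(diff(p) < 0))
  expect_error(pole_strength(structure(list(converged = FALSE),
                                       class = "iterative_state"), ws0),
               "converged")
})
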
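test_that("toy generation is bit-reproducible and respects its contracts", {
  t1 <- standard_toy()
  t2 <- standard_toy()
  expect_identical(t1$ref$orbital_energies, t2$ref$orbital_energies)
  expect_identical(t1$ref$mo_coefficients, t2$ref$mo_coefficients)
  expect_identical(t1$ao$ao_three_center, t2$ao$ao_three_center)
  expect_identical(t1$df$J_ia, t2$df$J_ia)
  ## generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(standard_toy()); after <- rnorm(3)
  expect_identical(before, after)
  ## guaranteed gap
  for (gap in c(0.2, 0.5)) {
    toy <- make_toy_reference(3, 3, 10, seed = 2, gap_min = gap)
    e <- orbital_energy_blocks(toy$ref)
    expect_gte(min(e$virt) - max(e$occ), gap)
  }
  expect_error(make_toy_reference(2, 2, 5, gap_min = -1), "infeasible")
  ## fragmented toys split sizes evenly and label orbitals
  dm <- make_toy_reference(4, 6, 20, seed = 11, fragments = 2)
  expect_equal(sort(unique(dm$fragment_of)), c(1L, 2L))
  expect_error(make_toy_reference(3, 6, 20, fragments = 2), "divide")
})

test_that("the fixture manifest regenerates deterministically", {
  man <- toy_manifest()
  expect_gte(sum(man$suite == "perturbative"), 20L)
  expect_gte(sum(man$suite == "iterative"), 10L)
  row <- man[man$seed == 103, ]
  toy <- toy_from_manifest(row)
  expect_identical(toy$ref$n_occupied_active, row$n_occ)
  expect_identical(toy$ref$n_virtual, row$n_virt)
})

test_that("oracle decomposition identities hold", {
  toy <- make_toy_reference(3, 4, 12, seed = 17)
  ## OS + SS parts sum to the unscaled total; zero scales give zero
  o <- dense_selfenergy_oracle(toy, 3, "ip", scales = c(1, 1))
  expect_equal(o$scaled, o$os + o$ss, tolerance = 1e-14)
  o0 <- dense_selfenergy_oracle(toy, 3, "ip", scales = c(0, 0))
  expect_identical(o0$scaled, 0)
  ## the oracle size guard refuses big systems
  big <- make_toy_reference(7, 9, 30, seed = 1)
  expect_error(dense_selfenergy_oracle(big, 1, "ip"), "size guard")
})

test_that("the unfolded oracle matrix solves the folded problem exactly", {
  ## two independent dense routes: eigenvalues of the explicit
  ## singles+doubles matrix versus per-root self-consistent folding by
  ## scalar iteration on omega
  toy <- make_toy_reference(3, 4, 12, seed = 23)
  scales <- c(1, 1)
  for (ch in c("ip", "ea")) {
    orc <- dense_adc2_oracle(toy, ch, scales)
    A <- orc$blocks$singles; Cb <- orc$blocks$coupling
    D <- orc$blocks$doubles_diag
    for (t in seq_len(orc$n_singles)) {
      r <- orc$root_for_target(t)
      omega <- orc$values[r] + 1e-3     # start off the root
      for (it in 1:100) {
        M <- A + Cb %*% (t(Cb) / (omega - D))
        ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
        sel <- which.max(abs(ev$vectors[t, ]))
        new_omega <- ev$values[sel]
        if (abs(new_omega - omega) < 1e-12) break
        omega <- new_omega
      }
      expect_equal(omega, orc$values[r], tolerance = 1e-10)
    }
  }
})

test_that("zero scales collapse the oracle roots onto orbital energies", {
  toy <- make_toy_reference(3, 4, 12, seed = 23)
  eps <- orbital_energy_blocks(toy$ref)
  oip <- dense_adc2_oracle(toy, "ip", scales = c(0, 0))
  singles_ip <- sort(oip$values[oip$singles_norm2 > 0.999999])
  expect_equal(singles_ip, sort(-eps$occ), tolerance = 1e-12)
  oea <- dense_adc2_oracle(toy, "ea", scales = c(0, 0))
  singles_ea <- sort(oea$values[oea$singles_norm2 > 0.999999])
  expect_equal(singles_ea, sort(eps$virt), tolerance = 1e-12)
})

test_that("a 1x1 singles space reduces to the scalar fixed-point root", {
  toy <- make_toy_reference(1, 2, 6, seed = 5)
  eps <- orbital_energy_blocks(toy$ref)
  orc <- dense_adc2_oracle(toy, "ip", scales = c(1, 1))
  ## scalar nonlinear equation omega = a + sum_c v_c^2/(omega - d_c)
  a <- drop(orc$blocks$singles)
  v <- drop(orc$blocks$coupling)
  d <- orc$blocks$doubles_diag
  omega <- a
  for (it in 1:200) omega <- a + sum(v^2 / (omega - d))
  r <- orc$root_for_target(1)
  expect_equal(orc$values[r], omega, tolerance = 1e-10)
  ## and the production solver lands on the same value
  ws <- prepare_sigma_workspace(toy$df, eps, "ip", c(1, 1))
  st <- solve_state(ws, 1L, conv_energy = 1e-12)
  expect_equal(st$omega, omega, tolerance = 1e-8)
})
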
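test_that("first-order states are signed orbital energies with unit vectors", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  ip <- first_order_states(toy$ref, "ip", 2)
  expect_equal(ip$omega_first, -eps$occ[c(4, 3)])
  expect_equal(ip$label, c("HOMO", "HOMO-1"))
  ea <- first_order_states(toy$ref, "ea", 3)
  expect_equal(ea$omega_first, eps$virt[1:3])
  expect_equal(ea$label, c("LUMO", "LUMO+1", "LUMO+2"))
  expect_error(first_order_states(toy$ref, "ip", 5), "exceeds")
  ## eps_HOMO = -0.5 Eh corresponds to 13.6057 eV
  expect_equal(round(hartree_to_ev(0.5), 4), 13.6057)
})

test_that("a degenerate HOMO yields two states in stable index order", {
  C <- diag(4)
  ref <- reference_state(C, c(-0.8, -0.5, -0.5, 0.4), 0, 3, 1)
  st <- first_order_states(ref, "ip", 2)
  expect_equal(st$orbital, c(3L, 2L))
  expect_equal(st$omega_first, c(0.5, 0.5))
})

test_that("V intermediates match the integrals they stand for", {
  toy <- make_toy_reference(3, 4, 12, seed = 19)
  eps <- orbital_energy_blocks(toy$ref)
  g <- oracle_mo_integrals(toy)
  k <- 3L
  v <- build_v_ija(toy$df, eps, k)
  for (j in 1:3) for (l in 1:3) for (a in 1:4) {
    expect_equal(v$direct[j, l, a], g[k, j, 3 + a, l], tolerance = 1e-12)
    expect_equal(v$exchange[j, l, a], g[k, l, 3 + a, j], tolerance = 1e-12)
  }
  cc <- 2L
  w <- build_v_iab(toy$df, eps, cc)
  for (a in 1:4) for (i in 1:3) for (b in 1:4)
    expect_equal(w$direct[a, i, b], g[3 + cc, 3 + a, i, 3 + b],
                 tolerance = 1e-12)
  ## zero factors give zero intermediates
  sp <- single_pair_df(g2 = 0)
  expect_identical(max(abs(build_v_ija(sp$df, sp$eps, 1)$direct)), 0)
  expect_identical(max(abs(build_v_iab(sp$df, sp$eps, 1)$direct)), 0)
  expect_error(build_v_ija(toy$df, eps, 5), "occupied")
  expect_error(build_v_iab(toy$df, eps, 9), "virtual")
})

test_that("perturbative corrections equal the dense self-energy oracle", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  for (k in c(1L, 4L)) {
    got <- vip_correction(toy$df, eps, k)
    want <- dense_selfenergy_oracle(toy, k, "ip")
    expect_equal(got$os, want$os, tolerance = 1e-12)
    expect_equal(got$ss, want$ss, tolerance = 1e-12)
  }
  for (cc in c(1L, 6L)) {
    got <- vea_correction(toy$df, eps, cc)
    want <- dense_selfenergy_oracle(toy, cc, "ea")
    expect_equal(got$os, want$os, tolerance = 1e-12)
    expect_equal(got$ss, want$ss, tolerance = 1e-12)
  }
})

test_that("the one-pair self-energy matches hand algebra", {
  toy <- make_toy_reference(1, 1, 4, seed = 3)
  eps <- orbital_energy_blocks(toy$ref)
  g <- oracle_mo_integrals(toy)
  ei <- eps$occ; ea <- eps$virt
  ## single occupied, single virtual: only opposite-spin survives
  os_hand <- -(g[1, 2, 1, 2]^2 / (ei + ei - 2 * ea) +
                 g[1, 1, 2, 1]^2 / (ei + ea - 2 * ei))
  want <- dense_selfenergy_oracle(toy, 1, "ip")
  expect_equal(want$os, os_hand, tolerance = 1e-13)
  expect_identical(want$ss, 0)
  got <- vip_correction(toy$df, eps, 1)
  expect_equal(got$os, os_hand, tolerance = 1e-12)
})

test_that("corrections are size-intensive over non-interacting fragments", {
  mono <- make_toy_reference(2, 3, 10, seed = 11)
  dim2 <- make_toy_reference(4, 6, 20, seed = 11, fragments = 2)
  em <- orbital_energy_blocks(mono$ref)
  ed <- orbital_energy_blocks(dim2$ref)
  for (k in 1:2) {
    kd <- which(abs(ed$occ - em$occ[k]) < 1e-12)
    pm <- vip_correction(mono$df, em, k)
    pd <- vip_correction(dim2$df, ed, kd[1])
    expect_equal(pm$os + pm$ss, pd$os + pd$ss, tolerance = 1e-8)
  }
  for (cc in 1:3) {
    cd <- which(abs(ed$virt - em$virt[cc]) < 1e-12)
    pm <- vea_correction(mono$df, em, cc)
    pd <- vea_correction(dim2$df, ed, cd[1])
    expect_equal(pm$os + pm$ss, pd$os + pd$ss, tolerance = 1e-8)
  }
})

test_that("apply_dh_scaling combines first and second order per contract", {
  res <- apply_dh_scaling(0.5, list(os = -0.01, ss = -0.002),
                          scaled_functional(1.3, 0), channel = "ip",
                          orbital = 4L)
  expect_equal(res$omega_final, 0.5 - 0.013, tolerance = 1e-14)
  expect_equal(res$final_eV, hartree_to_ev(res$omega_final))
  expect_identical(res$pole_strength, 1)   # perturbative ansatz
  expect_identical(res$iterations, 0L)
  ## plain (1,1) and global alpha_C scalings
  r11 <- apply_dh_scaling(0.5, list(os = -0.01, ss = -0.002),
                          scaled_functional(1, 1))
  expect_equal(r11$omega_final, 0.5 - 0.012)
  rqi <- apply_dh_scaling(0.5, list(os = -0.01, ss = -0.002),
                          resolve_functional("PBE-QIDH"))
  expect_equal(rqi$omega_final, 0.5 - 0.012 * 0.333333, tolerance = 1e-6)
  expect_error(apply_dh_scaling(0.5, list(os = 0, ss = 0),
                                resolve_functional("PBE0")),
               "no second-order correction")
})

test_that("a folded denominator hitting zero is flagged", {
  toy <- standard_toy()
  eps <- orbital_energy_blocks(toy$ref)
  bad_omega <- -(eps$occ[1] + eps$occ[2] - eps$virt[3])
  expect_error(vip_correction(toy$df, eps, 4, omega = bad_omega),
               "denominator")
})
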
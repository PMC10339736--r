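## shared helpers for building small fixtures in code

standard_toy <- function(seed = 7L, ...) {
  make_toy_reference(n_occ = 4L, n_virt = 6L, n_aux = 20L, seed = seed, ...)
}

## hand-built single-pair system: one occupied, one virtual, (ia|ia) = g2,
## eps = (-0.5, +0.5); constructed directly in the J representation
single_pair_df <- function(g2 = 0.1, eps_occ = -0.5, eps_virt = 0.5) {
  audit <- new.env(parent = emptyenv())
  audit$jab_requests <- integer(0)
  df <- structure(
    list(J_ia = array(sqrt(g2), c(1, 1, 1)),
         J_ij = array(0, c(1, 1, 1)),
         j_ab_slice = function(c_index) matrix(0, 1, 1),
         n_aux_effective = 1L, n_occ = 1L, n_virt = 1L, audit = audit),
    class = "df_tensor")
  list(df = df, eps = list(occ = eps_occ, virt = eps_virt))
}

write_water_xyz <- function(path, n_declared = 3L, scramble = FALSE) {
  atoms <- c("O 0.0000 0.0000 0.1173",
             "H 0.0000 0.7572 -0.4692",
             "H 0.0000 -0.7572 -0.4692")
  if (scramble) atoms <- atoms[c(2, 3, 1)]
  writeLines(c(as.character(n_declared), "water", atoms), path)
  path
}
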
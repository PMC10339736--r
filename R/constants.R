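#' @keywords internal
"_PACKAGE"

## Energies are held in hartree throughout; conversion to eV happens only at
## the reporting boundary (CODATA-2018 value).
HARTREE_EV <- 27.211386245988

## Periodic table, Z = 1..118, used for XYZ validation and frozen-core counts.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

## Count of frozen-core spatial orbitals per element: the orbitals of the
## preceding noble gas (H/He 0, Li-Ne 1, Na-Ar 5, K-Kr 9, Rb-Xe 18, Cs-Rn 27,
## Fr-Og 43).
.core_orbitals_for_z <- function(z) {
  shells <- c(2L, 10L, 18L, 36L, 54L, 86L, 118L)   # noble-gas electron counts
  cores <- c(0L, 1L, 5L, 9L, 18L, 27L, 43L)
  idx <- findInterval(z - 1L, shells) + 1L
  cores[idx]
}

atomic_number <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z
}

## ---- package-local counters -------------------------------------------------
## Lightweight instrumentation: multiply-add counts for the hot contractions
## (used to verify the advertised cost scaling empirically) and a counter for
## the once-per-job N^5 Y precompute.

.dh_counters <- new.env(parent = emptyenv())
.dh_counters$flops <- 0
.dh_counters$y_builds <- 0L

#' Reset the internal operation counters
#'
#' The package counts multiply-add operations of its dominant tensor
#' contractions and the number of times the N^5 ground-state Y intermediate
#' is rebuilt. These counters support empirical cost-scaling checks.
#'
#' @return Invisibly, the counter values before the reset.
#' @export
reset_counters <- function() {
  old <- read_counters()
  .dh_counters$flops <- 0
  .dh_counters$y_builds <- 0L
  invisible(old)
}

#' Read the internal operation counters
#'
#' @return A list with elements `flops` (multiply-add count of the dominant
#'   contractions since the last reset) and `y_builds` (number of N^5 Y
#'   intermediate constructions).
#' @export
read_counters <- function() {
  list(flops = .dh_counters$flops, y_builds = .dh_counters$y_builds)
}

.count_flops <- function(n) {
  .dh_counters$flops <- .dh_counters$flops + as.numeric(n)
  invisible(NULL)
}

#' Convert hartree to electronvolt
#'
#' @param x Energy in hartree.
#' @return Energy in eV (CODATA-2018 conversion, 27.211386245988 eV/Eh).
#' @export
hartree_to_ev <- function(x) x * HARTREE_EV
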
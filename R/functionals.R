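## Functional registry.
##
## The registry ships as a versioned plain-text table (inst/extdata). The
## class (family), the default ansatz, and the empirical-parameter count are
## authoritative fields; the numerical parameters (exact-exchange fraction,
## spin-resolved second-order scales, range-separation parameter) carry their
## own per-row source/citation fields.

.registry_cache <- new.env(parent = emptyenv())

.functional_families <- c("global_hybrid", "lc_hybrid", "global_DH",
                          "RS_DH", "LC_DH")

.normalize_functional_name <- function(name) {
  name <- gsub("\u03c9", "w", name)   # Greek omega -> w
  toupper(trimws(name))
}

#' The functional registry
#'
#' @return data.frame with one row per registered functional.
#' @export
functional_registry <- function() {
  if (is.null(.registry_cache$table)) {
    path <- system.file("extdata", "functionals.tsv", package = "dhipea")
    if (!nzchar(path)) path <- "inst/extdata/functionals.tsv"
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    .registry_cache$table <- tab
  }
  .registry_cache$table
}

#' Construct a functional configuration
#'
#' A `functional_config` carries everything the correlated stages need to
#' know about the functional under which the reference was produced: the
#' exact-exchange fraction, the opposite-/same-spin weights applied to the
#' second-order correction (a single global correlation fraction alpha_C is
#' encoded as `c_os = c_ss = alpha_C`), the range-separation parameter where
#' applicable, and the ansatz of the correlated step. Hybrid families define
#' no second-order machinery: their VIPs/VEAs are pure orbital-energy values.
#'
#' @param name Functional label.
#' @param family One of `global_hybrid`, `lc_hybrid`, `global_DH`, `RS_DH`,
#'   `LC_DH`.
#' @param alpha_x Fraction of exact exchange.
#' @param c_os,c_ss Non-negative opposite-/same-spin scales for the
#'   second-order terms.
#' @param omega Range-separation parameter in bohr^-1, or `NA`.
#' @param ansatz `"cisd"`, `"adc2"`, or `"none"`.
#' @param n_empirical_params Number of empirical parameters.
#' @param adc2_supported Whether the iterative ansatz is defined for this
#'   functional.
#' @param citation Free-text provenance of the numerical parameters.
#' @return Object of class `functional_config`.
#' @export
functional_config <- function(name, family, alpha_x, c_os, c_ss,
                              omega = NA_real_, ansatz = c("cisd", "adc2", "none"),
                              n_empirical_params = NA_integer_,
                              adc2_supported = TRUE, citation = "") {
  family <- match.arg(family, .functional_families)
  ansatz <- match.arg(ansatz)
  if (family %in% c("global_hybrid", "lc_hybrid")) {
    if (ansatz != "none" || c_os != 0 || c_ss != 0)
      stop("hybrid functional ", name, " defines no second-order correction: ",
           "ansatz must be 'none' with zero scales", call. = FALSE)
  }
  if (c_os < 0 || c_ss < 0)
    stop("second-order scales must be non-negative", call. = FALSE)
  structure(
    list(name = name, family = family, alpha_x = alpha_x,
         second_order_scales = c(os = c_os, ss = c_ss),
         range_sep_param = omega, ansatz = ansatz,
         n_empirical_params = as.integer(n_empirical_params),
         adc2_supported = isTRUE(adc2_supported), citation = citation),
    class = "functional_config")
}

#' Resolve a functional by name
#'
#' Case-insensitive lookup in the shipped registry (a Greek omega in the
#' query is treated as "w"). Hybrid families resolve with `ansatz = "none"`
#' and zero second-order scales, so that requesting their VIPs/VEAs reports
#' pure (negative) orbital energies.
#'
#' @param name Registered functional name, e.g. `"PBE0-2"`.
#' @param ansatz Correlated ansatz to attach: `"cisd"` (default for
#'   double hybrids), `"adc2"`, or `"none"`. Ignored for hybrids.
#' @return A `functional_config`.
#' @export
resolve_functional <- function(name, ansatz = NULL) {
  reg <- functional_registry()
  key <- .normalize_functional_name(name)
  hit <- match(key, .normalize_functional_name(reg$name))
  if (is.na(hit))
    stop("unknown functional ", sQuote(name), "; available: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  row <- reg[hit, ]
  hybrid <- row$family %in% c("global_hybrid", "lc_hybrid")
  if (is.null(ansatz)) ansatz <- if (hybrid) "none" else "cisd"
  if (hybrid) ansatz <- "none"
  if (ansatz == "adc2" && !isTRUE(row$adc2_supported))
    stop("the ADC(2)-based ansatz is not defined for ", row$name,
         call. = FALSE)
  functional_config(
    name = row$name, family = row$family, alpha_x = row$alpha_x,
    c_os = if (hybrid) 0 else row$c_os,
    c_ss = if (hybrid) 0 else row$c_ss,
    omega = row$omega, ansatz = ansatz,
    n_empirical_params = row$n_params,
    adc2_supported = isTRUE(row$adc2_supported),
    citation = paste0(row$citation, " [", row$param_source, "]"))
}

#' A bare functional configuration from explicit scales
#'
#' Convenience constructor used heavily with synthetic references: a global
#' double hybrid characterized only by its second-order spin scales.
#'
#' @param c_os,c_ss Opposite-/same-spin second-order scales.
#' @param ansatz `"cisd"` or `"adc2"`.
#' @param name Label.
#' @return A `functional_config`.
#' @export
scaled_functional <- function(c_os, c_ss, ansatz = "cisd",
                              name = sprintf("custom(%g,%g)", c_os, c_ss)) {
  functional_config(name = name, family = "global_DH", alpha_x = 1,
                    c_os = c_os, c_ss = c_ss, ansatz = ansatz,
                    n_empirical_params = 2L, citation = "user supplied")
}

#' @export
print.functional_config <- function(x, ...) {
  cat(sprintf("Functional %s [%s], ansatz %s\n", x$name, x$family, x$ansatz))
  cat(sprintf("  alpha_x = %g, scales (c_os, c_ss) = (%g, %g)",
              x$alpha_x, x$second_order_scales[["os"]],
              x$second_order_scales[["ss"]]))
  if (!is.na(x$range_sep_param))
    cat(sprintf(", omega = %g bohr^-1", x$range_sep_param))
  cat("\n")
  invisible(x)
}
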
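## Job orchestration: reference -> DF integrals -> states -> report.

.job_defaults <- list(
  method = "cisd", channel = "ip", n_states = 1L, frozen_core = "auto",
  conv_energy = 1e-6, max_iter = 50L, ea_sign = "attachment",
  drop_tol = 1e-10, backend = "toy")

#' Read a job configuration file
#'
#' Flat key-value job description in YAML. Recognized keys: `geometry`
#' (XYZ path), `functional` (registry name) or `scales` (`[c_os, c_ss]`),
#' `basis`, `aux_basis`, `method` (`orbital_energies`, `cisd`, `adc2`),
#' `channel` (`ip`, `ea`, `both`), `n_states`, `frozen_core` (`auto`,
#' `none`, or an integer), `conv_energy`, `max_iter`, `ea_sign`
#' (`attachment` or `ea`), `output`, `backend` (`toy`), and a nested `toy`
#' block with `n_occ`, `n_virt`, `n_aux`, `seed`, `gap_min`, `sigma`.
#'
#' @param path YAML file path.
#' @return Named list of job settings.
#' @export
read_job_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed job configuration", call. = FALSE)
  cfg
}

.resolve_job_functional <- function(config) {
  method <- config$method
  ansatz <- switch(method, orbital_energies = "none", cisd = "cisd",
                   adc2 = "adc2",
                   stop("unknown method ", sQuote(method), call. = FALSE))
  if (!is.null(config$functional)) {
    func <- resolve_functional(config$functional,
                               ansatz = if (ansatz == "none") NULL else ansatz)
    if (method != "orbital_energies" && func$ansatz == "none")
      stop("hybrid functional defines no second-order correction; use ",
           "method 'orbital_energies' with ", func$name, call. = FALSE)
    if (method == "adc2" && !func$adc2_supported)
      stop("the ADC(2)-based ansatz is not defined for ", func$name,
           call. = FALSE)
  } else if (!is.null(config$scales)) {
    sc <- as.numeric(config$scales)
    func <- scaled_functional(sc[1], sc[2],
                              ansatz = if (ansatz == "none") "cisd" else ansatz)
    if (ansatz == "none")
      func$second_order_scales[] <- 0
  } else {
    stop("job must specify a functional or explicit scales", call. = FALSE)
  }
  func
}

.state_record <- function(channel, label, orbital, omega_first,
                          corr_os = 0, corr_ss = 0, omega_final = NA_real_,
                          niter = 0L, pole = NA_real_, converged = TRUE,
                          error = NA_character_) {
  data.frame(channel = channel, orbital = label, orbital_index = orbital,
             omega1_eV = hartree_to_ev(omega_first),
             corr_os_eV = hartree_to_ev(corr_os),
             corr_ss_eV = hartree_to_ev(corr_ss),
             final_eV = hartree_to_ev(omega_final),
             niter = niter, pole_strength = pole, converged = converged,
             error = error, stringsAsFactors = FALSE)
}

.run_channel <- function(channel, config, func, ref, df, eps) {
  states <- first_order_states(ref, channel, config$n_states)
  scales <- unname(func$second_order_scales)
  flip <- channel == "ea" && identical(config$ea_sign, "ea")
  rows <- vector("list", nrow(states))
  ws <- NULL
  if (config$method == "adc2")
    ws <- prepare_sigma_workspace(df, eps, channel, scales)
  for (s in seq_len(nrow(states))) {
    orb <- states$orbital[s]; lab <- states$label[s]
    w1 <- states$omega_first[s]
    rec <- tryCatch({
      if (config$method == "orbital_energies") {
        .state_record(channel, lab, orb, w1, omega_final = w1, pole = 1)
      } else if (config$method == "cisd") {
        corr <- if (channel == "ip")
          vip_correction(df, eps, orb, scales)
        else vea_correction(df, eps, orb, scales)
        final <- w1 + scales[1] * corr$os + scales[2] * corr$ss
        .state_record(channel, lab, orb, w1,
                      corr_os = scales[1] * corr$os,
                      corr_ss = scales[2] * corr$ss,
                      omega_final = final, pole = 1)
      } else {
        st <- solve_state(ws, orb, conv_energy = config$conv_energy,
                          max_iter = config$max_iter)
        .state_record(channel, lab, orb, w1,
                      corr_os = NA_real_, corr_ss = NA_real_,
                      omega_final = st$omega, niter = st$iterations,
                      pole = pole_strength(st, ws))
      }
    }, error = function(e) {
      .state_record(channel, lab, orb, w1, omega_final = NA_real_,
                    converged = FALSE, error = conditionMessage(e))
    })
    if (flip) {
      rec$final_eV <- -rec$final_eV
      rec$omega1_eV <- -rec$omega1_eV
    }
    rows[[s]] <- rec
  }
  do.call(rbind, rows)
}

#' Run a full VIP/VEA job
#'
#' Orchestrates one calculation: resolve the functional, acquire the
#' reference from the backend, build the blocked DF tensor, and compute
#' the requested states. `method = "orbital_energies"` reports first-order
#' (Koopmans) values only; `"cisd"` adds the scaled perturbative (D)
#' correction; `"adc2"` runs the iterative folded solver with pole
#' strengths. `channel = "both"` runs `ip` then `ea`. States that fail to
#' converge are reported with a failure marker, never dropped.
#'
#' @param config Job configuration: a named list (see [read_job_config()]
#'   for the keys) or a path to a YAML file.
#' @param backend Optional SCF backend adapter; by default a synthetic toy
#'   backend configured from the `toy` block of the config.
#' @return Object of class `job_report`: list with `provenance`, `states`
#'   (one row per state), and `timing`.
#' @export
run_job <- function(config, backend = NULL) {
  if (is.character(config)) config <- read_job_config(config)
  config <- utils::modifyList(.job_defaults, config)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage, since) {
    timing[[stage]] <<- proc.time()[["elapsed"]] - since
    proc.time()[["elapsed"]]
  }
  func <- .resolve_job_functional(config)

  ## reference acquisition
  if (!is.null(config$geometry)) {
    mol <- load_geometry(config$geometry,
                         basis_name = config$basis %||% "cc-pVDZ",
                         aux_basis_name = config$aux_basis %||% "cc-pVDZ-RI")
    geometry_hash <- unname(tools::md5sum(config$geometry))
  } else {
    mol <- molecule_spec(data.frame(element = "He", x = 0, y = 0, z = 0),
                         comment = "synthetic reference placeholder")
    geometry_hash <- NA_character_
  }
  if (is.null(backend)) {
    if (!identical(config$backend, "toy"))
      stop("no backend adapter supplied for backend ",
           sQuote(config$backend), call. = FALSE)
    toy_args <- config$toy %||% list()
    backend <- do.call(toy_backend, toy_args)
  }
  acq <- acquire_reference(mol, func, backend)
  ref <- acq$ref
  t1 <- tick("reference", t0)

  ## frozen core: toy backends fix the partition themselves; an explicit
  ## or auto policy applied to a geometry re-partitions the reference
  if (!is.null(config$geometry) && !identical(config$frozen_core, "auto")) {
    n_fc <- select_frozen_core(mol, config$frozen_core,
                               n_occupied = ref$n_frozen_core +
                                 ref$n_occupied_active)
    total_occ <- ref$n_frozen_core + ref$n_occupied_active
    ref$n_frozen_core <- n_fc
    ref$n_occupied_active <- total_occ - n_fc
  }

  tr <- build_metric_inverse_sqrt(acq$ao$metric, drop_tol = config$drop_tol)
  df <- build_df_tensor(acq$ao$ao_three_center, ref$mo_coefficients,
                        df_spaces(ref), tr)
  eps <- orbital_energy_blocks(ref)
  t2 <- tick("integrals", t1)

  channels <- if (config$channel == "both") c("ip", "ea") else config$channel
  states <- do.call(rbind, lapply(channels, .run_channel, config = config,
                                  func = func, ref = ref, df = df,
                                  eps = eps))
  tick("states", t2)

  report <- structure(
    list(provenance = list(
           schema_version = 1L,
           package_version = as.character(utils::packageVersion("dhipea")),
           geometry_hash = geometry_hash,
           functional = func$name, ansatz = func$ansatz,
           scales = as.list(func$second_order_scales),
           basis = mol$basis_name, aux_basis = mol$aux_basis_name,
           frozen_core = ref$n_frozen_core,
           conv_energy = config$conv_energy,
           aux_rank = df$n_aux_effective,
           pole_strength_convention =
             "singles-block norm of the folded state; second-order terms spin-scaled"),
         states = states, timing = timing),
    class = "job_report")
  if (!is.null(config$output))
    write_report(report, format = "json", path = config$output)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.job_report <- function(x, ...) {
  cat("Job:", x$provenance$functional, "/", x$provenance$ansatz, "\n")
  df <- x$states
  df$omega1_eV <- sprintf("%.4f", df$omega1_eV)
  df$final_eV <- sprintf("%.4f", df$final_eV)
  print(df[, c("channel", "orbital", "omega1_eV", "final_eV", "niter",
               "pole_strength", "converged")], row.names = FALSE)
  invisible(x)
}

#' Write a job report to disk
#'
#' JSON output is schema-versioned and round-trips losslessly (the timing
#' block is excluded so identical jobs produce identical files); TSV output
#' has one row per state with the fixed column order `channel, orbital,
#' omega1_eV, corr_os_eV, corr_ss_eV, final_eV, niter, pole_strength` and
#' eV values printed to 4 decimals.
#'
#' @param report A `job_report`.
#' @param format `"json"` or `"tsv"`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, format = c("json", "tsv"), path) {
  format <- match.arg(format)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "json") {
    payload <- list(provenance = report$provenance, states = report$states)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    cols <- c("channel", "orbital", "omega1_eV", "corr_os_eV", "corr_ss_eV",
              "final_eV", "niter", "pole_strength")
    df <- report$states
    out <- df[, cols, drop = FALSE]
    for (cc in c("omega1_eV", "corr_os_eV", "corr_ss_eV", "final_eV"))
      out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.4f", out[[cc]]))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
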
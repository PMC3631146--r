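# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Reference per-site bacterial-load parameters
#'
#' Mean and SD of log10 CFU per (timepoint, site) used as the cohort
#' generator's defaults: baseline (T0) load over the future bracket area
#' and the four peri-bracket sites one week after bonding (T1) and one
#' week after archwire placement (T2).
#'
#' @return A tibble: `timepoint`, `site`, `mean`, `sd`.
#' @export
cfu_site_params <- function() {
  tibble::tribble(
    ~timepoint, ~site,          ~mean,  ~sd,
    "T0",       "BRACKET_AREA", 8.6332, 0.0207,
    "T1",       "BO",           9.0279, 0.0118,
    "T1",       "BG",           9.3366, 0.0057,
    "T1",       "BL",           9.0324, 0.0096,
    "T1",       "BR",           9.0360, 0.0131,
    "T2",       "BO",           9.0248, 0.0158,
    "T2",       "BG",           9.3908, 0.0177,
    "T2",       "BL",           9.3916, 0.0170,
    "T2",       "BR",           9.3837, 0.0170)
}

#' Reference periodontal parameters
#'
#' Gingival index (GI, ordinal 0-3 scale averaged per tooth) and probing
#' pocket depth (PD, mm) means and SDs per timepoint, used as the cohort
#' generator's defaults.
#'
#' @return A tibble: `measure`, `timepoint`, `mean`, `sd`.
#' @export
perio_params <- function() {
  tibble::tribble(
    ~measure, ~timepoint, ~mean,  ~sd,
    "gi",     "T0",       0.2222, 0.2229,
    "gi",     "T1",       0.2870, 0.2471,
    "gi",     "T2",       0.3611, 0.2532,
    "pd",     "T0",       0.6488, 0.1755,
    "pd",     "T1",       0.6759, 0.1677,
    "pd",     "T2",       0.7203, 0.2206)
}

#' Cohort-generator parameters
#'
#' @param n_patients Number of patients (default 27).
#' @param cfu Per-(timepoint, site) log10 CFU means/SDs; defaults to
#'   [cfu_site_params()].
#' @param perio GI/PD means and SDs per timepoint; defaults to
#'   [perio_params()].
#' @param rho_w Within-patient correlation in `[0, 1)`: the share of each
#'   measurement's variance carried by a shared patient effect.
#' @param ordinal_gi If `TRUE`, generated GI values are rounded to the
#'   ordinal 0-3 grid instead of being reported as continuous averages.
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(n_patients = 27, cfu = cfu_site_params(),
                          perio = perio_params(), rho_w = 0.5,
                          ordinal_gi = FALSE) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (rho_w < 0 || rho_w >= 1) stop("rho_w must be in [0, 1)", call. = FALSE)
  if (any(cfu$sd < 0) || any(perio$sd < 0))
    stop("SDs must be non-negative", call. = FALSE)
  structure(list(n_patients = n_patients, cfu = cfu, perio = perio,
                 rho_w = rho_w, ordinal_gi = isTRUE(ordinal_gi)),
            class = "cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient measurements around the per-group means with a
#' shared-patient-effect correlation structure: each value is
#' `mean + sd * (sqrt(rho_w) * z_patient + sqrt(1 - rho_w) * noise)`,
#' where `z_patient` is one standard-normal effect per patient and
#' measurement family (bacterial load, GI, PD).  GI is clipped to the
#' 0-3 scale and PD floored at 0.  Identical seeds give identical
#' cohorts.
#'
#' @param params A [cohort_params()].
#' @param seed Integer RNG seed.
#' @return A tibble of clinical records: `patient_id`, `timepoint`,
#'   `site`, `log10_cfu`, `gi`, `pd`.  T0 has a single `BRACKET_AREA` row
#'   per patient; T1/T2 have the four peri-bracket sites, with the
#'   tooth-level GI/PD repeated across site rows.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed, {
    np <- params$n_patients
    ids <- sprintf("P%03d", seq_len(np))
    rho <- params$rho_w
    z_cfu <- stats::rnorm(np)
    z_gi <- stats::rnorm(np)
    z_pd <- stats::rnorm(np)
    draw <- function(mean, sd, z) {
      mean + sd * (sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(np))
    }
    perio_wide <- tidyr::pivot_wider(params$perio, names_from = "measure",
                                     values_from = c("mean", "sd"))
    perio_vals <- purrr::map_dfr(seq_len(nrow(perio_wide)), function(i) {
      pw <- perio_wide[i, ]
      gi <- draw(pw$mean_gi, pw$sd_gi, z_gi)
      if (params$ordinal_gi) gi <- round(gi)
      tibble::tibble(patient_id = ids, timepoint = pw$timepoint,
                     gi = pmin(pmax(gi, 0), 3),
                     pd = pmax(draw(pw$mean_pd, pw$sd_pd, z_pd), 0))
    })
    cfu_vals <- purrr::map_dfr(seq_len(nrow(params$cfu)), function(i) {
      cf <- params$cfu[i, ]
      tibble::tibble(patient_id = ids, timepoint = cf$timepoint,
                     site = cf$site,
                     log10_cfu = draw(cf$mean, cf$sd, z_cfu))
    })
    out <- dplyr::left_join(cfu_vals, perio_vals,
                            by = c("patient_id", "timepoint"))
    dplyr::arrange(out, .data$patient_id,
                   factor(.data$timepoint, timepoint_levels),
                   factor(.data$site, site_levels))
  })
}

#' Dilution-plating parameters
#'
#' @param true_density True bacterial density, CFU/ml.
#' @param dilution_exponents Dilution series `10^-k`; integer exponents.
#' @param aliquot_volume Plated aliquot, ml (50 ul default).
#' @return A `plating_params` object.
#' @export
plating_params <- function(true_density, dilution_exponents = 0:9,
                           aliquot_volume = 0.05) {
  if (true_density <= 0) stop("true_density must be positive", call. = FALSE)
  if (aliquot_volume <= 0) stop("aliquot_volume must be positive", call. = FALSE)
  structure(list(true_density = true_density,
                 dilution_exponents = sort(as.integer(dilution_exponents)),
                 aliquot_volume = aliquot_volume),
            class = "plating_params")
}

#' Simulate serial-dilution plating
#'
#' Colony counts on each plate are Poisson with expectation
#' `true_density * aliquot_volume * 10^-k`.
#'
#' @param params A [plating_params()].
#' @param seed Integer RNG seed.
#' @return A tibble: `exponent`, `expected`, `count`.
#' @export
simulate_plating <- function(params, seed = 1) {
  stopifnot(inherits(params, "plating_params"))
  with_seed(seed, {
    lambda <- params$true_density * params$aliquot_volume *
      10^(-params$dilution_exponents)
    tibble::tibble(exponent = params$dilution_exponents,
                   expected = lambda,
                   count = stats::rpois(length(lambda), lambda))
  })
}

#' Estimate log10 density from a simulated dilution series
#'
#' Convenience round-trip: picks the first countable plate (0 < count <
#' 300) and applies [estimate_log10_cfu()].
#'
#' @param plates Output of [simulate_plating()].
#' @param aliquot_volume Plated aliquot, ml.
#' @return log10 CFU/ml, or `NA` if no plate is countable.
#' @export
estimate_from_plates <- function(plates, aliquot_volume = 0.05) {
  pl <- first_countable_plate(plates$count, plates$exponent)
  if (is.null(pl)) return(NA_real_)
  estimate_log10_cfu(pl$count, pl$exponent, aliquot_volume)
}
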
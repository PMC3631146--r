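#' Estimate log10 CFU/ml from a dilution plate
#'
#' Serial 10-fold dilutions of the 1 ml transport medium are plated as
#' 50 ul (0.05 ml) aliquots; a plate is countable only below 300 colonies.
#' The density estimate is `colony_count * 10^dilution_exponent /
#' aliquot_volume` CFU/ml, returned on the log10 scale.
#'
#' @param colony_count Integer colony count(s); must be `< 300`
#'   (uncountable-plate rule).  A zero count is below the detection limit
#'   and yields `NA` with a `below_detection` warning.
#' @param dilution_exponent Non-negative integer `k` for a `10^-k`
#'   dilution.
#' @param aliquot_volume Plated volume, ml.
#' @return log10 CFU per ml of transport medium.
#' @export
#' @examples
#' estimate_log10_cfu(150, 6)  # log10(3e9) = 9.477
estimate_log10_cfu <- function(colony_count, dilution_exponent,
                               aliquot_volume = 0.05) {
  if (any(dilution_exponent < 0) || any(dilution_exponent != round(dilution_exponent)))
    stop("dilution_exponent must be a non-negative integer", call. = FALSE)
  if (aliquot_volume <= 0) stop("aliquot_volume must be positive", call. = FALSE)
  if (any(colony_count < 0)) stop("negative colony count", call. = FALSE)
  if (any(colony_count >= 300))
    stop("uncountable plate: ", max(colony_count),
         " colonies >= 300; count the next dilution", call. = FALSE)
  out <- log10(colony_count * 10^dilution_exponent / aliquot_volume)
  if (any(colony_count == 0)) {
    out[colony_count == 0] <- NA_real_
    warning(warningCondition(
      "zero colonies: below detection limit",
      class = c("below_detection", "warning")))
  }
  out
}

#' First countable plate of a dilution series
#'
#' @param counts Colony counts, one per dilution.
#' @param exponents Matching dilution exponents.
#' @return A list `count`, `exponent` for the least-dilute plate with
#'   `0 < count < 300`, or `NULL` if none is countable.
#' @export
first_countable_plate <- function(counts, exponents) {
  ord <- order(exponents)
  counts <- counts[ord]; exponents <- exponents[ord]
  ok <- which(counts > 0 & counts < 300)
  if (length(ok) == 0) return(NULL)
  list(count = counts[ok[1]], exponent = exponents[ok[1]])
}

site_levels <- c("BRACKET_AREA", "BO", "BG", "BL", "BR")
timepoint_levels <- c("T0", "T1", "T2")

#' Per-site summary statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of a measurement
#' per (timepoint, site) group, ordered BO, BG, BL, BR within timepoint
#' (baseline BRACKET_AREA first).
#'
#' @param records A tibble of clinical records (see [generate_cohort()]):
#'   `patient_id`, `timepoint`, `site` and measurement columns.
#' @param variable Name of the measurement column (default `"log10_cfu"`).
#' @return A `site_summary` tibble: `timepoint`, `site`, `mean`, `sd`, `n`.
#' @export
summarize_sites <- function(records, variable = "log10_cfu") {
  stopifnot(variable %in% names(records))
  out <- records |>
    dplyr::filter(!is.na(.data[[variable]])) |>
    dplyr::group_by(timepoint = factor(.data$timepoint, timepoint_levels),
                    site = factor(.data$site, site_levels)) |>
    dplyr::summarise(mean = mean(.data[[variable]]),
                     sd = stats::sd(.data[[variable]]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$timepoint, .data$site)
  if (nrow(out) == 0) stop("no records to summarise", call. = FALSE)
  small <- out$n < 2
  if (any(small))
    stop("fewer than 2 records in group(s): ",
         paste(out$timepoint[small], out$site[small], sep = "/",
               collapse = ", "), call. = FALSE)
  out$timepoint <- as.character(out$timepoint)
  out$site <- as.character(out$site)
  out
}

#' Overall mean across the four peri-bracket sites
#'
#' Unweighted mean of the four site means at one timepoint.
#'
#' @param summaries A `site_summary` tibble containing exactly the four
#'   peri-bracket sites for one timepoint (extra timepoints are allowed if
#'   `timepoint` is given).
#' @param timepoint Optional timepoint to select.
#' @return The overall mean (scalar).
#' @export
overall_mean <- function(summaries, timepoint = NULL) {
  if (!is.null(timepoint))
    summaries <- dplyr::filter(summaries, .data$timepoint == !!timepoint)
  sites <- c("BO", "BG", "BL", "BR")
  miss <- setdiff(sites, summaries$site)
  if (length(miss) > 0)
    stop("missing site(s): ", paste(miss, collapse = ", "), call. = FALSE)
  summaries <- dplyr::filter(summaries, .data$site %in% sites)
  if (nrow(summaries) != 4)
    stop("expected exactly one summary row per peri-bracket site",
         call. = FALSE)
  mean(summaries$mean)
}

site_pairs <- list(c("BO", "BG"), c("BO", "BL"), c("BO", "BR"),
                   c("BG", "BL"), c("BG", "BR"), c("BL", "BR"))

#' Pairwise between-site differences at one timepoint
#'
#' For the six ordered site pairs (BO-BG, BO-BL, BO-BR, BG-BL, BG-BR,
#' BL-BR): the difference of site means and, when patient-level records
#' are supplied, the mean and SD of the within-patient differences with
#' the paired-t p-value.
#'
#' @param x Either patient-level records (with `patient_id`) or a
#'   `site_summary` tibble (means only; no p-values possible).
#' @param timepoint Timepoint to analyse, `"T1"` or `"T2"`.
#' @param variable Measurement column for patient-level input.
#' @return A tibble: `pair`, `diff`, `sd`, `p_value` (latter two `NA` for
#'   summary-level input).
#' @export
site_differences <- function(x, timepoint, variable = "log10_cfu") {
  sites <- c("BO", "BG", "BL", "BR")
  if ("patient_id" %in% names(x)) {
    recs <- dplyr::filter(x, .data$timepoint == !!timepoint)
    wide <- recs |>
      dplyr::select("patient_id", "site", dplyr::all_of(variable)) |>
      tidyr::pivot_wider(names_from = "site", values_from = dplyr::all_of(variable))
    if (!all(sites %in% names(wide)) || anyNA(wide[sites]))
      stop("unpaired records: every patient needs all four sites at ",
           timepoint, call. = FALSE)
    purrr::map_dfr(site_pairs, function(pr) {
      d <- wide[[pr[1]]] - wide[[pr[2]]]
      p <- if (stats::sd(d) == 0 && mean(d) == 0) NA_real_
           else tryCatch(paired_t(wide[[pr[1]]], wide[[pr[2]]])$p.value,
                         error = function(e) NA_real_)
      tibble::tibble(pair = paste(pr, collapse = "-"),
                     diff = mean(d), sd = stats::sd(d), p_value = p)
    })
  } else {
    sm <- dplyr::filter(x, .data$timepoint == !!timepoint,
                        .data$site %in% sites)
    if (nrow(sm) != 4)
      stop("need summaries for all four sites at ", timepoint, call. = FALSE)
    m <- stats::setNames(sm$mean, sm$site)
    purrr::map_dfr(site_pairs, function(pr)
      tibble::tibble(pair = paste(pr, collapse = "-"),
                     diff = unname(m[pr[1]] - m[pr[2]]),
                     sd = NA_real_, p_value = NA_real_))
  }
}

#' Paired t-test
#'
#' Classical paired t on the within-pair differences, with the p-value
#' from the t distribution on n - 1 degrees of freedom.
#'
#' @param sample_a,sample_b Matched numeric vectors, length >= 2.
#' @return A `paired_test` object: `statistic`, `df`, `p.value`,
#'   `estimate` (mean difference), `n`.
#' @export
paired_t <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b))
    stop("samples must be paired (equal length)", call. = FALSE)
  if (length(sample_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- sample_a - sample_b
  if (stats::sd(d) == 0)
    stop("degenerate input: all within-pair differences identical",
         call. = FALSE)
  ht <- stats::t.test(sample_a, sample_b, paired = TRUE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value, estimate = unname(ht$estimate),
                 n = length(d), method = "paired t-test"),
            class = "paired_test")
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped, ties are mid-ranked, and the statistic is
#' the sum of ranks of the positive differences.  The two-sided p-value is
#' exact (full enumeration of the 2^n sign assignments) for n <= 12
#' non-zero differences and a tie-corrected normal approximation with
#' continuity correction above.
#'
#' @param sample_a,sample_b Matched numeric vectors.
#' @return A `wilcoxon_signed_test` object: `statistic` (W), `p.value`,
#'   `n` (non-zero pairs), `exact`.
#' @export
wilcoxon_signed <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b))
    stop("samples must be paired (equal length)", call. = FALSE)
  d <- sample_a - sample_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate input: all within-pair differences are zero",
         call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12) {
    # exact null distribution over all sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Tdist <- as.vector(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Tdist <= W + eps), mean(Tdist >= W - eps)))
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(statistic = W, p.value = p, n = n, exact = exact,
                 method = "Wilcoxon signed-rank test"),
            class = "wilcoxon_signed_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("Paired t-test: t(", x$df, ") = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p.value, digits = 4), ", mean diff = ",
      format(x$estimate, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.wilcoxon_signed_test <- function(x, ...) {
  cat("Wilcoxon signed-rank: W = ", format(x$statistic), " (n = ", x$n,
      if (x$exact) ", exact" else ", normal approx.",
      "), p = ", format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname periflow-tidiers
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic,
                 df = x$df, p.value = x$p.value, method = x$method)
}

#' @rdname periflow-tidiers
#' @export
glance.paired_test <- function(x, ...) tidy(x)

#' Tidiers for periflow test objects
#'
#' broom-style [generics::tidy()] / [generics::glance()] methods returning
#' one-row tibbles.
#'
#' @param x A `paired_test` or `wilcoxon_signed_test` object.
#' @param ... Unused.
#' @name periflow-tidiers
#' @export
tidy.wilcoxon_signed_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n = x$n, exact = x$exact, method = x$method)
}

#' @rdname periflow-tidiers
#' @export
glance.wilcoxon_signed_test <- function(x, ...) tidy(x)

#' Longitudinal periodontal report
#'
#' Gingival index (GI) and pocket depth (PD) means and SDs at T0, T1 and
#' T2 with pairwise significance: GI compared by the Wilcoxon signed-rank
#' test (ordinal index), PD by the paired t-test, for T0-T1, T0-T2 and
#' T1-T2.  `P < 0.05` is the conventional significance threshold.
#' Measurements are tooth-level: per-patient values are averaged across
#' site rows within a timepoint before testing.  Degenerate cells
#' (all-zero differences) yield `NA` p-values; the report still renders.
#'
#' @param records Patient-level records with `patient_id`, `timepoint`,
#'   `gi`, `pd`; every patient must appear at all three timepoints.
#' @return A `longitudinal_report` tibble: one row per measure with
#'   `mean_T0`, `sd_T0`, ..., `p_T0_T1`, `p_T0_T2`, `p_T1_T2`.
#' @export
longitudinal_report <- function(records) {
  per <- records |>
    dplyr::group_by(.data$patient_id, .data$timepoint) |>
    dplyr::summarise(gi = mean(.data$gi), pd = mean(.data$pd),
                     .groups = "drop")
  wide_ok <- per |>
    dplyr::count(.data$patient_id) |>
    dplyr::pull(.data$n)
  tps <- sort(unique(per$timepoint))
  if (!identical(tps, c("T0", "T1", "T2")) || any(wide_ok != 3))
    stop("pairing broken: every patient needs records at T0, T1 and T2",
         call. = FALSE)
  comparisons <- list(c("T0", "T1"), c("T0", "T2"), c("T1", "T2"))
  one_measure <- function(var, test_fun) {
    wide <- tidyr::pivot_wider(per[c("patient_id", "timepoint", var)],
                               names_from = "timepoint",
                               values_from = dplyr::all_of(var))
    row <- tibble::tibble(measure = toupper(var))
    for (tp in c("T0", "T1", "T2")) {
      row[[paste0("mean_", tp)]] <- mean(wide[[tp]])
      row[[paste0("sd_", tp)]] <- stats::sd(wide[[tp]])
    }
    for (cmp in comparisons) {
      p <- tryCatch(test_fun(wide[[cmp[2]]], wide[[cmp[1]]])$p.value,
                    error = function(e) NA_real_)
      row[[paste0("p_", cmp[1], "_", cmp[2])]] <- p
    }
    row
  }
  out <- dplyr::bind_rows(one_measure("gi", wilcoxon_signed),
                          one_measure("pd", paired_t))
  class(out) <- c("longitudinal_report", class(out))
  out
}
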
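test_that("log10 CFU estimation follows the dilution arithmetic and counting rule", {
  # 150 colonies of a 10^-6 dilution of a 0.05 ml aliquot: 3e9 CFU/ml
  expect_equal(estimate_log10_cfu(150, 6), log10(150 * 1e6 / 0.05))
  expect_equal(estimate_log10_cfu(150, 6), 9.4771, tolerance = 1e-4)
  expect_equal(estimate_log10_cfu(1, 0), log10(20))
  expect_error(estimate_log10_cfu(300, 6), "uncountable")
  expect_error(estimate_log10_cfu(-1, 2), "negative")
  expect_warning(out <- estimate_log10_cfu(0, 3), class = "below_detection")
  expect_true(is.na(out))
})

test_that("log10 CFU estimate is strictly increasing in count and dilution", {
  counts <- c(1, 5, 50, 150, 299)
  expect_true(all(diff(estimate_log10_cfu(counts, 4)) > 0))
  ests <- vapply(0:8, function(k) estimate_log10_cfu(37, k), 1.0)
  expect_true(all(diff(ests) > 0))
})

test_that("first countable plate honours the <300 rule", {
  pl <- first_countable_plate(counts = c(2900, 310, 145, 14, 1, 0),
                              exponents = 0:5)
  expect_equal(pl$count, 145)
  expect_equal(pl$exponent, 2)
  expect_null(first_countable_plate(c(500, 400), 0:1))
})

test_that("site summaries compute mean and n-1 SD per group in canonical order", {
  recs <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), 4),
    timepoint = "T1",
    site = rep(c("BG", "BO", "BL", "BR"), each = 2),
    log10_cfu = c(9.2, 9.3, 9.0, 9.1, 9.0, 9.0, 8.9, 9.1))
  sm <- summarize_sites(recs)
  expect_equal(sm$site, c("BO", "BG", "BL", "BR"))
  expect_equal(sm$mean[sm$site == "BO"], 9.05)
  expect_equal(sm$sd[sm$site == "BO"], sd(c(9.0, 9.1)))
  expect_equal(sm$sd[sm$site == "BO"], 0.0707, tolerance = 1e-3)
  expect_equal(sm$sd[sm$site == "BL"], 0)
  solo <- recs[recs$patient_id == "P1", ]
  expect_error(summarize_sites(solo), "fewer than 2")
})

test_that("synthetic cohort summaries recover generating means within sampling error", {
  recs <- generate_cohort(cohort_params(), seed = 101)
  sm <- summarize_sites(recs)
  pars <- cfu_site_params()
  joined <- merge(sm, pars, by = c("timepoint", "site"),
                  suffixes = c("_obs", "_gen"))
  expect_equal(nrow(joined), 9)
  expect_true(all(abs(joined$mean_obs - joined$mean_gen) <=
                    3 * joined$sd_gen / sqrt(27)))
})

test_that("overall mean across sites reproduces the printed per-visit means", {
  pars <- cfu_site_params()
  sm <- tibble::tibble(timepoint = pars$timepoint, site = pars$site,
                       mean = pars$mean, sd = pars$sd, n = 27)
  expect_equal(round(overall_mean(sm, "T1"), 4), 9.1082)
  expect_equal(round(overall_mean(sm, "T2"), 4), 9.2977)
  same <- tibble::tibble(timepoint = "T1", site = c("BO", "BG", "BL", "BR"),
                         mean = 9.1, sd = 0.01, n = 27)
  expect_equal(overall_mean(same), 9.1)
  expect_error(overall_mean(sm[sm$site != "BG", ], "T1"), "BG")
})

test_that("pairwise site differences from printed means match the printed values", {
  pars <- cfu_site_params()
  sm <- tibble::tibble(timepoint = pars$timepoint, site = pars$site,
                       mean = pars$mean)
  d1 <- site_differences(sm, "T1")
  expect_equal(d1$pair, c("BO-BG", "BO-BL", "BO-BR", "BG-BL", "BG-BR", "BL-BR"))
  expect_equal(round(d1$diff, 4),
               c(-0.3087, -0.0045, -0.0081, 0.3042, 0.3006, -0.0036))
  d2 <- site_differences(sm, "T2")
  expect_equal(round(d2$diff, 4),
               c(-0.3660, -0.3668, -0.3589, -0.0008, 0.0071, 0.0079))
})

test_that("patient-level site differences equal within-patient difference means", {
  recs <- generate_cohort(cohort_params(n_patients = 12), seed = 5)
  d <- site_differences(recs, "T1")
  sm <- summarize_sites(recs)
  dm <- site_differences(sm[c("timepoint", "site", "mean")], "T1")
  # linearity: mean of within-patient differences = difference of means
  expect_equal(d$diff, dm$diff, tolerance = 1e-12)
  expect_true(all(is.finite(d$p_value)))
  # identical site distributions give zero differences and no test
  recs0 <- recs
  wide_mean <- tapply(recs0$log10_cfu, recs0$patient_id, mean)
  recs0$log10_cfu <- wide_mean[recs0$patient_id]
  d0 <- site_differences(recs0, "T1")
  expect_true(all(d0$diff == 0))
  # unpaired (missing site rows) errors
  expect_error(site_differences(recs[recs$site != "BL", ], "T1"), "unpaired")
})

test_that("paired t matches the textbook formula and is antisymmetric", {
  a <- c(5.1, 4.9, 5.3, 5.0)
  b <- c(4.8, 4.9, 5.0, 4.9)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p.value, p_hand)
  expect_equal(res$df, 3)
  swapped <- paired_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p.value, res$p.value)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(paired_t(1:3, 1:4), "paired")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p.value, p_hand)
})

test_that("Wilcoxon signed-rank exact p equals full sign enumeration", {
  set.seed(3)
  cases <- list(
    list(a = c(5.2, 4.1, 6.3, 2.2, 3.3, 4.8),
         b = c(4.0, 4.5, 5.1, 2.0, 2.1, 4.0)),
    list(a = c(1.0, 2.0, 3.0, 4.0, 5.5, 6.1, 0.5),
         b = c(1.5, 1.0, 3.0, 3.2, 5.0, 7.0, 0.7)),  # one zero difference
    list(a = c(2, 4, 6, 8, 10, 12),
         b = c(1, 5, 5, 7, 12, 10)))                 # tied |differences|
  for (cs in cases) {
    res <- wilcoxon_signed(cs$a, cs$b)
    d <- cs$a - cs$b
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    # exhaustive enumeration over all 2^n sign assignments
    Tdist <- numeric(2^n)
    for (m in seq_len(2^n) - 1) {
      signs <- as.integer(intToBits(m))[1:n]
      Tdist[m + 1] <- sum(r[signs == 1])
    }
    W <- sum(r[d > 0])
    p_exact <- min(1, 2 * min(mean(Tdist <= W + 1e-9),
                              mean(Tdist >= W - 1e-9)))
    expect_equal(res$statistic, W)
    expect_equal(res$p.value, p_exact)
    expect_true(res$exact)
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test in the tie-free exact regime", {
  a <- c(0.8, 1.9, 3.1, 4.4, 5.2, 6.9, 7.3, 8.8)
  b <- c(1.2, 1.1, 2.6, 5.0, 4.1, 6.0, 8.0, 7.95)  # distinct |differences|
  res <- wilcoxon_signed(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
})

test_that("Wilcoxon handles reflections and degenerate inputs", {
  a <- c(5.2, 4.1, 6.3, 2.2, 3.3, 4.8)
  b <- c(4.0, 4.5, 5.1, 2.0, 2.1, 4.0)
  res <- wilcoxon_signed(a, b)
  ref <- wilcoxon_signed(b, a)
  n <- res$n
  expect_equal(ref$statistic, n * (n + 1) / 2 - res$statistic)
  expect_equal(ref$p.value, res$p.value)
  # single non-zero difference among zeros: n = 1, exact p = 1
  one <- wilcoxon_signed(c(1, 2, 3, 4), c(1, 2, 3, 3.5))
  expect_equal(one$n, 1)
  expect_true(one$statistic %in% c(0, 1))
  expect_equal(one$p.value, 1)
  expect_error(wilcoxon_signed(1:4, 1:4), "degenerate")
})

test_that("paired t and Wilcoxon agree in effect sign on shifted data", {
  set.seed(21)
  for (i in 1:20) {
    base <- rnorm(15, 5, 1)
    shifted <- base + 0.5 + rnorm(15, 0, 0.2)
    tt <- paired_t(shifted, base)
    ww <- wilcoxon_signed(shifted, base)
    expect_gt(tt$statistic, 0)
    expect_gt(ww$statistic, ww$n * (ww$n + 1) / 4)  # above null mean
  }
})

test_that("longitudinal report reproduces the GI/PD table structure", {
  recs <- generate_cohort(cohort_params(), seed = 33)
  rep <- longitudinal_report(recs)
  expect_equal(rep$measure, c("GI", "PD"))
  expect_true(all(c("mean_T0", "sd_T2", "p_T0_T1", "p_T1_T2") %in% names(rep)))
  expect_true(all(rep$sd_T0 >= 0))
  # all-constant records: p-values NA but the report renders
  flat <- recs
  flat$gi <- 1; flat$pd <- 0.7
  frep <- longitudinal_report(flat)
  expect_equal(nrow(frep), 2)
  expect_true(all(is.na(frep[c("p_T0_T1", "p_T0_T2", "p_T1_T2")])))
  # broken pairing errors
  shuf <- recs
  shuf$patient_id[shuf$timepoint == "T2"] <-
    paste0("X", shuf$patient_id[shuf$timepoint == "T2"])
  expect_error(longitudinal_report(shuf), "pairing")
})

test_that("two-week PD comparisons reach significance more often than one-week", {
  hits <- c(t0t1 = 0, t0t2 = 0)
  for (seed in 1:100) {
    recs <- generate_cohort(cohort_params(), seed = seed)
    rep <- longitudinal_report(recs)
    pd <- rep[rep$measure == "PD", ]
    hits["t0t1"] <- hits["t0t1"] + (pd$p_T0_T1 < 0.05)
    hits["t0t2"] <- hits["t0t2"] + (pd$p_T0_T2 < 0.05)
  }
  expect_gt(hits[["t0t2"]], hits[["t0t1"]])
})
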
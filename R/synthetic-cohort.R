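#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration describing the joint distribution the
#' generator draws from: NPT prevalence, total IgE (lognormal), per-analyte
#' sensitization rates and level medians split by NPT outcome group, assay
#' floor/cap, SPT wheal and retrospective VAS distributions.
#'
#' Defaults emulate a poly-sensitized pediatric seasonal allergic rhinitis
#' cohort: ~85% NPT-positive prevalence, total IgE with median ~421 kU/L and
#' IQR ~199-737, strong NPT-group separation in Phl p 5 sensitization
#' (64% vs 18%), semi-quantitative specific IgE floored at 0.1 kU/L and
#' saturating at 100 kU/L, and retrospective severity VAS medians 7
#' (NPT-positive) vs 5 (NPT-negative).
#'
#' @param n_patients Number of patients to simulate.
#' @param prevalence_positive Probability a patient is NPT-positive.
#' @param total_ige_log_median Median of total IgE, kU/L (lognormal).
#' @param total_ige_log_sigma Log-scale SD of total IgE.
#' @param analytes Data frame with one row per analyte and columns
#'   `analyte`, `rate_pos`, `rate_neg` (sensitization probability by NPT
#'   group), `median_pos`, `median_neg` (lognormal median of the specific
#'   IgE level among sensitized patients, kU/L) and `sigma` (log-scale SD).
#' @param assay_floor,assay_cap Reporting limits of the specific IgE assay,
#'   kU/L. Non-sensitized analytes are coded exactly at the floor; levels
#'   are clipped (not resampled) into `[assay_floor, assay_cap]`.
#' @param vas_median_by_group Named numeric, medians of the retrospective
#'   severity VAS for the `positive` and `negative` groups (0-10 scale).
#' @param vas_sd SD of the latent normal behind the discretized VAS.
#' @param spt_median_by_group Named list with `positive` and `negative`
#'   numeric vectors of wheal medians (mm) for timothy and Bermuda grass.
#' @param spt_sd SD of the wheal distribution, mm.
#' @param sige_total_cap Logical; cap each specific IgE at the patient's
#'   total IgE (on by default, a physical constraint).
#' @param seed Integer seed; each generator stage uses a named substream of
#'   it so stages can be regenerated independently.
#'
#' @return A list of class `npt_cohort_config`.
#' @examples
#' cfg <- cohort_config(n_patients = 20, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_patients = 72,
                          prevalence_positive = 0.847,
                          total_ige_log_median = 421,
                          total_ige_log_sigma = 0.97,
                          analytes = default_analyte_panel(),
                          assay_floor = 0.1,
                          assay_cap = 100,
                          vas_median_by_group = c(positive = 7, negative = 5),
                          vas_sd = 2,
                          spt_median_by_group = list(
                            positive = c(timothy = 8, bermuda = 6),
                            negative = c(timothy = 6, bermuda = 4.5)
                          ),
                          spt_sd = 2,
                          sige_total_cap = TRUE,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      n_patients < 0 || n_patients != floor(n_patients)) {
    abort_npt("`n_patients` must be a non-negative integer.",
              "nptpredict_config_error")
  }
  check_probability(prevalence_positive, "prevalence_positive")
  check_probability(analytes$rate_pos, "analytes$rate_pos")
  check_probability(analytes$rate_neg, "analytes$rate_neg")
  if (any(analytes$median_pos <= 0) || any(analytes$median_neg <= 0)) {
    abort_npt("Analyte level medians must be positive.",
              "nptpredict_config_error")
  }
  if (total_ige_log_median <= 0) {
    abort_npt("`total_ige_log_median` must be positive.",
              "nptpredict_config_error")
  }
  if (!(assay_floor < assay_cap)) {
    abort_npt("`assay_floor` must be below `assay_cap`.",
              "nptpredict_config_error")
  }
  if (any(vas_median_by_group < 0) || any(vas_median_by_group > 10)) {
    abort_npt("VAS medians must lie in [0, 10].", "nptpredict_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence_positive = prevalence_positive,
      total_ige_log_median = total_ige_log_median,
      total_ige_log_sigma = total_ige_log_sigma,
      analytes = analytes,
      assay_floor = assay_floor,
      assay_cap = assay_cap,
      vas_median_by_group = vas_median_by_group,
      vas_sd = vas_sd,
      spt_median_by_group = spt_median_by_group,
      spt_sd = spt_sd,
      sige_total_cap = isTRUE(sige_total_cap),
      seed = as.integer(seed)
    ),
    class = "npt_cohort_config"
  )
}

#' Default grass-pollen analyte panel
#'
#' Sensitization rates and level medians by NPT outcome group for the two
#' whole extracts (timothy, Bermuda) and six grass-pollen molecules. The
#' Phl p 5 rates (64% in NPT-positives vs 18.2% in NPT-negatives) carry the
#' bulk of the group separation; Phl p 1 and Phl p 4 are near-ubiquitous
#' and uninformative; Phl p 7 and Phl p 12 are rare in both groups.
#' Medians are for the sensitized subpopulation.
#'
#' @return A tibble with columns `analyte`, `rate_pos`, `rate_neg`,
#'   `median_pos`, `median_neg`, `sigma`.
#' @export
default_analyte_panel <- function() {
  tibble::tribble(
    ~analyte,    ~rate_pos, ~rate_neg, ~median_pos, ~median_neg, ~sigma,
    "timothy",   0.98,      0.90,      95,          65,          1.0,
    "bermuda",   0.90,      0.60,      32,          3.0,         1.5,
    "phl_p_1",   0.97,      0.73,      91,          72,          0.8,
    "phl_p_4",   0.90,      0.80,      57,          56,          1.0,
    "phl_p_5",   0.640,     0.182,     35,          5,           1.5,
    "phl_p_7",   0.10,      0.09,      1.5,         1.5,         1.2,
    "phl_p_12",  0.10,      0.09,      1.5,         1.5,         1.2,
    "cyn_d_1",   0.80,      0.55,      55,          3.5,         1.5
  )
}

# Discretized truncated-normal draw on an integer scale [lo, hi] with the
# requested median; used for VAS scores.
draw_discrete_scale <- function(n, median, sd, lo = 0, hi = 10) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, mean = median, sd = sd))))
}

#' Generate a synthetic patient cohort
#'
#' Draws one row per patient: NPT outcome (Bernoulli at the configured
#' prevalence), demographics, SPT wheal sizes for the two grass extracts,
#' lognormal total IgE, and per-analyte specific IgE. For each analyte a
#' patient is sensitized with the group-specific rate; sensitized patients
#' receive a lognormal level (group-specific median) clipped into
#' `[assay_floor, assay_cap]`, non-sensitized patients are coded exactly at
#' the assay floor. Each specific IgE is additionally capped at the
#' patient's total IgE.
#'
#' @param config An [cohort_config()] object.
#' @return A tibble with one row per patient: `patient_id`, `age`, `sex`,
#'   `npt_positive` (0/1), `spt_timothy`, `spt_bermuda` (mm), `total_ige`
#'   (kU/L), one `sige_<analyte>` column per panel analyte (kU/L),
#'   `vas_severity_retro` and `vas_drug_efficacy` (0-10).
#' @examples
#' generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "npt_cohort_config"))
  n <- config$n_patients
  empty <- tibble::tibble(
    patient_id = character(), age = numeric(), sex = character(),
    npt_positive = integer(), spt_timothy = numeric(),
    spt_bermuda = numeric(), total_ige = numeric()
  )
  for (a in config$analytes$analyte) empty[[paste0("sige_", a)]] <- numeric()
  empty$vas_severity_retro <- integer()
  empty$vas_drug_efficacy <- integer()
  if (n == 0L) return(empty)

  with_substream(config$seed, "cohort", {
    npt <- as.integer(stats::runif(n) < config$prevalence_positive)
    grp <- ifelse(npt == 1L, "positive", "negative")
    age <- pmin(18, pmax(4, round(stats::rnorm(n, 14.3, 2.8), 1)))
    sex <- ifelse(stats::runif(n) < 46 / 72, "M", "F")

    spt_med <- config$spt_median_by_group
    spt_t <- pmax(0, stats::rnorm(n, ifelse(npt == 1L,
                                            spt_med$positive[["timothy"]],
                                            spt_med$negative[["timothy"]]),
                                  config$spt_sd))
    spt_b <- pmax(0, stats::rnorm(n, ifelse(npt == 1L,
                                            spt_med$positive[["bermuda"]],
                                            spt_med$negative[["bermuda"]]),
                                  config$spt_sd))

    total_ige <- stats::rlnorm(n, meanlog = log(config$total_ige_log_median),
                               sdlog = config$total_ige_log_sigma)

    out <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age, sex = sex, npt_positive = npt,
      spt_timothy = round(spt_t, 1), spt_bermuda = round(spt_b, 1),
      total_ige = round(total_ige, 1)
    )

    n_analytes <- nrow(config$analytes)
    lvl_mat <- matrix(config$assay_floor, n, n_analytes)
    sens_mat <- matrix(FALSE, n, n_analytes)
    # sensitized values stay strictly above the 0.35 kU/L positivity
    # threshold so the drawn sensitization flag is recoverable
    sens_lo <- 0.36
    for (i in seq_len(n_analytes)) {
      row <- config$analytes[i, ]
      rate <- ifelse(npt == 1L, row$rate_pos, row$rate_neg)
      sens_mat[, i] <- stats::runif(n) < rate
      med <- ifelse(npt == 1L, row$median_pos, row$median_neg)
      lvl <- stats::rlnorm(n, meanlog = log(med), sdlog = row$sigma)
      lvl <- pmin(config$assay_cap, pmax(sens_lo, lvl))
      lvl[!sens_mat[, i]] <- config$assay_floor
      lvl_mat[, i] <- lvl
    }
    if (config$sige_total_cap) {
      # keep the panel physically consistent with total IgE: the summed
      # specific IgE may not exceed 90% of total, so combined activities
      # stay below 100%; sensitized levels are rescaled where needed
      budget <- 0.9 * out$total_ige
      floor_sum <- rowSums(lvl_mat * !sens_mat)
      sens_sum <- rowSums(lvl_mat * sens_mat)
      factor <- pmin(1, pmax(0, (budget - floor_sum)) / pmax(sens_sum, 1e-9))
      lvl_mat[sens_mat] <- pmax(sens_lo, (lvl_mat * factor)[sens_mat])
      lvl_mat <- pmin(lvl_mat, out$total_ige)
    }
    for (i in seq_len(n_analytes)) {
      out[[paste0("sige_", config$analytes$analyte[i])]] <-
        round(lvl_mat[, i], 2)
    }

    vm <- config$vas_median_by_group
    out$vas_severity_retro <- as.integer(draw_discrete_scale(
      n, ifelse(npt == 1L, vm[["positive"]], vm[["negative"]]), config$vas_sd
    ))
    # drug-efficacy VAS: weakly separated (medians 8 vs 7)
    out$vas_drug_efficacy <- as.integer(draw_discrete_scale(
      n, ifelse(npt == 1L, 8, 7), config$vas_sd
    ))
    out
  })
}

#' Generate a synthetic daily pollen series
#'
#' Produces a unimodal seasonal hump of daily grass-pollen concentrations:
#' a Gaussian-shaped mean profile with multiplicative lognormal day-to-day
#' noise, rounded to whole grains and clipped to `[0, cap]`.
#'
#' @param start_date First day (coerced with [as.Date()]).
#' @param n_days Number of consecutive days (>= 1).
#' @param peak_day Day index (1-based) of the seasonal peak.
#' @param peak_height Mean concentration at the peak, grains/m^3. Zero
#'   yields an all-zero series.
#' @param width SD of the Gaussian profile, days.
#' @param noise_sdlog Log-scale SD of the multiplicative noise.
#' @param cap Maximum reportable concentration, grains/m^3 (default 199).
#' @param seed Integer seed (substreamed, so reproducible).
#' @return A tibble `date`, `grains_m3` of class `npt_pollen_series`.
#' @examples
#' generate_pollen_series("2016-04-01", n_days = 10, seed = 3)
#' @export
generate_pollen_series <- function(start_date = "2016-04-01",
                                   n_days = 120,
                                   peak_day = round(n_days / 2),
                                   peak_height = 120,
                                   width = n_days / 6,
                                   noise_sdlog = 0.5,
                                   cap = 199,
                                   seed = 1L) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1) {
    abort_npt("`n_days` must be >= 1.", "nptpredict_config_error")
  }
  n_days <- as.integer(n_days)
  with_substream(seed, "pollen", {
    t <- seq_len(n_days)
    profile <- peak_height * exp(-0.5 * ((t - peak_day) / width)^2)
    noise <- stats::rlnorm(n_days, meanlog = 0, sdlog = noise_sdlog)
    conc <- pmin(cap, pmax(0, round(profile * noise)))
    out <- tibble::tibble(
      date = as.Date(start_date) + t - 1L,
      grains_m3 = as.numeric(conc)
    )
    class(out) <- c("npt_pollen_series", class(out))
    out
  })
}

#' Generate synthetic e-diary rows for a cohort
#'
#' For every patient-day in the pollen series, daily scores rise
#' stochastically with `log(1 + pollen)` and with a per-patient latent
#' severity that is larger on average for NPT-positive patients. RTSS is
#' clipped to 0-18, CSMS to 0-6, VAS to 0-10.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (non-empty).
#' @param pollen A pollen series tibble (`date`, `grains_m3`).
#' @param exposure_coef Score increase per unit `log(1 + grains_m3)` on the
#'   VAS scale; RTSS and CSMS use range-proportional multiples.
#' @param latent_mean_by_group Named numeric: mean of the per-patient latent
#'   severity for the `positive` and `negative` NPT groups (VAS units).
#' @param latent_sd SD of the latent severity.
#' @param noise_sd SD of the day-level noise (VAS units).
#' @param baseline Baseline VAS-scale score on a pollen-free day.
#' @param seed Integer seed (substreamed).
#' @return A tibble `patient_id`, `date`, `rtss` (0-18), `csms` (0-6),
#'   `vas` (0-10), `medication_taken` (0/1); one row per patient-day.
#' @examples
#' cfg <- cohort_config(n_patients = 3, seed = 1)
#' pol <- generate_pollen_series(n_days = 7, seed = 1)
#' generate_diary(generate_cohort(cfg), pol, seed = 1)
#' @export
generate_diary <- function(cohort, pollen,
                           exposure_coef = 0.9,
                           latent_mean_by_group = c(positive = 1.6,
                                                    negative = 0),
                           latent_sd = 1,
                           noise_sd = 1.2,
                           baseline = 1,
                           seed = 1L) {
  if (nrow(cohort) == 0L) {
    abort_npt("`cohort` must contain at least one patient.",
              "nptpredict_input_error")
  }
  if (!all(c("date", "grains_m3") %in% names(pollen)) || nrow(pollen) == 0L) {
    abort_npt("`pollen` must be a non-empty series with `date`, `grains_m3`.",
              "nptpredict_input_error")
  }
  with_substream(seed, "diary", {
    n_pat <- nrow(cohort)
    latent <- stats::rnorm(
      n_pat,
      mean = ifelse(cohort$npt_positive == 1L,
                    latent_mean_by_group[["positive"]],
                    latent_mean_by_group[["negative"]]),
      sd = latent_sd
    )
    grid <- tidyr::expand_grid(
      patient_idx = seq_len(n_pat),
      day_idx = seq_len(nrow(pollen))
    )
    exposure <- log1p(pollen$grains_m3[grid$day_idx])
    lin <- baseline + latent[grid$patient_idx] + exposure_coef * exposure
    nr <- nrow(grid)
    vas <- lin + stats::rnorm(nr, 0, noise_sd)
    rtss <- 1.4 * lin + stats::rnorm(nr, 0, 1.4 * noise_sd)
    csms <- 0.45 * lin + stats::rnorm(nr, 0, 0.45 * noise_sd)
    med <- as.integer(stats::runif(nr) < stats::plogis(0.4 * (lin - 4)))
    tibble::tibble(
      patient_id = cohort$patient_id[grid$patient_idx],
      date = pollen$date[grid$day_idx],
      rtss = as.integer(pmin(18, pmax(0, round(rtss)))),
      csms = pmin(6, pmax(0, round(csms, 1))),
      vas = as.integer(pmin(10, pmax(0, round(vas)))),
      medication_taken = med
    )
  })
}

#' Read and write the cohort, diary and pollen CSV formats
#'
#' Plain-CSV serializers for the three tabular inputs. Dates are ISO-8601.
#' The readers validate ranges and uniqueness and report offending rows.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a validated
#'   tibble.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_diary_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_pollen_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
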
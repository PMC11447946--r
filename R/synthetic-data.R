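#' Study design specification
#'
#' Sampling and dosing design of a de novo kidney-transplant PK study:
#' `n_rich` subjects contribute a full 9-point profile on day 5
#' post-initiation (a pre-dose trough plus samples at 0.5, 1, 2, 4, 8, 12, 20
#' and 24 h after the day-5 dose) and troughs on days 10 and 15; the
#' remaining subjects contribute troughs on days 5, 10 and 15 only. Dosing is
#' once daily at 0.1 mg/kg rounded to the nearest 0.5 mg, for `n_days` days,
#' with the time origin at the first dose.
#'
#' @param n_total Total number of subjects.
#' @param n_rich Number of richly sampled subjects.
#' @param rich_offsets Day-5 sampling offsets (h after the day-5 dose; 0 is
#'   the pre-dose trough).
#' @param trough_days Trough occasions (study days).
#' @param n_days Days of once-daily dosing (>= max(trough_days)).
#' @param dose_per_kg Starting dose rule (mg/kg/day).
#' @param dose_increment Rounding grid for doses (mg).
#' @return List of class `"design_spec"`.
#' @export
design_spec <- function(n_total = 138, n_rich = 29,
                        rich_offsets = c(0, 0.5, 1, 2, 4, 8, 12, 20, 24),
                        trough_days = c(5, 10, 15), n_days = 15,
                        dose_per_kg = 0.1, dose_increment = 0.5) {
  stopifnot(n_rich <= n_total, n_rich >= 0, !is.unsorted(rich_offsets),
            n_days >= max(trough_days))
  structure(list(n_total = n_total, n_rich = n_rich,
                 rich_offsets = rich_offsets, trough_days = trough_days,
                 n_days = n_days, dose_per_kg = dose_per_kg,
                 dose_increment = dose_increment),
            class = "design_spec")
}

#' Covariate distributions of the study population
#'
#' Marginal distributions emulating the study population: age from a
#' truncated normal (median 54, range 19-82 in the study); bodyweight from a
#' truncated log-normal (median 70.5 kg, range 44-109); CYP3A5 genotype
#' frequencies 2.2% *1/*1, 12.3% *1/*3, 85.5% *3/*3 (so ~14.5% *1 carriers);
#' hematocrit rising over occasions as a random walk matching the day-5/10/15
#' medians of about 29.7/31.3/32.9%, clipped to the observed global range.
#' Covariates are drawn independently (only marginals are known).
#'
#' @param age_mean,age_sd,age_range Truncated-normal age parameters (years).
#' @param bw_median,bw_sdlog,bw_range Truncated log-normal bodyweight (kg).
#' @param genotype_freq Probabilities of (*1/*1, *1/*3, *3/*3).
#' @param hct_day5_mean,hct_day5_sd Day-5 hematocrit normal parameters (%).
#' @param hct_step_mean,hct_step_sd Per-occasion hematocrit increment (%).
#' @param hct_range Clipping bounds for hematocrit (%).
#' @param p_male Proportion of male patients (carried, unused by the model).
#' @return List of class `"covariate_distributions"`.
#' @export
covariate_distributions <- function(age_mean = 54, age_sd = 13,
                                    age_range = c(19, 82),
                                    bw_median = 70.5, bw_sdlog = 0.18,
                                    bw_range = c(44, 109),
                                    genotype_freq = c(0.022, 0.123, 0.855),
                                    hct_day5_mean = 29.7, hct_day5_sd = 4,
                                    hct_step_mean = 1.6, hct_step_sd = 1.5,
                                    hct_range = c(20.9, 46.6),
                                    p_male = 90 / 138) {
  stopifnot(abs(sum(genotype_freq) - 1) < 1e-8)
  structure(list(age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 bw_median = bw_median, bw_sdlog = bw_sdlog,
                 bw_range = bw_range, genotype_freq = genotype_freq,
                 hct_day5_mean = hct_day5_mean, hct_day5_sd = hct_day5_sd,
                 hct_step_mean = hct_step_mean, hct_step_sd = hct_step_sd,
                 hct_range = hct_range, p_male = p_male),
            class = "covariate_distributions")
}

rtrunc <- function(n, lo, hi, p, q) {
  u <- stats::runif(n, p(lo), p(hi))
  q(u)
}

#' Sample subject covariates
#'
#' Draws `n` subject records (age, bodyweight, sex, CYP3A5 genotype and
#' carrier status, hematocrit on days 5/10/15) from
#' [covariate_distributions()]. Reproducible given `seed`.
#'
#' @param n Number of subjects.
#' @param dists A [covariate_distributions()] object.
#' @param seed Integer seed (optional; uses the current RNG state if `NULL`).
#' @return Tibble with one row per subject.
#' @export
sample_covariates <- function(n, dists = covariate_distributions(),
                              seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  age <- rtrunc(n, dists$age_range[1], dists$age_range[2],
                function(x) stats::pnorm(x, dists$age_mean, dists$age_sd),
                function(u) stats::qnorm(u, dists$age_mean, dists$age_sd))
  bw <- rtrunc(n, dists$bw_range[1], dists$bw_range[2],
               function(x) stats::plnorm(x, log(dists$bw_median), dists$bw_sdlog),
               function(u) stats::qlnorm(u, log(dists$bw_median), dists$bw_sdlog))
  genotype <- sample(c("*1/*1", "*1/*3", "*3/*3"), n, replace = TRUE,
                     prob = dists$genotype_freq)
  sex <- ifelse(stats::runif(n) < dists$p_male, "M", "F")
  clip <- function(x) pmin(pmax(x, dists$hct_range[1]), dists$hct_range[2])
  h5 <- clip(stats::rnorm(n, dists$hct_day5_mean, dists$hct_day5_sd))
  h10 <- clip(h5 + stats::rnorm(n, dists$hct_step_mean, dists$hct_step_sd))
  h15 <- clip(h10 + stats::rnorm(n, dists$hct_step_mean, dists$hct_step_sd))
  tibble::tibble(
    ID = seq_len(n), age = age, bodyweight = bw, sex = sex,
    cyp3a5 = genotype, cyp3a5_carrier = genotype != "*3/*3",
    hct_day5 = h5, hct_day10 = h10, hct_day15 = h15
  )
}

#' Build the dataset skeleton (doses and scheduled samples)
#'
#' Expands subject records into a NONMEM-style dataset skeleton: once-daily
#' dose rows for `n_days` days and scheduled observation rows (DV = NA) per
#' the design. The first `n_rich` subjects receive the rich day-5 schedule.
#' Trough samples share the dose instant and are recorded before the dose
#' row.
#'
#' @param subjects Tibble from [sample_covariates()].
#' @param spec A [design_spec()].
#' @return A PK dataset skeleton tibble (passes [validate_pk_dataset()] after
#'   concentrations are filled in; DV is NA with MDV = 1 here).
#' @export
build_design <- function(subjects, spec = design_spec()) {
  stopifnot(nrow(subjects) >= spec$n_rich)
  n <- nrow(subjects)
  rich_ids <- subjects$ID[seq_len(min(spec$n_rich, n))]
  day5 <- 5L

  one_subject <- function(s) {
    dose_amt <- round(s$bodyweight * spec$dose_per_kg / spec$dose_increment) *
      spec$dose_increment
    dose_times <- (seq_len(spec$n_days) - 1) * 24
    doses <- tibble::tibble(TIME = dose_times, EVID = 1L, AMT = dose_amt,
                            MDV = 1L, DV = NA_real_, HCT = NA_real_,
                            DAY = as.integer(dose_times / 24) + 1L)
    hct_of_day <- function(day) {
      dplyr::case_when(day <= 7 ~ s$hct_day5,
                       day <= 12 ~ s$hct_day10,
                       TRUE ~ s$hct_day15)
    }
    if (s$ID %in% rich_ids) {
      t5 <- (day5 - 1) * 24 + spec$rich_offsets
      obs_days <- c(rep(day5, length(spec$rich_offsets)),
                    setdiff(spec$trough_days, day5))
      obs_times <- c(t5, (setdiff(spec$trough_days, day5) - 1) * 24)
    } else {
      obs_days <- spec$trough_days
      obs_times <- (spec$trough_days - 1) * 24
    }
    obs <- tibble::tibble(TIME = obs_times, EVID = 0L, AMT = NA_real_,
                          MDV = 1L, DV = NA_real_,
                          HCT = hct_of_day(obs_days),
                          DAY = as.integer(obs_days))
    rows <- dplyr::bind_rows(doses, obs)
    # sample-before-dose ordering at shared instants: EVID 0 first
    rows <- rows[order(rows$TIME, rows$EVID), ]
    rows$ID <- s$ID
    rows$AGE <- s$age
    rows$BW <- s$bodyweight
    rows$CYP3A5 <- as.integer(s$cyp3a5_carrier)
    rows
  }
  out <- dplyr::bind_rows(lapply(seq_len(n), function(i) one_subject(subjects[i, ])))
  dplyr::select(out, "ID", "TIME", "EVID", "AMT", "MDV", "DV", "HCT",
                "AGE", "BW", "CYP3A5", "DAY")
}

#' Simulate concentrations into a dataset skeleton
#'
#' Per subject: draws (eta_cl, eta_vc) from the log-normal between-patient
#' model, computes hematocrit-45-standardized predictions from the
#' individual two-compartment parameters, applies proportional residual
#' error, and back-transforms to the observed scale with the occasion's
#' hematocrit. Simulated concentrations at or below `floor` are redrawn.
#'
#' When `tdm = TRUE` a therapeutic-drug-monitoring rule is emulated: after
#' each trough occasion whose observed value leaves the 5-10 ng/mL target
#' range, subsequent daily doses are multiplied by (7.5 / trough), clipped to
#' [0.5x, 2x] of the current dose and rounded to the dose increment.
#'
#' @param skeleton Dataset skeleton from [build_design()].
#' @param theta,omega Generating parameters ([pk_theta()], [pk_omega()]).
#' @param seed Integer seed.
#' @param tdm Emulate dose titration (default off: estimation tests need dose
#'   histories independent of the observations).
#' @param floor Lower bound below which simulated concentrations are redrawn.
#' @param dose_increment Rounding grid for TDM dose updates (mg).
#' @return A PK dataset with DV filled in (observed scale) and MDV = 0 on
#'   observation rows. The generating etas are attached as attribute
#'   `"etas"`.
#' @export
simulate_dataset <- function(skeleton, theta = pk_theta(),
                             omega = pk_omega(), seed = NULL, tdm = FALSE,
                             floor = 0, dose_increment = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(skeleton$ID)
  etas <- tibble::tibble(
    ID = ids,
    eta_cl = stats::rnorm(length(ids), 0, omega$omega_cl),
    eta_vc = stats::rnorm(length(ids), 0, omega$omega_vc)
  )
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- skeleton[skeleton$ID == ids[i], ]
    p <- individual_params(theta, age = rows$AGE[1], bodyweight = rows$BW[1],
                           cyp3a5_carrier = rows$CYP3A5[1] == 1,
                           eta_cl = etas$eta_cl[i], eta_vc = etas$eta_vc[i])
    p <- as_structural_params(p)
    obs_idx <- which(rows$EVID == 0L)
    dose_idx <- which(rows$EVID == 1L)
    for (j in obs_idx) {
      doses_before <- rows[dose_idx, ]
      doses_before <- doses_before[doses_before$TIME < rows$TIME[j], ]
      f_std <- if (nrow(doses_before)) {
        conc_profile(p, tibble::tibble(time = doses_before$TIME,
                                       amount = doses_before$AMT),
                     rows$TIME[j])$conc
      } else 0
      y_std <- f_std
      if (omega$sigma_prop > 0 && f_std > 0) {
        repeat {
          y_std <- f_std * (1 + stats::rnorm(1, 0, omega$sigma_prop))
          if (y_std > floor) break
        }
      }
      rows$DV[j] <- destandardize_hct(y_std, rows$HCT[j])
      rows$MDV[j] <- 0L
      if (tdm && rows$TIME[j] %% 24 == 0) {
        trough <- rows$DV[j]
        if (trough < 5 || trough > 10) {
          later <- dose_idx[rows$TIME[dose_idx] >= rows$TIME[j]]
          if (length(later)) {
            cur <- rows$AMT[later[1]]
            new <- cur * min(max(7.5 / max(trough, 0.5), 0.5), 2)
            new <- max(round(new / dose_increment) * dose_increment,
                       dose_increment)
            rows$AMT[later] <- new
          }
        }
      }
    }
    out[[i]] <- rows
  }
  res <- dplyr::bind_rows(out)
  attr(res, "etas") <- etas
  res
}
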
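#' Fixed-effect parameter vector of the final population model
#'
#' The typical-value (fixed-effect) parameters of the covariate model:
#'
#' * `theta1` — typical CL/F (L/h) of a CYP3A5*1 carrier aged <= 60 y at 70 kg,
#' * `theta2` — multiplicative genotype factor on CL/F for CYP3A5*1
#'   non-carriers (dimensionless, < 1: non-carriers clear more slowly),
#' * `theta3` — CL/F decline (L/h per year of age) applied to patients older
#'   than 60 years,
#' * `vc70` — central volume Vc/F at 70 kg (L), allometric exponent 1,
#' * `vp` — peripheral volume Vp/F (L), not bodyweight-scaled,
#' * `cld70` — inter-compartmental clearance CLD/F at 70 kg (L/h),
#'   allometric exponent 0.75,
#' * `ka` — absorption rate constant (1/h), fixed at 2 by default,
#' * `alag` — absorption lag time (h).
#'
#' Defaults are the final-model point estimates for this population.
#'
#' @param theta1,theta2,theta3,vc70,vp,cld70,ka,alag Parameter values.
#' @param fixed Character vector naming parameters held fixed during
#'   estimation (default: `"ka"`, fixed at 2/h because sparse absorption-phase
#'   sampling cannot support its estimation).
#'
#' @return Named list of class `"pk_theta"` with a `fixed` attribute.
#' @export
#' @examples
#' pk_theta()
pk_theta <- function(theta1 = 26.5, theta2 = 0.666, theta3 = 0.0562,
                     vc70 = 327, vp = 298, cld70 = 51.9,
                     ka = 2, alag = 0.341, fixed = "ka") {
  th <- list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
             vc70 = vc70, vp = vp, cld70 = cld70, ka = ka, alag = alag)
  if (any(!vapply(th, function(x) is.finite(x) && x > 0, logical(1)))) {
    stop("all fixed-effect parameters must be finite and strictly positive",
         call. = FALSE)
  }
  bad <- setdiff(fixed, names(th))
  if (length(bad)) stop("unknown parameter(s) in `fixed`: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(th, class = "pk_theta", fixed = fixed)
}

#' Random-effect and residual variability parameters
#'
#' `omega_cl` and `omega_vc` are the standard deviations of the log-normal
#' subject-level random effects on CL/F and Vc/F (so 100*omega is the
#' approximate between-patient %CV); `sigma_prop` is the proportional
#' residual-error SD (fraction). Defaults are the final-model estimates.
#'
#' @param omega_cl,omega_vc SD of the log-scale random effects.
#' @param sigma_prop Proportional residual SD.
#' @return Named list of class `"pk_omega"`.
#' @export
pk_omega <- function(omega_cl = 0.321, omega_vc = 0.482, sigma_prop = 0.282) {
  om <- list(omega_cl = omega_cl, omega_vc = omega_vc, sigma_prop = sigma_prop)
  if (any(!vapply(om, function(x) is.finite(x) && x >= 0, logical(1)))) {
    stop("variability parameters must be finite and non-negative", call. = FALSE)
  }
  structure(om, class = "pk_omega")
}

#' Age category of the clearance-age breakpoint model
#'
#' Indicator equal to 0 for patients aged 60 years and younger and 1 for
#' patients strictly older than 60, the breakpoint at which typical CL/F
#' starts declining with age.
#'
#' @param age Age in years (vectorized).
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' agecat(c(19, 60, 60.5, 82))
agecat <- function(age) {
  stopifnot(all(age > 0))
  as.integer(age > 60)
}

#' Typical (covariate-predicted) structural parameters
#'
#' Maps fixed effects and subject covariates to typical individual structural
#' parameters:
#'
#' * CL/F = (theta1 * theta2^(1 - carrier) - theta3 * AGE * agecat(AGE)) *
#'   (BW/70)^0.75
#' * Vc/F = vc70 * (BW/70)
#' * CLD/F = cld70 * (BW/70)^0.75
#' * Vp/F = vp (not scaled: bodyweight scaling of Vp degraded the precision of
#'   the Vc random effect and is not part of the final model)
#'
#' Allometric exponents are fixed at 0.75 for flow parameters and 1 for the
#' central volume. Vectorized over subjects.
#'
#' @param theta A [pk_theta()] parameter vector.
#' @param age Age in years.
#' @param bodyweight Bodyweight in kg.
#' @param cyp3a5_carrier Logical (or 0/1): carries at least one CYP3A5*1
#'   allele.
#' @return A tibble with one row per subject and columns `CL`, `Vc`, `Vp`,
#'   `CLD`, `Ka`, `ALAG`. For a single subject the row can be passed directly
#'   to the structural-model functions.
#' @export
#' @examples
#' typical_params(pk_theta(), age = 54, bodyweight = 70, cyp3a5_carrier = TRUE)
typical_params <- function(theta, age, bodyweight, cyp3a5_carrier) {
  stopifnot(inherits(theta, "pk_theta"))
  n <- max(length(age), length(bodyweight), length(cyp3a5_carrier))
  age <- rep_len(age, n)
  bodyweight <- rep_len(bodyweight, n)
  carrier <- rep_len(as.integer(as.logical(cyp3a5_carrier)), n)
  if (any(age < 18 | age > 100)) {
    stop("age outside model support [18, 100]", call. = FALSE)
  }
  if (any(bodyweight < 30 | bodyweight > 150)) {
    stop("bodyweight outside model support [30, 150] kg", call. = FALSE)
  }
  wt75 <- (bodyweight / 70)^0.75
  cl70 <- theta$theta1 * theta$theta2^(1L - carrier) -
    theta$theta3 * age * agecat(age)
  if (any(cl70 <= 0)) {
    stop("covariates drive typical CL/F non-positive (outside model support)",
         call. = FALSE)
  }
  tibble::tibble(
    CL = cl70 * wt75,
    Vc = theta$vc70 * (bodyweight / 70),
    Vp = rep_len(theta$vp, n),
    CLD = theta$cld70 * wt75,
    Ka = rep_len(theta$ka, n),
    ALAG = rep_len(theta$alag, n)
  )
}

#' Standardize a whole-blood concentration to hematocrit 45%
#'
#' Tacrolimus is almost entirely bound to erythrocytes (blood/plasma ratios up
#' to ~50), so at a fixed unbound plasma concentration the whole-blood
#' concentration is essentially proportional to hematocrit. Standardization
#' rescales observed whole-blood concentrations to a common hematocrit of 45%
#' so that clearance and volumes are expressed on a hematocrit-independent
#' scale: `c45 = c_obs * 45 / hct`.
#'
#' @param conc Observed whole-blood concentration (ng/mL), vectorized.
#' @param hct Hematocrit (%), must lie in (10, 60).
#' @return Concentration standardized to hematocrit 45% (ng/mL).
#' @seealso [destandardize_hct()] for the exact inverse.
#' @export
#' @examples
#' standardize_hct(6, hct = 30) # 9 ng/mL
standardize_hct <- function(conc, hct) {
  check_hct(hct)
  stopifnot(all(conc >= 0 | is.na(conc)))
  conc * 45 / hct
}

#' Back-transform a standardized concentration to the observed scale
#'
#' Exact inverse of [standardize_hct()]: `c_obs = c45 * hct / 45`. Used by the
#' dose-scenario simulator to report exposures on the hematocrit-specific
#' observed scale.
#'
#' @param conc45 Concentration standardized to hematocrit 45% (ng/mL).
#' @inheritParams standardize_hct
#' @return Observed-scale concentration (ng/mL).
#' @export
destandardize_hct <- function(conc45, hct) {
  check_hct(hct)
  conc45 * hct / 45
}

check_hct <- function(hct) {
  if (any(!is.finite(hct) | hct <= 10 | hct >= 60)) {
    stop("hematocrit outside supported range (10, 60) %", call. = FALSE)
  }
  invisible(hct)
}

#' Individual structural parameters from random effects
#'
#' Applies the exponential (log-normal) between-patient variability model to
#' the typical values: `CL_i = TV_CL * exp(eta_cl)`, `Vc_i = TV_Vc *
#' exp(eta_vc)`; the remaining parameters stay at their typical values.
#'
#' @inheritParams typical_params
#' @param eta_cl,eta_vc Subject-level random effects on the log scale.
#' @return Tibble of individual parameters, one row per subject.
#' @export
individual_params <- function(theta, age, bodyweight, cyp3a5_carrier,
                              eta_cl = 0, eta_vc = 0) {
  n <- max(length(age), length(bodyweight), length(cyp3a5_carrier),
           length(eta_cl), length(eta_vc))
  tv <- typical_params(theta, rep_len(age, n), rep_len(bodyweight, n),
                       rep_len(cyp3a5_carrier, n))
  tv$CL <- tv$CL * exp(rep_len(eta_cl, n))
  tv$Vc <- tv$Vc * exp(rep_len(eta_vc, n))
  tv
}

#' Predict observations under the proportional residual-error model
#'
#' Evaluates the structural prediction `f` at the requested times under a
#' dosing history and, when `simulate = TRUE`, draws observations
#' `y = f * (1 + eps)` with `eps ~ N(0, sigma_prop^2)`. Predictions (and hence
#' simulated observations) are on the model's concentration scale, i.e. the
#' hematocrit-45-standardized scale when the model was built on standardized
#' data. Simulated values are not truncated at zero.
#'
#' @param params Individual structural parameters (coercible via
#'   [as_structural_params()]).
#' @param doses Dosing history data frame (`time`, `amount`).
#' @param times Observation times (h).
#' @param sigma_prop Proportional residual SD; `0` returns the prediction.
#' @param simulate Draw residual noise? Default `TRUE` when `sigma_prop > 0`.
#' @return Tibble with columns `time`, `pred` (f) and `y`.
#' @export
predict_observation <- function(params, doses, times, sigma_prop = 0,
                                simulate = sigma_prop > 0) {
  f <- conc_profile(params, doses, times)$conc
  y <- if (simulate && sigma_prop > 0) f * (1 + stats::rnorm(length(f), 0, sigma_prop)) else f
  tibble::tibble(time = times, pred = f, y = y)
}

#' Write / read a model configuration file
#'
#' Serializes the fixed effects (with fixed flags), variability parameters and
#' the hematocrit-standardization toggle to a YAML key-value file that
#' round-trips exactly.
#'
#' @param theta A [pk_theta()] vector.
#' @param omega A [pk_omega()] vector.
#' @param path File path.
#' @param standardize_hct Logical: model concentrations standardized to
#'   hematocrit 45%?
#' @return `path`, invisibly (for `write_model_config`); a list with `theta`,
#'   `omega`, `standardize_hct` (for `read_model_config`).
#' @export
write_model_config <- function(theta, omega, path, standardize_hct = TRUE) {
  stopifnot(inherits(theta, "pk_theta"), inherits(omega, "pk_omega"))
  cfg <- list(
    theta = lapply(unclass(theta), format, digits = 17),
    fixed = as.list(attr(theta, "fixed")),
    omega = lapply(unclass(omega), format, digits = 17),
    standardize_hct = standardize_hct
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  th <- lapply(cfg$theta, as.numeric)
  om <- lapply(cfg$omega, as.numeric)
  list(
    theta = do.call(pk_theta, c(th, list(fixed = unlist(cfg$fixed)))),
    omega = do.call(pk_omega, om),
    standardize_hct = isTRUE(cfg$standardize_hct)
  )
}
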
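#' Linear-up/log-down trapezoidal AUC
#'
#' Area under the concentration-time curve over `interval` by the linear-log
#' trapezoidal rule: linear trapezoids on non-decreasing segments (and on any
#' segment with a zero endpoint), logarithmic trapezoids on strictly
#' decreasing segments with positive endpoints. No extrapolation is
#' performed: the sampling must cover the interval (endpoints may coincide
#' with sample times).
#'
#' @param times Sampling times (h), strictly increasing.
#' @param concs Concentrations (ng/mL), non-negative.
#' @param interval Integration window `c(t0, t1)`; defaults to the sampled
#'   range.
#' @return AUC (ng·h/mL).
#' @export
#' @examples
#' auc_linlog(c(0, 24), c(5, 5)) # 120
auc_linlog <- function(times, concs, interval = range(times)) {
  stopifnot(length(times) == length(concs), length(times) >= 2,
            all(diff(times) > 0), all(concs >= 0),
            length(interval) == 2, interval[1] < interval[2])
  t0 <- interval[1]; t1 <- interval[2]
  if (t0 < times[1] - 1e-9 || t1 > times[length(times)] + 1e-9) {
    stop("interval [", t0, ", ", t1, "] not covered by the sampling times; ",
         "no extrapolation is performed", call. = FALSE)
  }
  # interpolate interval endpoints onto the profile using the rule's own
  # interpolant so the AUC is additive over sub-intervals
  interp <- function(tt) {
    if (tt <= times[1]) return(concs[1])
    i <- findInterval(tt, times)
    if (i >= length(times)) return(concs[length(concs)])
    tl <- times[i]; tr <- times[i + 1]; cl <- concs[i]; cr <- concs[i + 1]
    if (tt == tl) return(cl)
    w <- (tt - tl) / (tr - tl)
    if (cr < cl && cr > 0 && cl > 0) cl * (cr / cl)^w else cl + w * (cr - cl)
  }
  keep <- times > t0 & times < t1
  tt <- c(t0, times[keep], t1)
  cc <- c(interp(t0), concs[keep], interp(t1))
  dt <- diff(tt)
  c1 <- cc[-length(cc)]
  c2 <- cc[-1]
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(logdown,
                dt * (c1 - c2) / log(c1 / c2),
                dt * (c1 + c2) / 2)
  sum(seg)
}

#' Extract trough concentrations
#'
#' A trough is the observation taken just before a dose: the latest
#' observation within `window` hours before (or exactly at) a dose instant.
#' Occasions without a pre-dose sample yield no row (never imputed); several
#' eligible samples before one dose raise a warning and the latest is taken.
#'
#' @param data A PK dataset ([validate_pk_dataset()]).
#' @param window Pre-dose window (h).
#' @return Tibble with `ID`, `DAY`, `time`, `ctrough` (observed scale,
#'   ng/mL), `dose` (the mg amount of the dose that follows).
#' @export
trough_extract <- function(data, window = 1) {
  d <- validate_pk_dataset(data)
  obs <- d[d$EVID == 0L & d$MDV == 0L, ]
  dose <- d[d$EVID == 1L, ]
  out <- purrr::map_dfr(split(seq_len(nrow(dose)), seq_len(nrow(dose))), function(k) {
    drow <- dose[k, ]
    cand <- obs[obs$ID == drow$ID & obs$TIME <= drow$TIME &
                  obs$TIME > drow$TIME - window, ]
    if (!nrow(cand)) return(NULL)
    if (nrow(cand) > 1) {
      warning("multiple pre-dose samples before dose at t = ", drow$TIME,
              " h (ID ", drow$ID, "); taking the latest", call. = FALSE)
      cand <- cand[which.max(cand$TIME), ]
    }
    tibble::tibble(ID = drow$ID, DAY = cand$DAY, time = cand$TIME,
                   ctrough = cand$DV, dose = drow$AMT)
  })
  out
}

#' Geometric mean with confidence interval
#'
#' `exp(mean(log x) +/- t * SE(log x))`: the standard summary for
#' log-normally distributed exposure metrics.
#'
#' @param values Positive values, `n >= 2`.
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return Tibble with `geomean`, `ci_lo`, `ci_hi`, `n`.
#' @export
#' @examples
#' geomean_ci(c(4, 9)) # geometric mean 6
geomean_ci <- function(values, alpha = 0.05) {
  bad <- which(!(values > 0))
  if (length(bad)) {
    stop("non-positive value(s) at index ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(values) >= 2)
  lx <- log(values)
  m <- mean(lx)
  se <- stats::sd(lx) / sqrt(length(lx))
  q <- stats::qt(1 - alpha / 2, df = length(lx) - 1)
  tibble::tibble(geomean = exp(m), ci_lo = exp(m - q * se),
                 ci_hi = exp(m + q * se), n = length(lx))
}

#' Non-compartmental exposure metrics per subject-occasion
#'
#' For every subject-occasion with a complete 24-h profile, computes AUC over
#' the dosing interval by [auc_linlog()]; troughs come from
#' [trough_extract()]. Metrics are also dose-normalized.
#'
#' @param data A PK dataset.
#' @param window Pre-dose window for trough identification (h).
#' @return Tibble with one row per subject-occasion metric set: `ID`, `DAY`,
#'   `dose`, `ctrough`, `auc24`, `ctrough_per_dose`, `auc24_per_dose`. AUC
#'   columns are `NA` when the occasion lacks a full profile.
#' @export
nca_metrics <- function(data, window = 1) {
  d <- validate_pk_dataset(data)
  troughs <- trough_extract(d, window = window)
  obs <- d[d$EVID == 0L & d$MDV == 0L, ]
  dose <- d[d$EVID == 1L, ]
  aucs <- obs |>
    dplyr::group_by(.data$ID, .data$DAY) |>
    dplyr::group_modify(function(g, key) {
      dsub <- dose[dose$ID == key$ID, ]
      start <- max(dsub$TIME[dsub$TIME <= min(g$TIME)], -Inf)
      auc <- tryCatch(auc_linlog(g$TIME, g$DV, interval = c(start, start + 24)),
                      error = function(e) NA_real_)
      tibble::tibble(auc24 = auc)
    }) |>
    dplyr::ungroup()
  out <- dplyr::full_join(troughs, aucs, by = c("ID", "DAY"))
  out$ctrough_per_dose <- out$ctrough / out$dose
  out$auc24_per_dose <- out$auc24 / out$dose
  dplyr::arrange(out, .data$ID, .data$DAY)
}
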
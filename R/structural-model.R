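#' Structural parameter set for the two-compartment oral model
#'
#' Bundles the apparent disposition and absorption parameters of the
#' two-compartment open model with first-order absorption and lag time used
#' throughout the package. All parameters are "apparent" (confounded with the
#' oral bioavailability F, fixed at 1 because no intravenous reference data
#' exist for this population).
#'
#' @param CL Apparent blood clearance CL/F (L/h).
#' @param Vc Apparent central distribution volume Vc/F (L).
#' @param Vp Apparent peripheral distribution volume Vp/F (L).
#' @param CLD Apparent inter-compartmental clearance CLD/F (L/h).
#' @param Ka First-order absorption rate constant (1/h).
#' @param ALAG Absorption lag time (h), applied per dose event.
#' @param F Bioavailability fraction; must be 1.
#'
#' @return A named list of class `"structural_params"`.
#' @export
#' @examples
#' structural_params(CL = 17.65, Vc = 327, Vp = 298, CLD = 51.9)
structural_params <- function(CL, Vc, Vp, CLD, Ka = 2, ALAG = 0.341, F = 1) {
  vals <- c(CL = CL, Vc = Vc, Vp = Vp, CLD = CLD, Ka = Ka, ALAG = ALAG)
  if (any(!is.finite(vals)) || any(vals[c("CL", "Vc", "Vp", "CLD", "Ka")] <= 0)) {
    stop("structural parameters CL, Vc, Vp, CLD, Ka must be finite and strictly positive",
         call. = FALSE)
  }
  if (ALAG < 0) stop("ALAG must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(F, 1))) {
    stop("F is fixed at 1 (no intravenous data); got F = ", F, call. = FALSE)
  }
  structure(as.list(vals), class = "structural_params")
}

#' Coerce to a structural parameter set
#'
#' Accepts a `structural_params` object, a named list, or a one-row data frame
#' with columns CL, Vc, Vp, CLD, Ka, ALAG (as produced by [typical_params()]).
#'
#' @param x Object to coerce.
#' @return A `structural_params` object.
#' @export
as_structural_params <- function(x) {
  if (inherits(x, "structural_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop("need exactly one row to build a structural parameter set; got ",
           nrow(x), call. = FALSE)
    }
    x <- as.list(x)
  }
  structural_params(CL = x$CL, Vc = x$Vc, Vp = x$Vp, CLD = x$CLD,
                    Ka = x$Ka, ALAG = x$ALAG)
}

#' Hybrid (macro) constants of the tri-exponential oral solution
#'
#' Converts micro rate constants (k10 = CL/Vc, k12 = CLD/Vc, k21 = CLD/Vp)
#' into the disposition exponents `alpha > beta > 0` and the absorption-phase
#' coefficients A, B, C of the closed-form central-compartment solution
#'
#'   C(t) = dose_ug * (A exp(-alpha tau) + B exp(-beta tau) + C exp(-Ka tau)),
#'
#' with tau the time since the dose became available (time after dose minus
#' ALAG) and coefficients carrying the 1/Vc scale (units 1/L).
#'
#' @param params A [structural_params()] set (or coercible via
#'   [as_structural_params()]).
#' @param tol Relative degeneracy tolerance: `Ka`, `alpha` and `beta` must be
#'   pairwise separated by more than `tol * Ka`, otherwise the closed form is
#'   ill-conditioned and an error is raised.
#'
#' @return A list with `alpha`, `beta`, `A`, `B`, `C` and the micro constants
#'   `k10`, `k12`, `k21`.
#' @export
hybrid_constants <- function(params, tol = 1e-8) {
  p <- as_structural_params(params)
  k10 <- p$CL / p$Vc
  k12 <- p$CLD / p$Vc
  k21 <- p$CLD / p$Vp
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  # disc = (k10 + k12 - k21)^2 + 4 k12 k21 > 0 always for positive constants
  root <- sqrt(max(disc, 0))
  alpha <- (s + root) / 2
  beta <- k10 * k21 / alpha # numerically stable for small beta
  ka <- p$Ka
  gap <- tol * ka
  if (abs(ka - alpha) <= gap || abs(ka - beta) <= gap || abs(alpha - beta) <= gap) {
    stop("degenerate hybrid constants: Ka (", signif(ka, 6), ") collides with a ",
         "disposition exponent (alpha = ", signif(alpha, 6), ", beta = ",
         signif(beta, 6), "); perturb Ka or the disposition parameters",
         call. = FALSE)
  }
  A <- ka * (k21 - alpha) / (p$Vc * (ka - alpha) * (beta - alpha))
  B <- ka * (k21 - beta) / (p$Vc * (ka - beta) * (alpha - beta))
  C <- ka * (k21 - ka) / (p$Vc * (alpha - ka) * (beta - ka))
  list(alpha = alpha, beta = beta, A = A, B = B, C = C,
       k10 = k10, k12 = k12, k21 = k21)
}

#' Whole-blood concentration after a single oral dose
#'
#' Closed-form central-compartment concentration for a single dose of the
#' two-compartment model with first-order absorption and lag time. Doses are
#' in mg, volumes in L; the mg -> ug conversion (factor 1000) is applied here
#' once so that amount/volume is ug/L, i.e. ng/mL.
#'
#' @param params A [structural_params()] set (or coercible).
#' @param dose Dose amount (mg).
#' @param t Time since dose administration (h); vectorized.
#' @inheritParams hybrid_constants
#' @return Concentrations (ng/mL), zero for `t <= ALAG`.
#' @export
#' @examples
#' p <- structural_params(CL = 17.65, Vc = 327, Vp = 298, CLD = 51.9)
#' conc_single_dose(p, dose = 7, t = c(0, 1, 2, 12, 24))
conc_single_dose <- function(params, dose, t, tol = 1e-8) {
  p <- as_structural_params(params)
  stopifnot(dose > 0, all(t >= -1e-12))
  h <- hybrid_constants(p, tol = tol)
  tau <- t - p$ALAG
  out <- numeric(length(t))
  on <- tau > 0
  if (any(on)) {
    tp <- tau[on]
    out[on] <- dose * 1000 *
      (h$A * exp(-h$alpha * tp) + h$B * exp(-h$beta * tp) + h$C * exp(-p$Ka * tp))
  }
  pmax(out, 0)
}

#' Concentration profile under a multiple-dose history
#'
#' Superposition of [conc_single_dose()] over a dosing history. The system is
#' linear and time invariant, so the multiple-dose solution is the sum of
#' single-dose solutions shifted to each dose time.
#'
#' @param params A [structural_params()] set (or coercible).
#' @param doses A data frame with columns `time` (h since first dose) and
#'   `amount` (mg), sorted by time.
#' @param times Evaluation times (h since first dose), sorted.
#' @inheritParams hybrid_constants
#' @return Tibble with columns `time` and `conc` (ng/mL).
#' @export
conc_profile <- function(params, doses, times, tol = 1e-8) {
  p <- as_structural_params(params)
  stopifnot(is.data.frame(doses), all(c("time", "amount") %in% names(doses)),
            all(doses$amount > 0), all(doses$time >= 0),
            !is.unsorted(doses$time), !is.unsorted(times))
  h <- hybrid_constants(p, tol = tol)
  # tau matrix: rows = times, cols = doses
  tau <- outer(times, doses$time + p$ALAG, "-")
  on <- tau > 0
  tau[!on] <- 0
  terms <- h$A * exp(-h$alpha * tau) + h$B * exp(-h$beta * tau) +
    h$C * exp(-p$Ka * tau)
  terms[!on] <- 0
  conc <- as.vector(terms %*% (doses$amount * 1000))
  tibble::tibble(time = times, conc = pmax(conc, 0))
}
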
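#' Covariate effect specification
#'
#' Describes one candidate (or retained) covariate effect on typical CL/F,
#' in one of three forms:
#'
#' * `"categorical"` — multiplicative group factor `theta^z` for a 0/1
#'   subject-level column (reference group z = 0),
#' * `"age_breakpoint"` — subtraction `theta * AGE` applied only to patients
#'   older than 60 years (typical CL/F is flat in age up to 60),
#' * `"power"` — multiplicative `(cov/median)^theta` on a positive
#'   subject-level covariate centred at its median.
#'
#' @param covariate Name of the subject-level covariate column (lower case;
#'   built-ins: `age`, `bw`, `carrier`, `noncarrier`, plus any extra numeric
#'   column of the dataset).
#' @param form Effect form.
#' @param name Parameter name; defaults to a name derived from the covariate.
#' @param init Initial value for estimation.
#' @param median Covariate median (power form only).
#' @return A list of class `"covariate_spec"`.
#' @export
covariate_spec <- function(covariate,
                           form = c("categorical", "age_breakpoint", "power"),
                           name = NULL, init = NULL, median = NULL) {
  form <- match.arg(form)
  if (form == "power" && (is.null(median) || median <= 0)) {
    stop("power form needs a positive covariate `median`", call. = FALSE)
  }
  if (is.null(name)) {
    name <- switch(form,
                   categorical = paste0("beta_", covariate),
                   age_breakpoint = "theta3",
                   power = paste0("pwr_", covariate))
  }
  if (is.null(init)) {
    init <- switch(form, categorical = 1, age_breakpoint = 0.02, power = 0)
  }
  structure(list(covariate = covariate, form = form, name = name,
                 init = init, median = median,
                 scale = if (form == "power") "identity" else "log"),
            class = "covariate_spec")
}

#' @rdname covariate_spec
#' @export
spec_genotype <- function(init = 0.666) {
  covariate_spec("noncarrier", "categorical", name = "theta2", init = init)
}

#' @rdname covariate_spec
#' @export
spec_age <- function(init = 0.0562) {
  covariate_spec("age", "age_breakpoint", name = "theta3", init = init)
}

#' Covariate effects of the final model
#'
#' CYP3A5 genotype (carrier vs non-carrier multiplier on CL/F) and the
#' age breakpoint at 60 years.
#' @return Named list of [covariate_spec()] objects.
#' @export
final_covariates <- function() {
  list(genotype = spec_genotype(), age = spec_age())
}

#' Estimation control settings
#'
#' @param se Compute standard errors (finite-difference Hessian of the OFV)?
#' @param rel_tol Outer relative convergence tolerance.
#' @param iter_max,eval_max Outer iteration/evaluation budget.
#' @param inner_gtol Gradient tolerance of the inner (eta-mode) Newton solve.
#' @param inner_maxit Inner iteration cap.
#' @param hess_step Finite-difference step (transformed scale) for the
#'   standard-error Hessian.
#' @param trace Print outer-optimizer progress.
#' @return List of control settings.
#' @export
fit_control <- function(se = TRUE, rel_tol = 1e-7, iter_max = 300,
                        eval_max = 2000, inner_gtol = 1e-5, inner_maxit = 30,
                        hess_step = 5e-3, trace = 0) {
  list(se = se, rel_tol = rel_tol, iter_max = iter_max, eval_max = eval_max,
       inner_gtol = inner_gtol, inner_maxit = inner_maxit,
       hess_step = hess_step, trace = trace)
}

# ---- parameter packing -----------------------------------------------------

build_parspec <- function(theta, omega, specs) {
  fixed_th <- attr(theta, "fixed") %||% character()
  fixed_om <- attr(omega, "fixed") %||% character()
  nm <- c("theta1", "vc70", "vp", "cld70", "ka", "alag")
  entries <- lapply(nm, function(p) {
    list(name = p, init = theta[[p]], scale = "log",
         free = !(p %in% fixed_th), where = "theta")
  })
  for (sp in specs) {
    init <- if (!is.null(theta[[sp$name]])) theta[[sp$name]] else sp$init
    entries <- c(entries, list(list(name = sp$name, init = init,
                                    scale = sp$scale,
                                    free = !(sp$name %in% fixed_th),
                                    where = "theta")))
  }
  for (p in c("omega_cl", "omega_vc", "sigma_prop")) {
    entries <- c(entries, list(list(
      name = p, init = omega[[p]], scale = "log",
      free = !(p %in% fixed_om) && omega[[p]] > 0, where = "omega"
    )))
  }
  names(entries) <- vapply(entries, `[[`, "", "name")

  trans <- function(x, scale) if (scale == "log") log(x) else x
  inv <- function(x, scale) if (scale == "log") exp(x) else x

  free_names <- names(entries)[vapply(entries, `[[`, TRUE, "free")]
  start <- vapply(entries[free_names],
                  function(e) trans(e$init, e$scale), numeric(1))

  unpack <- function(p_free) {
    th <- list(); om <- list()
    for (e in entries) {
      val <- if (e$free) inv(p_free[[e$name]], e$scale) else e$init
      if (e$where == "theta") th[[e$name]] <- val else om[[e$name]] <- val
    }
    list(th = th, om = om)
  }
  list(entries = entries, free_names = free_names, start = start,
       unpack = unpack)
}

# ---- objective-function value ---------------------------------------------

#' Approximate marginal-likelihood objective function value
#'
#' -2 times the log approximate marginal likelihood of the population model,
#' summed over subjects, with the additive n*log(2*pi) constant excluded
#' (NONMEM convention, so OFV differences are comparable to chi-square
#' quantiles). The per-subject integral over the random effects is
#' approximated by a Laplace expansion at the eta mode, with the residual
#' variance evaluated at the individual prediction (conditional estimation
#' with interaction). With all random-effect SDs equal to zero this reduces
#' exactly to the fixed-effects -2 log likelihood.
#'
#' @param data A PK dataset (see [validate_pk_dataset()]).
#' @param theta A [pk_theta()] vector.
#' @param omega A [pk_omega()] vector.
#' @param covariates List of active [covariate_spec()] effects (default: the
#'   final model's genotype + age effects).
#' @param standardize Standardize concentrations to hematocrit 45% before
#'   computing the likelihood (the final model's concentration scale)?
#' @return The OFV (scalar).
#' @export
ofv_laplace <- function(data, theta = pk_theta(), omega = pk_omega(),
                        covariates = final_covariates(), standardize = TRUE) {
  comp <- compile_pkdata(data, standardize)
  engine <- make_engine(comp, covariates)
  th <- theta_engine_list(theta, covariates)
  engine$ofv(th, unclass(omega))
}

theta_engine_list <- function(theta, specs) {
  th <- unclass(theta)
  for (sp in specs) {
    if (is.null(th[[sp$name]])) th[[sp$name]] <- sp$init
  }
  th
}

#' Likelihood-ratio significance of an OFV drop
#'
#' Maps a drop in OFV between nested models to a chi-square p-value. The
#' conventional thresholds for one degree of freedom are 3.841 (p = 0.05,
#' forward inclusion), 7.879 (p = 0.005) and 10.83 (p = 0.001, backward
#' retention).
#'
#' @param delta_ofv OFV drop (positive; vectorized).
#' @param df Degrees of freedom (number of added parameters).
#' @param alpha Significance level for the pass/fail decision.
#' @return Tibble with `delta_ofv`, `df`, `p_value`, `significant`.
#' @export
#' @examples
#' lrt_threshold(c(3.841, 7.879, 10.83))
lrt_threshold <- function(delta_ofv, df = 1, alpha = 0.05) {
  stopifnot(df >= 1)
  p <- stats::pchisq(delta_ofv, df = df, lower.tail = FALSE)
  tibble::tibble(delta_ofv = delta_ofv, df = df, p_value = p,
                 significant = p < alpha)
}

# ---- maximum-likelihood fit ------------------------------------------------

#' Fit the population pharmacokinetic model
#'
#' Maximizes the Laplacian approximate marginal likelihood over the free
#' fixed effects (log-transformed), random-effect SDs and the proportional
#' residual SD, using a quasi-Newton (PORT/nlminb) outer optimization with a
#' Nelder-Mead restart if the first pass fails to converge. Standard errors
#' come from the inverse finite-difference Hessian of the OFV; the condition
#' number is the eigenvalue ratio of the correlation matrix of the estimates.
#'
#' @inheritParams ofv_laplace
#' @param control A [fit_control()] list.
#' @return An object of class `"tac_fit"`: a list with the estimated `theta`
#'   and `omega`, `ofv`, a parameter table `par` (term, estimate, rse_pct,
#'   fixed), empirical-Bayes estimates `ebes`, `shrinkage`,
#'   `condition_number`, `convergence` (0 = converged) and bookkeeping
#'   fields. Supports [tidy()], [glance()] and `print()`.
#' @export
pk_fit <- function(data, theta = pk_theta(), omega = pk_omega(),
                   covariates = final_covariates(), standardize = TRUE,
                   control = fit_control()) {
  comp <- compile_pkdata(data, standardize)
  engine <- make_engine(comp, covariates)
  ps <- build_parspec(theta, omega, covariates)
  if (!length(ps$free_names)) stop("no free parameters to estimate", call. = FALSE)

  nev <- 0L
  obj <- function(p) {
    names(p) <- ps$free_names
    u <- ps$unpack(as.list(p))
    nev <<- nev + 1L
    engine$ofv(u$th, u$om, inner_gtol = control$inner_gtol,
               inner_maxit = control$inner_maxit)
  }

  opt <- stats::nlminb(ps$start, obj,
                       control = list(rel.tol = control$rel_tol,
                                      iter.max = control$iter_max,
                                      eval.max = control$eval_max,
                                      trace = control$trace))
  convergence <- opt$convergence
  message_txt <- opt$message
  if (convergence != 0) {
    # second quasi-Newton pass from the endpoint often converges cleanly
    opt2 <- stats::nlminb(opt$par, obj,
                          control = list(rel.tol = control$rel_tol,
                                         iter.max = control$iter_max,
                                         eval.max = control$eval_max))
    if (opt2$objective <= opt$objective + 1e-8) {
      opt <- opt2
      convergence <- opt2$convergence
      message_txt <- opt2$message
    }
  }
  if (convergence != 0) {
    # derivative-free restart from the quasi-Newton endpoint
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
    if (opt2$value <= opt$objective + 1e-8) {
      opt <- list(par = opt2$par, objective = opt2$value,
                  convergence = opt2$convergence, message = "Nelder-Mead restart")
      convergence <- opt2$convergence
      message_txt <- "Nelder-Mead restart"
    }
  }
  par_hat <- opt$par
  names(par_hat) <- ps$free_names
  u <- ps$unpack(as.list(par_hat))

  # standard errors from the OFV Hessian: cov = 2 * H^-1 on transformed scale
  se_trans <- rep(NA_real_, length(par_hat))
  names(se_trans) <- ps$free_names
  condition_number <- NA_real_
  vcov_trans <- NULL
  if (isTRUE(control$se)) {
    H <- tryCatch(fd_hessian(obj, par_hat, control$hess_step),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        se_trans <- sqrt(diag(V))
        names(se_trans) <- ps$free_names
        vcov_trans <- V
        ev <- eigen(stats::cov2cor(V), symmetric = TRUE,
                    only.values = TRUE)$values
        if (min(ev) > 0) condition_number <- max(ev) / min(ev)
      }
    }
  }

  det <- engine$details(u$th, u$om, inner_gtol = control$inner_gtol,
                        inner_maxit = control$inner_maxit)
  ebes <- tibble::tibble(ID = comp$ids, eta_cl = det$E[, 1L],
                         eta_vc = det$E[, 2L])
  iwres <- (comp$y - det$f) / (u$om$sigma_prop * det$f)
  shk <- list(
    eta_cl = if (u$om$omega_cl > 0)
      100 * (1 - stats::sd(det$E[, 1L]) / u$om$omega_cl) else NA_real_,
    eta_vc = if (u$om$omega_vc > 0)
      100 * (1 - stats::sd(det$E[, 2L]) / u$om$omega_vc) else NA_real_,
    eps = 100 * (1 - stats::sd(iwres))
  )

  par_tbl <- purrr::map_dfr(ps$entries, function(e) {
    est <- if (e$free) {
      if (e$scale == "log") exp(par_hat[[e$name]]) else par_hat[[e$name]]
    } else e$init
    rse <- if (e$free && is.finite(se_trans[[e$name]])) {
      if (e$scale == "log") 100 * se_trans[[e$name]]
      else 100 * se_trans[[e$name]] / abs(est)
    } else NA_real_
    tibble::tibble(term = e$name, estimate = est, rse_pct = rse,
                   fixed = !e$free, block = e$where)
  })

  theta_hat <- pk_theta(
    theta1 = u$th$theta1,
    theta2 = u$th$theta2 %||% theta$theta2,
    theta3 = u$th$theta3 %||% theta$theta3,
    vc70 = u$th$vc70, vp = u$th$vp, cld70 = u$th$cld70,
    ka = u$th$ka, alag = u$th$alag, fixed = attr(theta, "fixed")
  )
  omega_hat <- pk_omega(u$om$omega_cl, u$om$omega_vc, u$om$sigma_prop)
  attr(omega_hat, "fixed") <- attr(omega, "fixed")

  structure(list(
    theta = theta_hat, omega = omega_hat, ofv = opt$objective,
    par = par_tbl, ebes = ebes, iwres = iwres, shrinkage = shk,
    condition_number = condition_number, convergence = convergence,
    message = message_txt, vcov_trans = vcov_trans,
    covariates = covariates, standardize = standardize,
    n_subjects = comp$ns, n_obs = comp$n_obs, n_eval = nev,
    data = data
  ), class = "tac_fit")
}

fd_hessian <- function(fn, par, step = 5e-3) {
  p <- length(par)
  H <- matrix(0, p, p)
  f0 <- fn(par)
  pert <- function(i, di, j = NULL, dj = 0) {
    x <- par
    x[i] <- x[i] + di
    if (!is.null(j)) x[j] <- x[j] + dj
    fn(x)
  }
  for (i in seq_len(p)) {
    H[i, i] <- (pert(i, step) - 2 * f0 + pert(i, -step)) / step^2
    if (i < p) for (j in seq((i + 1), p)) {
      H[i, j] <- H[j, i] <-
        (pert(i, step, j, step) - pert(i, step, j, -step) -
           pert(i, -step, j, step) + pert(i, -step, j, -step)) / (4 * step^2)
    }
  }
  H
}

#' Empirical-Bayes estimates of the random effects
#'
#' Per-subject posterior modes of (eta_cl, eta_vc) at fixed population
#' parameters. A subject without observations has mode (0, 0), the prior
#' mode.
#'
#' @inheritParams ofv_laplace
#' @return Tibble with `ID`, `eta_cl`, `eta_vc`.
#' @export
empirical_bayes <- function(data, theta = pk_theta(), omega = pk_omega(),
                            covariates = final_covariates(),
                            standardize = TRUE) {
  comp <- compile_pkdata(data, standardize)
  engine <- make_engine(comp, covariates)
  det <- engine$details(theta_engine_list(theta, covariates), unclass(omega),
                        inner_gtol = 1e-6)
  tibble::tibble(ID = comp$ids, eta_cl = det$E[, 1L], eta_vc = det$E[, 2L])
}

#' Eta and epsilon shrinkage
#'
#' Eta shrinkage is `100 * (1 - SD(EBE)/omega)` per random effect; epsilon
#' shrinkage is `100 * (1 - SD(IWRES))` with individual weighted residuals
#' `IWRES = (y - f)/(sigma_prop * f)`. High shrinkage means the data carry
#' little subject-level information and EBE-based diagnostics are unreliable.
#'
#' @param x A `"tac_fit"` object, or a data frame of EBEs with columns
#'   `eta_cl`, `eta_vc`.
#' @param omega A [pk_omega()] vector (when `x` is a data frame).
#' @param iwres Optional vector of individual weighted residuals.
#' @return Tibble with `quantity` and `shrinkage_pct`.
#' @export
shrinkage <- function(x, omega = NULL, iwres = NULL) {
  if (inherits(x, "tac_fit")) {
    s <- x$shrinkage
    return(tibble::tibble(quantity = c("eta_cl", "eta_vc", "eps"),
                          shrinkage_pct = c(s$eta_cl, s$eta_vc, s$eps)))
  }
  stopifnot(is.data.frame(x), nrow(x) >= 2, inherits(omega, "pk_omega"))
  out <- tibble::tibble(
    quantity = c("eta_cl", "eta_vc"),
    shrinkage_pct = c(
      if (omega$omega_cl > 0) 100 * (1 - stats::sd(x$eta_cl) / omega$omega_cl) else NA_real_,
      if (omega$omega_vc > 0) 100 * (1 - stats::sd(x$eta_vc) / omega$omega_vc) else NA_real_
    )
  )
  if (!is.null(iwres)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      quantity = "eps", shrinkage_pct = 100 * (1 - stats::sd(iwres))))
  }
  out
}

# ---- stepwise covariate search --------------------------------------------

#' Forward-backward stepwise covariate search
#'
#' Candidates are added one at a time; at each forward step the candidate
#' with the largest OFV drop is included if the drop reaches
#' `forward_dofv` (chi-square, 1 df) *and* the between-patient variance of
#' the targeted parameter (omega_cl^2) falls by at least `bpv_drop`
#' relative — the clinical-significance rule. Backward elimination then
#' removes any included covariate whose removal raises the OFV by less than
#' `backward_dofv`.
#'
#' @inheritParams pk_fit
#' @param candidates Named list of [covariate_spec()] candidates.
#' @param base_covariates Covariate effects always present (default none).
#' @param forward_dofv,backward_dofv OFV thresholds (3.841 = p 0.05 forward;
#'   10.83 = p 0.001 backward).
#' @param bpv_drop Minimum relative reduction in omega_cl^2 for clinical
#'   significance (default 0.10).
#' @return List with `fit` (final model fit), `selected` (names of retained
#'   candidates) and `log` (tibble audit trail of OFVs and BPVs).
#' @export
covariate_search <- function(data, theta = pk_theta(), omega = pk_omega(),
                             candidates = final_covariates(),
                             base_covariates = list(),
                             forward_dofv = 3.841, backward_dofv = 10.83,
                             bpv_drop = 0.10, standardize = TRUE,
                             control = fit_control(se = FALSE)) {
  if (is.null(names(candidates))) names(candidates) <- vapply(candidates, `[[`, "", "name")
  fit_with <- function(specs) {
    pk_fit(data, theta, omega, covariates = specs,
           standardize = standardize, control = control)
  }
  included <- base_covariates
  current <- fit_with(included)
  log <- list()
  note <- function(phase, candidate, f_new, decision) {
    tibble::tibble(
      phase = phase, candidate = candidate,
      ofv = f_new$ofv, delta_ofv = current$ofv - f_new$ofv,
      omega_cl = f_new$omega$omega_cl,
      bpv_var_drop = 1 - f_new$omega$omega_cl^2 / current$omega$omega_cl^2,
      decision = decision
    )
  }
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    trials <- purrr::map(remaining, function(sp) {
      tryCatch(fit_with(c(included, list(sp))), error = function(e) NULL)
    })
    ok <- !vapply(trials, is.null, TRUE)
    if (!any(ok)) break
    dofv <- vapply(trials[ok], function(f) current$ofv - f$ofv, numeric(1))
    bpv <- vapply(trials[ok], function(f)
      1 - f$omega$omega_cl^2 / current$omega$omega_cl^2, numeric(1))
    pass <- dofv >= forward_dofv & bpv >= bpv_drop
    for (nm in names(trials[ok])) {
      log[[length(log) + 1L]] <- note(
        "forward", nm, trials[ok][[nm]],
        if (pass[[nm]]) "eligible" else "rejected")
    }
    if (!any(pass)) break
    best <- names(which.max(dofv[pass]))
    included <- c(included, remaining[best])
    current <- trials[[best]]
    remaining <- remaining[setdiff(names(remaining), best)]
    for (k in seq_along(log)) {
      if (log[[k]]$phase == "forward" && log[[k]]$candidate == best &&
          log[[k]]$ofv == current$ofv) log[[k]]$decision <- "included"
    }
  }
  # backward elimination over the candidates that were included
  incl_names <- setdiff(names(included), names(base_covariates))
  for (nm in incl_names) {
    reduced <- included[setdiff(names(included), nm)]
    f_red <- tryCatch(fit_with(reduced), error = function(e) NULL)
    if (is.null(f_red)) next
    increase <- f_red$ofv - current$ofv
    keep <- increase >= backward_dofv
    log[[length(log) + 1L]] <- tibble::tibble(
      phase = "backward", candidate = nm, ofv = f_red$ofv,
      delta_ofv = increase, omega_cl = f_red$omega$omega_cl,
      bpv_var_drop = 1 - current$omega$omega_cl^2 / f_red$omega$omega_cl^2,
      decision = if (keep) "retained" else "removed")
    if (!keep) {
      included <- reduced
      current <- f_red
    }
  }
  list(fit = current,
       selected = setdiff(names(included) %||% character(0),
                          names(base_covariates) %||% character(0)),
       log = dplyr::bind_rows(log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
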
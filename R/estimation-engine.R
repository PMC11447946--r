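# Internal marginal-likelihood engine.
#
# The approximate marginal likelihood is computed subject by subject with a
# Laplace approximation at the mode of the penalized individual deviance
# ("conditional estimation with interaction": the residual variance is
# evaluated at the individual prediction). All subjects are advanced
# simultaneously by a vectorized safeguarded Newton iteration, so one OFV
# evaluation touches each (observation, dose) pair exactly once per stencil
# point.

F_FLOOR <- 1e-6 # ng/mL; predictions below this make a proportional error model degenerate

#' @keywords internal
compile_pkdata <- function(data, standardize = TRUE) {
  d <- validate_pk_dataset(data)
  ids <- unique(d$ID)
  ns <- length(ids)
  idx <- match(d$ID, ids)

  first <- !duplicated(d$ID)
  cov <- list(
    age = d$AGE[first],
    bw = d$BW[first],
    carrier = as.integer(d$CYP3A5[first]),
    id = ids
  )
  cov$noncarrier <- 1L - cov$carrier
  cov$wt75 <- (cov$bw / 70)^0.75
  cov$bwn <- cov$bw / 70
  # any extra numeric columns become subject-level covariates (first value)
  extra <- setdiff(names(d), c("ID", "TIME", "EVID", "AMT", "MDV", "DV",
                               "HCT", "AGE", "BW", "CYP3A5", "DAY"))
  for (nm in extra) {
    if (is.numeric(d[[nm]])) cov[[tolower(nm)]] <- d[[nm]][first]
  }

  is_obs <- d$EVID == 0L & d$MDV == 0L
  is_dose <- d$EVID == 1L
  obs <- d[is_obs, ]
  dose <- d[is_dose, ]
  subj_o <- idx[is_obs]
  subj_d <- idx[is_dose]

  y <- if (standardize) standardize_hct(obs$DV, obs$HCT) else obs$DV
  n_obs <- nrow(obs)

  # (observation, prior dose) pairs within subject; same-instant trough
  # samples precede the dose, so strict inequality is correct.
  trip <- dplyr::inner_join(
    tibble::tibble(o = seq_len(n_obs), s = subj_o, t_obs = obs$TIME),
    tibble::tibble(s = subj_d, t_dose = dose$TIME, amt = dose$AMT),
    by = "s", relationship = "many-to-many"
  )
  trip <- trip[trip$t_dose < trip$t_obs, ]
  trip <- trip[order(trip$o), ]

  list(
    ns = ns, ids = ids, cov = cov,
    n_obs = n_obs, subj_o = subj_o, y = y,
    obs_time = obs$TIME, obs_hct = obs$HCT, obs_day = obs$DAY,
    n_trip = nrow(trip),
    trip_o = trip$o, trip_s = trip$s,
    trip_dt = trip$t_obs - trip$t_dose,
    trip_amt = trip$amt * 1000
  )
}

group_sum <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    tmp <- rowsum(x, g, reorder = FALSE)
    out[as.integer(rownames(tmp))] <- tmp[, 1L]
  }
  out
}

# Typical CL at 70 kg from theta + active covariate specs (two passes:
# multiplicative forms first, then the age-breakpoint subtraction).
typical_cl70 <- function(th, comp, specs) {
  cl70 <- rep(th$theta1, comp$ns)
  for (sp in specs) {
    if (sp$form == "categorical") {
      z <- comp$cov[[sp$covariate]]
      cl70 <- cl70 * th[[sp$name]]^z
    } else if (sp$form == "power") {
      v <- comp$cov[[sp$covariate]]
      cl70 <- cl70 * (v / sp$median)^th[[sp$name]]
    }
  }
  for (sp in specs) {
    if (sp$form == "age_breakpoint") {
      cl70 <- cl70 - th[[sp$name]] * comp$cov$age * (comp$cov$age > 60)
    }
  }
  cl70
}

# Structural predictions for all observations given per-subject CL and Vc.
predict_f <- function(comp, CL, Vc, CLD, Vp, ka, alag) {
  k10 <- CL / Vc
  k12 <- CLD / Vc
  k21 <- CLD / Vp
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(pmax(s * s - 4 * k10 * k21, 0))) / 2
  beta <- k10 * k21 / alpha
  da <- ka - alpha
  db <- ka - beta
  dab <- alpha - beta
  # guard transient near-degeneracy during optimization
  da <- ifelse(abs(da) < 1e-10, 1e-10, da)
  db <- ifelse(abs(db) < 1e-10, 1e-10, db)
  dab <- ifelse(abs(dab) < 1e-10, 1e-10, dab)
  cA <- ka * (k21 - alpha) / (Vc * da * (-dab))
  cB <- ka * (k21 - beta) / (Vc * db * dab)
  cC <- ka * (k21 - ka) / (Vc * da * db)

  st <- comp$trip_s
  tau <- comp$trip_dt - alag
  pos <- tau > 0
  contrib <- (cA[st] * exp(-alpha[st] * tau) +
                cB[st] * exp(-beta[st] * tau) +
                cC[st] * exp(-ka * tau)) * comp$trip_amt
  contrib[!pos] <- 0
  group_sum(contrib, comp$trip_o, comp$n_obs)
}

# Penalized individual deviance h_i(eta) for all subjects at once.
# E is ns x 2 (columns: eta_cl, eta_vc); fixed dims are simply left at zero
# by the caller and carry no penalty.
make_hfun <- function(comp, th, om, TV) {
  sig2 <- om$sigma_prop^2
  iv1 <- if (om$omega_cl > 0) 1 / om$omega_cl^2 else 0
  iv2 <- if (om$omega_vc > 0) 1 / om$omega_vc^2 else 0
  force(TV)
  function(E) {
    CL <- TV$CL * exp(E[, 1L])
    Vc <- TV$Vc * exp(E[, 2L])
    f <- predict_f(comp, CL, Vc, TV$CLD, TV$Vp, th$ka, th$alag)
    f <- pmax(f, F_FLOOR)
    v <- sig2 * f * f
    r <- log(v) + (comp$y - f)^2 / v
    group_sum(r, comp$subj_o, comp$ns) + E[, 1L]^2 * iv1 + E[, 2L]^2 * iv2
  }
}

# Vectorized safeguarded Newton for the inner eta problem.
# free: logical length 2, which eta dimensions are free.
laplace_inner <- function(hfun, E0, free, gtol = 1e-4, max_iter = 30, d = 1e-3) {
  ns <- nrow(E0)
  E <- E0
  E[, !free] <- 0
  k <- sum(free)
  if (k == 0L) {
    h0 <- hfun(E)
    return(list(E = E, h = h0, logdet = numeric(ns), niter = 0L))
  }
  shift <- function(E, d1, d2) {
    En <- E
    if (free[1L]) En[, 1L] <- En[, 1L] + d1
    if (free[2L]) En[, 2L] <- En[, 2L] + d2
    En
  }
  h0 <- hfun(E)
  stencil <- function(E, h0) {
    if (k == 2L) {
      hp1 <- hfun(shift(E, d, 0)); hm1 <- hfun(shift(E, -d, 0))
      hp2 <- hfun(shift(E, 0, d)); hm2 <- hfun(shift(E, 0, -d))
      hpp <- hfun(shift(E, d, d)); hpm <- hfun(shift(E, d, -d))
      hmp <- hfun(shift(E, -d, d)); hmm <- hfun(shift(E, -d, -d))
      list(
        g1 = (hp1 - hm1) / (2 * d), g2 = (hp2 - hm2) / (2 * d),
        H11 = (hp1 - 2 * h0 + hm1) / d^2, H22 = (hp2 - 2 * h0 + hm2) / d^2,
        H12 = (hpp - hpm - hmp + hmm) / (4 * d^2)
      )
    } else if (free[1L]) {
      hp1 <- hfun(shift(E, d, 0)); hm1 <- hfun(shift(E, -d, 0))
      list(g1 = (hp1 - hm1) / (2 * d), g2 = numeric(ns),
           H11 = (hp1 - 2 * h0 + hm1) / d^2, H22 = rep(1, ns), H12 = numeric(ns))
    } else {
      hp2 <- hfun(shift(E, 0, d)); hm2 <- hfun(shift(E, 0, -d))
      list(g1 = numeric(ns), g2 = (hp2 - hm2) / (2 * d),
           H11 = rep(1, ns), H22 = (hp2 - 2 * h0 + hm2) / d^2, H12 = numeric(ns))
    }
  }
  niter <- 0L
  st <- NULL
  for (iter in seq_len(max_iter)) {
    niter <- iter
    st <- stencil(E, h0)
    gmax <- pmax(abs(st$g1) * free[1L], abs(st$g2) * free[2L])
    if (max(gmax) < gtol) break
    det <- st$H11 * st$H22 - st$H12^2
    ok <- st$H11 > 0 & det > 0
    s1 <- ifelse(ok, -(st$H22 * st$g1 - st$H12 * st$g2) / det,
                 -st$g1 / pmax(abs(st$H11), 1))
    s2 <- ifelse(ok, -(st$H11 * st$g2 - st$H12 * st$g1) / det,
                 -st$g2 / pmax(abs(st$H22), 1))
    s1 <- pmin(pmax(s1, -3), 3) * free[1L]
    s2 <- pmin(pmax(s2, -3), 3) * free[2L]
    step <- rep(1, ns)
    En <- E
    En[, 1L] <- E[, 1L] + s1
    En[, 2L] <- E[, 2L] + s2
    hn <- hfun(En)
    worse <- !is.finite(hn) | hn > h0 + 1e-10
    tries <- 0L
    while (any(worse) && tries < 8L) {
      step[worse] <- step[worse] / 2
      En[worse, 1L] <- E[worse, 1L] + step[worse] * s1[worse]
      En[worse, 2L] <- E[worse, 2L] + step[worse] * s2[worse]
      htry <- hfun(En)
      hn[worse] <- htry[worse]
      worse <- !is.finite(hn) | hn > h0 + 1e-10
      tries <- tries + 1L
    }
    moved <- !worse & (abs(s1 * step) + abs(s2 * step)) > 1e-12
    if (!any(moved)) break
    E[moved, ] <- En[moved, ]
    h0[moved] <- hn[moved]
  }
  if (is.null(st)) st <- stencil(E, h0)
  if (k == 2L) {
    det <- pmax(st$H11 * st$H22 - st$H12^2, 1e-12)
    logdet <- log(det / 4)
  } else {
    Hf <- if (free[1L]) st$H11 else st$H22
    logdet <- log(pmax(Hf, 1e-12) / 2)
  }
  list(E = E, h = h0, logdet = logdet, niter = niter, grad = cbind(st$g1, st$g2))
}

# Engine factory: closes over the compiled dataset and keeps a warm-start
# cache of eta modes across OFV evaluations.
make_engine <- function(comp, specs) {
  cache <- new.env(parent = emptyenv())
  cache$E <- matrix(0, comp$ns, 2L)

  typical <- function(th) {
    cl70 <- typical_cl70(th, comp, specs)
    if (any(cl70 <= 0) || any(!is.finite(cl70))) return(NULL)
    list(
      CL = cl70 * comp$cov$wt75,
      Vc = th$vc70 * comp$cov$bwn,
      CLD = th$cld70 * comp$cov$wt75,
      Vp = rep(th$vp, comp$ns)
    )
  }

  details <- function(th, om, inner_gtol = 1e-4, inner_maxit = 30) {
    TV <- typical(th)
    if (is.null(TV)) return(NULL)
    free <- c(om$omega_cl > 0, om$omega_vc > 0)
    hfun <- make_hfun(comp, th, om, TV)
    sol <- laplace_inner(hfun, cache$E, free,
                         gtol = inner_gtol, max_iter = inner_maxit)
    cache$E <- sol$E
    logdet_omega <- sum(c(
      if (free[1L]) 2 * log(om$omega_cl) else 0,
      if (free[2L]) 2 * log(om$omega_vc) else 0
    ))
    ofv <- sum(sol$h) + comp$ns * logdet_omega + sum(sol$logdet)
    CL <- TV$CL * exp(sol$E[, 1L])
    Vc <- TV$Vc * exp(sol$E[, 2L])
    f <- predict_f(comp, CL, Vc, TV$CLD, TV$Vp, th$ka, th$alag)
    list(ofv = ofv, E = sol$E, f = pmax(f, F_FLOOR), TV = TV,
         niter = sol$niter)
  }

  ofv <- function(th, om, ...) {
    det <- details(th, om, ...)
    if (is.null(det) || !is.finite(det$ofv)) return(1e10)
    det$ofv
  }

  list(ofv = ofv, details = details, comp = comp,
       reset = function() cache$E <- matrix(0, comp$ns, 2L))
}
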
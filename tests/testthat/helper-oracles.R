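# Independent numerical oracles used across tests.

# Oracle 1: concentrations by numerical integration of the three-state ODE
# system (depot -> central <-> peripheral, elimination from central), with
# each dose entering the depot as an event at dose time + ALAG. This path is
# independent of the closed-form tri-exponential solution.
ode_profile_oracle <- function(params, doses, times, rtol = 1e-10,
                               atol = 1e-12) {
  p <- tacropop::as_structural_params(params)
  k10 <- p$CL / p$Vc
  k12 <- p$CLD / p$Vc
  k21 <- p$CLD / p$Vp
  deriv <- function(t, y, parms) {
    list(c(
      -p$Ka * y[1],
      p$Ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
      k12 * y[2] - k21 * y[3]
    ))
  }
  ev_times <- doses$time + p$ALAG
  events <- data.frame(var = "depot", time = ev_times,
                       value = doses$amount * 1000, method = "add")
  tt <- sort(unique(c(0, times, ev_times)))
  out <- deSolve::lsoda(c(depot = 0, central = 0, periph = 0), tt, deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        events = list(data = events))
  conc <- out[match(times, out[, "time"]), "central"] / p$Vc
  unname(conc)
}

ode_single_oracle <- function(params, dose, times, ...) {
  ode_profile_oracle(params, data.frame(time = 0, amount = dose), times, ...)
}

# Oracle 2: analytic integral of the superposed tri-exponential from t0 to
# t1 (used to check the linear-log trapezoid on dense grids).
analytic_auc <- function(params, doses, t0, t1) {
  p <- tacropop::as_structural_params(params)
  h <- tacropop::hybrid_constants(p)
  term <- function(coef, rate) {
    sapply(seq_len(nrow(doses)), function(i) {
      s <- doses$time[i] + p$ALAG
      lo <- max(t0, s); hi <- max(t1, s)
      if (hi <= lo) return(0)
      doses$amount[i] * 1000 * coef / rate *
        (exp(-rate * (lo - s)) - exp(-rate * (hi - s)))
    })
  }
  sum(term(h$A, h$alpha)) + sum(term(h$B, h$beta)) + sum(term(h$C, p$Ka))
}

# Random valid structural parameter sets spanning a broad plausible range.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tacropop::structural_params(
      CL = exp(runif(1, log(5), log(60))),
      Vc = exp(runif(1, log(80), log(900))),
      Vp = exp(runif(1, log(80), log(900))),
      CLD = exp(runif(1, log(10), log(150))),
      Ka = exp(runif(1, log(0.8), log(4))),
      ALAG = runif(1, 0, 0.8)
    )
  })
}
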
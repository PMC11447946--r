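#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted population PK model
#'
#' One row per model parameter: estimate, relative standard error (%),
#' whether the parameter was fixed, and its block (fixed effect vs
#' variability).
#'
#' @param x A `"tac_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `rse_pct`, `fixed`,
#'   `block`.
#' @method tidy tac_fit
#' @export
tidy.tac_fit <- function(x, ...) {
  x$par
}

#' @rdname tidy.tac_fit
#' @method glance tac_fit
#' @export
glance.tac_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv,
    condition_number = x$condition_number,
    shrinkage_cl_pct = x$shrinkage$eta_cl,
    shrinkage_vc_pct = x$shrinkage$eta_vc,
    shrinkage_eps_pct = x$shrinkage$eps,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    convergence = x$convergence
  )
}

#' @export
print.tac_fit <- function(x, digits = 4, ...) {
  cat("Population PK fit (two-compartment oral, Laplacian conditional estimation)\n")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f; convergence = %d\n",
              x$n_subjects, x$n_obs, x$ofv, x$convergence))
  tab <- x$par
  tab$estimate <- signif(tab$estimate, digits)
  tab$rse_pct <- signif(tab$rse_pct, 3)
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("  eta shrinkage: CL %.1f%%, Vc %.1f%%; eps %.1f%%\n",
              x$shrinkage$eta_cl, x$shrinkage$eta_vc, x$shrinkage$eps))
  if (is.finite(x$condition_number %||% NA)) {
    cat(sprintf("  condition number: %.1f\n", x$condition_number))
  }
  invisible(x)
}

#' Plot a prediction-corrected VPC
#'
#' Observed percentiles (lines and points) over the simulated confidence
#' bands per percentile, against time after dose.
#'
#' @param object A `"pk_vpc"` object from [pcvpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_vpc
#' @export
autoplot.pk_vpc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$percentile <- factor(df$percentile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tad)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi,
                                      group = .data$percentile),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    group = .data$percentile,
                                    linetype = .data$percentile),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "firebrick") +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (ng/mL)",
                  linetype = "Percentile") +
    ggplot2::theme_minimal()
}

#' Plot simulated dose-scenario exposures
#'
#' Boxplots of simulated C_trough or AUC_24 by dose, faceted by genotype and
#' hematocrit stratum.
#'
#' @param object A `"pk_scenario_grid"` object from [scenario_grid()].
#' @param metric `"ctrough"` or `"auc24"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_scenario_grid
#' @export
autoplot.pk_scenario_grid <- function(object, metric = c("ctrough", "auc24"),
                                      ...) {
  metric <- match.arg(metric)
  df <- object$metrics
  df$stratum <- sprintf("HCT %g-%g%%", df$hct_lo, df$hct_hi)
  df$dose_f <- factor(df$dose)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_f,
                                        y = .data[[metric]],
                                        fill = factor(.data$age))) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::facet_grid(genotype ~ stratum) +
    ggplot2::labs(x = "Once-daily dose (mg)", fill = "Age (y)",
                  y = if (metric == "ctrough") "C_trough (ng/mL)"
                      else "AUC_24 (ng·h/mL)") +
    ggplot2::theme_minimal()
  if (metric == "ctrough") {
    p <- p + ggplot2::geom_hline(yintercept = c(5, 10), linetype = "dashed")
  }
  p
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC (%d simulations, %d bins)\n",
              attr(x, "n_sim"), length(unique(x$tad))))
  NextMethod()
}

#' @export
print.pk_scenario <- function(x, ...) {
  cat("Dose-scenario simulation\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @importFrom rlang .data
NULL
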
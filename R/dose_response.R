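# Four-parameter logistic dose-response fitting on log10 dose.

#' Evaluate the four-parameter logistic curve
#'
#' `response(x) = ECmax + (FV0 - ECmax) / (1 + 10^((x - EC50) * hillslope))`
#' with `x = log10(dose)`. At `x = EC50` the curve equals the midpoint of the
#' two plateaus.
#'
#' @param x log10 dose.
#' @param FV0 response plateau at zero dose.
#' @param ECmax response plateau at saturating dose.
#' @param EC50 log10 dose of half effect.
#' @param hillslope slope parameter.
#' @return Numeric vector of responses.
#' @export
logistic4 <- function(x, FV0, ECmax, EC50, hillslope) {
  ECmax + (FV0 - ECmax) / (1 + 10^((x - EC50) * hillslope))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [logistic4()] on log10-transformed doses. The vehicle
#' condition (dose 0) cannot enter the log-dose regression; it is used only
#' to anchor the starting value of `FV0`. A response that is flat to within
#' `flat_tol` is returned with both plateaus at the mean, the hillslope
#' pinned at 0, and `degenerate = TRUE` rather than being fit.
#'
#' @param doses drug concentrations (vehicle = 0 allowed); at least 5
#'   distinct positive doses required.
#' @param response the response metric at each dose (FV, RV, or GR).
#' @param metric name of the metric being fit (recorded in the result).
#' @param flat_tol standard-deviation threshold below which the response is
#'   treated as flat.
#' @return An object of class `dose_response_fit`: a list with elements
#'   `FV0`, `ECmax`, `EC50`, `hillslope`, `metric`, `rss`, `degenerate`,
#'   and `fv50` (the dose, on the linear scale, at half-maximal effect).
#' @export
fit_dose_response <- function(doses, response, metric = "FV", flat_tol = 1e-8) {
  check_that(length(doses) == length(response), "`doses` and `response` lengths differ")
  check_that(all(doses >= 0), "doses must be >= 0")
  pos <- doses > 0
  check_that(length(unique(doses[pos])) >= 5,
             "need at least 5 distinct positive doses")
  x <- log10(doses[pos])
  y <- response[pos]

  if (stats::sd(response) < flat_tol) {
    fit <- list(FV0 = mean(response), ECmax = mean(response), EC50 = NA_real_,
                hillslope = 0, metric = metric, rss = 0, degenerate = TRUE,
                fv50 = NA_real_)
    class(fit) <- "dose_response_fit"
    return(fit)
  }

  fv0_start <- if (any(!pos)) mean(response[!pos]) else y[which.min(x)]
  start <- c(FV0 = fv0_start, ECmax = y[which.max(x)],
             EC50 = stats::median(x), hillslope = 1)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - logistic4(x, p[1], p[2], p[3], p[4]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  # info codes 1:3 are convergence; 0 and >4 are failures
  if (!fit$info %in% 1:4) {
    stop(sprintf(
      "dose-response fit failed to converge (%s); best iterate FV0=%.4g ECmax=%.4g EC50=%.4g hill=%.4g (rss = %.4g)",
      fit$message, fit$par[1], fit$par[2], fit$par[3], fit$par[4], fit$deviance
    ), call. = FALSE)
  }
  cf <- as.list(fit$par)
  out <- list(
    FV0 = cf$FV0, ECmax = cf$ECmax, EC50 = cf$EC50, hillslope = cf$hillslope,
    metric = metric, rss = fit$deviance, degenerate = FALSE,
    fv50 = 10^cf$EC50
  )
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4-parameter logistic fit of %s%s\n", x$metric,
              if (x$degenerate) " [degenerate: flat response]" else ""))
  cat(sprintf("  plateaus  : FV0 = %.4g, ECmax = %.4g\n", x$FV0, x$ECmax))
  cat(sprintf("  EC50      : %.4g (log10 dose; dose = %.4g)\n", x$EC50, x$fv50))
  cat(sprintf("  hillslope : %.4g   rss = %.3g\n", x$hillslope, x$rss))
  invisible(x)
}
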
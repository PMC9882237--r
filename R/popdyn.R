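# Biphasic population dynamics: exponential growth until drug-induced
# proliferation arrest, then exponential decay of the killable fraction of
# the arrested cohort. This is the forward model shared by the relative-
# viability simulations and the screen death-rate inference.

#' Parameters of the biphasic growth-then-death response
#'
#' Untreated populations grow exponentially with doubling time `tau_c`.
#' Under treatment, growth continues at the clone's own rate until arrest at
#' `t_arrest`; thereafter the killable fraction `LFp` of the arrested cohort
#' decays exponentially with rate `d` (in halvings per hour), while the
#' residual fraction `1 - LFp` persists. Setting `arrest_enabled = FALSE`
#' lets growth continue through the death phase (death still engages at
#' `t_arrest`); `death_enabled = FALSE` forces `d = 0`.
#'
#' @param tau_c untreated doubling time in hours (> 0).
#' @param t_arrest time of proliferation arrest under treatment, hours (>= 0).
#' @param d drug-induced death rate in halvings per hour (>= 0).
#' @param LFp maximum killable fraction, in (0, 1]. `LFp = 1` recovers pure
#'   exponential decay of the whole cohort.
#' @param arrest_enabled logical; does treatment arrest proliferation?
#' @param death_enabled logical; does treatment kill?
#' @return An object of class `biphasic_params`.
#' @examples
#' wt <- biphasic_params(tau_c = 24, t_arrest = 24, d = 1/72)
#' simulate_population(wt, times = seq(0, 96, by = 24))
#' @export
biphasic_params <- function(tau_c = 24, t_arrest = 24, d = 1 / 72, LFp = 1,
                            arrest_enabled = TRUE, death_enabled = TRUE) {
  check_that(is_scalar_num(tau_c) && tau_c > 0, "`tau_c` must be a positive number")
  check_that(is_scalar_num(t_arrest) && t_arrest >= 0, "`t_arrest` must be >= 0")
  check_that(is_scalar_num(d) && d >= 0, "`d` must be >= 0")
  check_that(is_scalar_num(LFp) && LFp > 0 && LFp <= 1, "`LFp` must be in (0, 1]")
  structure(
    list(
      tau_c = tau_c, g = 1 / tau_c, t_arrest = t_arrest, d = d, LFp = LFp,
      arrest_enabled = isTRUE(arrest_enabled),
      death_enabled = isTRUE(death_enabled)
    ),
    class = "biphasic_params"
  )
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat("Biphasic response parameters\n")
  cat(sprintf("  doubling time   : %.3g h (g = %.4g doublings/h)\n", x$tau_c, x$g))
  cat(sprintf("  arrest onset    : %.3g h  [%s]\n", x$t_arrest,
              if (x$arrest_enabled) "arrest on" else "arrest off"))
  cat(sprintf("  death rate      : %.4g halvings/h  [%s]\n", x$d,
              if (x$death_enabled) "death on" else "death off"))
  cat(sprintf("  killable LFp    : %.3g\n", x$LFp))
  invisible(x)
}

# survivor fraction of the cohort exposed to death, vectorized over t
survivor_fraction <- function(params, t) {
  d <- if (params$death_enabled) params$d else 0
  ta <- params$t_arrest
  s <- (1 - params$LFp) + params$LFp * 2^(-d * pmax(0, t - ta))
  s[t <= ta] <- 1
  s
}

#' Simulate live and dead cell numbers under the biphasic model
#'
#' Treated arm: `live(t) = N0 * 2^(g * min(t, t_arrest)) * S(t)` with survivor
#' fraction `S(t) = 1` before arrest and
#' `S(t) = (1 - LFp) + LFp * 2^(-d * (t - t_arrest))` after. Cumulative dead
#' cells are the cohort complement, so `live + dead` is conserved after
#' arrest. With `arrest_enabled = FALSE` the pre-death growth factor
#' `2^(g * t)` applies throughout.
#'
#' @param params a [biphasic_params()] object.
#' @param times hours since drugging; sorted, starting at 0.
#' @param n0 starting live cell number (> 0).
#' @return A data frame with columns `time_h`, `live`, `dead`.
#' @export
simulate_population <- function(params, times, n0 = 1) {
  stopifnot(inherits(params, "biphasic_params"))
  check_that(is.numeric(times) && length(times) > 0 && all(is.finite(times)),
             "`times` must be finite numbers")
  check_that(all(times >= 0), "negative times are invalid")
  check_that(!is.unsorted(times), "`times` must be sorted increasing")
  check_that(is_scalar_num(n0) && n0 > 0, "`n0` must be > 0")

  g <- params$g
  grown <- if (params$arrest_enabled) {
    n0 * 2^(g * pmin(times, params$t_arrest))
  } else {
    n0 * 2^(g * times)
  }
  s <- survivor_fraction(params, times)
  data.frame(time_h = times, live = grown * s, dead = grown * (1 - s))
}

#' Relative viability over time for the four arrest/death scenarios
#'
#' Computes `RV(t) = live_treated(t) / live_untreated(t)` where the untreated
#' arm grows exponentially at the same `tau_c`, for the four combinations of
#' arrest and death being enabled or disabled. The "neither" scenario is the
#' untreated arm itself, so `RV = 1` at all times.
#'
#' @param wt a [biphasic_params()] object giving the wild-type treated response.
#' @param horizon assay length in hours.
#' @param n_times number of evenly spaced timepoints (including 0).
#' @return A data frame with columns `time_h`, `scenario`, `rv`. Scenarios are
#'   `"arrest+death"`, `"arrest"`, `"death"`, `"neither"`.
#' @export
simulate_rv_scenarios <- function(wt, horizon = 168, n_times = 169) {
  stopifnot(inherits(wt, "biphasic_params"))
  times <- seq(0, horizon, length.out = n_times)
  untreated <- 2^(wt$g * times)
  scen <- list(
    "arrest+death" = c(TRUE, TRUE),
    "arrest"       = c(TRUE, FALSE),
    "death"        = c(FALSE, TRUE),
    "neither"      = c(FALSE, FALSE)
  )
  out <- lapply(names(scen), function(nm) {
    p <- biphasic_params(
      tau_c = wt$tau_c, t_arrest = wt$t_arrest, d = wt$d, LFp = wt$LFp,
      arrest_enabled = scen[[nm]][1], death_enabled = scen[[nm]][2]
    )
    traj <- simulate_population(p, times)
    data.frame(time_h = times, scenario = nm, rv = traj$live / untreated)
  })
  do.call(rbind, out)
}

#' Finite-difference sensitivity of relative viability to the death rate
#'
#' For each consecutive pair of death rates, computes
#' `(RV(t; d_hi) - RV(t; d_lo)) / (d_hi - d_lo)` at each timepoint under the
#' arrest+death scenario. The magnitude of this sensitivity rises to a peak
#' after death onset and decays toward zero as untreated proliferation
#' dominates the RV scale, which is why endpoint RV carries almost no
#' information about the death rate.
#'
#' @param wt a [biphasic_params()] object (its `d` is ignored; the grid is
#'   taken from `death_rates`).
#' @param death_rates increasing death rates (halvings/h), length >= 2.
#' @param times evaluation times in hours.
#' @return A data frame with columns `time_h`, `d_lo`, `d_hi`, `sensitivity`.
#' @export
rv_death_sensitivity <- function(wt, death_rates = c(0, 0.05),
                                 times = seq(0, 168, by = 1)) {
  stopifnot(inherits(wt, "biphasic_params"))
  check_that(length(death_rates) >= 2 && !is.unsorted(death_rates, strictly = TRUE),
             "`death_rates` must be >= 2 strictly increasing values")
  untreated <- 2^(wt$g * times)
  rv_at <- function(d) {
    p <- biphasic_params(tau_c = wt$tau_c, t_arrest = wt$t_arrest, d = d,
                         LFp = wt$LFp)
    simulate_population(p, times)$live / untreated
  }
  rvs <- lapply(death_rates, rv_at)
  out <- lapply(seq_len(length(death_rates) - 1L), function(i) {
    data.frame(
      time_h = times,
      d_lo = death_rates[i], d_hi = death_rates[i + 1L],
      sensitivity = (rvs[[i + 1L]] - rvs[[i]]) / (death_rates[i + 1L] - death_rates[i])
    )
  })
  do.call(rbind, out)
}

#' Predicted normalized log2 fold changes for a knockout clone
#'
#' Runs the biphasic forward model for a clone with growth rate `g` and
#' drug-induced death rate `d`, and for the wild-type reference carried by
#' `design`, and returns the two screen contrasts as log2 ratios of
#' clone-to-reference relative abundance (the in-silico analogue of anchoring
#' sequencing depth to non-targeting guides):
#' `l2fc_tx_unt`, the treated vs untreated contrast at `T_tx`, and
#' `l2fc_unt_t0`, the untreated vs T0 contrast over `T_unt0`.
#'
#' With `LFp = 1` these reduce to the closed forms
#' `l2fc_unt_t0 = (g - g_wt) * T_unt0` and
#' `l2fc_tx_unt = (g - g_wt) * (t_arrest - T_tx) - (d - d_wt) * (T_tx - t_arrest)`.
#'
#' @param g clone growth rate(s), doublings/h. Vectorized.
#' @param d clone drug-induced death rate(s), halvings/h. Vectorized.
#' @param design an [assay_design()] object.
#' @return A data frame with columns `g`, `d`, `l2fc_tx_unt`, `l2fc_unt_t0`.
#' @export
predict_l2fc <- function(g, d, design) {
  stopifnot(inherits(design, "assay_design"))
  check_that(all(g > 0), "growth rates must be > 0")
  check_that(all(d >= 0), "death rates must be >= 0")
  if (design$T_tx <= design$t_arrest) {
    warning("T_tx <= t_arrest: death phase never engaged in the treated contrast")
  }
  n <- max(length(g), length(d))
  g <- rep_len(g, n)
  d <- rep_len(d, n)

  live_tx <- function(g, d) {
    # treated-arm live cells at T_tx: clone grows at its own rate to arrest
    s <- (1 - design$LFp_wt) +
      design$LFp_wt * 2^(-d * pmax(0, design$T_tx - design$t_arrest))
    2^(g * pmin(design$T_tx, design$t_arrest)) * s
  }
  tx <- log2(live_tx(g, d)) - log2(live_tx(design$g_wt, design$d_wt))
  unt_at_ttx <- (g - design$g_wt) * design$T_tx
  data.frame(
    g = g, d = d,
    l2fc_tx_unt = tx - unt_at_ttx,
    l2fc_unt_t0 = (g - design$g_wt) * design$T_unt0
  )
}
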
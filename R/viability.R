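# Death-specific drug-response metrics from plate-reader data: the assay
# measures dead-cell fluorescence kinetically plus lysed-plate totals at the
# start and end of the assay; everything else is derived from those numbers.

#' Infer total-cell fluorescence at intermediate timepoints
#'
#' Total cell number is measured directly (by lysis) only at the assay start
#' and end; intermediate totals are interpolated with a simple exponential
#' growth model: `total(t) = t0_total * (end_total / t0_total)^(t / T_end)`.
#' The endpoints match the inputs exactly.
#'
#' @param t0_total lysed-plate fluorescence at assay start (> 0).
#' @param end_total lysed-plate fluorescence at assay end (> 0).
#' @param times hours since drugging, within `[0, t_end]`.
#' @param t_end assay length in hours; defaults to `max(times)`.
#' @return Numeric vector of total fluorescence at `times`.
#' @examples
#' infer_total_timecourse(1000, 4000, times = c(0, 24, 48), t_end = 48)
#' @export
infer_total_timecourse <- function(t0_total, end_total, times, t_end = max(times)) {
  check_that(is_scalar_num(t0_total) && t0_total > 0, "`t0_total` must be > 0")
  check_that(is_scalar_num(end_total) && end_total > 0, "`end_total` must be > 0")
  check_that(is_scalar_num(t_end) && t_end > 0, "`t_end` must be > 0")
  check_that(all(times >= 0 & times <= t_end), "`times` must lie in [0, t_end]")
  if (end_total < t0_total) {
    warning("end_total < t0_total: population shrank over the assay")
  }
  t0_total * (end_total / t0_total)^(times / t_end)
}

#' Compute lethal fraction, fractional viability, relative viability, and GR
#'
#' All inputs are background-subtracted fluorescence on a common gain, so
#' fluorescence ratios equal cell-number ratios. Live signal is
#' `total - dead`, with small negative values clipped to zero (a warning
#' reports how many). Definitions:
#' \itemize{
#'   \item `FV = live / (live + dead)`, `LF = 1 - FV` (death-specific);
#'   \item `RV = live_treated / live_untreated` (conflates arrest and death);
#'   \item `GR = 2^(log2(live_tx / live_T0) / log2(live_unt / live_T0)) - 1`,
#'     the growth-rate-normalized response: 1 means unperturbed growth,
#'     0 complete arrest, negative values net population shrinkage.
#' }
#' GR requires a growing untreated reference; if `untreated_live <= live_t0`
#' at a timepoint, GR there is `NA` and the returned `gr_defined` flag is
#' `FALSE` rather than the point being dropped.
#'
#' @param dead dead-cell fluorescence series (treated wells).
#' @param total total-cell fluorescence series (same timepoints).
#' @param untreated_live live-cell fluorescence of untreated companion wells.
#' @param live_t0 live-cell fluorescence at drugging time (shared baseline).
#' @return A data frame with columns `LF`, `FV`, `RV`, `GR`, `gr_defined`.
#' @export
compute_metrics <- function(dead, total, untreated_live, live_t0) {
  n <- length(dead)
  check_that(length(total) == n && length(untreated_live) == n,
             "`dead`, `total`, `untreated_live` must have equal length")
  check_that(is_scalar_num(live_t0) && live_t0 > 0, "`live_t0` must be > 0")
  live <- total - dead
  n_clip <- sum(live < 0)
  if (n_clip > 0) {
    warning(sprintf("clipped %d negative live value(s) to 0", n_clip))
    live <- pmax(live, 0)
  }
  fv <- ifelse(total > 0, live / (live + dead), NA_real_)
  rv <- live / untreated_live
  gr_defined <- untreated_live > live_t0
  gr <- rep(NA_real_, n)
  ok <- gr_defined & live > 0
  gr[ok] <- 2^(log2(live[ok] / live_t0) / log2(untreated_live[ok] / live_t0)) - 1
  # complete kill: treated live == 0 while reference grows -> GR -> -1 limit
  gr[gr_defined & live == 0] <- -1
  if (any(!gr_defined)) {
    warning(sprintf("GR undefined at %d timepoint(s): untreated reference not growing",
                    sum(!gr_defined)))
  }
  data.frame(LF = 1 - fv, FV = fv, RV = rv, GR = gr, gr_defined = gr_defined)
}

#' Subtract plate background fluorescence
#'
#' Subtracts the mean cell-free-well signal from a fluorescence series and
#' clips negative results to zero, reporting how many values were clipped.
#'
#' @param signal fluorescence series.
#' @param background fluorescence of cell-free wells (scalar or vector; the
#'   mean is used).
#' @return Background-subtracted series.
#' @export
subtract_background <- function(signal, background) {
  adj <- signal - mean(background)
  n_clip <- sum(adj < 0)
  if (n_clip > 0) {
    warning(sprintf("clipped %d negative background-subtracted value(s) to 0", n_clip))
  }
  pmax(adj, 0)
}
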
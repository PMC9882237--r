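# GRADE: an angle-ratio statistic for the coordination between growth
# inhibition and death activation across doses of one drug.

#' Compute the GRADE coordination score from paired (GR, FV) dose responses
#'
#' Fractional viability is first normalized for the basal death rate of the
#' cell line: `LF_norm = max(0, (LF - basal_LF) / (1 - basal_LF))` and
#' `FV_norm = 1 - LF_norm`, which pins untreated wells to `FV_norm = 1`.
#' Doses with `GR >= 0` (growth-positive responses) are fit by least squares
#' to a line of `FV_norm` on GR, giving the observed slope `m_drug`. The
#' maximum slope achievable over the same GR range is that of the line from
#' `(GR = 1, FV_norm = 1)` to `(GR = min observed, FV_norm = 0)`, i.e.
#' `m_max = 1 / (1 - GR_min)`. GRADE is the angle ratio
#' `atan(m_drug) / atan(m_max)`: 1 when death is maximally coupled to growth
#' inhibition, 0 when doses inhibit growth without killing.
#'
#' @param gr GR values across doses.
#' @param fv fractional viability at the same doses.
#' @param basal_lf basal lethal fraction from vehicle wells, in `[0, 1)`.
#' @return An object of class `grade_result`: list with `m_drug`, `m_max`,
#'   `grade`, `n_doses_used`, `gr_min`.
#' @export
compute_grade <- function(gr, fv, basal_lf = 0) {
  check_that(length(gr) == length(fv), "`gr` and `fv` lengths differ")
  check_that(is_scalar_num(basal_lf) && basal_lf >= 0 && basal_lf < 1,
             "`basal_lf` must be in [0, 1)")
  lf_norm <- pmax(0, ((1 - fv) - basal_lf) / (1 - basal_lf))
  fv_norm <- 1 - lf_norm

  keep <- !is.na(gr) & gr >= 0
  if (sum(keep) < 2) {
    stop("GRADE undefined: fewer than 2 doses with GR >= 0", call. = FALSE)
  }
  gr_k <- gr[keep]
  fv_k <- fv_norm[keep]

  m_drug <- if (stats::sd(gr_k) == 0) {
    stop("GRADE undefined: no spread in GR over the GR >= 0 doses", call. = FALSE)
  } else {
    unname(stats::coef(stats::lm(fv_k ~ gr_k))[2])
  }
  gr_min <- min(gr_k)
  m_max <- 1 / (1 - gr_min)

  out <- list(m_drug = m_drug, m_max = m_max,
              grade = atan(m_drug) / atan(m_max),
              n_doses_used = sum(keep), gr_min = gr_min)
  class(out) <- "grade_result"
  out
}

#' @export
print.grade_result <- function(x, ...) {
  cat("GRADE growth/death coordination\n")
  cat(sprintf("  m_drug = %.4g  m_max = %.4g (over GR in [%.3g, 1])\n",
              x$m_drug, x$m_max, x$gr_min))
  cat(sprintf("  GRADE  = %.4g  (%d doses used)\n", x$grade, x$n_doses_used))
  invisible(x)
}
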
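# Death-rate inference from screen fold changes: the biphasic forward model
# maps (growth rate, death rate) to a treated-vs-untreated L2FC; because
# death engages only after proliferation arrest, the map is monotone in the
# death rate at fixed growth rate, so the observed L2FC pins the death rate
# once the clone's growth rate is known from the untreated-vs-T0 contrast.

#' Screen assay design and wild-type reference rates
#'
#' Defaults are calibrated so the wild-type treated arm reaches a lethal
#' fraction of ~0.5 at 96 h (one untreated doubling per day, arrest at 24 h,
#' one halving per 72 h of the arrested cohort), matching a screen dosed for
#' roughly half-lethal response by assay end.
#'
#' @param T_tx treated-contrast duration, hours.
#' @param T_unt0 untreated-vs-T0 contrast duration, hours.
#' @param t_arrest arrest onset under drug, hours (0 < t_arrest < T_tx).
#' @param g_wt wild-type growth rate, doublings/h.
#' @param d_wt wild-type drug-induced death rate, halvings/h.
#' @param LFp_wt maximum killable fraction of the wild-type response.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(T_tx = 96, T_unt0 = 96, t_arrest = 24,
                         g_wt = 1 / 24, d_wt = 1 / 72, LFp_wt = 1) {
  check_that(is_scalar_num(T_tx) && T_tx > 0, "`T_tx` must be > 0")
  check_that(is_scalar_num(T_unt0) && T_unt0 > 0, "`T_unt0` must be > 0")
  check_that(is_scalar_num(t_arrest) && t_arrest >= 0 && t_arrest < T_tx,
             "need 0 <= t_arrest < T_tx")
  check_that(is_scalar_num(g_wt) && g_wt > 0, "`g_wt` must be > 0")
  check_that(is_scalar_num(d_wt) && d_wt >= 0, "`d_wt` must be >= 0")
  check_that(is_scalar_num(LFp_wt) && LFp_wt > 0 && LFp_wt <= 1,
             "`LFp_wt` must be in (0, 1]")
  structure(list(T_tx = T_tx, T_unt0 = T_unt0, t_arrest = t_arrest,
                 g_wt = g_wt, d_wt = d_wt, LFp_wt = LFp_wt),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Screen assay design\n")
  cat(sprintf("  treated contrast : %g h (arrest at %g h)\n", x$T_tx, x$t_arrest))
  cat(sprintf("  untreated vs T0  : %g h\n", x$T_unt0))
  cat(sprintf("  wild-type rates  : g = %.4g doublings/h, d = %.4g halvings/h, LFp = %.3g\n",
              x$g_wt, x$d_wt, x$LFp_wt))
  invisible(x)
}

#' Infer a clone's growth rate from its untreated-vs-T0 fold change
#'
#' With depth anchored to non-targeting guides, a wild-type clone maps to
#' `l2fc_unt_t0 = 0`, so `g_hat = g_wt + l2fc_unt_t0 / T_unt0`. Implied
#' rates at or below zero are floored at `g_floor` and flagged.
#'
#' @param l2fc_unt_t0 log2 fold change, untreated vs T0. Vectorized.
#' @param design an [assay_design()].
#' @param g_floor positive floor for the inferred rate.
#' @return Data frame with columns `g_hat`, `g_floored`.
#' @export
infer_growth_rate <- function(l2fc_unt_t0, design, g_floor = 1e-4) {
  stopifnot(inherits(design, "assay_design"))
  g_hat <- design$g_wt + l2fc_unt_t0 / design$T_unt0
  floored <- !is.na(g_hat) & g_hat <= 0
  g_hat[floored] <- g_floor
  data.frame(g_hat = g_hat, g_floored = floored)
}

#' Build the growth-by-death phase diagram of predicted fold changes
#'
#' Fills the surface of treated-vs-untreated L2FC over all (growth rate,
#' death rate) combinations with [predict_l2fc()], and asserts the
#' monotonicity (non-increasing along each axis) on which unique inversion
#' relies.
#'
#' @param design an [assay_design()].
#' @param g_grid increasing growth rates; defaults to 0.1-2x wild type.
#' @param d_grid increasing death rates; defaults to 0.1-2x wild type
#'   (prepended with 0).
#' @return An object of class `phase_diagram`: list with `g_grid`, `d_grid`,
#'   `l2fc_surface` (genes x: rows g, cols d), and `achievable_range`
#'   (per-g min/max L2FC over the death-rate axis).
#' @export
build_phase_diagram <- function(design,
                                g_grid = seq(0.1, 2, length.out = 40) * design$g_wt,
                                d_grid = c(0, seq(0.1, 2, length.out = 39) * design$d_wt)) {
  stopifnot(inherits(design, "assay_design"))
  check_that(!is.unsorted(g_grid, strictly = TRUE), "`g_grid` must be strictly increasing")
  check_that(!is.unsorted(d_grid, strictly = TRUE), "`d_grid` must be strictly increasing")
  grid <- expand.grid(g = g_grid, d = d_grid)
  surface <- matrix(predict_l2fc(grid$g, grid$d, design)$l2fc_tx_unt,
                    nrow = length(g_grid), ncol = length(d_grid),
                    dimnames = list(NULL, NULL))
  if (any(apply(surface, 1, function(r) any(diff(r) > 1e-12))) ||
      any(apply(surface, 2, function(cl) any(diff(cl) > 1e-12)))) {
    stop("phase-diagram surface is not monotone non-increasing in g and d; inversion would be ill-posed",
         call. = FALSE)
  }
  structure(
    list(g_grid = g_grid, d_grid = d_grid, l2fc_surface = surface,
         achievable_range = data.frame(g = g_grid,
                                       l2fc_min = apply(surface, 1, min),
                                       l2fc_max = apply(surface, 1, max)),
         design = design),
    class = "phase_diagram"
  )
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %d growth rates x %d death rates\n",
              length(x$g_grid), length(x$d_grid)))
  cat(sprintf("  L2FC surface spans [%.3g, %.3g]\n",
              min(x$l2fc_surface), max(x$l2fc_surface)))
  invisible(x)
}

#' Invert the forward model: death rate from observed L2FC and growth rate
#'
#' Solves `predict_l2fc(g_hat, d)$l2fc_tx_unt == l2fc_tx_unt` for `d` by
#' bisection on `[0, d_max]` to an absolute tolerance of `tol` in `d`. If
#' the observed L2FC lies outside the achievable range for `g_hat` (above
#' the no-death ceiling, or below the saturation floor when `LFp_wt < 1` or
#' below the `d_max` cap), `d_hat` is clipped to that boundary and
#' `on_manifold` is `FALSE`.
#'
#' @param l2fc_tx_unt observed treated-vs-untreated log2 fold change.
#'   Vectorized.
#' @param g_hat inferred growth rate(s), > 0. Recycled against the L2FCs.
#' @param design an [assay_design()].
#' @param d_max upper bracket for the death rate (default 10x wild type).
#' @param tol absolute bisection tolerance in `d`.
#' @return Data frame with columns `d_hat`, `on_manifold`.
#' @export
infer_death_rate <- function(l2fc_tx_unt, g_hat, design,
                             d_max = 10 * design$d_wt, tol = 1e-8) {
  stopifnot(inherits(design, "assay_design"))
  check_that(all(g_hat > 0), "`g_hat` must be > 0")
  n <- max(length(l2fc_tx_unt), length(g_hat))
  target <- rep_len(l2fc_tx_unt, n)
  g <- rep_len(g_hat, n)

  f <- function(d) predict_l2fc(g, d, design)$l2fc_tx_unt
  hi_val <- f(rep_len(0, n))        # L2FC is maximal at d = 0
  lo_val <- f(rep_len(d_max, n))    # and minimal at the d_max cap

  d_hat <- rep(NA_real_, n)
  on_manifold <- rep(TRUE, n)
  above <- target >= hi_val
  below <- target <= lo_val
  d_hat[above] <- 0
  d_hat[below] <- d_max
  on_manifold[above & target > hi_val + tol] <- FALSE
  on_manifold[below & target < lo_val - tol] <- FALSE

  open <- which(!above & !below)
  if (length(open)) {
    lo <- rep(0, length(open))
    hi <- rep(d_max, length(open))
    g_open <- g[open]
    t_open <- target[open]
    fo <- function(d) predict_l2fc(g_open, d, design)$l2fc_tx_unt
    # bisection: forward model is decreasing in d
    while (max(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      val <- fo(mid)
      take_upper <- val > t_open    # predicted still too high -> need more death
      lo[take_upper] <- mid[take_upper]
      hi[!take_upper] <- mid[!take_upper]
    }
    d_hat[open] <- (lo + hi) / 2
  }
  d_hat[is.na(target)] <- NA_real_
  on_manifold[is.na(target)] <- NA
  data.frame(d_hat = d_hat, on_manifold = on_manifold)
}

#' Classify the error a conventional fold-change analysis would make
#'
#' The conventional call of a gene's death-regulatory role is
#' `sign(-l2fc_tx_unt)` (depletion = sensitizing = faster death) where
#' `|l2fc| > tau_fc`, else null; the rate-based call is `sign(l2dr)` where
#' `|l2dr| > tau_dr`, else null. Type I: conventional call with a null true
#' effect. Type II: conventional null with a true effect. Type III: both
#' non-null with opposite signs (the inverted inference seen for slow-growing
#' DNA-repair knockouts).
#'
#' @param l2fc_tx_unt conventional treated-vs-untreated log2 fold change.
#' @param l2dr log2 ratio of inferred to wild-type death rate.
#' @param tau_fc minimal absolute L2FC effect.
#' @param tau_dr minimal absolute L2DR effect.
#' @return Character vector in `{"none", "I", "II", "III"}`.
#' @export
classify_error_type <- function(l2fc_tx_unt, l2dr, tau_fc = 0.25, tau_dr = 0.25) {
  conv <- ifelse(abs(l2fc_tx_unt) > tau_fc, sign(-l2fc_tx_unt), 0)
  true <- ifelse(abs(l2dr) > tau_dr, sign(l2dr), 0)
  out <- rep("none", length(conv))
  out[conv != 0 & true == 0] <- "I"
  out[conv == 0 & true != 0] <- "II"
  out[conv != 0 & true != 0 & conv != true] <- "III"
  out[is.na(conv) | is.na(true)] <- NA_character_
  out
}

#' Full death-rate analysis of a screen count matrix
#'
#' Pipeline: trim guides, normalize depth to non-targeting guides, compute
#' guide-level L2FC for both contrasts, collapse to genes, build
#' non-targeting pseudo-genes, infer per-gene growth and death rates by
#' inverting the biphasic forward model, convert to L2DR
#' (`log2(d_hat / d_wt)`, floored at `l2dr_floor` when the death rate clips
#' to zero), score L2DR and growth rates against the pseudo-gene null, and
#' classify the error the conventional L2FC analysis would make.
#'
#' @param cm a raw [count_matrix()] with T0, untreated, and treated samples.
#' @param design an [assay_design()].
#' @param pseudocount pseudocount for [compute_l2fc()].
#' @param guides_per_gene guides per non-targeting pseudo-gene.
#' @param n_boot bootstrap resamples for the empirical p-value.
#' @param seed RNG seed (pseudo-gene shuffle and bootstrap).
#' @param min_nontargeting minimum usable non-targeting guides for
#'   normalization.
#' @param tau_fc,tau_dr effect thresholds for [classify_error_type()].
#' @param l2dr_floor lower bound applied to L2DR so boundary-clipped death
#'   rates stay finite for scoring.
#' @return An object of class `screen_analysis`: list with `results` (one
#'   row per targeting gene: gene, n_guides, l2fc_tx_unt, l2fc_unt_t0,
#'   g_hat, d_hat, on_manifold, l2dr, z, p_empiric, fdr, error_class),
#'   `null_genes` (the pseudo-gene table with the same rate columns), and
#'   `manifest` (parameters and seed of the run).
#' @export
analyze_screen <- function(cm, design, pseudocount = 1, guides_per_gene = 6,
                           n_boot = 10000, seed = 1, min_nontargeting = 50,
                           tau_fc = 0.25, tau_dr = 0.25, l2dr_floor = -10) {
  stopifnot(inherits(cm, "count_matrix"), inherits(design, "assay_design"))
  for (cond in c("T0", "untreated", "treated")) {
    check_that(cond %in% cm$samples$condition,
               sprintf("condition '%s' missing from the screen", cond))
  }
  cm_f <- filter_guides(cm)
  cm_n <- normalize_depth(cm_f, min_nontargeting = min_nontargeting)

  tx <- compute_l2fc(cm_n, c("treated", "untreated"), pseudocount)
  unt <- compute_l2fc(cm_n, c("untreated", "T0"), pseudocount)

  # relabel surviving non-targeting guides with pseudo-gene ids
  pseudo <- make_pseudo_genes(cm_n, guides_per_gene, seed = seed)
  relabel <- function(df) {
    m <- match(df$sgrna_id, pseudo$sgrna_id)
    df$gene[!is.na(m)] <- pseudo$pseudo_gene[stats::na.omit(m)]
    df[!df$is_nontargeting | !is.na(m), , drop = FALSE]
  }
  tx <- relabel(tx)
  unt <- relabel(unt)

  gene_tx <- collapse_genes(tx, "l2fc")
  gene_unt <- collapse_genes(unt, "l2fc")
  merged <- merge(gene_tx, gene_unt, by = "gene", suffixes = c("_tx", "_unt"))
  names(merged)[names(merged) == "l2fc_tx"] <- "l2fc_tx_unt"
  names(merged)[names(merged) == "l2fc_unt"] <- "l2fc_unt_t0"

  gr <- infer_growth_rate(merged$l2fc_unt_t0, design)
  dr <- infer_death_rate(merged$l2fc_tx_unt, gr$g_hat, design)
  merged$g_hat <- gr$g_hat
  merged$d_hat <- dr$d_hat
  merged$on_manifold <- dr$on_manifold
  merged$l2dr <- pmax(log2(pmax(merged$d_hat, 0) / design$d_wt), l2dr_floor)

  is_pseudo <- startsWith(merged$gene, "NT_PSEUDO_")
  null_l2dr <- merged$l2dr[is_pseudo]
  scored <- score_vs_null(merged$l2dr[!is_pseudo], null_l2dr,
                          n_boot = n_boot, seed = seed + 1L)
  g_scored <- score_vs_null(merged$g_hat[!is_pseudo], merged$g_hat[is_pseudo],
                            n_boot = n_boot, seed = seed + 2L)

  results <- merged[!is_pseudo, , drop = FALSE]
  results$z <- scored$z
  results$p_empiric <- scored$p_empiric
  results$fdr <- scored$fdr
  results$z_growth <- g_scored$z
  results$error_class <- classify_error_type(results$l2fc_tx_unt, results$l2dr,
                                             tau_fc, tau_dr)
  results <- results[order(results$gene), , drop = FALSE]
  rownames(results) <- NULL
  null_genes <- merged[is_pseudo, , drop = FALSE]
  rownames(null_genes) <- NULL

  manifest <- list(
    seed = seed, pseudocount = pseudocount, guides_per_gene = guides_per_gene,
    n_boot = n_boot, tau_fc = tau_fc, tau_dr = tau_dr,
    l2dr_floor = l2dr_floor, design = unclass(design),
    n_guides_in = nrow(cm$counts), n_guides_used = nrow(cm_n$counts),
    size_factors = as.list(cm_n$size_factors),
    l2fc_method = "pseudocounted log-ratio of replicate-mean counts normalized to non-targeting guides"
  )
  structure(list(results = results, null_genes = null_genes, manifest = manifest),
            class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat(sprintf("Screen death-rate analysis: %d genes, %d pseudo-genes\n",
              nrow(x$results), nrow(x$null_genes)))
  cat(sprintf("  genes at FDR < 0.1: %d\n", sum(x$results$fdr < 0.1, na.rm = TRUE)))
  cat(sprintf("  error classes vs conventional L2FC: %s\n",
              paste(sprintf("%s=%d", names(table(x$results$error_class)),
                            table(x$results$error_class)), collapse = " ")))
  invisible(x)
}

#' Write the analysis outputs as tab-delimited tables
#'
#' @param analysis a `screen_analysis` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_screen_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "screen_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene = file.path(dir, "gene_death_rates.tsv"),
    null = file.path(dir, "pseudo_gene_rates.tsv"),
    manifest = file.path(dir, "run_manifest.json")
  )
  utils::write.table(analysis$results, paths["gene"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(analysis$null_genes, paths["null"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(analysis$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
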
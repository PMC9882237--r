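# Ground-truthed synthetic inputs: pooled-screen count matrices with known
# per-gene growth/death perturbations (GeCKO-like library structure, scaled
# down), and plate-reader-style viability timecourses. Generation uses only
# the forward population model; the inverse step lives in the inference
# code, keeping recovery tests non-circular.

#' Configuration for a synthetic chemo-genetic screen
#'
#' Defaults emulate the screened library's structure at test scale: 6 guides
#' per gene, 1,000 non-targeting guides, 400x coverage, three replicates per
#' condition, and gamma-Poisson (negative binomial) count overdispersion.
#' Effect classes mirror the gene sets that matter for the analysis:
#' essential (reduced growth), repair-like (reduced growth and increased
#' death), death sensitizers (increased death only), and death suppressors
#' (decreased death only).
#'
#' @param n_genes number of targeting genes (full library scale 19,050
#'   supported; tests default to 1,000).
#' @param guides_per_gene guides per targeting gene.
#' @param n_nontargeting number of non-targeting guides.
#' @param coverage expected reads per guide per sample.
#' @param n_replicates replicates per condition.
#' @param frac_essential,frac_repair,frac_death_up,frac_death_down class
#'   fractions (must sum to <= 1; the rest are neutral).
#' @param g_log2_mean,g_log2_sd magnitude (log2 scale) of growth-rate
#'   multipliers for growth-perturbed classes.
#' @param d_log2_mean,d_log2_sd magnitude (log2 scale) of death-rate
#'   multipliers for death-perturbed classes.
#' @param guide_jitter_sd sgRNA-efficacy variation: relative sd applied to
#'   the log2 effect of each guide (a zero gene effect stays exactly zero).
#' @param dispersion gamma-Poisson overdispersion of sequencing counts
#'   (variance = mu + dispersion * mu^2).
#' @param baseline_log2_sd library-composition spread of per-guide baseline
#'   abundance (log2 scale).
#' @param seed mandatory RNG seed.
#' @return An object of class `synthetic_screen_config`.
#' @export
synthetic_screen_config <- function(n_genes = 1000, guides_per_gene = 6,
                                    n_nontargeting = 1000, coverage = 400,
                                    n_replicates = 3,
                                    frac_essential = 0.1, frac_repair = 0.05,
                                    frac_death_up = 0.05, frac_death_down = 0.05,
                                    g_log2_mean = 1, g_log2_sd = 0.25,
                                    d_log2_mean = 1, d_log2_sd = 0.25,
                                    guide_jitter_sd = 0.1, dispersion = 0.01,
                                    baseline_log2_sd = 0.25, seed = 1) {
  fracs <- c(frac_essential, frac_repair, frac_death_up, frac_death_down)
  check_that(all(fracs >= 0) && sum(fracs) <= 1,
             "class fractions must be >= 0 and sum to <= 1")
  check_that(coverage > 0, "`coverage` must be > 0")
  check_that(dispersion >= 0, "`dispersion` must be >= 0")
  check_that(is_scalar_num(seed), "`seed` is mandatory")
  structure(as.list(environment()), class = "synthetic_screen_config")
}

#' Draw the ground-truth table of per-gene growth and death multipliers
#'
#' Deterministic under the config seed. Class identities are sampled; class
#' counts are deterministic (`round(frac * n_genes)`). Gene-level log2
#' multipliers are drawn from the configured normal spreads (growth down for
#' essential and repair-like genes; death up or down for the death classes)
#' and clamped to biologically plausible ranges. Guide-level multipliers
#' jitter the gene effect multiplicatively on the log2 scale, so neutral
#' genes have exactly neutral guides.
#'
#' @param config a [synthetic_screen_config()].
#' @return An object of class `truth_table`: list with `genes` (gene, class,
#'   g_mult, d_mult) and `guides` (sgrna_id, gene, g_mult, d_mult).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  n <- config$n_genes
  counts <- c(
    essential = round(config$frac_essential * n),
    repair_like = round(config$frac_repair * n),
    death_up = round(config$frac_death_up * n),
    death_down = round(config$frac_death_down * n)
  )
  check_that(sum(counts) <= n, "class fractions leave no room for neutral genes")

  with_seed(config$seed, {
    genes <- sprintf("GENE%05d", seq_len(n))
    cls <- rep("neutral", n)
    picked <- sample(n, sum(counts))
    cls[picked] <- rep(names(counts), counts)

    g_log2 <- rep(0, n)
    d_log2 <- rep(0, n)
    grow_down <- cls %in% c("essential", "repair_like")
    death_up <- cls %in% c("repair_like", "death_up")
    death_down <- cls == "death_down"
    g_log2[grow_down] <- -pmin(pmax(
      stats::rnorm(sum(grow_down), config$g_log2_mean, config$g_log2_sd), 0.1), 3)
    d_log2[death_up] <- pmin(pmax(
      stats::rnorm(sum(death_up), config$d_log2_mean, config$d_log2_sd), 0.1), 3)
    d_log2[death_down] <- -pmin(pmax(
      stats::rnorm(sum(death_down), config$d_log2_mean, config$d_log2_sd), 0.1), 3)

    gene_tab <- data.frame(gene = genes, class = cls,
                           g_mult = 2^g_log2, d_mult = 2^d_log2,
                           stringsAsFactors = FALSE)

    k <- config$guides_per_gene
    guide_g <- rep(g_log2, each = k) *
      (1 + stats::rnorm(n * k, 0, config$guide_jitter_sd))
    guide_d <- rep(d_log2, each = k) *
      (1 + stats::rnorm(n * k, 0, config$guide_jitter_sd))
    guide_tab <- data.frame(
      sgrna_id = sprintf("%s_sg%d", rep(genes, each = k), rep(seq_len(k), n)),
      gene = rep(genes, each = k),
      g_mult = 2^guide_g, d_mult = 2^guide_d,
      stringsAsFactors = FALSE
    )
    structure(list(genes = gene_tab, guides = guide_tab, config = config),
              class = "truth_table")
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("Synthetic screen ground truth: %d genes\n", nrow(x$genes)))
  tab <- table(x$genes$class)
  cat(sprintf("  %s\n", paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Simulate sequencing counts for a synthetic screen
#'
#' Expected clone abundances at T0, at the end of the untreated arm, and at
#' the end of the treated arm are computed per guide with the biphasic
#' forward model (each guide's growth and death rates are the wild-type
#' rates scaled by its truth multipliers; non-targeting guides are exactly
#' wild type). Reads are drawn per sample as gamma-Poisson counts at depth
#' `coverage * n_guides`, with independent replicates.
#'
#' @param truth a [generate_truth()] result.
#' @param design an [assay_design()].
#' @param config optionally override the config carried by `truth`.
#' @return A list with `cm` (a [count_matrix()]), `truth`, and `manifest`.
#' @export
simulate_screen_counts <- function(truth, design, config = truth$config) {
  stopifnot(inherits(truth, "truth_table"), inherits(design, "assay_design"))
  guides <- rbind(
    truth$guides,
    data.frame(sgrna_id = sprintf("NT_sg%04d", seq_len(config$n_nontargeting)),
               gene = NONTARGETING_LABEL, g_mult = 1, d_mult = 1,
               stringsAsFactors = FALSE)
  )
  n_guides <- nrow(guides)
  g <- design$g_wt * guides$g_mult
  d <- design$d_wt * guides$d_mult

  # expected relative abundance per arm (forward model only)
  s_tx <- (1 - design$LFp_wt) +
    design$LFp_wt * 2^(-d * max(0, design$T_tx - design$t_arrest))
  ab <- with_seed(config$seed + 1L, {
    baseline <- 2^stats::rnorm(n_guides, 0, config$baseline_log2_sd)
    list(
      T0 = baseline,
      untreated = baseline * 2^(g * design$T_unt0),
      treated = baseline * 2^(g * min(design$T_tx, design$t_arrest)) * s_tx
    )
  })
  for (arm in names(ab)) {
    a <- ab[[arm]]
    share <- a / sum(a)
    underflowed <- mean(share < 1e-4 / n_guides) > 0.5
    if (!all(is.finite(a)) || sum(a) <= 0 || underflowed) {
      stop(sprintf("expected abundances in the %s arm collapsed (near-extinction); use milder effect sizes",
                   arm), call. = FALSE)
    }
  }

  depth <- config$coverage * n_guides
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = c("T0", "untreated", "treated"),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%d", samples$condition, samples$replicate)
  samples <- samples[, c("sample_id", "condition", "replicate")]

  counts <- with_seed(config$seed + 2L, {
    m <- matrix(0L, n_guides, nrow(samples),
                dimnames = list(guides$sgrna_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      p <- ab[[samples$condition[j]]]
      mu <- depth * p / sum(p)
      m[, j] <- if (config$dispersion > 0) {
        stats::rnbinom(n_guides, mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(n_guides, mu)
      }
    }
    m
  })

  cm <- count_matrix(counts, guides[, c("sgrna_id", "gene")], samples)
  manifest <- list(seed = config$seed, config = unclass(config),
                   design = unclass(design), depth = depth)
  list(cm = cm, truth = truth, manifest = manifest)
}

#' Generate plate-reader-style viability timecourses with known kinetics
#'
#' Simulates treated and untreated wells from the biphasic model, converts
#' cell numbers to fluorescence through a constant per-cell signal, and adds
#' multiplicative lognormal noise with the stated coefficient of variation.
#' Returns the kinetic dead-cell plate, the lysed-plate totals, and the
#' noise-free ground-truth lethal fraction of the treated arm.
#'
#' @param params a [biphasic_params()] object for the treated response.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_timepoints number of timepoints (>= 6).
#' @param horizon assay length, hours.
#' @param dose_um nominal treated dose recorded in the table.
#' @param n_wells replicate wells per arm.
#' @param signal_per_cell fluorescence units per cell.
#' @param n0 starting cells per well.
#' @param seed RNG seed.
#' @return A list with `plate` (well, dose_um, time_h, dead_signal),
#'   `totals` (well, total_signal_t0, total_signal_end), `lf_true`
#'   (time_h, lf), and `params`.
#' @export
generate_plate_timecourse <- function(params, noise_cv = 0.05,
                                      n_timepoints = 13, horizon = 96,
                                      dose_um = 31.6, n_wells = 3,
                                      signal_per_cell = 1, n0 = 2000,
                                      seed = 1) {
  stopifnot(inherits(params, "biphasic_params"))
  check_that(n_timepoints >= 6, "need >= 6 timepoints")
  times <- seq(0, horizon, length.out = n_timepoints)
  treated <- simulate_population(params, times, n0 = n0)
  unt_params <- biphasic_params(tau_c = params$tau_c, t_arrest = params$t_arrest,
                                d = 0, LFp = params$LFp,
                                arrest_enabled = FALSE, death_enabled = FALSE)
  untreated <- simulate_population(unt_params, times, n0 = n0)

  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(x, n) {
    if (noise_cv == 0) rep(x, length.out = n) else
      rep(x, length.out = n) * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  with_seed(seed, {
    arms <- list(treated = treated, untreated = untreated)
    doses <- c(treated = dose_um, untreated = 0)
    plate <- do.call(rbind, lapply(names(arms), function(arm) {
      do.call(rbind, lapply(seq_len(n_wells), function(w) {
        data.frame(
          well = sprintf("%s_%d", toupper(substr(arm, 1, 3)), w),
          dose_um = doses[[arm]], time_h = times,
          dead_signal = noisy(arms[[arm]]$dead * signal_per_cell, n_timepoints),
          stringsAsFactors = FALSE
        )
      }))
    }))
    totals <- do.call(rbind, lapply(names(arms), function(arm) {
      tot <- (arms[[arm]]$live + arms[[arm]]$dead) * signal_per_cell
      data.frame(
        well = sprintf("%s_%d", toupper(substr(arm, 1, 3)), seq_len(n_wells)),
        total_signal_t0 = noisy(tot[1], n_wells),
        total_signal_end = noisy(tot[n_timepoints], n_wells),
        stringsAsFactors = FALSE
      )
    }))
    lf_true <- data.frame(
      time_h = times,
      lf = treated$dead / (treated$live + treated$dead)
    )
    list(plate = plate, totals = totals, lf_true = lf_true, params = params)
  })
}

#' Benchmark inferred death rates against the synthetic ground truth
#'
#' @param truth a [generate_truth()] result.
#' @param analysis a `screen_analysis` from [analyze_screen()] run on counts
#'   simulated from the same truth.
#' @param tau minimal absolute L2DR / L2FC treated as a directional call.
#' @return An object of class `benchmark_report`: list with
#'   `spearman_death` (true vs inferred death multiplier, death-modulating
#'   genes), `sign_concordance` (per class, rate-based and conventional),
#'   `fisher` (direction-call odds ratios for each method),
#'   `error_census` (table of conventional error classes), and `merged`
#'   (the joined gene table).
#' @export
benchmark_recovery <- function(truth, analysis, tau = 0.25) {
  stopifnot(inherits(truth, "truth_table"), inherits(analysis, "screen_analysis"))
  merged <- merge(truth$genes, analysis$results, by = "gene")
  check_that(nrow(merged) > 0, "no overlapping genes between truth and results")
  dm <- merged[merged$class %in% c("repair_like", "death_up", "death_down"), ]

  spearman_death <- if (nrow(dm) >= 3) {
    stats::cor(dm$d_mult, dm$d_hat, method = "spearman")
  } else NA_real_

  true_sign <- sign(log2(dm$d_mult))
  conc <- function(called_sign) mean(called_sign == true_sign)
  by_class <- lapply(split(dm, dm$class), function(df) {
    ts <- sign(log2(df$d_mult))
    c(l2dr = mean(sign(df$l2dr) == ts),
      conventional = mean(sign(-df$l2fc_tx_unt) == ts))
  })

  fisher_for <- function(called) {
    has_call <- abs(called) > tau
    a <- sum(has_call & true_sign > 0 & called > 0)
    b <- sum(has_call & true_sign > 0 & called < 0)
    c_ <- sum(has_call & true_sign < 0 & called > 0)
    d_ <- sum(has_call & true_sign < 0 & called < 0)
    concordance_test(matrix(c(a, b, c_, d_), 2, byrow = TRUE))
  }
  fisher <- list(l2dr = fisher_for(dm$l2dr),
                 conventional = fisher_for(-dm$l2fc_tx_unt))

  structure(
    list(spearman_death = spearman_death,
         sign_concordance = by_class,
         fisher = fisher,
         error_census = table(merged$error_class),
         merged = merged),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Synthetic-screen recovery benchmark\n")
  cat(sprintf("  Spearman rho (true vs inferred death multiplier): %.3f\n",
              x$spearman_death))
  for (cl in names(x$sign_concordance)) {
    v <- x$sign_concordance[[cl]]
    cat(sprintf("  %-12s sign concordance: L2DR %.2f, conventional L2FC %.2f\n",
                cl, v["l2dr"], v["conventional"]))
  }
  cat(sprintf("  direction-call OR: L2DR %.3g, conventional %.3g\n",
              x$fisher$l2dr$odds_ratio, x$fisher$conventional$odds_ratio))
  cat("  conventional-analysis error census: ")
  cat(paste(sprintf("%s=%d", names(x$error_census), x$error_census),
            collapse = " "), "\n")
  invisible(x)
}
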
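# Ground-truth generation and synthetic-data realism checks.

test_that("truth tables are deterministic with exact class counts", {
  cfg <- synthetic_screen_config(n_genes = 1000, seed = 31)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$guides, t2$guides)
  tab <- table(t1$genes$class)
  expect_equal(unname(tab["essential"]), 100)
  expect_equal(unname(tab["repair_like"]), 50)
  expect_equal(unname(tab["death_up"]), 50)
  expect_equal(unname(tab["death_down"]), 50)

  t3 <- generate_truth(synthetic_screen_config(n_genes = 1000, seed = 32))
  expect_false(identical(t1$genes$class, t3$genes$class))
})

test_that("zero effect fractions give an all-neutral truth with unit multipliers", {
  cfg <- synthetic_screen_config(n_genes = 50, frac_essential = 0,
                                 frac_repair = 0, frac_death_up = 0,
                                 frac_death_down = 0, seed = 1)
  tr <- generate_truth(cfg)
  expect_true(all(tr$genes$class == "neutral"))
  expect_true(all(tr$genes$g_mult == 1 & tr$genes$d_mult == 1))
  # efficacy jitter preserves exactly-neutral guides
  expect_true(all(tr$guides$g_mult == 1 & tr$guides$d_mult == 1))
})

test_that("class labels are consistent with the multipliers they imply", {
  tr <- generate_truth(synthetic_screen_config(n_genes = 500, seed = 8))
  g <- tr$genes
  expect_true(all(g$g_mult[g$class == "essential"] < 1))
  expect_true(all(g$d_mult[g$class == "essential"] == 1))
  expect_true(all(g$g_mult[g$class == "repair_like"] < 1 &
                    g$d_mult[g$class == "repair_like"] > 1))
  expect_true(all(g$d_mult[g$class == "death_up"] > 1))
  expect_true(all(g$d_mult[g$class == "death_down"] < 1))
  expect_true(all(g$g_mult[g$class == "neutral"] == 1 &
                    g$d_mult[g$class == "neutral"] == 1))
})

test_that("invalid class fractions are rejected", {
  expect_error(synthetic_screen_config(frac_essential = 0.6, frac_repair = 0.5),
               "sum to <= 1")
})

test_that("simulated counts are deterministic under seed and scale with coverage", {
  des <- default_design()
  cfg <- synthetic_screen_config(n_genes = 50, n_nontargeting = 100, seed = 13)
  tr <- generate_truth(cfg)
  c1 <- simulate_screen_counts(tr, des)$cm$counts
  c2 <- simulate_screen_counts(tr, des)$cm$counts
  expect_identical(c1, c2)

  cfg2x <- synthetic_screen_config(n_genes = 50, n_nontargeting = 100,
                                   coverage = 800, seed = 13)
  c3 <- simulate_screen_counts(generate_truth(cfg2x), des, config = cfg2x)$cm$counts
  expect_equal(sum(c3) / sum(c1), 2, tolerance = 0.02)
})

test_that("count overdispersion is recoverable by method of moments", {
  des <- default_design()
  cfg <- synthetic_screen_config(n_genes = 400, n_nontargeting = 200,
                                 frac_essential = 0, frac_repair = 0,
                                 frac_death_up = 0, frac_death_down = 0,
                                 dispersion = 0.05, baseline_log2_sd = 0,
                                 n_replicates = 6, seed = 19)
  sim <- simulate_screen_counts(generate_truth(cfg), des)
  t0 <- sim$cm$counts[, sim$cm$samples$condition == "T0"]
  mu <- rowMeans(t0)
  v <- apply(t0, 1, var)
  disp_hat <- median((v - mu) / mu^2)
  expect_equal(disp_hat, 0.05, tolerance = 0.2)
})

test_that("the treated wild-type arm reaches ~50% lethal fraction by assay end", {
  des <- default_design()
  wt <- biphasic_params(tau_c = 1 / des$g_wt, t_arrest = des$t_arrest,
                        d = des$d_wt, LFp = des$LFp_wt)
  traj <- simulate_population(wt, des$T_tx)
  expect_equal(traj$dead / (traj$live + traj$dead), 0.5, tolerance = 1e-9)
})

test_that("noise-free plate timecourses refit to the generating kinetics", {
  params <- biphasic_params(tau_c = 24, t_arrest = 24, d = 1 / 72)
  tc <- generate_plate_timecourse(params, noise_cv = 0, seed = 3)
  fit <- fit_led(tc$lf_true$time_h, tc$lf_true$lf)
  expect_equal(fit$D0, 24, tolerance = 1e-3)
  expect_equal(fit$DR, log(2) / 72, tolerance = 1e-3)  # halvings/h on the e-scale
  expect_equal(fit$LF0, 0, tolerance = 1e-6)
})

test_that("a deathless response yields a flat, degenerate lethal fraction", {
  params <- biphasic_params(tau_c = 24, t_arrest = 24, d = 0)
  tc <- generate_plate_timecourse(params, noise_cv = 0, seed = 3)
  fit <- fit_led(tc$lf_true$time_h, tc$lf_true$lf)
  expect_true(fit$degenerate)
  expect_equal(fit$DR, 0)
})

test_that("fitted metrics are invariant to the per-cell signal constant", {
  params <- biphasic_params(tau_c = 24, t_arrest = 24, d = 1 / 48)
  tc1 <- generate_plate_timecourse(params, noise_cv = 0.05, signal_per_cell = 1,
                                   seed = 10)
  tc2 <- generate_plate_timecourse(params, noise_cv = 0.05, signal_per_cell = 2,
                                   seed = 10)
  expect_equal(tc2$plate$dead_signal, 2 * tc1$plate$dead_signal)
  lf_from <- function(tc) {
    w <- tc$plate$well == "TRE_1"
    tot <- infer_total_timecourse(tc$totals$total_signal_t0[1],
                                  tc$totals$total_signal_end[1],
                                  times = tc$plate$time_h[w])
    tc$plate$dead_signal[w] / tot
  }
  expect_equal(lf_from(tc1), lf_from(tc2), tolerance = 1e-12)
})

test_that("catastrophic effect sizes trip the extinction guard", {
  des <- default_design()
  cfg <- synthetic_screen_config(n_genes = 20, n_nontargeting = 50,
                                 frac_death_up = 0.5, d_log2_mean = 40,
                                 d_log2_sd = 0, seed = 2)
  tr <- generate_truth(cfg)
  # force effectively total extinction of the treated arm
  tr$guides$d_mult[] <- 2^40
  expect_error(simulate_screen_counts(tr, des), "extinction|milder|collapsed")
})
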
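test_that("max_deviation follows the baseline-difference definition", {
  expect_equal(max_deviation(c(5, 5, 5), c(0, 2, 4)), 0)
  expect_equal(max_deviation(c(5.0, 6.5, 5.2), c(0, 2, 4)), 1.5)
  expect_equal(max_deviation(c(5.0, 6.5, 5.2), c(0, 2, 4), signed = TRUE), 1.5)
  expect_equal(max_deviation(c(5.0, 4.0, 5.2), c(0, 2, 4), signed = TRUE), -1.0)
  # missing interior point is skipped
  expect_equal(max_deviation(c(5.0, 6.5, NA, 5.2), c(0, 2, 4, 8)), 1.5)
  expect_error(max_deviation(c(NA, 6.5), c(0, 2)), "Baseline")
})

test_that("the time-course gate passes features deviating in either group", {
  design <- make_design()
  tps <- sort(unique(design$time_h))
  fc <- rbind(
    c(0, 2, 2, 2, 2, 2),   # PD-only ramp from baseline
    rep(0, 6),             # null
    c(0, 0, 0, 0, 0, 0))
  cohort <- latent_cohort(n_features = 3, design = design, group_fc = fc,
                          noise_sd = 0, seed = 1)
  # give feature 3 an HC + PD shared deviation (activation-like)
  shared <- design$sample_id[design$time_h > 0]
  cohort$exprs[3, shared] <- cohort$exprs[3, shared] + 1.5
  gate <- tc_gate(cohort)
  expect_equal(gate$passes_tc_gate, c(TRUE, FALSE, TRUE))
  expect_equal(gate$median_dev_pd[1], 2)
  expect_equal(gate$median_dev_hc[1], 0)
  expect_equal(gate$median_dev_hc[3], 1.5)
})

test_that("activation-ramp features all pass the gate; pure nulls do not", {
  cfg <- sim_config(n_features = 1000, n_mirnas = 0, noise_sd = 0.1, seed = 21)
  sig <- sim_signals(cfg, n_activation = 50, n_group_spikes = 0, n_coupled = 0)
  sim <- simulate_cohort(cfg, sig)
  cohort <- preprocess_cohort(sim$mrna)
  gate <- tc_gate(cohort)
  act <- sig$feature_id[sig$signal_class == "activation_shared"]
  expect_true(all(gate$passes_tc_gate[gate$feature_id %in% act]))
  nulls <- sig$feature_id[sig$signal_class == "null"]
  expect_lte(mean(gate$passes_tc_gate[gate$feature_id %in% nulls]), 0.05)
})

test_that("forcing lambda = 0 reproduces the ordinary unequal-variance t", {
  design <- make_design(donors_per_group = 5, time_points = c(0, 2))
  cohort <- latent_cohort(n_features = 20, design = design, noise_sd = 1,
                          seed = 31)
  fit <- shrinkage_t(cohort, time_h = 2, lambda = 0)
  sub <- cohort$design[cohort$design$time_h == 2, ]
  oracle <- welch_t_oracle(
    cohort$exprs[, sub$sample_id[sub$group == "PD"]],
    cohort$exprs[, sub$sample_id[sub$group == "HC"]])
  expect_equal(fit$stats$t_shrink, unname(oracle))
})

test_that("forcing lambda = 1 pools variances: |t| ranks like |mean difference|", {
  design <- make_design(donors_per_group = 4, time_points = c(0, 4))
  cohort <- latent_cohort(n_features = 30, design = design, noise_sd = 1,
                          seed = 32)
  fit <- shrinkage_t(cohort, time_h = 4, lambda = 1)
  md <- abs(fit$stats$mean_pd - fit$stats$mean_hc)
  expect_equal(order(abs(fit$stats$t_shrink)), order(md))
  g <- glance(fit)
  expect_equal(g$lambda_pd, 1)
  expect_equal(g$lambda_hc, 1)
})

test_that("identical per-feature variances make shrinkage a no-op", {
  design <- make_design(donors_per_group = 3, time_points = c(0, 2))
  cohort <- latent_cohort(n_features = 8, design = design, noise_sd = 0, seed = 1)
  sub <- design$sample_id[design$time_h == 2]
  # same spread in every feature, different means
  cohort$exprs[, sub] <- cohort$exprs[, sub] + seq_len(8) +
    matrix(rep(c(-1, 0, 1, -1, 0, 1), each = 8), nrow = 8)
  fit <- shrinkage_t(cohort, time_h = 2)
  td <- tidy(fit)
  expect_equal(td$v_star_pd, td$v_pd)
  expect_equal(td$v_star_hc, td$v_hc)
})

test_that("estimated shrinkage intensity always lies in [0, 1]", {
  for (s in 1:10) {
    design <- make_design(donors_per_group = 5, time_points = c(0, 8))
    cohort <- latent_cohort(n_features = 40, design = design, noise_sd = runif(1, 0.1, 2),
                            seed = s)
    g <- glance(shrinkage_t(cohort, time_h = 8))
    expect_gte(g$lambda_pd, 0)
    expect_lte(g$lambda_pd, 1)
    expect_gte(g$lambda_hc, 0)
    expect_lte(g$lambda_hc, 1)
    # shrunk variances stay between v and the target
    td <- tidy(shrinkage_t(cohort, time_h = 8))
    lo <- pmin(td$v_pd, g$v_target_pd)
    hi <- pmax(td$v_pd, g$v_target_pd)
    expect_true(all(td$v_star_pd >= lo - 1e-12 & td$v_star_pd <= hi + 1e-12))
  }
})

test_that("differential table medians, signs, and BH scope are correct", {
  design <- make_design(donors_per_group = 5, time_points = c(0, 2))
  cohort <- latent_cohort(n_features = 12, design = design, noise_sd = 0, seed = 1)
  sub <- design[design$time_h == 2, ]
  # feature 1: PD values 1..5, HC values 0..4 -> medians 3 vs 2
  cohort$exprs[1, sub$sample_id[sub$group == "PD"]] <- 1:5
  cohort$exprs[1, sub$sample_id[sub$group == "HC"]] <- 0:4
  # feature 2: identical group values
  cohort$exprs[2, sub$sample_id] <- rep(c(2, 3, 4, 5, 6), 2)
  for (f in 3:12) {
    cohort$exprs[f, sub$sample_id] <- rnorm(10, 0, 1)
  }
  tab <- differential_table(cohort)
  r1 <- tab[tab$feature_id == "f001" & tab$time_h == 2, ]
  expect_equal(r1$median_log2fc, 1)
  r2 <- tab[tab$feature_id == "f002" & tab$time_h == 2, ]
  expect_equal(r2$median_log2fc, 0)
  expect_equal(r2$t_shrink, 0)
  # sign of t agrees with the sign of the mean difference
  fit <- shrinkage_t(cohort, time_h = 2)
  nz <- fit$stats[fit$stats$mean_pd != fit$stats$mean_hc, ]
  expect_true(all(sign(nz$t_shrink) == sign(nz$mean_pd - nz$mean_hc)))
  # p_adj >= p_raw and equals the step-up oracle within each time point
  expect_true(all(tab$p_adj >= tab$p_raw))
  for (tp in unique(tab$time_h)) {
    sub_p <- tab[tab$time_h == tp, ]
    expect_equal(sub_p$p_adj, bh_oracle(sub_p$p_raw))
  }
})

test_that("empty gated sets yield an empty table with a warning", {
  cohort <- latent_cohort(n_features = 5, design = make_design(), seed = 1)
  expect_warning(tab <- differential_table(cohort, features = character(0)),
                 "Empty")
  expect_equal(nrow(tab), 0)
})

test_that("core classification reproduces the window/direction patterns", {
  th <- tc_thresholds()
  tab <- dplyr::bind_rows(
    # TNFRSF8-like: significant increases at 0 and 2 h only
    diff_row("tnfrsf8_like", c(0, 2, 4, 8, 12, 24),
             fc = c(2.18, 1.16, 0.2, 0, 0, 0),
             p_adj = c(0.0090, 0.0495, 0.4, 0.9, 0.9, 0.9)),
    # VCAN-like: up at 0 h, down at 4 h -> mixed direction
    diff_row("vcan_like", c(0, 2, 4, 8, 12, 24),
             fc = c(1.20, 0.1, -0.66, 0, 0, 0),
             p_adj = c(0.0313, 0.6, 0.0486, 0.9, 0.9, 0.9)),
    # HCAR3-like: significant at 2, 4 and 24 h -> all three phases
    diff_row("hcar3_like", c(0, 2, 4, 8, 12, 24),
             fc = c(0.2, 0.97, 1.5, 0.3, 0.2, 3.08),
             p_adj = c(0.8, 0.0317, 0.02, 0.4, 0.6, 0.0491)),
    diff_row("quiet", c(0, 2, 4, 8, 12, 24),
             fc = rep(0.1, 6), p_adj = rep(0.9, 6))
  )
  core <- classify_core(tab, th)
  r <- core[core$feature_id == "tnfrsf8_like", ]
  expect_true(r$is_core)
  expect_equal(r$windows, "early")
  expect_equal(r$direction, "increased")
  expect_equal(r$recurrence, 2L)
  r <- core[core$feature_id == "vcan_like", ]
  expect_equal(r$direction, "mixed")
  expect_equal(r$core_time_points, "0,4")
  r <- core[core$feature_id == "hcar3_like", ]
  expect_equal(r$windows, "early,intermediary,late")
  expect_false(core$is_core[core$feature_id == "quiet"])
  venn <- venn_windows(core)
  expect_equal(sum(venn$n), 3)
  expect_equal(venn$n[venn$region == "early+intermediary+late"], 1L)
})

test_that("significance alone or fold change alone does not make a core gene", {
  tab <- dplyr::bind_rows(
    diff_row("sig_only", 0, fc = 0.3, p_adj = 0.01),
    diff_row("fc_only", 0, fc = 1.2, p_adj = 0.2)
  )
  core <- classify_core(tab)
  expect_false(any(core$is_core))
})

test_that("marker QC passes under equal kinetics and flags missing markers", {
  design <- make_design()
  tps <- sort(unique(design$time_h))
  ramp <- matrix(rep(2 * (1 - exp(-tps / 4)), each = 3), 3)
  cohort <- latent_cohort(n_features = 3, design = design, noise_sd = 0, seed = 1)
  for (j in seq_len(nrow(design))) {
    cohort$exprs[, j] <- 8 + ramp[, match(design$time_h[j], tps)]
  }
  qc <- marker_qc(cohort, c("f001", "f002", "f003"))
  expect_true(qc$passed)
  expect_true(all(qc$report$p_value == 1))
  qc2 <- marker_qc(cohort, c("f001", "not_there"))
  expect_true(is.na(qc2$passed))
  expect_equal(qc2$missing, "not_there")
})

test_that("flat markers fail induction QC", {
  cohort <- latent_cohort(n_features = 2, design = make_design(),
                          noise_sd = 0, seed = 1)
  qc <- marker_qc(cohort, c("f001", "f002"))
  expect_false(qc$passed)
  expect_false(any(qc$induced))
})

test_that("marker QC passes under the QC null across seeds", {
  design <- make_design()
  tps <- sort(unique(design$time_h))
  passes <- vapply(1:20, function(s) {
    cohort <- latent_cohort(n_features = 3, design = design, noise_sd = 0.3,
                            seed = 100 + s)
    ramp <- 2 * (1 - exp(-tps / 4))
    for (j in seq_len(nrow(design))) {
      cohort$exprs[, j] <- cohort$exprs[, j] + ramp[match(design$time_h[j], tps)]
    }
    marker_qc(cohort, c("f001", "f002", "f003"))$passed
  }, logical(1))
  expect_gte(mean(passes), 0.9)
})
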
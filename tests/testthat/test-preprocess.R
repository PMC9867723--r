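test_that("normexp fitting recovers known convolution parameters within 5%", {
  set.seed(101)
  x <- rnorm(1e5, 50, 5) + rexp(1e5, 1 / 200)
  fit <- fit_normexp(x)
  expect_lt(abs(fit$mu - 50) / 50, 0.05)
  expect_lt(abs(fit$sigma - 5) / 5, 0.05)
  expect_lt(abs(fit$alpha - 200) / 200, 0.05)
})

test_that("purely exponential data give alpha near the sample mean", {
  set.seed(7)
  x <- rexp(2e4, 1 / 300)
  fit <- fit_normexp(x)
  expect_lt(abs(fit$alpha - mean(x)) / mean(x), 0.05)
})

test_that("degenerate intensity vectors are rejected with guidance", {
  expect_error(fit_normexp(rep(100, 50)), "constant")
  expect_error(fit_normexp(c(1, 2, 3)), "at least 10")
})

test_that("conditional expected signal matches the quadrature oracle", {
  params <- list(mu = 100, sigma = 10, alpha = 500)
  for (x in c(50, 90, 105, 130, 200, 1000)) {
    expected <- normexp_quadrature(x, 100, 10, 500, offset = 16)
    got <- normexp_expected_signal(x, params, offset = 16)
    expect_lt(abs(got - expected) / expected, 1e-6)
  }
})

test_that("corrected intensities are positive, monotone, and ~x - mu + offset for large x", {
  params <- list(mu = 100, sigma = 10, alpha = 500)
  x <- c(-50, 0, 60, 100, 160, 300, 5000)
  y <- normexp_expected_signal(x, params, offset = 16)
  expect_true(all(y > 0))
  expect_true(all(diff(y) >= 0))
  big <- 100 + 5 * 10 + 500 # far above mu + 5 sigma
  expect_equal(normexp_expected_signal(10 * big, params, offset = 16),
               10 * big - 100 + 16, tolerance = 1e-3)
})

test_that("quantile normalization applies the rank/row-mean rule", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # ties within a column get the mean of the tied rank means
  mt <- cbind(c(1, 1, 2), c(3, 4, 5))
  expect_equal(unname(quantile_normalize(mt)),
               cbind(c(2.25, 2.25, 3.5), c(2, 2.5, 3.5)))
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  set.seed(11)
  m <- matrix(rexp(600, 1 / 50), 100, 6,
              dimnames = list(sprintf("f%03d", 1:100), paste0("s", 1:6)))
  q1 <- quantile_normalize(m)
  expect_identical(quantile_normalize(q1), q1)
  sorted <- apply(q1, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(diff(range(colMeans(q1))), 0)
  # identical columns are a fixed point
  same <- matrix(rep(c(1, 5, 9), 3), 3, 3,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  expect_equal(quantile_normalize(same), same)
  # within-column rank order preserved
  expect_equal(order(q1[, 1]), order(m[, 1]))
})

test_that("log2 transform handles identities and names offending entries", {
  m <- matrix(c(16, 1, 2, 8), 2, 2,
              dimnames = list(c("fa", "fb"), c("s1", "s2")))
  out <- log2_transform(m)
  expect_equal(out["fa", "s1"], 4)
  expect_equal(out["fb", "s1"], 0)
  bad <- m
  bad["fb", "s2"] <- -1
  expect_error(log2_transform(bad), "fb.*s2")
})

test_that("pipeline stages refuse out-of-order input", {
  sim <- simulate_cohort(sim_config(n_features = 30, n_mirnas = 0, seed = 1))
  raw <- sim$mrna
  expect_identical(raw$stage, "raw")
  expect_error(quantile_normalize(raw), "requires stage")
  expect_error(log2_transform(raw), "requires stage")
  expect_error(remove_batch_effect(raw), "requires stage")
  bg <- normexp_correct(raw)
  expect_identical(bg$stage, "bgcorr")
  expect_error(normexp_correct(bg), "requires stage")
  qn <- quantile_normalize(bg)
  lg <- log2_transform(qn)
  expect_identical(lg$stage, "log2")
  expect_identical(remove_batch_effect(lg)$stage, "batchcorr")
})

test_that("an additive batch offset is removed exactly on a balanced design", {
  design <- make_design(donors_per_group = 4, n_batches = 2)
  cohort <- latent_cohort(n_features = 40, design = design, noise_sd = 0.3,
                          seed = 9)
  delta <- seq(0.5, 2, length.out = 40)
  in_b2 <- design$sample_id[design$batch == 2]
  cohort$exprs[, in_b2] <- cohort$exprs[, in_b2] + delta
  out <- remove_batch_effect(cohort)
  b1 <- rowMeans(out$exprs[, design$sample_id[design$batch == 1]])
  b2 <- rowMeans(out$exprs[, in_b2])
  expect_lt(max(abs(b1 - b2)), 1e-10)
})

test_that("batch removal preserves a spiked group effect", {
  design <- make_design(donors_per_group = 5, n_batches = 2)
  tps <- sort(unique(design$time_h))
  fc <- matrix(2, 60, length(tps)) # 2 log2 units at every time point
  cohort <- latent_cohort(n_features = 60, design = design, group_fc = fc,
                          noise_sd = 0.2, seed = 4)
  delta <- rnorm(60, 0, 0.5)
  in_b2 <- design$sample_id[design$batch == 2]
  cohort$exprs[, in_b2] <- cohort$exprs[, in_b2] + delta
  out <- remove_batch_effect(cohort)
  sub <- design[design$time_h == 8, ]
  diff_med <- apply(out$exprs[, sub$sample_id[sub$group == "PD"]], 1, median) -
    apply(out$exprs[, sub$sample_id[sub$group == "HC"]], 1, median)
  expect_lt(abs(median(diff_med) - 2), 0.1)
})

test_that("batch removal is a no-op when data carry no batch component", {
  design <- make_design(donors_per_group = 3, n_batches = 2)
  # expression depends only on the preserved group x time cell: the OLS
  # batch coefficients are exactly zero
  tps <- sort(unique(design$time_h))
  fc <- outer(seq_len(10) / 10, seq_along(tps) / 2)
  cohort <- latent_cohort(n_features = 10, design = design, group_fc = fc,
                          noise_sd = 0, seed = 2)
  out <- remove_batch_effect(cohort)
  expect_lt(max(abs(out$exprs - cohort$exprs)), 1e-12)
})

test_that("confounded batch structure is reported with aliased terms", {
  design <- make_design(donors_per_group = 2, n_batches = 1)
  design$batch <- ifelse(design$group == "PD", 1L, 2L) # batch == group
  cohort <- latent_cohort(n_features = 5, design = design, seed = 1)
  expect_error(remove_batch_effect(cohort), "confounded")
  design1 <- make_design(donors_per_group = 2, n_batches = 1)
  cohort1 <- latent_cohort(n_features = 5, design = design1, seed = 1)
  expect_error(remove_batch_effect(cohort1), "at least 2 batch")
})
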
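# Small cohorts built in code.

make_design <- function(donors_per_group = 5, time_points = c(0, 2, 4, 8, 12, 24),
                        n_batches = 2) {
  donors <- c(paste0("PD", seq_len(donors_per_group)),
              paste0("HC", seq_len(donors_per_group)))
  groups <- rep(c("PD", "HC"), each = donors_per_group)
  out <- expand.grid(i = seq_along(donors), time_h = time_points,
                     KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%sh", donors[out$i], out$time_h),
    donor = donors[out$i],
    group = groups[out$i],
    time_h = out$time_h,
    batch = ((out$i - 1L) %% n_batches) + 1L
  )
}

# log2-stage cohort from an explicit latent model:
# latent[f, s] = baseline + group_fc[f, t]*(group == PD) + noise
latent_cohort <- function(n_features = 50, design = make_design(),
                          group_fc = NULL, noise_sd = 0, baseline = 8,
                          seed = 1, stage = "log2") {
  set.seed(seed)
  tps <- sort(unique(design$time_h))
  ids <- sprintf("f%03d", seq_len(n_features))
  if (is.null(group_fc)) group_fc <- matrix(0, n_features, length(tps))
  x <- matrix(baseline, n_features, nrow(design),
              dimnames = list(ids, design$sample_id))
  ti <- match(design$time_h, tps)
  for (j in seq_len(nrow(design))) {
    x[, j] <- baseline + (design$group[j] == "PD") * group_fc[, ti[j]]
  }
  x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x))
  tcellkinetics::tc_cohort(x, design, stage = stage)
}

# differential-table row builder for classification tests
diff_row <- function(feature_id, time_h, fc, p_adj, p_raw = p_adj / 2) {
  tibble::tibble(
    feature_id = feature_id, time_h = time_h, median_log2fc = fc,
    t_shrink = sign(fc) * 3, p_raw = p_raw, p_adj = p_adj,
    n_pd = 5L, n_hc = 5L
  )
}
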
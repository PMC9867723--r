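#' Simulation configuration for a synthetic activation cohort
#'
#' Defines the dimensions and noise structure of a synthetic two-group
#' (patients `PD` vs healthy controls `HC`) time-course cohort. The default
#' design mirrors the motivating study: 5 donors per group sampled at
#' 0, 2, 4, 8, 12 and 24 h after in vitro T-cell activation (60 samples per
#' assay), with samples hybridised in batches.
#'
#' Raw intensities are built as `background + signal`: a normal background
#' component `N(background_mean, background_sd^2)` plus a per-feature
#' exponential amplitude (mean `signal_rate`, the abundance scale across
#' features) modulated by `2^latent`, where the latent log2 expression is
#' `activation kinetics + group effect + batch offset + N(0, noise_sd^2)`.
#' The exponential-across-features amplitude reproduces the marginal
#' intensity distribution that normexp background correction assumes, while
#' within-feature noise stays at `noise_sd` log2 units.
#'
#' @param n_features number of transcript features.
#' @param n_mirnas number of miRNA features (second assay, same donors).
#' @param donors_per_group donors per group.
#' @param time_points_h strictly increasing sampling times, must include 0.
#' @param n_batches number of hybridisation batches; donors are interleaved
#'   across batches within each group so batch is never confounded with the
#'   group-by-time design.
#' @param noise_sd residual SD of the latent log2 expression.
#' @param background_mean,background_sd normal background component
#'   (intensity units).
#' @param signal_rate mean of the per-feature exponential signal amplitude.
#' @param batch_sd SD of per-feature batch offsets (log2 units).
#' @param seed integer seed; with the seed fixed the generator is
#'   bit-reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_features = 2000,
                       n_mirnas = 200,
                       donors_per_group = 5,
                       time_points_h = c(0, 2, 4, 8, 12, 24),
                       n_batches = 2,
                       noise_sd = 0.4,
                       background_mean = 50,
                       background_sd = 5,
                       signal_rate = 500,
                       batch_sd = 0.2,
                       seed = 1L) {
  if (n_features < 1 || n_mirnas < 0 || donors_per_group < 1 || n_batches < 1) {
    abort("Dimensions must be positive.")
  }
  if (is.unsorted(time_points_h, strictly = TRUE) || time_points_h[1] != 0) {
    abort("`time_points_h` must be strictly increasing and start at 0.")
  }
  if (noise_sd < 0 || background_sd < 0 || batch_sd < 0) abort("SDs must be non-negative.")
  if (signal_rate <= 0) abort("`signal_rate` must be strictly positive.")
  structure(
    list(
      n_features = as.integer(n_features), n_mirnas = as.integer(n_mirnas),
      donors_per_group = as.integer(donors_per_group),
      time_points_h = as.numeric(time_points_h),
      n_batches = as.integer(n_batches),
      noise_sd = noise_sd, background_mean = background_mean,
      background_sd = background_sd, signal_rate = signal_rate,
      batch_sd = batch_sd, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

feature_ids <- function(n, prefix) sprintf("%s_%04d", prefix, seq_len(n))

#' Ground-truth signal table for a synthetic cohort
#'
#' Builds the spike-in plan consumed by [simulate_cohort()]. Each row
#' describes one feature: its class (`activation_shared` kinetics common to
#' both groups, `group_up`/`group_down` group-differential spikes confined
#' to an activation window, `mixed_direction` alternating-sign deregulation,
#' `mirna_coupled` anti-correlated miRNA/target pairs, or `null`), the
#' effect size in log2 units, and the active time windows
#' (early = 0–2 h, intermediary = 4–8 h, late = 12–24 h).
#'
#' @param config a [sim_config()].
#' @param n_activation features with shared activation kinetics (amplitudes
#'   drawn 1–3 log2 units, identical in both groups).
#' @param n_group_spikes group-differential features (half up, half down in
#'   PD) at `spike_log2fc`.
#' @param spike_log2fc absolute spike size, log2 units.
#' @param spike_window window(s) in which spikes are active.
#' @param n_mixed features with `+spike_log2fc` in the early window and
#'   `-spike_log2fc` in the intermediary window.
#' @param n_coupled anti-correlated miRNA/target-gene pairs; miRNA direction
#'   alternates, windows cycle through five patterns so pair profiles differ.
#' @param coupled_log2fc absolute amplitude of coupled pairs.
#'
#' @return A tibble with columns `feature_id`, `assay`, `signal_class`,
#'   `effect_log2fc`, `active_window` (comma-separated), `partner_id`.
#' @export
sim_signals <- function(config,
                        n_activation = 200,
                        n_group_spikes = 100,
                        spike_log2fc = 2,
                        spike_window = "early",
                        n_mixed = 0,
                        n_coupled = 50,
                        coupled_log2fc = 3) {
  stopifnot(inherits(config, "sim_config"))
  n_special <- n_activation + n_group_spikes + n_mixed + n_coupled
  if (n_special > config$n_features) abort("More signal features than `n_features`.")
  if (n_coupled > config$n_mirnas) abort("More coupled pairs than `n_mirnas`.")
  genes <- feature_ids(config$n_features, "gene")
  mirs <- feature_ids(config$n_mirnas, "mir")

  idx <- 0L
  take <- function(n) {
    out <- genes[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  act <- take(n_activation)
  n_up <- ceiling(n_group_spikes / 2)
  up <- take(n_up)
  down <- take(n_group_spikes - n_up)
  mixed <- take(n_mixed)
  targets <- take(n_coupled)
  nulls <- genes[seq(idx + 1L, length.out = config$n_features - idx)]

  win_str <- function(w) paste(w, collapse = ",")
  coupled_wins <- list(
    "early", "intermediary", "late",
    c("early", "intermediary"), c("intermediary", "late")
  )

  rows <- list(
    tibble(
      feature_id = act, assay = "mrna", signal_class = "activation_shared",
      effect_log2fc = if (n_activation) seq(1, 3, length.out = n_activation) else numeric(),
      active_window = NA_character_, partner_id = NA_character_
    ),
    tibble(
      feature_id = up, assay = "mrna", signal_class = "group_up",
      effect_log2fc = rep(spike_log2fc, length(up)),
      active_window = win_str(spike_window), partner_id = NA_character_
    ),
    tibble(
      feature_id = down, assay = "mrna", signal_class = "group_down",
      effect_log2fc = rep(-spike_log2fc, length(down)),
      active_window = win_str(spike_window), partner_id = NA_character_
    ),
    tibble(
      feature_id = mixed, assay = "mrna", signal_class = "mixed_direction",
      effect_log2fc = rep(spike_log2fc, length(mixed)),
      active_window = "early,intermediary", partner_id = NA_character_
    )
  )
  if (n_coupled > 0) {
    mir_ids <- mirs[seq_len(n_coupled)]
    mir_sign <- rep_len(c(1, -1), n_coupled)
    wins <- vapply(seq_len(n_coupled),
                   function(i) win_str(coupled_wins[[(i - 1L) %% 5L + 1L]]),
                   character(1))
    rows <- c(rows, list(
      tibble(
        feature_id = mir_ids, assay = "mirna", signal_class = "mirna_coupled",
        effect_log2fc = mir_sign * coupled_log2fc,
        active_window = wins, partner_id = targets
      ),
      tibble(
        feature_id = targets, assay = "mrna", signal_class = "mirna_coupled",
        effect_log2fc = -mir_sign * coupled_log2fc,
        active_window = wins, partner_id = mir_ids
      )
    ))
    null_mirs <- mirs[seq(n_coupled + 1L, length.out = config$n_mirnas - n_coupled)]
  } else {
    null_mirs <- mirs
  }
  rows <- c(rows, list(
    tibble(
      feature_id = nulls, assay = "mrna", signal_class = "null",
      effect_log2fc = 0, active_window = NA_character_, partner_id = NA_character_
    ),
    tibble(
      feature_id = null_mirs, assay = "mirna", signal_class = "null",
      effect_log2fc = 0, active_window = NA_character_, partner_id = NA_character_
    )
  ))
  out <- bind_rows(rows)
  validate_signals(out, config)
  out
}

validate_signals <- function(signals, config) {
  signals <- as_tibble(signals)
  req <- c("feature_id", "assay", "signal_class", "effect_log2fc",
           "active_window", "partner_id")
  if (length(setdiff(req, names(signals)))) {
    abort("Signal table lacks required columns.")
  }
  if (anyDuplicated(signals[c("feature_id", "assay")])) {
    abort("Duplicate feature ids in signal table.")
  }
  universe <- c(feature_ids(config$n_features, "gene"),
                feature_ids(config$n_mirnas, "mir"))
  unknown <- setdiff(signals$feature_id, universe)
  if (length(unknown)) {
    abort(paste0("Signal features outside configured dimensions: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  cp <- signals$signal_class == "mirna_coupled"
  if (any(is.na(signals$partner_id[cp])) || any(!is.na(signals$partner_id[!cp]))) {
    abort("`partner_id` must be set iff signal_class is 'mirna_coupled'.")
  }
  bad_partner <- setdiff(signals$partner_id[cp], signals$feature_id)
  if (length(bad_partner)) abort("Unknown partner ids in signal table.")
  if (any(signals$effect_log2fc == 0 & signals$signal_class != "null") ||
      any(signals$effect_log2fc != 0 & signals$signal_class == "null")) {
    abort("effect_log2fc must be 0 exactly for class 'null'.")
  }
  invisible(signals)
}

# saturating activation ramp: 0 at t = 0, ~plateau by 8-12 h (tau = 4 h)
activation_ramp <- function(time_h, tau = 4) 1 - exp(-time_h / tau)

window_mask <- function(active_window, time_h) {
  if (is.na(active_window)) return(rep(0, length(time_h)))
  wins <- tc_windows()
  hrs <- unlist(wins[strsplit(active_window, ",")[[1]]], use.names = FALSE)
  as.numeric(time_h %in% hrs)
}

# latent per-timepoint group difference (PD - HC) of one signal row
latent_group_effect <- function(row, time_h) {
  switch(row$signal_class,
    group_up = ,
    group_down = ,
    mirna_coupled = row$effect_log2fc * window_mask(row$active_window, time_h),
    mixed_direction = {
      wins <- strsplit(row$active_window, ",")[[1]]
      abs(row$effect_log2fc) *
        (window_mask(wins[1], time_h) - window_mask(wins[2], time_h))
    },
    rep(0, length(time_h))
  )
}

#' Generate a synthetic activation cohort with ground truth
#'
#' Draws raw intensity matrices for the transcriptome and miRNA assays of a
#' seeded synthetic cohort, together with the sample design and the verbatim
#' spike-in truth table for recovery tests. See [sim_config()] for the
#' intensity model.
#'
#' @param config a [sim_config()].
#' @param signals a signal table from [sim_signals()], or `NULL` for an
#'   all-null cohort (no activation, no group differences).
#'
#' @return A list of class `tc_simulation` with elements `mrna` and `mirna`
#'   (raw-stage [tc_cohort()]s), `design` (shared sample metadata) and
#'   `truth` (the signal table).
#' @export
simulate_cohort <- function(config, signals = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(signals)) {
    signals <- sim_signals(config, n_activation = 0, n_group_spikes = 0,
                           n_mixed = 0, n_coupled = 0)
  } else {
    signals <- validate_signals(signals, config)
  }
  set.seed(config$seed)

  tp <- config$time_points_h
  npg <- config$donors_per_group
  donors <- c(paste0("PD", seq_len(npg)), paste0("HC", seq_len(npg)))
  groups <- rep(c("PD", "HC"), each = npg)
  design <- tidyr::expand_grid(
    donor_i = seq_along(donors), time_h = tp
  ) |>
    mutate(
      donor = donors[.data$donor_i],
      group = groups[.data$donor_i],
      # interleave donors across batches within each group
      batch = ((.data$donor_i - 1L) %% config$n_batches) + 1L,
      sample_id = sprintf("%s_%sh", .data$donor, .data$time_h)
    ) |>
    select("sample_id", "donor", "group", "time_h", "batch")

  build_assay <- function(n, prefix, assay) {
    ids <- feature_ids(n, prefix)
    sig <- signals[signals$assay == assay, ]
    sig <- sig[match(ids, sig$feature_id), ]

    ramp <- activation_ramp(tp)
    act_amp <- ifelse(!is.na(sig$signal_class) &
                        sig$signal_class == "activation_shared",
                      sig$effect_log2fc, 0)
    # features x timepoints latent components
    act_mat <- outer(act_amp, ramp)
    grp_mat <- matrix(0, n, length(tp))
    has_grp <- which(!is.na(sig$signal_class) &
                       sig$signal_class %in%
                         c("group_up", "group_down", "mixed_direction", "mirna_coupled"))
    for (i in has_grp) {
      grp_mat[i, ] <- latent_group_effect(sig[i, ], tp)
    }

    amplitude <- rexp(n, rate = 1 / config$signal_rate)
    batch_off <- matrix(rnorm(n * config$n_batches, 0, config$batch_sd),
                        n, config$n_batches)

    ns <- nrow(design)
    latent <- matrix(0, n, ns, dimnames = list(ids, design$sample_id))
    t_idx <- match(design$time_h, tp)
    for (j in seq_len(ns)) {
      latent[, j] <- act_mat[, t_idx[j]] +
        (design$group[j] == "PD") * grp_mat[, t_idx[j]] +
        batch_off[, design$batch[j]]
    }
    latent <- latent + matrix(rnorm(n * ns, 0, config$noise_sd), n, ns)
    raw <- matrix(rnorm(n * ns, config$background_mean, config$background_sd),
                  n, ns) + amplitude * 2^latent
    raw <- pmax(raw, 1e-6)
    dimnames(raw) <- list(ids, design$sample_id)
    tc_cohort(raw, design, stage = "raw", assay = assay)
  }

  mrna <- build_assay(config$n_features, "gene", "mrna")
  mirna <- if (config$n_mirnas > 0) build_assay(config$n_mirnas, "mir", "mirna") else NULL

  structure(
    list(mrna = mrna, mirna = mirna, design = design, truth = signals,
         config = config),
    class = "tc_simulation"
  )
}

#' @export
print.tc_simulation <- function(x, ...) {
  cat("<tc_simulation>\n")
  print(x$mrna)
  if (!is.null(x$mirna)) print(x$mirna)
  tab <- table(x$truth$signal_class)
  cat("  truth:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Latent per-timepoint group-difference profile of a truth row
#'
#' Returns the noise-free PD-minus-HC log2 difference at each time point for
#' one feature of the truth table, as used by the generator. Useful for
#' checking spike construction and for latent-correlation properties of
#' coupled miRNA/target pairs.
#'
#' @param truth the truth tibble from [simulate_cohort()].
#' @param feature_id feature identifier.
#' @param time_points_h time grid.
#' @return Numeric vector of log2 differences, one per time point.
#' @export
latent_fc_profile <- function(truth, feature_id, time_points_h = c(0, 2, 4, 8, 12, 24)) {
  row <- truth[truth$feature_id == feature_id, ]
  if (nrow(row) != 1) abort(paste0("Feature not found in truth: ", feature_id))
  latent_group_effect(as.list(row), time_points_h)
}
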
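empty_core <- function() {
  tibble(feature_id = character(), is_core = logical(),
         core_time_points = character(), windows = character(),
         direction = character(), recurrence = integer())
}

# deterministic decoy gene-set collection built around the spiked truth
synthetic_collection <- function(sim, n_decoys = 20, set_size = 50) {
  genes <- rownames(sim$mrna$exprs)
  truth <- sim$truth
  up <- truth$feature_id[truth$assay == "mrna" & truth$signal_class == "group_up"]
  down <- truth$feature_id[truth$assay == "mrna" & truth$signal_class == "group_down"]
  set.seed(sim$config$seed + 104729L) # independent of the generator stream
  decoys <- lapply(seq_len(n_decoys), function(i) sample(genes, set_size))
  names(decoys) <- sprintf("decoy_%03d", seq_len(n_decoys))
  sets <- decoys
  if (length(up)) sets$spiked_up <- up
  if (length(down)) sets$spiked_down <- down
  sets
}

#' Run the full time-course analysis pipeline on a synthetic cohort
#'
#' Orchestrates, in order: cohort simulation, the study's missing-sample
#' drop, preprocessing (batch correction for the transcriptome assay only,
#' mirroring the motivating study), activation-marker QC, the two-step
#' differential procedure (time-course gate, per-timepoint shrinkage-t
#' table, core classification), MDS ordination, inverse-correlation
#' miRNA-target matching, and over-representation analysis of the
#' direction-split core genes against a seeded synthetic gene-set
#' collection. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param signals a signal table ([sim_signals()]), or `NULL` for the
#'   default spike plan of `sim_signals(config)`.
#' @param thresholds a [tc_thresholds()].
#' @param offset normexp offset.
#' @param drop `list(donor =, time_h =)` sample to remove from the
#'   transcriptome assay (default: donor `PD5` at 4 h, as in the study
#'   design), or `NULL` to keep all samples.
#' @param collection gene-set collection for ORA, or `NULL` for a seeded
#'   synthetic collection of decoy sets plus the spiked sets.
#' @return A list of class `tc_run` with `report` (plain named list of
#'   counts and settings, ready for [write_report()]) and the intermediate
#'   objects (`sim`, processed cohorts, differential tables, `core`,
#'   `mds`, `matches`, `ora`).
#' @export
run_pipeline <- function(config = sim_config(),
                         signals = NULL,
                         thresholds = tc_thresholds(),
                         offset = 16,
                         drop = list(donor = "PD5", time_h = 4),
                         collection = NULL) {
  signals <- signals %||% sim_signals(config)
  sim <- simulate_cohort(config, signals)

  mrna_raw <- sim$mrna
  if (!is.null(drop)) mrna_raw <- drop_sample(mrna_raw, drop$donor, drop$time_h)
  mrna <- preprocess_cohort(mrna_raw, offset = offset, batch_correct = TRUE)
  mirna <- if (!is.null(sim$mirna)) {
    preprocess_cohort(sim$mirna, offset = offset, batch_correct = FALSE)
  }

  truth <- sim$truth
  markers <- truth |>
    filter(.data$assay == "mrna", .data$signal_class == "activation_shared") |>
    arrange(dplyr::desc(abs(.data$effect_log2fc)))
  qc <- if (nrow(markers)) marker_qc(mrna, head(markers$feature_id, 3))

  gate <- tc_gate(mrna, thresholds)
  gated <- gate$feature_id[gate$passes_tc_gate]
  diff_gated <- suppressWarnings(differential_table(mrna, features = gated))
  core <- if (nrow(diff_gated)) classify_core(diff_gated, thresholds) else empty_core()
  venn <- venn_windows(core)

  dmat <- sample_distances(mrna, mode = "combined")
  mds <- classical_mds(dmat, k = 2)

  mirna_results <- NULL
  if (!is.null(mirna)) {
    mgate <- tc_gate(mirna, thresholds)
    mgated <- mgate$feature_id[mgate$passes_tc_gate]
    mdiff <- suppressWarnings(differential_table(mirna, features = mgated))
    mcore <- if (nrow(mdiff)) classify_core(mdiff, thresholds) else empty_core()
    dirs <- mcore |>
      filter(.data$is_core, .data$direction %in% c("increased", "decreased"))
    matches <- NULL
    if (nrow(dirs)) {
      gene_fc <- fc_profiles(differential_table(mrna, lambda = 1))
      mir_fc <- fc_profiles(mdiff, features = dirs$feature_id)
      matches <- match_targets(mir_fc, gene_fc, dirs)
    }
    mirna_results <- list(gate = mgate, diff = mdiff, core = mcore,
                          matches = matches)
  }

  split <- direction_split(core)
  collection <- collection %||% synthetic_collection(sim)
  reference <- rownames(mrna$exprs)
  ora_up <- if (length(split$increased)) {
    suppressWarnings(ora(split$increased, collection, reference))
  }
  ora_down <- if (length(split$decreased)) {
    suppressWarnings(ora(split$decreased, collection, reference))
  }

  n_match <- if (!is.null(mirna_results$matches)) {
    m <- mirna_results$matches
    as.list(table(m$mirna_id[m$match]))
  } else list()

  report <- list(
    settings = list(
      seed = config$seed, offset = offset,
      gate_log2 = thresholds$gate_log2, grp_log2fc = thresholds$grp_log2fc,
      alpha = thresholds$alpha, min_recurrence = thresholds$min_recurrence,
      config_hash = rlang::hash(config),
      dropped_sample = if (is.null(drop)) NULL else
        paste0(drop$donor, "@", drop$time_h, "h")
    ),
    n_features = nrow(mrna$exprs),
    n_samples = ncol(mrna$exprs),
    marker_qc_passed = if (is.null(qc)) NA else qc$passed,
    n_gated = length(gated),
    n_significant = sum(vapply(
      split(diff_gated$p_adj <= thresholds$alpha, diff_gated$feature_id),
      any, logical(1))),
    n_group_fc = sum(vapply(
      split(abs(diff_gated$median_log2fc) >= thresholds$grp_log2fc,
            diff_gated$feature_id),
      any, logical(1))),
    n_core = sum(core$is_core),
    venn = as.list(setNames(venn$n, venn$region)),
    direction_counts = list(
      increased = length(split$increased),
      decreased = length(split$decreased),
      excluded = length(split$excluded)
    ),
    recurrent = list(
      increased = sum(core$is_core & core$direction == "increased" &
                        core$recurrence >= thresholds$min_recurrence),
      decreased = sum(core$is_core & core$direction == "decreased" &
                        core$recurrence >= thresholds$min_recurrence),
      mixed = sum(core$is_core & core$direction == "mixed" &
                    core$recurrence >= thresholds$min_recurrence)
    ),
    mds = list(gof = mds$gof, axis_separable = axis_separable(mds)),
    mirna = if (!is.null(mirna_results)) list(
      n_gated = sum(mirna_results$gate$passes_tc_gate),
      n_core = sum(mirna_results$core$is_core),
      matches_per_mirna = n_match
    ),
    ora = list(
      n_enriched_increased = if (is.null(ora_up)) 0L else
        sum(ora_up$p_adj <= thresholds$alpha),
      n_enriched_decreased = if (is.null(ora_down)) 0L else
        sum(ora_down$p_adj <= thresholds$alpha)
    )
  )

  structure(
    list(report = report, sim = sim, mrna = mrna, mirna = mirna,
         marker_qc = qc, gate = gate, differential = diff_gated, core = core,
         venn = venn, mds = mds, mirna_results = mirna_results,
         ora = list(increased = ora_up, decreased = ora_down)),
    class = "tc_run"
  )
}

#' @export
print.tc_run <- function(x, ...) {
  r <- x$report
  cat("<tc_run>\n")
  cat(sprintf("  features: %d, samples: %d (seed %d)\n",
              r$n_features, r$n_samples, r$settings$seed))
  cat(sprintf("  gated: %d, significant: %d, core: %d (up %d / down %d / mixed %d)\n",
              r$n_gated, r$n_significant, r$n_core,
              r$direction_counts$increased, r$direction_counts$decreased,
              r$direction_counts$excluded))
  if (!is.null(r$mirna)) {
    cat(sprintf("  miRNAs: %d core, matches for %d miRNA(s)\n",
                r$mirna$n_core, length(r$mirna$matches_per_mirna)))
  }
  invisible(x)
}

#' Write a pipeline run report as JSON
#'
#' Serialises the `report` element of a [run_pipeline()] result. Output is
#' byte-identical across repeated runs with the same seed.
#'
#' @param run a `tc_run` object (or a bare report list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path) {
  report <- if (inherits(run, "tc_run")) run$report else run
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
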
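#' Analysis thresholds for the two-step differential procedure
#'
#' @param gate_log2 time-course gate on the absolute group-median log2
#'   deviation from baseline (default 0.5; set `log2(1.5)` for a 1.5-fold
#'   gate).
#' @param grp_log2fc group-comparison gate on |median log2 fold change|
#'   (default 0.5).
#' @param alpha significance gate on BH-adjusted p-values (default 0.05).
#' @param min_recurrence minimal number of core time points for a gene to
#'   count as recurrently deregulated (default 2).
#' @return A list of class `tc_thresholds`.
#' @export
tc_thresholds <- function(gate_log2 = 0.5, grp_log2fc = 0.5, alpha = 0.05,
                          min_recurrence = 2L) {
  if (gate_log2 <= 0 || grp_log2fc <= 0 || min_recurrence < 1) {
    abort("Thresholds must be strictly positive.")
  }
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  structure(
    list(gate_log2 = gate_log2, grp_log2fc = grp_log2fc, alpha = alpha,
         min_recurrence = as.integer(min_recurrence)),
    class = "tc_thresholds"
  )
}

#' Maximum log2 deviation from the baseline time point
#'
#' For a single sample trajectory, computes the deviations
#' `value(t) - value(0)` for every available `t > 0` and returns the largest
#' in absolute value. With `signed = TRUE` the deviation keeps its sign
#' (taken at the time point of maximum magnitude, first such time point on
#' ties); missing interior time points are skipped.
#'
#' @param values log2 expression values along the trajectory.
#' @param time_h matching time points (hours).
#' @param baseline_time baseline (default 0); must be present.
#' @param signed return the signed deviation at the maximising time point?
#' @return A single numeric deviation (non-negative unless `signed`).
#' @export
max_deviation <- function(values, time_h, baseline_time = 0, signed = FALSE) {
  if (length(values) != length(time_h)) abort("`values` and `time_h` lengths differ.")
  b <- which(time_h == baseline_time & !is.na(values))
  if (!length(b)) abort("Baseline time point is missing; it is required.")
  keep <- time_h != baseline_time & !is.na(values)
  if (!any(keep)) abort("Need at least one non-baseline time point.")
  dev <- values[keep] - values[b[1]]
  i <- which.max(abs(dev))
  if (signed) dev[i] else abs(dev[i])
}

# signed max deviation per feature for one donor's trajectory matrix
# (features x timepoints, baseline first column)
.signed_maxdev <- function(x, baseline_col) {
  d <- x[, -baseline_col, drop = FALSE] - x[, baseline_col]
  i <- max.col(abs(d), ties.method = "first")
  d[cbind(seq_len(nrow(d)), i)]
}

#' Step 1: time-course deviation gate
#'
#' For every feature, the per-sample (per-donor trajectory) maximum log2
#' deviation from the baseline time point is computed, keeping its sign at
#' the maximising time point; the signed scores are aggregated per group by
#' the median; a feature passes the gate when the absolute group median
#' reaches `gate_log2` in at least one of the two groups.
#'
#' @param cohort a preprocessed (`log2` or `batchcorr` stage) [tc_cohort()].
#' @param thresholds a [tc_thresholds()].
#' @param baseline_time baseline hour (default 0).
#' @return A tibble with one row per feature: `feature_id`,
#'   `median_dev_pd`, `median_dev_hc` (signed log2 medians) and
#'   `passes_tc_gate`.
#' @export
tc_gate <- function(cohort, thresholds = tc_thresholds(), baseline_time = 0) {
  check_stage(cohort, c("log2", "batchcorr"), "tc_gate")
  design <- cohort$design
  if (!all(c("PD", "HC") %in% design$group)) abort("Both groups must be present.")
  donors <- unique(design$donor)
  scores <- matrix(NA_real_, nrow(cohort$exprs), length(donors),
                   dimnames = list(rownames(cohort$exprs), donors))
  for (d in donors) {
    sub <- design[design$donor == d, ]
    sub <- sub[order(sub$time_h), ]
    if (!baseline_time %in% sub$time_h) {
      abort(sprintf("Donor '%s' lacks the %s h baseline sample.", d, baseline_time))
    }
    x <- cohort$exprs[, sub$sample_id, drop = FALSE]
    scores[, d] <- .signed_maxdev(x, which(sub$time_h == baseline_time))
  }
  pd <- donors[donors %in% design$donor[design$group == "PD"]]
  hc <- donors[donors %in% design$donor[design$group == "HC"]]
  med_pd <- apply(scores[, pd, drop = FALSE], 1, median)
  med_hc <- apply(scores[, hc, drop = FALSE], 1, median)
  tibble(
    feature_id = rownames(cohort$exprs),
    median_dev_pd = unname(med_pd),
    median_dev_hc = unname(med_hc),
    passes_tc_gate = unname(pmax(abs(med_pd), abs(med_hc)) >= thresholds$gate_log2)
  )
}

# James-Stein shrinkage of per-feature variances toward their median
# (distribution-free shrinkage-t variance estimator)
shrink_variances <- function(x) {
  n <- ncol(x)
  if (n < 2) abort("Variance shrinkage needs at least 2 samples.")
  ctr <- x - rowMeans(x)
  w <- ctr^2
  v <- rowSums(w) / (n - 1)
  wbar <- rowMeans(w)
  var_v <- n / (n - 1)^3 * rowSums((w - wbar)^2)
  v_target <- median(v)
  denom <- sum((v - v_target)^2)
  lambda <- if (denom == 0) 1 else min(1, sum(var_v) / denom)
  list(v = v, v_star = lambda * v_target + (1 - lambda) * v,
       lambda = lambda, v_target = v_target)
}

#' Step 2: shrinkage t-test between groups at one time point
#'
#' Per-feature empirical variances within each group are shrunk toward the
#' median variance across features with a James-Stein-derived intensity
#' `lambda* = min(1, sum(Var_hat(v_g)) / sum((v_g - v_median)^2))`, and the
#' statistic is
#' `t = (mean_PD - mean_HC) / sqrt(v*_PD/n_PD + v*_HC/n_HC)`.
#' Two-sided p-values use the Student-t reference with
#' `n_PD + n_HC - 2` degrees of freedom (a deterministic, conservative
#' convention; the shrinkage estimator itself has no exact null), or a
#' normal approximation.
#'
#' @param cohort a preprocessed [tc_cohort()].
#' @param time_h the time point to test.
#' @param features feature ids to test (default all).
#' @param lambda force the shrinkage intensity for both groups (`0` gives
#'   the ordinary unequal-variance t, `1` fully pooled variances); `NULL`
#'   (default) estimates it from the data.
#' @param p_method `"t"` (default) or `"normal"`.
#' @return An object of class `shrinkage_fit`; see [tidy.shrinkage_fit()]
#'   and [glance.shrinkage_fit()].
#' @export
shrinkage_t <- function(cohort, time_h, features = NULL, lambda = NULL,
                        p_method = c("t", "normal")) {
  check_stage(cohort, c("log2", "batchcorr"), "shrinkage_t")
  p_method <- match.arg(p_method)
  design <- cohort$design[cohort$design$time_h == time_h, ]
  if (nrow(design) == 0) abort(sprintf("No samples at %s h.", format(time_h)))
  ids <- features %||% rownames(cohort$exprs)
  missing_ids <- setdiff(ids, rownames(cohort$exprs))
  if (length(missing_ids)) {
    abort(paste0("Unknown feature(s): ", paste(head(missing_ids, 3), collapse = ", ")))
  }
  xs <- lapply(c(PD = "PD", HC = "HC"), function(g) {
    cols <- design$sample_id[design$group == g]
    if (length(cols) < 2) {
      abort(sprintf("Group %s has fewer than 2 samples at %s h.", g, format(time_h)))
    }
    cohort$exprs[ids, cols, drop = FALSE]
  })
  shr <- lapply(xs, function(x) {
    s <- shrink_variances(x)
    if (!is.null(lambda)) {
      s$lambda <- lambda
      s$v_star <- lambda * s$v_target + (1 - lambda) * s$v
    }
    s
  })
  n <- vapply(xs, ncol, integer(1))
  m <- lapply(xs, rowMeans)
  se <- sqrt(shr$PD$v_star / n["PD"] + shr$HC$v_star / n["HC"])
  tstat <- ifelse(se == 0 & m$PD == m$HC, 0, (m$PD - m$HC) / se)
  df <- sum(n) - 2
  p <- if (p_method == "t") 2 * pt(-abs(tstat), df) else 2 * stats::pnorm(-abs(tstat))
  structure(
    list(
      stats = tibble(
        feature_id = ids, mean_pd = m$PD, mean_hc = m$HC,
        t_shrink = unname(tstat), p_raw = unname(p),
        n_pd = unname(n["PD"]), n_hc = unname(n["HC"])
      ),
      shrink = shr, df = df, time_h = time_h, p_method = p_method
    ),
    class = "shrinkage_fit"
  )
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf(
    "<shrinkage_fit> %d features at %s h; lambda* PD=%.3f HC=%.3f (df=%d)\n",
    nrow(x$stats), format(x$time_h), x$shrink$PD$lambda, x$shrink$HC$lambda, x$df
  ))
  invisible(x)
}

#' Per-timepoint differential table (median log2 FC + shrinkage t + BH)
#'
#' For each analysed time point and each (gated) feature, computes the
#' group-median log2 fold change `median(PD) - median(HC)`, the shrinkage-t
#' statistic with its two-sided p-value, and Benjamini-Hochberg adjusted
#' p-values; the BH adjustment runs across features separately within each
#' time point.
#'
#' @param cohort a preprocessed [tc_cohort()].
#' @param features feature ids to test, typically the gate survivors from
#'   [tc_gate()]; default all features. An empty set returns an empty table
#'   with a warning.
#' @param lambda,p_method passed to [shrinkage_t()].
#' @return A tibble keyed by (`feature_id`, `time_h`) with columns
#'   `median_log2fc`, `t_shrink`, `p_raw`, `p_adj`, `n_pd`, `n_hc`.
#' @export
differential_table <- function(cohort, features = NULL, lambda = NULL,
                               p_method = "t") {
  check_stage(cohort, c("log2", "batchcorr"), "differential_table")
  ids <- features %||% rownames(cohort$exprs)
  if (length(ids) == 0) {
    warn("Empty feature set; returning an empty differential table.")
    return(tibble(
      feature_id = character(), time_h = numeric(), median_log2fc = numeric(),
      t_shrink = numeric(), p_raw = numeric(), p_adj = numeric(),
      n_pd = integer(), n_hc = integer()
    ))
  }
  design <- cohort$design
  out <- lapply(sort(unique(design$time_h)), function(tp) {
    fit <- shrinkage_t(cohort, tp, features = ids, lambda = lambda,
                       p_method = p_method)
    sub <- design[design$time_h == tp, ]
    med <- function(g) {
      cols <- sub$sample_id[sub$group == g]
      apply(cohort$exprs[ids, cols, drop = FALSE], 1, median)
    }
    fit$stats |>
      mutate(
        time_h = tp,
        median_log2fc = unname(med("PD") - med("HC")),
        p_adj = p.adjust(.data$p_raw, method = "BH")
      ) |>
      select("feature_id", "time_h", "median_log2fc", "t_shrink",
             "p_raw", "p_adj", "n_pd", "n_hc")
  })
  bind_rows(out)
}

#' Classify core deregulated features and their activation windows
#'
#' A feature is a core deregulated gene when, at one or more time points, it
#' shows both `p_adj <= alpha` and `|median_log2fc| >= grp_log2fc`. Core
#' time points are mapped to the activation windows early (0-2 h),
#' intermediary (4-8 h) and late (12-24 h); the direction is `increased`
#' or `decreased` when all core fold changes share a sign and `mixed`
#' otherwise; recurrence counts the core time points.
#'
#' @param table a differential table from [differential_table()].
#' @param thresholds a [tc_thresholds()].
#' @return A tibble with one row per feature: `is_core`,
#'   `core_time_points` (comma-separated hours), `windows`
#'   (comma-separated), `direction`, `recurrence`.
#' @export
classify_core <- function(table, thresholds = tc_thresholds()) {
  table |>
    group_by(.data$feature_id) |>
    summarise(.groups = "drop", {
      core <- .data$p_adj <= thresholds$alpha &
        abs(.data$median_log2fc) >= thresholds$grp_log2fc
      tp <- sort(.data$time_h[core])
      fc <- .data$median_log2fc[core]
      wins <- intersect(names(tc_windows()), unique(window_of(tp)))
      tibble(
        is_core = any(core),
        core_time_points = if (any(core)) paste(tp, collapse = ",") else NA_character_,
        windows = if (any(core)) paste(wins, collapse = ",") else NA_character_,
        direction = if (!any(core)) NA_character_
          else if (all(fc > 0)) "increased"
          else if (all(fc < 0)) "decreased"
          else "mixed",
        recurrence = sum(core)
      )
    }) |>
    arrange(.data$feature_id)
}

#' Venn partition of core genes across activation windows
#'
#' Counts core features by their exclusive/shared window membership
#' (e.g. features found only in the early window, shared between early and
#' intermediary, present in all three phases).
#'
#' @param core output of [classify_core()].
#' @return A tibble with `region` (window combination joined by `+`) and
#'   `n`; regions with zero features are included. The column sum equals
#'   the number of core features.
#' @export
venn_windows <- function(core) {
  combos <- list(
    "early", "intermediary", "late",
    c("early", "intermediary"), c("intermediary", "late"),
    c("early", "late"), c("early", "intermediary", "late")
  )
  labels <- vapply(combos, paste, character(1), collapse = "+")
  wins <- strsplit(core$windows[core$is_core], ",")
  member <- vapply(labels, function(l) 0L, integer(1))
  for (w in wins) {
    l <- paste(intersect(names(tc_windows()), w), collapse = "+")
    member[l] <- member[l] + 1L
  }
  tibble(region = labels, n = unname(member[labels]))
}

#' Activation-marker quality control
#'
#' Verifies effective induction of T-cell activation using marker
#' transcripts (e.g. CD69, IFIT3, NME1 in the motivating study): per marker
#' and time point it reports group medians, expression ranges and a
#' two-sided unpaired t-test p-value. QC passes when every requested marker
#' is present, rises from its baseline median in both groups, and shows no
#' significant group difference at any time point; significance is judged
#' on BH-adjusted p-values across the marker-by-timepoint report, so the
#' check keeps its false-alarm rate at `alpha` regardless of how many
#' markers and time points are screened.
#'
#' @param cohort a preprocessed [tc_cohort()].
#' @param marker_ids feature ids of the activation markers.
#' @param alpha significance level for the per-timepoint comparisons.
#' @param var_equal classic unpaired t (`TRUE`, default) or Welch.
#' @return A list of class `marker_qc` with the per-marker/timepoint
#'   `report` tibble, the `missing` markers, per-marker `induced` flags and
#'   the overall `passed` flag (`NA` when markers are missing).
#' @export
marker_qc <- function(cohort, marker_ids, alpha = 0.05, var_equal = TRUE) {
  check_stage(cohort, c("log2", "batchcorr"), "marker_qc")
  missing_ids <- setdiff(marker_ids, rownames(cohort$exprs))
  present <- setdiff(marker_ids, missing_ids)
  design <- cohort$design
  tps <- sort(unique(design$time_h))
  report <- tidyr::expand_grid(marker = present, time_h = tps) |>
    purrr::pmap(function(marker, time_h) {
      sub <- design[design$time_h == time_h, ]
      x <- cohort$exprs[marker, sub$sample_id]
      pd <- x[sub$group == "PD"]
      hc <- x[sub$group == "HC"]
      p <- if (sd(pd) == 0 && sd(hc) == 0 && median(pd) == median(hc)) 1
        else t.test(pd, hc, var.equal = var_equal)$p.value
      tibble(
        marker = marker, time_h = time_h,
        median_pd = median(pd), median_hc = median(hc),
        min_pd = min(pd), max_pd = max(pd),
        min_hc = min(hc), max_hc = max(hc),
        p_value = p
      )
    }) |>
    bind_rows() |>
    mutate(p_adj = p.adjust(.data$p_value, method = "BH"))
  induced <- vapply(present, function(m) {
    r <- report[report$marker == m, ]
    base <- r[r$time_h == min(tps), ]
    later <- r[r$time_h > min(tps), ]
    max(later$median_pd) > base$median_pd && max(later$median_hc) > base$median_hc
  }, logical(1))
  passed <- if (length(missing_ids)) NA else
    all(induced) && all(report$p_adj > alpha)
  structure(
    list(report = report, missing = missing_ids,
         induced = induced, alpha = alpha, passed = passed),
    class = "marker_qc"
  )
}

#' @export
print.marker_qc <- function(x, ...) {
  status <- if (is.na(x$passed)) "INCOMPLETE (missing markers)"
    else if (x$passed) "PASS" else "FAIL"
  cat(sprintf("<marker_qc> %s; markers: %s\n", status,
              paste(unique(x$report$marker), collapse = ", ")))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
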
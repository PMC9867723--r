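#' Expression cohort container
#'
#' A `tc_cohort` bundles a features-by-samples expression matrix with its
#' sample metadata (donor, group, time point, batch) and a processing-stage
#' tag. Stages advance strictly in the order
#' `raw -> bgcorr -> qnorm -> log2 -> batchcorr`; each preprocessing step
#' checks the stage of its input and refuses out-of-order application.
#'
#' @param exprs numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param design a data frame with columns `sample_id`, `donor`, `group`
#'   (`"PD"` or `"HC"`), `time_h`, `batch`; one row per matrix column.
#' @param stage processing stage of `exprs`.
#' @param assay assay label, e.g. `"mrna"` or `"mirna"`.
#'
#' @return An object of class `tc_cohort`.
#' @export
tc_cohort <- function(exprs, design,
                      stage = c("raw", "bgcorr", "qnorm", "log2", "batchcorr"),
                      assay = "mrna") {
  stage <- match.arg(stage)
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    abort("`exprs` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(exprs)) || anyDuplicated(rownames(exprs))) {
    abort("`exprs` must have unique rownames (feature ids).")
  }
  if (is.null(colnames(exprs)) || anyDuplicated(colnames(exprs))) {
    abort("`exprs` must have unique colnames (sample ids).")
  }
  design <- as_tibble(design)
  req <- c("sample_id", "donor", "group", "time_h", "batch")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(paste0("`design` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!setequal(design$sample_id, colnames(exprs)) ||
      nrow(design) != ncol(exprs)) {
    abort("`design$sample_id` must match the matrix columns exactly.")
  }
  design <- design[match(colnames(exprs), design$sample_id), ]
  bad <- setdiff(unique(design$group), c("PD", "HC"))
  if (length(bad)) abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")))
  structure(
    list(exprs = exprs, design = design, stage = stage, assay = assay),
    class = "tc_cohort"
  )
}

#' @export
print.tc_cohort <- function(x, ...) {
  cat(sprintf(
    "<tc_cohort> %s assay: %d features x %d samples [stage: %s]\n",
    x$assay, nrow(x$exprs), ncol(x$exprs), x$stage
  ))
  tab <- table(x$design$group)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  time points (h):", paste(sort(unique(x$design$time_h)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tc_cohort <- function(x) dim(x$exprs)

stage_index <- function(stage) {
  match(stage, c("raw", "bgcorr", "qnorm", "log2", "batchcorr"))
}

check_stage <- function(cohort, expected, op) {
  if (!inherits(cohort, "tc_cohort")) abort(paste0("`", op, "()` expects a tc_cohort."))
  if (!cohort$stage %in% expected) {
    abort(sprintf(
      "%s() requires stage %s, got '%s' (pipeline order is raw -> bgcorr -> qnorm -> log2 -> batchcorr).",
      op, paste(sQuote(expected), collapse = " or "), cohort$stage
    ))
  }
  invisible(cohort)
}

#' Remove one sample column from a cohort
#'
#' Emulates a failed assay (in the motivating study one patient yielded no
#' data at the 4 h time point): the (donor, time) column is removed from the
#' matrix and the design, and all downstream group statistics are computed
#' over the remaining samples. No imputation is performed anywhere.
#'
#' @param cohort a [tc_cohort()].
#' @param donor donor identifier as in `cohort$design$donor`.
#' @param time_h time point in hours.
#'
#' @return The cohort without that column.
#' @export
drop_sample <- function(cohort, donor, time_h) {
  stopifnot(inherits(cohort, "tc_cohort"))
  hit <- cohort$design$donor == donor & cohort$design$time_h == time_h
  if (!any(hit)) {
    abort(sprintf("No sample for donor '%s' at %s h.", donor, format(time_h)))
  }
  keep <- cohort$design$sample_id[!hit]
  cohort$exprs <- cohort$exprs[, keep, drop = FALSE]
  cohort$design <- cohort$design[!hit, ]
  cohort
}
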
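#' Fit the normexp convolution model to one sample's intensities
#'
#' Models observed intensities as `X = B + S` with background
#' `B ~ Normal(mu, sigma^2)` and signal `S ~ Exponential(mean alpha)`, the
#' standard model for single-channel microarray background correction.
#' Fitting is by joint maximum likelihood of the convolution density
#' (limma's `normexp.fit`, method `"mle"`); a moment-matching initialiser
#' (`method = "moments"`: mu from the low quantiles, alpha from the mean
#' excess) is available as a fallback for ill-conditioned columns.
#'
#' @param x numeric vector of positive intensities (one sample column).
#' @param method `"mle"` (default) or `"moments"`.
#' @return A list of class `normexp_params` with elements `mu`, `sigma`,
#'   `alpha`.
#' @export
fit_normexp <- function(x, method = c("mle", "moments")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 10) abort("Need at least 10 finite intensities to fit normexp.")
  if (sd(x) == 0) {
    abort("Intensities are constant; normexp background cannot be fitted. Skip background correction for this sample.")
  }
  limma_method <- if (method == "mle") "mle" else "saddle"
  if (method == "moments") {
    mu <- mean(x[x <= stats::quantile(x, 0.05)])
    sigma <- max(sd(x[x <= stats::quantile(x, 0.1)]), 1e-6)
    alpha <- max(mean(x) - mu, 1e-6)
    par <- c(mu, log(sigma), log(alpha))
  } else {
    par <- limma::normexp.fit(x, method = "mle")$par
  }
  structure(
    list(mu = par[1], sigma = exp(par[2]), alpha = exp(par[3])),
    class = "normexp_params"
  )
}

#' @export
print.normexp_params <- function(x, ...) {
  cat(sprintf("<normexp_params> mu=%.4g sigma=%.4g alpha=%.4g\n",
              x$mu, x$sigma, x$alpha))
  invisible(x)
}

#' Conditional expected signal under the normexp model
#'
#' For observed intensity `x`, returns `E[S | X = x] + offset` under
#' `X = Normal(mu, sigma^2) + Exponential(mean alpha)`. The conditional
#' expectation is evaluated analytically (limma's `normexp.signal`); the
#' offset (16 by default throughout the pipeline) keeps corrected values
#' strictly positive and damps log-ratio variance at low intensities.
#'
#' @param x numeric vector of observed intensities.
#' @param params a `normexp_params` object (or list with mu/sigma/alpha).
#' @param offset non-negative constant added after correction.
#' @return Corrected intensities, strictly positive, monotone in `x`.
#' @export
normexp_expected_signal <- function(x, params, offset = 0) {
  if (offset < 0) abort("`offset` must be non-negative.")
  par <- c(params$mu, log(params$sigma), log(params$alpha))
  limma::normexp.signal(par, x) + offset
}

#' Background-correct a raw cohort (normexp + offset)
#'
#' Fits the normexp model per sample column and replaces every intensity by
#' its conditional expected signal plus `offset`. Advances the cohort stage
#' from `raw` to `bgcorr`.
#'
#' @param cohort a raw-stage [tc_cohort()].
#' @param offset constant added after correction (default 16).
#' @param method fitting method, see [fit_normexp()].
#' @return The corrected cohort; fitted per-sample parameters are attached
#'   as a tibble in `cohort$normexp`.
#' @export
normexp_correct <- function(cohort, offset = 16, method = c("mle", "moments")) {
  check_stage(cohort, "raw", "normexp_correct")
  method <- match.arg(method)
  fits <- lapply(seq_len(ncol(cohort$exprs)), function(j) {
    fit_normexp(cohort$exprs[, j], method = method)
  })
  out <- cohort$exprs
  for (j in seq_along(fits)) {
    out[, j] <- normexp_expected_signal(cohort$exprs[, j], fits[[j]], offset = offset)
  }
  cohort$exprs <- out
  cohort$normexp <- tibble(
    sample_id = colnames(out),
    mu = vapply(fits, `[[`, numeric(1), "mu"),
    sigma = vapply(fits, `[[`, numeric(1), "sigma"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    offset = offset
  )
  cohort$stage <- "bgcorr"
  cohort
}

#' Quantile-normalize expression columns
#'
#' Forces every sample column to the same empirical distribution: the mean
#' of the across-column order statistics, assigned by within-column rank.
#' Tied values receive the mean of the tied rank means, which makes the
#' operation deterministic and idempotent. Works on a plain matrix or on a
#' `bgcorr`-stage cohort (advancing it to `qnorm`).
#'
#' @param x numeric matrix or [tc_cohort()].
#' @param ... unused.
#' @return Same type as the input.
#' @export
quantile_normalize <- function(x, ...) UseMethod("quantile_normalize")

#' @rdname quantile_normalize
#' @export
quantile_normalize.matrix <- function(x, ...) {
  if (nrow(x) == 0 || ncol(x) == 0) abort("Cannot quantile-normalize an empty matrix.")
  if (anyNA(x)) abort("Missing values are not supported (dropped samples are absent columns).")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' @rdname quantile_normalize
#' @export
quantile_normalize.tc_cohort <- function(x, ...) {
  check_stage(x, "bgcorr", "quantile_normalize")
  x$exprs <- quantile_normalize(x$exprs)
  x$stage <- "qnorm"
  x
}

#' Log2-transform expression values
#'
#' Elementwise log2. All values must be strictly positive (guaranteed after
#' normexp correction with a positive offset); the first offending feature
#' and sample are named otherwise.
#'
#' @param x numeric matrix or `qnorm`-stage [tc_cohort()].
#' @param ... unused.
#' @return Same type as the input (cohort advances to stage `log2`).
#' @export
log2_transform <- function(x, ...) UseMethod("log2_transform")

#' @rdname log2_transform
#' @export
log2_transform.matrix <- function(x, ...) {
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-positive value at feature '%s', sample '%s'; log2 requires positive input.",
      rownames(x)[bad[1, 1]] %||% bad[1, 1], colnames(x)[bad[1, 2]] %||% bad[1, 2]
    ))
  }
  log2(x)
}

#' @rdname log2_transform
#' @export
log2_transform.tc_cohort <- function(x, ...) {
  check_stage(x, "qnorm", "log2_transform")
  x$exprs <- log2_transform(x$exprs)
  x$stage <- "log2"
  x
}

#' Remove batch effects from log2 expression
#'
#' Per feature, fits ordinary least squares of expression on the preserved
#' group-by-time design cells plus sum-to-zero batch contrasts, and
#' subtracts the fitted batch component (limma's `removeBatchEffect`). The
#' preserved-design fitted means are unchanged by the subtraction. Fails
#' with the aliased terms listed if batch is confounded with the design.
#'
#' @param cohort a `log2`-stage [tc_cohort()].
#' @return The corrected cohort (stage `batchcorr`); the batch model
#'   (levels, contrasts, per-feature coefficients in log2 units) is attached
#'   as `cohort$batch_model`.
#' @export
remove_batch_effect <- function(cohort) {
  check_stage(cohort, "log2", "remove_batch_effect")
  design <- cohort$design
  batch <- factor(design$batch)
  if (nlevels(batch) < 2) {
    abort("Batch correction needs at least 2 batch levels.")
  }
  cell <- factor(paste(design$group, design$time_h, sep = "."))
  dmat <- model.matrix(~cell)
  contrasts(batch) <- stats::contr.sum(levels(batch))
  bmat <- model.matrix(~batch)[, -1, drop = FALSE]
  full <- cbind(dmat, bmat)
  qrf <- qr(full)
  if (qrf$rank < ncol(full)) {
    aliased <- colnames(full)[qrf$pivot[seq(qrf$rank + 1L, ncol(full))]]
    abort(paste0("Batch is confounded with the group-by-time design; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  corrected <- limma::removeBatchEffect(cohort$exprs, batch = batch, design = dmat)
  # per-feature batch coefficients for reporting (same OLS fit)
  fit <- limma::lmFit(cohort$exprs, full)
  coefs <- fit$coefficients[, colnames(bmat), drop = FALSE]
  cohort$exprs <- corrected
  cohort$batch_model <- list(
    batch_levels = levels(batch),
    preserved_design = levels(cell),
    coefficients = coefs
  )
  cohort$stage <- "batchcorr"
  cohort
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in fixed order: normexp background correction with `offset`,
#' quantile normalization, log2 transform and (optionally) batch removal.
#' The motivating study batch-corrected the transcriptome assay only, so
#' `batch_correct` defaults to `TRUE` for mRNA cohorts and should be set
#' `FALSE` for miRNA cohorts to mirror it.
#'
#' @param cohort a raw-stage [tc_cohort()].
#' @param offset normexp offset (default 16).
#' @param batch_correct apply batch removal after log2?
#' @param method normexp fitting method, see [fit_normexp()].
#' @return The processed cohort at stage `batchcorr` (or `log2` when
#'   `batch_correct = FALSE`).
#' @export
preprocess_cohort <- function(cohort, offset = 16, batch_correct = TRUE,
                              method = "mle") {
  out <- normexp_correct(cohort, offset = offset, method = method)
  out <- quantile_normalize(out)
  out <- log2_transform(out)
  if (batch_correct) out <- remove_batch_effect(out)
  out
}
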
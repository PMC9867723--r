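#' Tidy a shrinkage-t fit
#'
#' One row per feature with group means, the shrinkage-t statistic, its
#' two-sided p-value, the raw and shrunk variance estimates for both
#' groups, and the sample sizes.
#'
#' @param x a [shrinkage_t()] fit.
#' @param ... unused.
#' @return A tibble.
#' @method tidy shrinkage_fit
#' @export
tidy.shrinkage_fit <- function(x, ...) {
  x$stats |>
    mutate(
      v_pd = unname(x$shrink$PD$v),
      v_star_pd = unname(x$shrink$PD$v_star),
      v_hc = unname(x$shrink$HC$v),
      v_star_hc = unname(x$shrink$HC$v_star)
    )
}

#' Glance at a shrinkage-t fit
#'
#' @param x a [shrinkage_t()] fit.
#' @param ... unused.
#' @return A one-row tibble with the per-group shrinkage intensities and
#'   targets, the degrees of freedom and the number of features.
#' @method glance shrinkage_fit
#' @export
glance.shrinkage_fit <- function(x, ...) {
  tibble(
    time_h = x$time_h,
    n_features = nrow(x$stats),
    lambda_pd = x$shrink$PD$lambda,
    lambda_hc = x$shrink$HC$lambda,
    v_target_pd = x$shrink$PD$v_target,
    v_target_hc = x$shrink$HC$v_target,
    df = x$df,
    p_method = x$p_method
  )
}

#' Tidy an MDS embedding
#'
#' @param x a [classical_mds()] result.
#' @param ... unused.
#' @return A tibble with `label`, the embedding coordinates and, when
#'   available, the `group` of each label.
#' @method tidy tc_mds
#' @export
tidy.tc_mds <- function(x, ...) {
  out <- bind_cols(tibble(label = rownames(x$points)), as_tibble(x$points))
  if (!is.null(x$groups)) out$group <- unname(x$groups[out$label])
  out
}

#' Glance at an MDS embedding
#'
#' @param x a [classical_mds()] result.
#' @param ... unused.
#' @return A one-row tibble with the embedding dimension, the two leading
#'   eigenvalues, the number of negative eigenvalues and the
#'   goodness-of-fit (fraction of positive eigenvalue mass captured).
#' @method glance tc_mds
#' @export
glance.tc_mds <- function(x, ...) {
  tibble(
    k = x$k,
    eig1 = x$eig[1],
    eig2 = x$eig[2],
    n_negative_eig = sum(x$eig < 0),
    gof = x$gof
  )
}
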
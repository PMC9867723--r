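#' Pairwise Euclidean distances between sample profiles
#'
#' In `"combined"` mode each donor's per-timepoint expression columns are
#' concatenated feature-wise into one long vector (the combined time-course
#' view) and distances are computed between donors; time points missing for
#' any donor (a dropped sample) are excluded from the concatenation for all
#' donors, keeping the comparison complete and deterministic. In
#' `"per_sample"` mode distances are computed between individual sample
#' columns.
#'
#' @param cohort a preprocessed [tc_cohort()].
#' @param mode `"combined"` (one point per donor) or `"per_sample"`.
#' @return A `dist` object with donor or sample labels; the label-to-group
#'   mapping is attached as attribute `groups`.
#' @export
sample_distances <- function(cohort, mode = c("combined", "per_sample")) {
  check_stage(cohort, c("log2", "batchcorr"), "sample_distances")
  mode <- match.arg(mode)
  design <- cohort$design
  if (mode == "per_sample") {
    if (ncol(cohort$exprs) < 3) abort("Need at least 3 samples.")
    d <- dist(t(cohort$exprs))
    attr(d, "groups") <- setNames(design$group, design$sample_id)
    return(d)
  }
  donors <- unique(design$donor)
  if (length(donors) < 3) abort("Need at least 3 donors.")
  counts <- table(design$donor, design$time_h)
  complete_tp <- colnames(counts)[colSums(counts == 1) == length(donors)]
  if (!length(complete_tp)) abort("No time point is complete across donors.")
  vecs <- vapply(donors, function(dn) {
    sub <- design[design$donor == dn & design$time_h %in% as.numeric(complete_tp), ]
    sub <- sub[order(sub$time_h), ]
    as.vector(cohort$exprs[, sub$sample_id])
  }, numeric(nrow(cohort$exprs) * length(complete_tp)))
  d <- dist(t(vecs))
  attr(d, "Labels") <- donors
  attr(d, "groups") <- setNames(
    design$group[match(donors, design$donor)], donors)
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: square the distances, double-center
#' (`B = -1/2 J D^2 J`), eigendecompose, and use the top-`k` eigenvectors
#' scaled by the square roots of their eigenvalues as coordinates
#' (`stats::cmdscale` with `eig = TRUE`). Negative eigenvalues are
#' reported but never used for coordinates. Coordinates are centered and
#' defined up to rotation/reflection.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k embedding dimension (default 2).
#' @return An object of class `tc_mds` with `points` (labels x k),
#'   `eig` (all eigenvalues, non-increasing), `gof` (fraction of positive
#'   eigenvalue mass captured by `k` dimensions) and `groups` (if carried
#'   by `d`).
#' @export
classical_mds <- function(d, k = 2) {
  m <- as.matrix(d)
  if (nrow(m) < k + 1) abort("Need at least k + 1 labels.")
  if (all(m == 0)) abort("All distances are zero; no configuration to embed.")
  fit <- cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) { # degenerate configurations can return fewer axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  colnames(pts) <- paste0("dim", seq_len(k))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(pmax(eig, 0))
  structure(
    list(points = pts, eig = eig,
         gof = if (pos > 0) sum(pmax(head(eig, k), 0)) / pos else 0,
         k = k, groups = attr(d, "groups")),
    class = "tc_mds"
  )
}

#' @export
print.tc_mds <- function(x, ...) {
  cat(sprintf("<tc_mds> %d labels embedded in %d dimensions (GOF %.3f)\n",
              nrow(x$points), x$k, x$gof))
  invisible(x)
}

#' Are the groups perfectly separated along one embedding axis?
#'
#' Checks whether a single MDS dimension suffices to separate the PD and HC
#' labels (every PD coordinate on one side of every HC coordinate).
#'
#' @param mds a [classical_mds()] result with group labels.
#' @return `TRUE` if some axis separates the groups.
#' @export
axis_separable <- function(mds) {
  g <- mds$groups[rownames(mds$points)]
  if (is.null(g)) abort("No group labels attached to the embedding.")
  any(vapply(seq_len(ncol(mds$points)), function(j) {
    a <- mds$points[g == "PD", j]
    b <- mds$points[g == "HC", j]
    max(a) < min(b) || max(b) < min(a)
  }, logical(1)))
}
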
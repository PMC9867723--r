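#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation of a test
#' gene list relative to a reference universe (e.g. all protein-coding
#' genes). With `N` reference genes, `K` of them in the set, and a test set
#' of `n` genes overlapping the set in `k`, the upper-tail hypergeometric
#' p-value is `P(X >= k)`. Benjamini-Hochberg adjustment runs across all
#' tested sets jointly.
#'
#' @param test_set character vector of gene ids; ids outside `reference`
#'   are dropped with a warning.
#' @param collection named list of gene sets (see [read_gmt()]), or a
#'   single character vector treated as one set.
#' @param reference the gene universe (character vector).
#' @param min_size sets with fewer than `min_size` members inside the
#'   reference are skipped (default 2) and listed in the `skipped`
#'   attribute.
#' @return A tibble with one row per tested set: `set_name`, `k`, `K`,
#'   `n`, `N`, `p_raw`, `p_adj`, ordered by `p_adj` then `p_raw`.
#' @export
ora <- function(test_set, collection, reference, min_size = 2) {
  if (is.character(collection)) collection <- list(set = collection)
  if (!length(collection)) abort("Empty gene-set collection.")
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    abort("Collection sets must have unique names.")
  }
  reference <- unique(reference)
  if (!length(reference)) abort("Empty reference universe.")
  test_set <- unique(test_set)
  outside <- setdiff(test_set, reference)
  if (length(outside)) {
    warn(sprintf("%d test gene(s) outside the reference were dropped.",
                 length(outside)))
    test_set <- intersect(test_set, reference)
  }
  if (!length(test_set)) abort("Test set is empty after intersection with the reference.")

  N <- length(reference)
  n <- length(test_set)
  sizes <- vapply(collection, function(s) length(intersect(unique(s), reference)),
                  integer(1))
  skipped <- names(collection)[sizes < min_size]
  keep <- names(collection)[sizes >= min_size]
  res <- purrr::map(keep, function(nm) {
    members <- intersect(unique(collection[[nm]]), reference)
    K <- length(members)
    k <- length(intersect(test_set, members))
    tibble(
      set_name = nm, k = k, K = K, n = n, N = N,
      p_raw = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  }) |>
    bind_rows()
  if (!nrow(res)) abort("No gene set reached `min_size` within the reference.")
  res <- res |>
    mutate(p_adj = p.adjust(.data$p_raw, method = "BH")) |>
    arrange(.data$p_adj, .data$p_raw, .data$set_name)
  attr(res, "skipped") <- skipped
  res
}

#' Split core genes by direction of deregulation
#'
#' Partitions core deregulated features into an increased, a decreased and
#' an excluded set; features without a uniform direction over their core
#' time points (`mixed`) are excluded from enrichment, as are non-core
#' rows. The three sets are disjoint and cover all core features.
#'
#' @param core output of [classify_core()].
#' @return A list with character vectors `increased`, `decreased`,
#'   `excluded`.
#' @export
direction_split <- function(core) {
  core <- core[core$is_core, ]
  list(
    increased = core$feature_id[core$direction == "increased"],
    decreased = core$feature_id[core$direction == "decreased"],
    excluded = core$feature_id[core$direction == "mixed"]
  )
}
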
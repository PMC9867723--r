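#' Fold-change profiles over the time course
#'
#' Extracts, for every feature of a differential table, the vector of
#' group-median log2 fold changes (PD minus HC) ordered by time — the
#' time-course change profile used for miRNA-target matching.
#'
#' @param table a [differential_table()] result.
#' @param features features to extract (default all in the table).
#' @return A numeric matrix, features in rows, one column per time point
#'   (column names are the hours).
#' @export
fc_profiles <- function(table, features = NULL) {
  ids <- features %||% unique(table$feature_id)
  missing_ids <- setdiff(ids, table$feature_id)
  if (length(missing_ids)) {
    abort(paste0("Feature(s) absent from the table: ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  tps <- sort(unique(table$time_h))
  wide <- table |>
    filter(.data$feature_id %in% ids) |>
    select("feature_id", "time_h", "median_log2fc") |>
    tidyr::pivot_wider(names_from = "time_h", values_from = "median_log2fc")
  m <- as.matrix(wide[, as.character(tps), drop = FALSE])
  rownames(m) <- wide$feature_id
  m[ids, , drop = FALSE]
}

#' Match miRNAs to putative targets by inverse profile correlation
#'
#' A (miRNA, gene) pair is a putative regulatory match when the Pearson
#' correlation between their per-timepoint median log2 fold-change profiles
#' is at most `theta_pcc` (default -0.5) and the gene's fold change is
#' direction-consistent with the miRNA: targets of a miRNA increased in PD
#' must reach a median log2 FC of `-theta_fc` or lower at one or more time
#' points, targets of a decreased miRNA `+theta_fc` or higher. Pairs with a
#' zero-variance profile or fewer than 3 shared time points are skipped and
#' counted.
#'
#' @param mirna_profiles matrix from [fc_profiles()] for the miRNAs of
#'   interest (typically the core deregulated miRNAs).
#' @param gene_profiles matrix from [fc_profiles()] for candidate genes.
#' @param mirna_directions data frame with columns `feature_id` and
#'   `direction` (`"increased"`/`"decreased"` in PD) covering every miRNA.
#' @param theta_pcc correlation gate (pairs pass when `pcc <= theta_pcc`).
#' @param theta_fc absolute fold-change gate for the target gene.
#' @return A tibble with one row per (miRNA, gene) pair: `pcc`,
#'   `passes_pcc`, `passes_fc_gate`, `match`; skipped pairs are recorded in
#'   the `skipped` attribute.
#' @export
match_targets <- function(mirna_profiles, gene_profiles, mirna_directions,
                          theta_pcc = -0.5, theta_fc = 0.3) {
  if (ncol(mirna_profiles) != ncol(gene_profiles) ||
      !identical(colnames(mirna_profiles), colnames(gene_profiles))) {
    abort("miRNA and gene profiles must share the same time points.")
  }
  mirna_directions <- as_tibble(mirna_directions)
  dir <- mirna_directions$direction[
    match(rownames(mirna_profiles), mirna_directions$feature_id)]
  if (anyNA(dir) || !all(dir %in% c("increased", "decreased"))) {
    abort("Every miRNA needs a direction of 'increased' or 'decreased'.")
  }
  if (ncol(mirna_profiles) < 3) abort("Need at least 3 shared time points.")

  sd0_mir <- apply(mirna_profiles, 1, sd) == 0
  sd0_gene <- apply(gene_profiles, 1, sd) == 0
  skipped <- tibble(
    feature_id = c(rownames(mirna_profiles)[sd0_mir],
                   rownames(gene_profiles)[sd0_gene]),
    role = rep(c("mirna", "gene"), c(sum(sd0_mir), sum(sd0_gene))),
    reason = "zero-variance profile (PCC undefined)"
  )
  mp <- mirna_profiles[!sd0_mir, , drop = FALSE]
  gp <- gene_profiles[!sd0_gene, , drop = FALSE]
  dir <- dir[!sd0_mir]

  pcc_mat <- if (nrow(mp) && nrow(gp)) cor(t(mp), t(gp)) else
    matrix(numeric(), nrow(mp), nrow(gp))

  gene_min <- apply(gp, 1, min)
  gene_max <- apply(gp, 1, max)
  out <- purrr::map(seq_len(nrow(mp)), function(i) {
    fc_ok <- if (dir[i] == "increased") gene_min <= -theta_fc else gene_max >= theta_fc
    tibble(
      mirna_id = rownames(mp)[i],
      gene_id = rownames(gp),
      mirna_direction = dir[i],
      pcc = unname(pcc_mat[i, ]),
      passes_pcc = unname(pcc_mat[i, ] <= theta_pcc),
      passes_fc_gate = unname(fc_ok)
    )
  }) |>
    bind_rows() |>
    mutate(match = .data$passes_pcc & .data$passes_fc_gate)
  attr(out, "skipped") <- skipped
  out
}

#' Flag matches with experimentally validated target evidence
#'
#' Intersects putative matches with a validated miRNA-target table (same
#' schema as miRTargetLink-style exports: `mirna_id`, `gene_id`,
#' `evidence`). A match is `validated` when the pair appears with evidence
#' tier `"strong"` (case-insensitive). All matches are retained.
#'
#' @param matches output of [match_targets()].
#' @param targets data frame with columns `mirna_id`, `gene_id`,
#'   `evidence`; malformed rows (missing fields) are skipped and counted in
#'   the `n_skipped_rows` attribute.
#' @return `matches` with `validated` and `evidence` columns added.
#' @export
intersect_validated <- function(matches, targets) {
  targets <- as_tibble(targets)
  req <- c("mirna_id", "gene_id", "evidence")
  if (length(setdiff(req, names(targets)))) {
    abort("Target table needs columns mirna_id, gene_id, evidence.")
  }
  ok <- complete.cases(targets[req]) &
    targets$mirna_id != "" & targets$gene_id != ""
  n_skipped <- sum(!ok)
  targets <- targets[ok, req]
  strong <- targets |>
    filter(tolower(.data$evidence) == "strong") |>
    dplyr::distinct(.data$mirna_id, .data$gene_id)
  evid <- targets |>
    group_by(.data$mirna_id, .data$gene_id) |>
    summarise(evidence = paste(sort(unique(.data$evidence)), collapse = ";"),
              .groups = "drop")
  out <- matches |>
    left_join(evid, by = c("mirna_id", "gene_id")) |>
    mutate(validated = paste(.data$mirna_id, .data$gene_id) %in%
             paste(strong$mirna_id, strong$gene_id))
  attr(out, "n_skipped_rows") <- n_skipped
  attr(out, "skipped") <- attr(matches, "skipped")
  out
}
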
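file_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("tcellkinetics"))
  paste0("# tcellkinetics ", ver,
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config)) paste0(" config=", rlang::hash(config)))
}

write_tsv_commented <- function(x, path, seed = NULL, config = NULL) {
  # %.17g guarantees exact round-trip of doubles through the TSV
  dbl <- vapply(x, is.double, logical(1))
  x[dbl] <- lapply(x[dbl], function(col) sprintf("%.17g", col))
  writeLines(file_header(seed = seed, config = config), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row whose first column is `feature_id` followed by one
#' column per sample; comment lines starting with `#` are skipped.
#' Duplicate feature or sample ids are rejected.
#'
#' @param path TSV file path.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  # base parser: correctly rounded doubles, so fixtures round-trip exactly
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id") {
    abort(sprintf("%s: first column must be 'feature_id'.", path))
  }
  if (anyDuplicated(tab$feature_id)) {
    dup <- tab$feature_id[duplicated(tab$feature_id)][1]
    line <- which(tab$feature_id == dup)[2] + 1L
    abort(sprintf("%s:%d: duplicate feature id '%s'.", path, line, dup))
  }
  if (anyDuplicated(names(tab))) abort(sprintf("%s: duplicate sample ids.", path))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("%s: non-numeric expression values.", path))
  rownames(m) <- tab$feature_id
  m
}

#' Read a sample design table from TSV
#'
#' Expects columns `sample_id`, `donor`, `group`, `time_h`, `batch`.
#'
#' @param path TSV file path.
#' @param matrix optional expression matrix to cross-check: every matrix
#'   column must appear in the design (the missing id is named otherwise).
#' @return A tibble.
#' @export
read_design <- function(path, matrix = NULL) {
  design <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  req <- c("sample_id", "donor", "group", "time_h", "batch")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(matrix)) {
    absent <- setdiff(colnames(matrix), design$sample_id)
    if (length(absent)) {
      abort(sprintf("%s: design lacks matrix sample id '%s'.", path, absent[1]))
    }
  }
  design
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes. Members are deduplicated; duplicate
#' set names are rejected with their line number.
#'
#' @param path GMT file path.
#' @return A named list of character vectors; descriptions are kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short)) {
    abort(sprintf("%s:%d: GMT line needs name, description and >= 1 member.",
                  path, short[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("%s:%d: duplicate set name '%s'.", path,
                  which(duplicated(nm))[1], nm[duplicated(nm)][1]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2), nm)
  sets
}

#' Read a validated miRNA-target table from TSV
#'
#' Expects columns `mirna_id`, `gene_id`, `evidence` (the schema of
#' miRTargetLink-style exports).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_targets <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  req <- c("mirna_id", "gene_id", "evidence")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' Write a simulated cohort as TSV fixture files
#'
#' Writes `matrix.tsv` (and `mirna_matrix.tsv` when a miRNA assay is
#' present), `design.tsv` and `truth.tsv` into `dir`. Files carry a header
#' comment with the tool version, config hash and seed, and round-trip
#' through [read_expression_matrix()] / [read_design()].
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "tc_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$config$seed
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  mat_tbl <- function(cohort) {
    bind_cols(tibble(feature_id = rownames(cohort$exprs)),
              as_tibble(cohort$exprs))
  }
  write_tsv_commented(mat_tbl(sim$mrna), paths["matrix"],
                      seed = seed, config = sim$config)
  if (!is.null(sim$mirna)) {
    paths["mirna_matrix"] <- file.path(dir, "mirna_matrix.tsv")
    write_tsv_commented(mat_tbl(sim$mirna), paths["mirna_matrix"],
                        seed = seed, config = sim$config)
  }
  write_tsv_commented(sim$design, paths["design"], seed = seed, config = sim$config)
  write_tsv_commented(sim$truth, paths["truth"], seed = seed, config = sim$config)
  invisible(paths)
}

#' @importFrom dplyr bind_cols
NULL
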
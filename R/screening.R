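#' Screen clinical parameters against an expression clustering
#'
#' The end-to-end pipeline: scale the log-ratio matrix to `[-1, 1]`, cluster
#' the samples by average linkage under the correlation distance (or accept a
#' precomputed tree), bin each clinical column to nominal categories, and
#' evaluate every column with [evaluate_label()]. The report has one row per
#' evaluable column, sorted by NTI descending, so the labels most correlated
#' with the expression clustering rank first.
#'
#' Samples present in only one of the two inputs are dropped (with a message);
#' all-missing or single-valued columns after binning are reported with
#' `nti = 0, p = 1`. Given the same inputs, `r` and `seed`, the report is
#' fully reproducible.
#'
#' @param expr Samples x genes numeric matrix of raw log-ratios, with sample
#'   ids as rownames. Ignored when `tree` is supplied (evaluate-only mode).
#' @param clinical Data frame of clinical columns; `sample_col` names the
#'   sample-id column.
#' @param binning Optional named list of [binning_spec()] rules (e.g. from
#'   [load_binning_config()]); unlisted columns pass through as nominal.
#' @param sample_col Name of the sample-id column in `clinical`
#'   (default `"sample_id"`).
#' @param tree Optional precomputed `ape::phylo` tree over the samples;
#'   skips scaling and clustering.
#' @param scaling Scaling mode, see [scale_log_ratios()].
#' @param r Permutations / ordered-tree draws per label (default 10000).
#' @param seed Optional integer seed governing all randomness.
#' @param tail,degenerate Passed to [evaluate_label()].
#' @param bh Add a Benjamini-Hochberg adjusted `p_adj` column (default
#'   `FALSE`; the raw per-label p-values are the primary output).
#' @return A tibble of class `nti_screen` with columns `label`, `kappa`,
#'   `n_missing`, `ti`, `ti_min`, `ti_max`, `nti`, `p_value`, `stars` (and
#'   `p_adj` if `bh`), sorted by `nti` descending. The tree and the full
#'   per-label results are attached as attributes `"tree"` and `"results"`.
#' @examples
#' sim <- simulate_labeled_expression(n_samples = 24, n_genes = 40, seed = 1)
#' rep <- nti_screen(sim$expr, sim$clinical, r = 200, seed = 1)
#' rep$label[1]
#' @export
nti_screen <- function(expr = NULL, clinical, binning = NULL,
                       sample_col = "sample_id", tree = NULL,
                       scaling = c("global_maxabs", "per_gene_maxabs"),
                       r = 10000, seed = NULL,
                       tail = c("geq", "gt"),
                       degenerate = c("include", "skip"), bh = FALSE) {
  scaling <- match.arg(scaling)
  tail <- match.arg(tail)
  degenerate <- match.arg(degenerate)
  if (!is.null(seed)) set.seed(seed)
  clinical <- tibble::as_tibble(clinical)
  if (!sample_col %in% names(clinical))
    stop("clinical table has no '", sample_col, "' column", call. = FALSE)
  clin_ids <- as.character(clinical[[sample_col]])

  if (is.null(tree)) {
    if (is.null(expr)) stop("need an expression matrix or a tree", call. = FALSE)
    expr <- as.matrix(expr)
    if (is.null(rownames(expr)))
      stop("expression matrix needs sample ids as rownames", call. = FALSE)
    common <- intersect(rownames(expr), clin_ids)
    if (length(common) == 0)
      stop("no samples shared between expression matrix and clinical table",
           call. = FALSE)
    dropped <- (nrow(expr) - length(common)) + (length(clin_ids) - length(common))
    if (dropped > 0)
      message(dropped, " sample(s) present in only one input dropped; ",
              length(common), " remain")
    expr <- expr[common, , drop = FALSE]
    scaled <- scale_log_ratios(expr, mode = scaling)
    tree <- cluster_average_linkage(scaled)
  } else {
    common <- intersect(tree$tip.label, clin_ids)
    if (length(common) < length(tree$tip.label))
      stop("clinical table lacks ", length(tree$tip.label) - length(common),
           " sample(s) present in the tree", call. = FALSE)
  }
  clinical <- clinical[match(tree$tip.label, clin_ids), , drop = FALSE]

  label_cols <- setdiff(names(clinical), sample_col)
  results <- list()
  for (col in label_cols) {
    spec <- binning[[col]] %||% binning_spec(col, "passthrough")
    labels <- bin_column(clinical[[col]], spec)
    names(labels) <- tree$tip.label
    if (all(is.na(labels))) {
      message("column '", col, "' skipped: all values missing")
      next
    }
    results[[col]] <- suppressWarnings(
      evaluate_label(tree, labels, r = r, tail = tail,
                     degenerate = degenerate, label_name = col)
    )
  }
  if (length(results) == 0) stop("no evaluable clinical columns", call. = FALSE)
  report <- dplyr::bind_rows(lapply(results, glance.nti_result))
  names(report)[names(report) == "label_name"] <- "label"
  if (bh) report$p_adj <- stats::p.adjust(report$p_value, method = "BH")
  report <- dplyr::arrange(report, dplyr::desc(.data$nti), .data$p_value)
  attr(report, "tree") <- tree
  attr(report, "results") <- results
  class(report) <- c("nti_screen", class(report))
  report
}

#' Write a screening report as TSV
#'
#' @param report An [nti_screen()] tibble.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_screen_report <- function(report, file) {
  out <- as.data.frame(report)
  out$stars <- format_stars(out$stars)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects genes as rows and samples as columns (first column = gene ids), the
#' common export orientation; use `transpose = FALSE` if samples are already
#' rows.
#'
#' @param path TSV (default) or CSV file.
#' @param transpose If `TRUE` (default) the file holds genes as rows and is
#'   transposed to samples x genes.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A samples x genes numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path, transpose = TRUE, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (transpose) t(m) else m
}

#' Read a clinical table from TSV/CSV
#'
#' @inheritParams read_expression_matrix
#' @return A tibble; the first column is taken as the sample id unless a
#'   `sample_id` column exists.
#' @export
read_clinical_table <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tibble::as_tibble(df)
}
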
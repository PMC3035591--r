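#' Simulate an expression matrix with planted class structure
#'
#' Generates a samples x genes log-ratio matrix in which `kappa` near-evenly
#' sized sample classes differ by class-specific mean shifts on random marker
#' gene subsets, plus Gaussian noise — a deliberately simple stand-in for
#' marker-gene signatures that makes every pipeline stage testable without
#' real data. The accompanying clinical table carries one signal column (the
#' ground-truth class, with a fraction masked as missing) and any number of
#' null columns drawn independently of the data.
#'
#' @param n_samples,n_genes Matrix dimensions (defaults 40 x 100).
#' @param kappa Number of planted classes (default 2).
#' @param effect Per-class mean shift magnitude in log-ratio units
#'   (default 2); 0 plants no signal.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.5).
#' @param missing_frac Fraction of signal labels masked as `NA` (default 0).
#' @param n_null_labels Number of label columns independent of the data
#'   (default 5).
#' @param marker_frac Fraction of genes carrying each class's shift
#'   (default 0.3).
#' @param seed Optional integer seed.
#' @return A list with `expr` (raw log-ratio matrix, rownames are sample ids),
#'   `clinical` (tibble: `sample_id`, `signal`, `null_1` ... ), and `truth`
#'   (unmasked class factor).
#' @export
simulate_labeled_expression <- function(n_samples = 40, n_genes = 100,
                                        kappa = 2, effect = 2, noise_sd = 0.5,
                                        missing_frac = 0, n_null_labels = 5,
                                        marker_frac = 0.3, seed = NULL) {
  stopifnot(kappa >= 1, effect >= 0, missing_frac >= 0, missing_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  classes <- paste0("class", seq_len(kappa))
  truth <- factor(classes[rep_len(seq_len(kappa), n_samples)], levels = classes)
  truth <- truth[sample.int(n_samples)] # random assignment, near-even sizes
  n_markers <- max(1L, round(marker_frac * n_genes))
  shift <- matrix(0, kappa, n_genes)
  for (k in seq_len(kappa)) {
    genes <- sample.int(n_genes, n_markers)
    shift[k, genes] <- effect * sample(c(-1, 1), n_markers, replace = TRUE)
  }
  expr <- shift[as.integer(truth), , drop = FALSE] +
    matrix(stats::rnorm(n_samples * n_genes, sd = noise_sd), n_samples, n_genes)
  dimnames(expr) <- list(ids, sprintf("g%04d", seq_len(n_genes)))
  signal <- as.character(truth)
  if (missing_frac > 0) {
    signal[sample.int(n_samples, round(missing_frac * n_samples))] <- NA
  }
  clinical <- tibble::tibble(sample_id = ids, signal = signal)
  for (j in seq_len(n_null_labels)) {
    clinical[[paste0("null_", j)]] <-
      sample(classes, n_samples, replace = TRUE)
  }
  names(truth) <- ids
  list(expr = expr, clinical = clinical, truth = truth)
}

#' Write a simulated fixture set to disk
#'
#' Materializes the TSV files the command-line interface reads: the expression
#' matrix (genes as rows, samples as columns) and the clinical table.
#'
#' @param dir Output directory (created if needed).
#' @param ... Passed to [simulate_labeled_expression()].
#' @return Invisibly, the paths written.
#' @export
write_fixture_set <- function(dir, ...) {
  sim <- simulate_labeled_expression(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  m <- t(sim$expr) # genes as rows, samples as columns
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clinical, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(expression = expr_path, clinical = clin_path))
}
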
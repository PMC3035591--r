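#' Empirical p-value of an observed Tree Index
#'
#' The fraction of permutation-null TIs at or above the observed value,
#' floored at `1/r`: even when no permuted TI reaches the observed one the
#' smallest achievable p-value is `1/r`, so `r > 1000` permutations are needed
#' before a rejection at the 0.1% level is possible at all. The default tail
#' comparator is "equal or higher" (`>=`); the strict variant (`>`) is
#' available for reproduction studies.
#'
#' @param observed_ti Observed Tree Index `t`.
#' @param permuted_tis Numeric vector of null TIs `t_i` (from
#'   [estimate_ti_min()], whose draws serve double duty).
#' @param tail `"geq"` (default) counts `t_i >= t`; `"gt"` counts `t_i > t`.
#' @return The empirical p-value in `[1/r, 1]`.
#' @examples
#' empirical_p(2, rep(1, 100)) # 1/100 floor
#' @export
empirical_p <- function(observed_ti, permuted_tis, tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  r <- length(permuted_tis)
  if (r == 0) stop("no permuted TIs supplied", call. = FALSE)
  # guard against float round-off splitting exact ties (index values of
  # permutations are sums of the same log-gamma terms in different orders)
  eps <- 1e-9 * max(1, abs(observed_ti))
  k <- if (tail == "geq") sum(permuted_tis >= observed_ti - eps)
       else sum(permuted_tis > observed_ti + eps)
  max(k / r, 1 / r)
}

#' Significance stars for a p-value
#'
#' @param p A p-value in `(0, 1]`.
#' @return An integer 0-3: 3 if `p < 0.001`, 2 if `p < 0.01`, 1 if `p < 0.05`,
#'   else 0 (the null of no correlation cannot be rejected).
#' @examples
#' stars(0.1846) # 0: no significant correlation
#' @export
stars <- function(p) {
  as.integer(p < 0.05) + as.integer(p < 0.01) + as.integer(p < 0.001)
}

format_stars <- function(s) vapply(s, function(x) strrep("*", x), character(1))

#' Evaluate one label against a cluster tree
#'
#' The full single-label analysis: observed Tree Index, Monte-Carlo envelope
#' (`TI_min` from label permutations on the fixed tree, `TI_max` from random
#' ordered trees), Normalized Tree Index, and the empirical p-value. The
#' permutation draws used for `TI_min` are reused as the null distribution of
#' the p-value; the p-value attached to the NTI is the TI's p-value, since the
#' normalization only shifts and scales the index and leaves tail fractions
#' unchanged. The null keeps the observed tree fixed and permutes only the
#' labels; randomizing the tree as well would inflate the search space and
#' answer a different question.
#'
#' @inheritParams estimate_ti_min
#' @param tail Tail comparator for the p-value, see [empirical_p()].
#' @param label_name Name recorded in the result (defaults to `"label"`).
#' @return An object of class `nti_result`: a list with `label_name`, `kappa`,
#'   `n_missing`, `ti`, `ti_min`, `ti_max`, `nti`, `p_value`, `stars`, `r`,
#'   `clamped`, plus the null draws (`permuted_tis`) and the per-split
#'   diagnostics of the observed tree. See [tidy.nti_result()] and
#'   [glance.nti_result()].
#' @examples
#' tr <- read_tree("((A,B),(C,D));")
#' res <- evaluate_label(tr, c(A = 1, B = 1, C = 2, D = 2), r = 500, seed = 1)
#' res$nti
#' @export
evaluate_label <- function(tree, labels, r = 10000, seed = NULL,
                           tail = c("geq", "gt"),
                           degenerate = c("include", "skip"),
                           label_name = "label") {
  tail <- match.arg(tail)
  degenerate <- match.arg(degenerate)
  if (!is.null(seed)) set.seed(seed)
  labels <- align_labels(labels, tree)
  lc <- label_codes(labels)
  if (all(lc$codes == 0L))
    stop("all labels are missing for '", label_name, "'", call. = FALSE)
  obs <- tree_index(tree, labels, degenerate = degenerate)
  if (lc$kappa <= 1) {
    warning("single-class label '", label_name,
            "': no correlation is measurable (NTI = 0, p = 1)")
    return(structure(list(
      label_name = label_name, kappa = lc$kappa,
      n_missing = obs$n_missing, n_used = length(labels) - obs$n_missing,
      ti = obs$ti, ti_min = 0, ti_max = 0, nti = 0,
      p_value = 1, stars = 0L, r = r, clamped = FALSE,
      permuted_tis = rep(obs$ti, r), splits = obs$splits
    ), class = "nti_result"))
  }
  env_min <- estimate_ti_min(tree, labels, r = r, degenerate = degenerate)
  env_max <- estimate_ti_max(labels, r = r, degenerate = degenerate)
  val <- nti(obs$ti, env_min$ti_min, env_max$ti_max)
  p <- empirical_p(obs$ti, env_min$permuted_tis, tail = tail)
  structure(list(
    label_name = label_name, kappa = lc$kappa,
    n_missing = obs$n_missing, n_used = length(labels) - obs$n_missing,
    ti = obs$ti, ti_min = env_min$ti_min, ti_max = env_max$ti_max,
    nti = as.numeric(val), p_value = p, stars = stars(p), r = r,
    clamped = attr(val, "clamped"),
    permuted_tis = env_min$permuted_tis, splits = obs$splits
  ), class = "nti_result")
}

#' @export
print.nti_result <- function(x, ...) {
  cat("NTI evaluation of '", x$label_name, "' (kappa = ", x$kappa,
      ", missing = ", x$n_missing, ")\n", sep = "")
  cat(sprintf("  TI = %.4f  [TI_min = %.4f, TI_max = %.4f]\n",
              x$ti, x$ti_min, x$ti_max))
  cat(sprintf("  NTI = %.4f   p = %.4g %s   (r = %d)\n",
              x$nti, x$p_value, format_stars(x$stars), x$r))
  invisible(x)
}
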
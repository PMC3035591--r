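#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-split diagnostics of a Tree Index
#'
#' @param x A [tree_index()] result.
#' @param ... Unused.
#' @return A tibble with one row per split: `split` (pre-order id), `N`
#'   (non-missing parent size), `n_children`, `probability`, `score`,
#'   `degenerate`.
#' @export
tidy.tree_index <- function(x, ...) x$splits

#' One-row summary of a Tree Index
#'
#' @inheritParams tidy.tree_index
#' @return A one-row tibble: `ti`, `mean_score`, `R`, `kappa`, `n_missing`.
#' @export
glance.tree_index <- function(x, ...) {
  tibble::tibble(ti = x$ti, mean_score = x$mean_score, R = x$R,
                 kappa = x$kappa, n_missing = x$n_missing)
}

#' Per-split diagnostics of a label evaluation
#'
#' @param x An [evaluate_label()] result.
#' @param ... Unused.
#' @return The per-split diagnostic tibble of the observed tree (columns as in
#'   [tidy.tree_index()]).
#' @export
tidy.nti_result <- function(x, ...) x$splits

#' One-row summary of a label evaluation
#'
#' @inheritParams tidy.nti_result
#' @return A one-row tibble: `label_name`, `kappa`, `n_missing`, `ti`,
#'   `ti_min`, `ti_max`, `nti`, `p_value`, `stars`.
#' @export
glance.nti_result <- function(x, ...) {
  tibble::tibble(label_name = x$label_name, kappa = x$kappa,
                 n_missing = x$n_missing, ti = x$ti, ti_min = x$ti_min,
                 ti_max = x$ti_max, nti = x$nti, p_value = x$p_value,
                 stars = x$stars)
}
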
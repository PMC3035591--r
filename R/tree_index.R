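#' Count table of one split
#'
#' Tabulates the class distribution of one split: the parent cluster holds `N`
#' non-missing labelled samples of `kappa` classes (`n`), divided over `l`
#' subclusters of sizes `m` with per-class counts `M`. Missing-labelled leaves
#' are excluded from all counts, the only convention under which the
#' sampling-without-replacement model below stays well-defined.
#'
#' @param split One element of [enumerate_splits()]: a list of character
#'   vectors of sample ids, one per child.
#' @param labels Label vector named by sample id (`NA` = missing).
#' @return A list with `N`, `n` (per-class totals), `m` (per-child sizes),
#'   `M` (l x kappa count matrix), `probability` and `score`.
#' @examples
#' split_counts(list(c("A", "B"), c("C", "D")),
#'              c(A = "x", B = "x", C = "y", D = "y"))
#' @export
split_counts <- function(split, labels) {
  lc <- label_codes(labels)
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by sample id", call. = FALSE)
  M <- t(vapply(split, function(ch) {
    tabulate(lc$codes[match(ch, ids)], nbins = lc$kappa)
  }, integer(lc$kappa)))
  if (lc$kappa == 0) M <- matrix(0L, length(split), 0)
  m <- rowSums(M)
  n <- colSums(M)
  rec <- list(N = sum(m), n = n, m = m, M = M, classes = lc$classes)
  rec$score <- splitting_score(rec)
  rec$probability <- exp(-rec$score)
  rec
}

check_counts <- function(rec) {
  M <- as.matrix(rec$M)
  if (!isTRUE(all.equal(unname(rowSums(M)), unname(as.numeric(rec$m)))) ||
      !isTRUE(all.equal(unname(colSums(M)), unname(as.numeric(rec$n)))) ||
      sum(M) != rec$N || any(M < 0))
    stop("inconsistent split counts: row/column sums of M must equal m and n",
         call. = FALSE)
  invisible(rec)
}

#' Probability of a split's class distribution
#'
#' The probability of drawing the observed subcluster class counts `M` when the
#' `m_i` subcluster members are sampled without replacement from the parent's
#' `N` members with class totals `n` (a product of multivariate hypergeometric
#' terms):
#' \deqn{p(M; N, n, m) = \frac{\prod_i m_i! / \prod_\lambda m_{i\lambda}!}
#'                            {N! / \prod_\lambda n_\lambda!}}
#' Computed in log space via log-gamma and exponentiated; degenerate splits
#' (a single class, a single non-empty subcluster, or `N <= 1`) give 1 by the
#' empty-product convention.
#'
#' @param rec A count record from [split_counts()] (or any list with fields
#'   `N`, `n`, `m`, `M`).
#' @return The probability, in `(0, 1]`.
#' @export
split_probability <- function(rec) {
  exp(-splitting_score(rec))
}

#' Splitting score of one split
#'
#' The negative log of [split_probability()]:
#' \deqn{S_r = \ln N! - \sum_\lambda \ln n_\lambda!
#'       - \sum_i (\ln m_i! - \sum_\lambda \ln m_{i\lambda}!)}
#' evaluated with log-gamma so that parent clusters with thousands of members
#' never overflow.
#'
#' @inheritParams split_probability
#' @return The score, `>= 0`.
#' @export
splitting_score <- function(rec) {
  check_counts(rec)
  s <- lfactorial(rec$N) - sum(lfactorial(rec$n)) -
    sum(lfactorial(rec$m)) + sum(lfactorial(rec$M))
  max(s, 0)
}

#' Tree Index of a labelled cluster tree
#'
#' Scores every split of the tree with [splitting_score()] and returns their
#' population standard deviation,
#' \eqn{TI = \sqrt{(1/R) \sum_r (S_r - \bar S)^2}}, over the `R` splits. A
#' high TI indicates strong correlation between the label and the tree; it is
#' however biased upwards by the number of classes, which is what [nti()]
#' corrects.
#'
#' @param tree An `ape::phylo` cluster tree over the labelled samples.
#' @param labels Label vector, named by sample id or given in tip order
#'   (`NA` = missing).
#' @param degenerate `"include"` (default) keeps degenerate splits (no
#'   non-missing members on more than one side, or `N <= 1`) in `R` with score
#'   0, so `R` stays a pure topology property; `"skip"` drops them from `R`.
#' @return An object of class `tree_index` with fields `ti`, `scores`,
#'   `mean_score`, `R`, `kappa`, `n_missing`, and a per-split diagnostic table
#'   (see [tidy.tree_index()]).
#' @examples
#' tr <- read_tree("((A,B),(C,D));")
#' tree_index(tr, c(A = 1, B = 1, C = 2, D = 2))$ti # ln(6) * sqrt(2) / 3
#' @export
tree_index <- function(tree, labels, degenerate = c("include", "skip")) {
  degenerate <- match.arg(degenerate)
  if (is_single_leaf(tree) || ape::Ntip(tree) < 2)
    stop("tree must have at least 2 leaves", call. = FALSE)
  labels <- align_labels(labels, tree)
  lc <- label_codes(labels)
  idx <- split_index(tree)
  tab <- cpp_split_table(idx$tips, idx$child_ptr, idx$split_ptr,
                         lc$codes, max(lc$kappa, 1L))
  keep <- if (degenerate == "skip") !tab$degenerate else rep(TRUE, length(tab$score))
  scores <- tab$score[keep]
  R <- length(scores)
  ti <- if (R == 0) 0 else {
    m <- mean(scores)
    sqrt(sum((scores - m)^2) / R)
  }
  structure(list(
    ti = ti,
    scores = scores,
    mean_score = if (R) mean(scores) else 0,
    R = R,
    kappa = lc$kappa,
    n_missing = sum(lc$codes == 0L),
    degenerate = degenerate,
    splits = tibble::tibble(
      split = seq_along(tab$score),
      N = tab$N,
      n_children = tab$n_children,
      probability = exp(-tab$score),
      score = tab$score,
      degenerate = tab$degenerate
    )
  ), class = "tree_index")
}

#' @export
print.tree_index <- function(x, ...) {
  cat("Tree Index: ", format(x$ti, digits = 4),
      " (", x$R, " splits, kappa = ", x$kappa,
      ", missing = ", x$n_missing, ")\n", sep = "")
  invisible(x)
}

# fast path: TI from a precomputed split index + integer codes
ti_fast <- function(idx, codes, kappa, skip_degenerate = FALSE) {
  cpp_ti(idx$tips, idx$child_ptr, idx$split_ptr, codes,
         max(kappa, 1L), skip_degenerate)
}
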
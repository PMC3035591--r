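#' Monte-Carlo floor of the Tree Index
#'
#' Permutes the label vector `r` times over the fixed observed tree and
#' computes the Tree Index of each permutation. The minimum estimates
#' `TI_min`, the index value expected when the label is placed on the tree at
#' random; the full set of permuted TIs doubles as the null distribution for
#' the empirical p-value, so one set of draws serves both purposes.
#'
#' @inheritParams tree_index
#' @param r Number of permutations (default 10000).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A list with `ti_min`, `permuted_tis` (length `r`) and `r`.
#' @export
estimate_ti_min <- function(tree, labels, r = 10000, seed = NULL,
                            degenerate = c("include", "skip")) {
  degenerate <- match.arg(degenerate)
  stopifnot(r >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- align_labels(labels, tree)
  lc <- label_codes(labels)
  idx <- split_index(tree)
  tis <- cpp_permuted_tis(idx$tips, idx$child_ptr, idx$split_ptr, lc$codes,
                          max(lc$kappa, 1L), as.integer(r),
                          degenerate == "skip")
  list(ti_min = min(tis), permuted_tis = tis, r = r)
}

#' Build one random ordered tree
#'
#' An ordered tree is the idealized, maximally label-concordant topology: one
#' pure subtree per class, each holding all samples of that class, merged by
#' `kappa - 1` random pairwise joins. The internal shape of each pure subtree
#' does not affect the index (every within-class split has probability 1), so
#' it is drawn as a random caterpillar. Missing-labelled samples are attached
#' as one extra pure subtree; under the missing-exclusion counting rule their
#' placement cannot change the index.
#'
#' @param labels Label vector named by sample id (`NA` = missing).
#' @return A list with `tree` (an `ape::phylo` over all samples) and `labels`
#'   (the same labels, usable directly since leaves keep their sample ids).
#' @export
build_ordered_tree <- function(labels) {
  ids <- names(labels)
  if (is.null(ids)) {
    ids <- paste0("S", seq_along(labels))
    names(labels) <- ids
  }
  lc <- label_codes(labels)
  if (all(lc$codes == 0L)) stop("all labels are missing", call. = FALSE)
  groups <- split(ids, lc$codes)
  # random caterpillar Newick for one group
  caterpillar <- function(v) {
    v <- sample(v)
    nwk <- v[1]
    for (k in seq_along(v)[-1]) nwk <- paste0("(", nwk, ",", v[k], ")")
    nwk
  }
  subs <- vapply(groups, caterpillar, character(1))
  while (length(subs) > 1) {
    pick <- sample.int(length(subs), 2)
    subs <- c(subs[-pick], paste0("(", subs[pick[1]], ",", subs[pick[2]], ")"))
  }
  tree <- read_tree(paste0(subs, ";"))
  list(tree = tree, labels = labels)
}

#' Monte-Carlo ceiling of the Tree Index
#'
#' Draws `r` random ordered trees (see [build_ordered_tree()]) for the given
#' label and returns the maximum Tree Index over the draws as the estimate of
#' `TI_max`. Only the `kappa - 1` join splits of an ordered tree can score
#' non-zero, so each draw is simulated directly on per-class counts.
#'
#' @inheritParams estimate_ti_min
#' @param labels Label vector (`NA` = missing).
#' @return A list with `ti_max`, `ordered_tis` (length `r`) and `r`.
#' @export
estimate_ti_max <- function(labels, r = 10000, seed = NULL,
                            degenerate = c("include", "skip")) {
  degenerate <- match.arg(degenerate)
  stopifnot(r >= 1)
  if (!is.null(seed)) set.seed(seed)
  lc <- label_codes(labels)
  if (lc$kappa <= 1) {
    if (lc$kappa == 1)
      warning("single-class label: TI_max = 0 and the index cannot be normalized")
    return(list(ti_max = 0, ordered_tis = rep(0, r), r = r))
  }
  counts <- tabulate(lc$codes[lc$codes > 0L], nbins = lc$kappa)
  tis <- cpp_ordered_tis(as.integer(counts), sum(lc$codes == 0L),
                         as.integer(r), degenerate == "skip")
  list(ti_max = max(tis), ordered_tis = tis, r = r)
}

#' Normalized Tree Index
#'
#' Rescales an observed Tree Index by its Monte-Carlo envelope,
#' \eqn{NTI = (TI - TI_{min}) / (TI_{max} - TI_{min})}, clamped into
#' `[0, 1]`: the empirical envelope can be overshot in either direction, in
#' which case the index is set to 0 or 1. Frequent clamping means the
#' envelope was estimated with too few repetitions.
#'
#' @param ti Observed Tree Index.
#' @param ti_min,ti_max Envelope estimates from [estimate_ti_min()] and
#'   [estimate_ti_max()].
#' @return The normalized index in `[0, 1]`, with attribute `"clamped"`
#'   (`TRUE` if the raw value fell outside `[0, 1]`). When
#'   `ti_max == ti_min` (e.g. a single-class label) the index is 0 with a
#'   warning.
#' @export
nti <- function(ti, ti_min, ti_max) {
  if (ti_max <= ti_min) {
    warning("degenerate envelope (TI_max = TI_min); NTI set to 0")
    return(structure(0, clamped = FALSE))
  }
  raw <- (ti - ti_min) / (ti_max - ti_min)
  structure(min(max(raw, 0), 1), clamped = (raw < 0 || raw > 1))
}
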
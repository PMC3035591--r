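#' Scale a log-ratio matrix to [-1, 1]
#'
#' Divides log-ratios by a maximum absolute value so that every entry lies in
#' `[-1, 1]`, the range assumed by [correlation_distance()].
#'
#' @param raw A samples x genes numeric matrix of log-ratios (finite values).
#' @param mode `"global_maxabs"` (default) divides the whole matrix by its
#'   matrix-wide maximum absolute value; `"per_gene_maxabs"` divides each gene
#'   column by its own maximum absolute value. An all-zero matrix (or column)
#'   is left at zero.
#' @return The scaled matrix, same dimensions and dimnames.
#' @examples
#' scale_log_ratios(rbind(c(2, -4), c(1, 0)))
#' @export
scale_log_ratios <- function(raw, mode = c("global_maxabs", "per_gene_maxabs")) {
  mode <- match.arg(mode)
  raw <- as.matrix(raw)
  bad <- which(!is.finite(raw))
  if (length(bad)) {
    pos <- arrayInd(utils::head(bad, 5), dim(raw))
    stop("non-finite entries at (row, col): ",
         paste(apply(pos, 1, paste, collapse = ","), collapse = "; "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  if (mode == "global_maxabs") {
    m <- max(abs(raw))
    if (m > 0) raw <- raw / m
  } else {
    m <- apply(abs(raw), 2, max)
    m[m == 0] <- 1
    raw <- sweep(raw, 2, m, "/")
  }
  raw
}

#' Correlation distance between scaled expression profiles
#'
#' The dissimilarity `d_ij = 1/2 - sum_k(x_ik * x_jk) / (2g)` between two
#' length-`g` profiles with entries in `[-1, 1]`. It lies in `[0, 1]`: 0 is
#' attained only by identical sign vectors (every entry +-1), 1 only by
#' antipodal sign vectors. It is an uncentered inner-product dissimilarity,
#' not `1 - ` Pearson correlation; in particular the self-distance of a
#' non-saturated profile is positive.
#'
#' @param x,y Numeric vectors of equal length with entries in `[-1, 1]`.
#' @return A distance in `[0, 1]`.
#' @examples
#' correlation_distance(c(1, 1), c(-1, -1)) # antipodal: 1
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  0.5 - sum(x * y) / (2 * length(x))
}

#' All pairwise correlation distances of a scaled matrix
#'
#' @param x A samples x genes matrix with entries in `[-1, 1]`.
#' @return A symmetric samples x samples matrix of [correlation_distance()]
#'   values.
#' @export
correlation_distance_matrix <- function(x) {
  x <- as.matrix(x)
  d <- 0.5 - tcrossprod(x) / (2 * ncol(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Average-linkage clustering of samples
#'
#' Hierarchical agglomerative clustering (UPGMA) of the rows of a scaled
#' log-ratio matrix under the correlation distance. Merges pick the pair of
#' clusters with the smallest average pairwise distance; exact ties are broken
#' by the lexicographically smallest pair of cluster creation indices (leaves
#' are created first, in row order), so degenerate inputs still yield one
#' deterministic tree.
#'
#' @param x A samples x genes matrix with entries in `[-1, 1]` (see
#'   [scale_log_ratios()]), or `NULL` if `dist` is given.
#' @param dist Optional precomputed symmetric distance matrix (overrides `x`).
#' @return A strictly binary `ape::phylo` tree over the samples, with merge
#'   heights as node depths.
#' @export
cluster_average_linkage <- function(x = NULL, dist = NULL) {
  if (is.null(dist)) {
    if (is.null(x)) stop("need a matrix or a distance matrix", call. = FALSE)
    x <- as.matrix(x)
    if (nrow(x) == 0) stop("no samples to cluster", call. = FALSE)
    dist <- correlation_distance_matrix(x)
  }
  dist <- as.matrix(dist)
  d <- nrow(dist)
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("S", seq_len(d))
  if (d == 1) return(single_leaf_tree(labels))

  # active cluster bookkeeping: creation index (leaves 1..d, merges d+step),
  # size, and current average-linkage distances
  active <- seq_len(d)
  create <- seq_len(d)
  size <- rep(1L, d)
  node_of <- -seq_len(d)       # hclust convention: negative leaf, positive step
  D <- dist
  diag(D) <- Inf
  merge <- matrix(0L, d - 1L, 2L)
  height <- numeric(d - 1L)
  for (step in seq_len(d - 1L)) {
    n <- length(active)
    sub <- D[active, active, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub <= mn + 1e-12 & upper.tri(sub), arr.ind = TRUE)
    # deterministic tie rule: smallest (min, max) pair of creation indices
    ci <- create[active[cand[, 1]]]
    cj <- create[active[cand[, 2]]]
    lo <- pmin(ci, cj); hi <- pmax(ci, cj)
    pick <- order(lo, hi)[1]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    merge[step, ] <- sort(c(node_of[i], node_of[j]))
    height[step] <- D[i, j]
    # UPGMA update into slot i
    wi <- size[i]; wj <- size[j]
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      D[i, others] <- (wi * D[i, others] + wj * D[j, others]) / (wi + wj)
      D[others, i] <- D[i, others]
    }
    size[i] <- wi + wj
    create[i] <- d + step
    node_of[i] <- step
    active <- setdiff(active, j)
  }
  hc <- structure(list(merge = merge, height = cummax_heights(height),
                       order = hclust_leaf_order(merge),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "correlation"),
                  class = "hclust")
  ape::as.phylo(hc)
}

# UPGMA heights are monotone in exact arithmetic; guard against round-off
# inversions so ape accepts the tree
cummax_heights <- function(h) cummax(h)
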
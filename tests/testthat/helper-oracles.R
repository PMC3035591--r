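# Independent oracles used across the suite. All brute-force: enumeration or
# closed forms, never the package's log-gamma / C++ paths.

# --- split probability by exhaustive assignment enumeration -----------------
# Enumerates every way to deal N labelled elements (class codes `pool`) into
# subclusters of sizes m, and returns the fraction whose per-subcluster class
# counts equal M. l <= 3 supported.
enum_split_probability <- function(pool, m, M) {
  N <- length(pool)
  stopifnot(sum(m) == N, length(m) >= 1, length(m) <= 3)
  kappa <- ncol(M)
  counts_of <- function(idx) tabulate(pool[idx], nbins = kappa)
  hits <- 0; total <- 0
  first_sets <- if (m[1] == 0) list(integer(0)) else
    asplit(utils::combn(N, m[1]), 2)
  for (a in first_sets) {
    a <- as.integer(a)
    rest <- setdiff(seq_len(N), a)
    if (length(m) == 1) {
      total <- total + 1
      if (all(counts_of(a) == M[1, ])) hits <- hits + 1
    } else if (length(m) == 2) {
      total <- total + 1
      ok <- all(counts_of(a) == M[1, ]) && all(counts_of(rest) == M[2, ])
      if (ok) hits <- hits + 1
    } else {
      second_sets <- if (m[2] == 0) list(integer(0)) else
        asplit(utils::combn(length(rest), m[2]), 2)
      for (b in second_sets) {
        bidx <- rest[as.integer(b)]
        cidx <- setdiff(rest, bidx)
        total <- total + 1
        ok <- all(counts_of(a) == M[1, ]) && all(counts_of(bidx) == M[2, ]) &&
          all(counts_of(cidx) == M[3, ])
        if (ok) hits <- hits + 1
      }
    }
  }
  hits / total
}

# all l x kappa nonnegative integer matrices with row sums m and column sums n
enum_tables <- function(m, n) {
  l <- length(m); kappa <- length(n)
  out <- list()
  rec <- function(row, remaining_cols, acc) {
    if (row > l) {
      if (all(remaining_cols == 0)) out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    # all compositions of m[row] into kappa parts bounded by remaining_cols
    comp <- function(j, left, parts) {
      if (j > kappa) {
        if (left == 0) rec(row + 1, remaining_cols - parts,
                           rbind(acc, parts))
        return(invisible())
      }
      for (v in 0:min(left, remaining_cols[j])) comp(j + 1, left - v, c(parts, v))
    }
    comp(1, m[row], integer(0))
    invisible()
  }
  rec(1, n, NULL)
  out
}

# all compositions of N into k nonnegative parts
compositions <- function(N, k) {
  if (k == 1) return(list(N))
  out <- list()
  for (v in 0:N) for (rest in compositions(N - v, k - 1))
    out[[length(out) + 1]] <- c(v, rest)
  out
}

# --- brute-force TI extremes ------------------------------------------------
# population-SD Tree Index computed through the exported per-split API only
ti_of <- function(tree, labels) tree_index(tree, labels)$ti

# minimum/maximum TI over every permutation of the label values on a fixed tree
all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))))
}

brute_ti_over_placements <- function(tree, labels) {
  ids <- names(labels)
  vapply(all_permutations(unname(labels)), function(p) {
    names(p) <- ids
    ti_of(tree, p)
  }, numeric(1))
}

# maximum TI over every rooted binary topology with these (fixed) leaf labels
brute_ti_over_topologies <- function(labels) {
  trees <- phangorn::allTrees(length(labels), rooted = TRUE,
                              tip.label = names(labels))
  vapply(trees, function(tr) ti_of(tr, labels), numeric(1))
}

# --- misc helpers -------------------------------------------------------------
random_labeled_tree <- function(d, kappa, missing_frac = 0) {
  tr <- ape::rtree(d, rooted = TRUE)
  lab <- sample(paste0("c", seq_len(kappa)), d, replace = TRUE)
  if (missing_frac > 0) lab[sample.int(d, round(missing_frac * d))] <- NA
  names(lab) <- tr$tip.label
  list(tree = tr, labels = lab)
}

quartet_tree <- function() read_tree("((A,B),(C,D));")
quartet_labels <- function() c(A = "1", B = "1", C = "2", D = "2")
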
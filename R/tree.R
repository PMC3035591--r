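#' Read a cluster tree
#'
#' Reads a rooted cluster tree whose leaves are sample identifiers, either from
#' Newick text (or a file containing it) or from a merge list describing an
#' agglomerative clustering.
#'
#' The merge-list dialect is the common linkage-matrix convention: rows are
#' 0-based agglomeration steps over two integer columns (plus an optional
#' height column); leaves are numbered `0..d-1` and the cluster created at step
#' `s` is node `d + s`. A merge list over `d` leaves therefore has `d - 1`
#' rows and yields a strictly binary tree.
#'
#' @param source Newick text, a path to a file, or (for `dialect =
#'   "merge_list"`) a data frame / matrix with two integer columns and an
#'   optional third height column.
#' @param dialect `"newick"` (default) or `"merge_list"`.
#' @param tip_labels Optional character vector of sample identifiers for the
#'   merge-list dialect (leaf `i` gets `tip_labels[i + 1]`); defaults to
#'   `"0".."d-1"`.
#' @return An `ape::phylo` tree. Every internal node has at least two
#'   children; leaf names are the sample identifiers.
#' @examples
#' tr <- read_tree("((A,B),(C,D));")
#' length(enumerate_splits(tr))
#' @export
read_tree <- function(source, dialect = c("newick", "merge_list"),
                      tip_labels = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "newick") {
    txt <- source
    if (length(txt) == 1 && !grepl(";", txt) && file.exists(txt)) {
      txt <- paste(readLines(txt, warn = FALSE), collapse = "")
    }
    txt <- trimws(txt)
    # ape cannot represent a single-leaf tree; "name;" is handled directly
    if (grepl("^[^();,]+;$", txt)) {
      return(single_leaf_tree(sub(";$", "", txt)))
    }
    tr <- tryCatch(
      suppressWarnings(ape::read.tree(text = txt)),
      error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
    )
    if (is.null(tr)) stop("malformed Newick: could not parse '", txt, "'", call. = FALSE)
    validate_tree(tr)
    tr
  } else {
    merges <- as.matrix(source)
    if (is.character(merges) && length(merges) == 1 && file.exists(source)) {
      merges <- as.matrix(utils::read.table(source, header = FALSE))
    }
    merge_list_to_tree(merges, tip_labels)
  }
}

single_leaf_tree <- function(name) {
  structure(list(tip.label = name, Nnode = 0L,
                 edge = matrix(integer(0), 0, 2)),
            class = c("single_leaf", "phylo"))
}

is_single_leaf <- function(tree) inherits(tree, "single_leaf")

merge_list_to_tree <- function(merges, tip_labels = NULL) {
  if (is.null(dim(merges)) || ncol(merges) < 2)
    stop("merge list needs two integer columns", call. = FALSE)
  heights <- if (ncol(merges) >= 3) as.numeric(merges[, 3]) else seq_len(nrow(merges))
  merges <- merges[, 1:2, drop = FALSE]
  storage.mode(merges) <- "integer"
  d <- nrow(merges) + 1L
  if (is.null(tip_labels)) tip_labels <- as.character(0:(d - 1L))
  if (length(tip_labels) != d)
    stop("need ", d, " tip labels, got ", length(tip_labels), call. = FALSE)
  # convert to hclust convention: negative = leaf (1-based), positive = step
  conv <- function(v) ifelse(v < d, -(v + 1L), v - d + 1L)
  m <- cbind(conv(merges[, 1]), conv(merges[, 2]))
  seen <- logical(2L * d - 1L)
  for (s in seq_len(nrow(merges))) {
    for (id in merges[s, ]) {
      if (id < 0 || id >= d + s - 1)
        stop("merge list row ", s, ": node id ", id, " not yet created", call. = FALSE)
      if (seen[id + 1L])
        stop("merge list row ", s, ": node id ", id, " used twice", call. = FALSE)
      seen[id + 1L] <- TRUE
    }
  }
  hc <- structure(list(merge = m, height = as.numeric(heights),
                       order = hclust_leaf_order(m),
                       labels = tip_labels, method = "average"),
                  class = "hclust")
  tr <- ape::as.phylo(hc)
  validate_tree(tr)
  tr
}

# leaf ordering compatible with a merge matrix (needed for a valid hclust object)
hclust_leaf_order <- function(merge) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

validate_tree <- function(tree) {
  if (is_single_leaf(tree)) return(invisible(tree))
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  tab <- tabulate(tree$edge[, 1], nbins = ape::Ntip(tree) + tree$Nnode)
  internal <- tab[(ape::Ntip(tree) + 1):length(tab)]
  if (any(internal == 1))
    stop("internal node with a single child", call. = FALSE)
  invisible(tree)
}

#' Write a cluster tree to Newick text
#'
#' @param tree An `ape::phylo` tree (multifurcations allowed).
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_tree <- function(tree, file = NULL) {
  txt <- if (is_single_leaf(tree)) paste0(tree$tip.label, ";")
         else ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Enumerate the splits of a cluster tree
#'
#' Each internal node of a rooted cluster tree splits its leaf set into the
#' leaf sets of its children. Splits are returned in pre-order from the root;
#' the Tree Index itself is invariant to split order.
#'
#' @param tree An `ape::phylo` tree.
#' @return A list with one element per internal node; each element is a list of
#'   character vectors, the sample identifiers under each child.
#' @examples
#' enumerate_splits(read_tree("((A,B),(C,D));"))[[1]]
#' @export
enumerate_splits <- function(tree) {
  idx <- split_index(tree)
  lapply(seq_len(length(idx$split_ptr) - 1L), function(r) {
    kids <- (idx$split_ptr[r] + 1L):idx$split_ptr[r + 1L]
    lapply(kids, function(c) {
      tip_i <- idx$tips[(idx$child_ptr[c] + 1L):idx$child_ptr[c + 1L]]
      idx$tip_labels[tip_i]
    })
  })
}

# Flattened split structure consumed by the C++ core:
#   tips (1-based tip indices), child_ptr / split_ptr (0-based offsets),
#   tip_labels. Splits in pre-order from the root.
split_index <- function(tree) {
  validate_tree(tree)
  if (is_single_leaf(tree) || ape::Ntip(tree) < 2) {
    return(list(tips = integer(0), child_ptr = 0L, split_ptr = 0L,
                tip_labels = tree$tip.label))
  }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  # accumulate descendant tip sets bottom-up
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  children <- split(edge[, 2], edge[, 1])
  # pre-order over internal nodes
  root <- ntip + 1L
  order_nodes <- integer(nnode)
  stack <- root; k <- 0L
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; order_nodes[k] <- nd
    kids <- children[[as.character(nd)]]
    kids_int <- kids[kids > ntip]
    if (length(kids_int)) stack <- c(stack, rev(kids_int))
  }
  tips <- integer(0); child_ptr <- 0L; split_ptr <- 0L
  tip_acc <- vector("list", 0); cp <- list(0L)
  n_children_total <- 0L
  child_lengths <- integer(0)
  split_sizes <- integer(nnode)
  all_tips <- vector("list", sum(lengths(children)))
  ci <- 0L
  for (j in seq_len(nnode)) {
    nd <- order_nodes[j]
    kids <- children[[as.character(nd)]]
    split_sizes[j] <- length(kids)
    for (ch in kids) {
      ci <- ci + 1L
      all_tips[[ci]] <- desc[[ch]]
      child_lengths <- c(child_lengths, length(desc[[ch]]))
    }
  }
  tips <- unlist(all_tips[seq_len(ci)], use.names = FALSE)
  child_ptr <- c(0L, cumsum(child_lengths))
  split_ptr <- c(0L, cumsum(split_sizes))
  list(tips = as.integer(tips), child_ptr = as.integer(child_ptr),
       split_ptr = as.integer(split_ptr), tip_labels = tree$tip.label)
}
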
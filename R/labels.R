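#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib ntindex, .registration = TRUE
NULL

# Labels are plain vectors (character / factor / anything coercible) with NA as
# the missing marker. Internally they become integer codes 0 = missing,
# 1..kappa = class, where kappa counts the classes actually present unless a
# factor supplies explicit levels.

label_codes <- function(labels) {
  if (is.factor(labels)) {
    classes <- levels(labels)
    codes <- as.integer(labels)
  } else {
    v <- as.character(labels)
    classes <- sort(unique(v[!is.na(v)]))
    codes <- match(v, classes)
  }
  codes[is.na(codes)] <- 0L
  list(codes = codes, classes = classes, kappa = length(classes))
}

# align a label vector to the tree's tip order; names win over position
align_labels <- function(labels, tree) {
  tips <- tree$tip.label
  if (!is.null(names(labels))) {
    miss <- setdiff(tips, names(labels))
    if (length(miss))
      stop("labels missing for samples: ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    labels[tips]
  } else {
    if (length(labels) != length(tips))
      stop("labels (", length(labels), ") and tree leaves (", length(tips),
           ") differ in length; name the labels by sample id to align them",
           call. = FALSE)
    labels
  }
}

#' Permute a label vector
#'
#' Uniformly random permutation of the full label vector; missing markers are
#' permuted along with the values, so the multiset of values is preserved.
#'
#' @param labels A label vector (`NA` = missing).
#' @return A permutation of `labels`.
#' @export
permute_labels <- function(labels) {
  labels[sample.int(length(labels))]
}
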
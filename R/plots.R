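#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null distribution of one label evaluation
#'
#' Histogram of the permutation-null Tree Indices with the observed TI marked,
#' annotated with the empirical p-value — the tail fraction at or beyond the
#' line.
#'
#' @param object An [evaluate_label()] result.
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nti_result <- function(object, bins = 40, ...) {
  df <- tibble::tibble(ti = object$permuted_tis)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ti)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$ti, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      title = paste0("Permutation null for '", object$label_name, "'"),
      subtitle = sprintf("TI = %.3f, NTI = %.3f, p = %.4g %s (r = %d)",
                         object$ti, object$nti, object$p_value,
                         format_stars(object$stars), object$r),
      x = "Tree Index under permuted labels", y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Screening report overview
#'
#' Bar chart of the Normalized Tree Index per clinical parameter, ordered by
#' NTI, with significance stars above each bar (one/two/three for the 5%, 1%
#' and 0.1% levels).
#'
#' @param object An [nti_screen()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nti_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$nti)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = format_stars(.data$stars)),
                       vjust = -0.2, hjust = 0.5, size = 5) +
    ggplot2::coord_flip(ylim = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "Normalized Tree Index",
                  title = "Label-cluster correlation screening") +
    ggplot2::theme_minimal()
}

#' Dendrogram colored by a label
#'
#' Draws the cluster tree with leaves colored by class and missing labels in
#' black. A branch takes a class color only when every non-missing leaf below
#' it belongs to that class; mixed branches are neutral grey. Optionally
#' annotated with the evaluation result.
#'
#' @param tree An `ape::phylo` cluster tree.
#' @param labels Label vector named by sample id (`NA` = missing).
#' @param result Optional [evaluate_label()] result for the annotation line.
#' @param palette Class colors (recycled from a fixed default palette).
#' @return A ggplot object.
#' @export
plot_colored_tree <- function(tree, labels, result = NULL, palette = NULL) {
  labels <- align_labels(labels, tree)
  lc <- label_codes(labels)
  if (is.null(palette))
    palette <- rep(c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
                     "#A65628", "#F781BF", "#17BECF"),
                   length.out = max(lc$kappa, 1))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  # node depths: leaf = 0, parent = child max + 1 (cladogram layout)
  depth <- numeric(ntip + nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    depth[p] <- max(depth[p], depth[ch] + 1)
  }
  # x positions: leaves in plotting order, internal nodes at child mean
  xpos <- numeric(ntip + nnode)
  ord <- hclust_like_order(tr)
  xpos[ord] <- seq_len(ntip)
  for (e in seq_len(nrow(tr$edge))) { # postorder: children first
    p <- tr$edge[e, 1]
    kids <- tr$edge[tr$edge[, 1] == p, 2]
    xpos[p] <- mean(xpos[kids])
  }
  # per-node class: 0 = mixed, -1 = missing-only, lambda = pure class
  node_class <- integer(ntip + nnode)
  node_class[seq_len(ntip)] <- ifelse(lc$codes == 0L, -1L, lc$codes)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    kids <- tr$edge[tr$edge[, 1] == p, 2]
    cls <- unique(node_class[kids])
    cls_nm <- setdiff(cls, -1L)
    node_class[p] <- if (length(cls_nm) == 1 && all(cls_nm != 0)) cls_nm
                     else if (length(cls_nm) == 0) -1L else 0L
  }
  col_of <- function(cl) {
    ifelse(cl > 0, palette[pmax(cl, 1)], ifelse(cl == -1L, "black", "grey55"))
  }
  segs <- do.call(rbind, lapply(seq_len(nrow(tr$edge)), function(e) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    rbind(
      data.frame(x = xpos[ch], xend = xpos[ch], y = depth[p], yend = depth[ch],
                 col = col_of(node_class[ch])),
      data.frame(x = xpos[p], xend = xpos[ch], y = depth[p], yend = depth[p],
                 col = col_of(node_class[ch]))
    )
  }))
  tipdf <- data.frame(x = xpos[seq_len(ntip)], y = -0.15,
                      label = tr$tip.label,
                      col = col_of(node_class[seq_len(ntip)]))
  sub <- if (!is.null(result))
    sprintf("TI = %.3f, NTI = %.3f, p = %.4g %s", result$ti, result$nti,
            result$p_value, format_stars(result$stars))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          colour = segs$col, linewidth = 0.6) +
    ggplot2::geom_text(data = tipdf,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       colour = tipdf$col, angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.18 * max(depth) - 0.5, NA)) +
    ggplot2::labs(title = if (!is.null(result)) result$label_name,
                  subtitle = sub, x = NULL, y = "merge depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

# left-to-right tip order implied by the tree's edge structure
hclust_like_order <- function(tr) {
  ntip <- ape::Ntip(tr)
  cw <- stats::reorder(tr, "cladewise")
  cw$edge[cw$edge[, 2] <= ntip, 2]
}
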
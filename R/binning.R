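#' Binning rule for one clinical column
#'
#' The index operates on nominal labels only, so ordinal and interval clinical
#' columns must first be reduced to a few categories, and sparse nominal
#' categories may be merged. A `binning_spec` captures one such rule.
#'
#' @param column Column name the rule applies to.
#' @param kind `"passthrough"` (nominal as-is, default), `"interval_bins"`
#'   (numeric values cut at `breaks`), or `"category_merge"` (raw categories
#'   renamed/merged via `merge_map`).
#' @param breaks Strictly increasing numeric cut points for
#'   `"interval_bins"`; `breaks[i]` is the lower edge of category `i` and the
#'   last category is unbounded above. With the default left-closed
#'   convention, category `i` covers `[breaks[i], breaks[i+1])` — e.g. body
#'   mass index breaks `c(18.5, 25, 30)` put 25 in the second (overweight)
#'   category. Values below `breaks[1]` are unmapped (missing, with a
#'   warning).
#' @param categories Output class names; for `"interval_bins"` one per break.
#' @param merge_map Named character vector `raw -> merged` for
#'   `"category_merge"`; raw categories absent from the map are unmapped.
#' @param missing_tokens Raw strings treated as missing (default `""`, `"NA"`,
#'   `"?"`).
#' @param closed `"left"` (default, `[a, b)`) or `"right"` (`(a, b]`) bin
#'   boundary convention.
#' @return A `binning_spec` object.
#' @export
binning_spec <- function(column,
                         kind = c("passthrough", "interval_bins", "category_merge"),
                         breaks = NULL, categories = NULL, merge_map = NULL,
                         missing_tokens = c("", "NA", "?"),
                         closed = c("left", "right")) {
  kind <- match.arg(kind)
  closed <- match.arg(closed)
  if (!is.null(breaks)) breaks <- as.numeric(unlist(breaks))
  if (kind == "interval_bins") {
    if (is.null(breaks) || anyNA(breaks) || is.unsorted(breaks, strictly = TRUE))
      stop("interval_bins needs strictly increasing breaks", call. = FALSE)
    if (is.null(categories)) categories <- paste0("bin", seq_along(breaks))
    if (length(categories) != length(breaks))
      stop("need one category per break (", length(breaks), "), got ",
           length(categories), call. = FALSE)
  }
  if (kind == "category_merge") {
    if (is.null(merge_map) || is.null(names(merge_map)))
      stop("category_merge needs a named merge_map", call. = FALSE)
    if (anyDuplicated(names(merge_map)))
      stop("raw category mapped twice: ",
           names(merge_map)[duplicated(names(merge_map))][1], call. = FALSE)
    if (is.null(categories)) categories <- unique(unname(merge_map))
  }
  structure(list(column = column, kind = kind, breaks = breaks,
                 categories = categories, merge_map = merge_map,
                 missing_tokens = missing_tokens, closed = closed),
            class = "binning_spec")
}

#' Apply a binning rule to a raw clinical column
#'
#' @param raw Vector of raw values (numeric for interval rules, otherwise
#'   coerced to character).
#' @param spec A [binning_spec()].
#' @return A factor label vector; unmapped or missing raw values become `NA`
#'   (with a warning for unmapped ones).
#' @examples
#' bmi <- binning_spec("BMI", "interval_bins", breaks = c(18.5, 25, 30),
#'                     categories = c("normal", "overweight", "obese"))
#' bin_column(c(22, 27.3, 31, NA), bmi)
#' @export
bin_column <- function(raw, spec) {
  stopifnot(inherits(spec, "binning_spec"))
  chr <- as.character(raw)
  chr[chr %in% spec$missing_tokens] <- NA
  if (spec$kind == "passthrough") {
    return(factor(chr))
  }
  if (spec$kind == "interval_bins") {
    num <- suppressWarnings(as.numeric(chr))
    non_numeric <- !is.na(chr) & is.na(num)
    idx <- findInterval(num, spec$breaks, left.open = (spec$closed == "right"))
    idx[idx == 0] <- NA
    unmapped <- (!is.na(num) & is.na(idx)) | non_numeric
    if (any(unmapped))
      warning(sum(unmapped), " value(s) in '", spec$column,
              "' below the first break or non-numeric; treated as missing")
    out <- spec$categories[idx]
    out[non_numeric] <- NA
    return(factor(out, levels = spec$categories))
  }
  # category_merge
  out <- unname(spec$merge_map[chr])
  unmapped <- !is.na(chr) & is.na(out)
  if (any(unmapped))
    warning(sum(unmapped), " raw categor(ies) in '", spec$column,
            "' not covered by the merge map (",
            paste(utils::head(unique(chr[unmapped]), 3), collapse = ", "),
            "); treated as missing")
  factor(out, levels = spec$categories)
}

#' Load a binning configuration
#'
#' Reads a YAML configuration with one entry per clinical column under a
#' top-level `columns:` key; columns without an entry default to nominal
#' passthrough. Each entry has the fields of [binning_spec()], e.g.
#'
#' ```yaml
#' columns:
#'   BMI:
#'     kind: interval_bins
#'     breaks: [18.5, 25, 30]
#'     categories: [normal, overweight, obese]
#' ```
#'
#' @param source Path to a YAML file, or YAML text.
#' @return A named list of [binning_spec()] objects.
#' @export
load_binning_config <- function(source) {
  cfg <- if (length(source) == 1 && file.exists(source)) yaml::read_yaml(source)
         else yaml::yaml.load(paste(source, collapse = "\n"))
  cols <- cfg$columns
  if (is.null(cols)) return(list())
  if (anyDuplicated(names(cols)))
    stop("duplicate column spec: ", names(cols)[duplicated(names(cols))][1],
         call. = FALSE)
  out <- lapply(names(cols), function(nm) {
    e <- cols[[nm]]
    binning_spec(
      column = nm,
      kind = e$kind %||% "passthrough",
      breaks = e$breaks,
      categories = if (!is.null(e$categories)) as.character(e$categories),
      merge_map = if (!is.null(e$merge)) unlist(e$merge),
      missing_tokens = if (!is.null(e$missing_tokens)) as.character(e$missing_tokens)
                       else c("", "NA", "?"),
      closed = e$closed %||% "left"
    )
  })
  names(out) <- names(cols)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
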
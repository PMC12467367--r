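#' Define a clinical ordinal scale
#'
#' A scale specification describes the instrument independently of any data:
#' the ordered items, the category-count groups they belong to, and the
#' scoring polarity. Items within a group share the number of active rating
#' categories (and, under the grouped-threshold model, the category
#' thresholds). Categories are coded `0 .. n_categories - 1`, with 0 the
#' least of the measured attribute within the item (e.g. no impairment
#' impact, or most independent).
#'
#' @param scale_id single string identifying the scale.
#' @param items data frame with columns `item_id`, `label`, `domain_tag`,
#'   `group_id` (one row per item, in instrument order). `label` and
#'   `domain_tag` may be omitted and default to the item id and `""`.
#' @param groups data frame with columns `group_id`, `n_categories`.
#' @param polarity `"higher_is_better"` (e.g. independence scales) or
#'   `"higher_is_worse"` (e.g. impairment-impact scales). Polarity is
#'   metadata: all internal arithmetic uses raw categories; reporting layers
#'   use it to label the direction of improvement.
#' @param domain_vocabulary character vector of admissible `domain_tag`
#'   values; the default covers dressing, grooming, transfer/mobility,
#'   feeding, communication and pervasive item domains plus the empty tag.
#'
#' @return An object of class `scale_spec`.
#' @examples
#' spec <- scale_spec(
#'   "toy",
#'   items  = data.frame(item_id = c("a", "b", "c"),
#'                       group_id = c("dich", "dich", "tri")),
#'   groups = data.frame(group_id = c("dich", "tri"), n_categories = c(2, 3)))
#' spec
#' @export
scale_spec <- function(scale_id, items, groups,
                       polarity = c("higher_is_worse", "higher_is_better"),
                       domain_vocabulary = c("D", "G", "T", "F", "C", "P", "")) {
  polarity <- match.arg(polarity)
  if (!is.character(scale_id) || length(scale_id) != 1L || !nzchar(scale_id))
    stop_rk("scale_id must be a non-empty string", "raschkey_validation_error")
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  if (!all(c("item_id", "group_id") %in% names(items)))
    stop_rk("items needs columns item_id and group_id",
            "raschkey_validation_error")
  if (is.null(items$label)) items$label <- items$item_id
  if (is.null(items$domain_tag)) items$domain_tag <- ""
  items <- items[, c("item_id", "label", "domain_tag", "group_id")]
  if (!all(c("group_id", "n_categories") %in% names(groups)))
    stop_rk("groups needs columns group_id and n_categories",
            "raschkey_validation_error")
  groups <- groups[, c("group_id", "n_categories")]
  groups$n_categories <- as.integer(groups$n_categories)

  if (nrow(items) < 2L)
    stop_rk("a scale needs at least 2 items", "raschkey_validation_error")
  if (anyDuplicated(items$item_id))
    stop_rk(sprintf("duplicate item ids: %s",
                    paste(unique(items$item_id[duplicated(items$item_id)]),
                          collapse = ", ")),
            "raschkey_validation_error")
  if (anyDuplicated(groups$group_id))
    stop_rk("duplicate group ids", "raschkey_validation_error")
  bad <- setdiff(items$group_id, groups$group_id)
  if (length(bad))
    stop_rk(sprintf("items reference unknown groups: %s",
                    paste(bad, collapse = ", ")),
            "raschkey_validation_error")
  if (any(groups$n_categories < 2L))
    stop_rk("every group needs n_categories >= 2", "raschkey_validation_error")
  if (any(!items$domain_tag %in% domain_vocabulary))
    stop_rk(sprintf("domain tags outside the vocabulary: %s",
                    paste(setdiff(items$domain_tag, domain_vocabulary),
                          collapse = ", ")),
            "raschkey_validation_error")

  structure(list(scale_id = scale_id, items = items, groups = groups,
                 polarity = polarity,
                 domain_vocabulary = domain_vocabulary),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec '%s'>\n", x$scale_id))
  cat(sprintf("  %d items in %d category-count group(s); polarity: %s\n",
              nrow(x$items), nrow(x$groups), x$polarity))
  tab <- table(factor(x$items$group_id, levels = x$groups$group_id))
  for (g in x$groups$group_id)
    cat(sprintf("  group '%s': %d categories, %d item(s)\n", g,
                x$groups$n_categories[x$groups$group_id == g], tab[[g]]))
  cat(sprintf("  maximum raw score: %d\n", max_raw_score(x)))
  invisible(x)
}

#' Number of categories per item
#' @param spec a [scale_spec()].
#' @param item_ids items to look up (default: all, in order).
#' @return Integer vector of category counts, named by item id.
#' @export
item_categories <- function(spec, item_ids = spec$items$item_id) {
  stopifnot(inherits(spec, "scale_spec"))
  idx <- match(item_ids, spec$items$item_id)
  if (anyNA(idx))
    stop_rk(sprintf("unknown items: %s",
                    paste(item_ids[is.na(idx)], collapse = ", ")),
            "raschkey_config_error")
  m <- spec$groups$n_categories[match(spec$items$group_id[idx],
                                      spec$groups$group_id)]
  names(m) <- item_ids
  m
}

#' Maximum attainable raw score of a scale (or an item subset)
#' @inheritParams item_categories
#' @return Integer: sum over items of (number of categories - 1).
#' @export
max_raw_score <- function(spec, item_ids = spec$items$item_id) {
  sum(item_categories(spec, item_ids) - 1L)
}

#' Read / write scale specifications as JSON
#'
#' Serialization is schema-versioned and key-ordered so that a
#' read-then-write round trip is byte-identical.
#'
#' @param spec a [scale_spec()].
#' @param path file path.
#' @return `write_scale_spec` returns `path` invisibly; `read_scale_spec`
#'   returns a [scale_spec()].
#' @export
write_scale_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scale_spec"))
  x <- list(
    schema = "raschkey/scale_spec/1",
    scale_id = spec$scale_id,
    polarity = spec$polarity,
    domain_vocabulary = spec$domain_vocabulary,
    groups = spec$groups,
    items = spec$items)
  write_json_canonical(x, path)
}

#' @rdname write_scale_spec
#' @export
read_scale_spec <- function(path) {
  x <- read_json_file(path)
  if (!identical(x$schema, "raschkey/scale_spec/1"))
    stop_rk(sprintf("unrecognized scale_spec schema in %s", path),
            "raschkey_io_error")
  scale_spec(x$scale_id, x$items, x$groups, polarity = x$polarity,
             domain_vocabulary = x$domain_vocabulary)
}
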
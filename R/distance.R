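# Nested-object edit distance.
#
# The distance between two message trees is the number of leaf paths present
# in exactly one tree plus the number of shared paths with unequal values.
# Repeated sub-lists inside a message are first aligned by the minimal-cost
# pairing of their items (recursively), so list order never creates spurious
# edits. distance(x, EMPTY) equals the number of populated leaves of x.

# Scalar equality: numbers compare after numeric parse (5 == 5.0, "5" == 5);
# otherwise strings compare exactly after trimming outer whitespace.
scalar_equal <- function(a, b) {
  na <- suppressWarnings(as.numeric(a))
  nb <- suppressWarnings(as.numeric(b))
  if (!is.na(na) && !is.na(nb)) return(isTRUE(na == nb))
  if (is.character(a) && is.character(b)) return(str_trim(a) == str_trim(b))
  isTRUE(a == b)
}

empty_diff <- function() {
  tibble(
    path_gt = character(), path_pred = character(),
    value_gt = list(), value_pred = list(),
    status = character()
  )
}

diff_row <- function(path_gt, path_pred, value_gt, value_pred, status) {
  tibble(
    path_gt = path_gt, path_pred = path_pred,
    value_gt = list(value_gt), value_pred = list(value_pred),
    status = status
  )
}

# All leaves of one side, labelled as removal (side = "gt") or addition.
one_sided_diff <- function(x, path, side) {
  rows <- walk_leaves(x, concrete = path, general = path)
  if (length(rows) == 0) return(empty_diff())
  if (side == "gt") {
    tibble(
      path_gt = map_chr(rows, "path"), path_pred = NA_character_,
      value_gt = map(rows, "value"), value_pred = rep(list(NULL), length(rows)),
      status = "removal"
    )
  } else {
    tibble(
      path_gt = NA_character_, path_pred = map_chr(rows, "path"),
      value_gt = rep(list(NULL), length(rows)), value_pred = map(rows, "value"),
      status = "addition"
    )
  }
}

#' Leaf-level diff of two message trees
#'
#' Aligns two trees and classifies every leaf as `accurate` (shared path,
#' equal value), `alteration` (shared path, unequal value), `removal`
#' (ground-truth only) or `addition` (prediction only). Repeated sub-lists
#' are aligned by minimal-cost bipartite pairing before comparison.
#'
#' @param gt,pred Message trees; either may be `NULL` (the empty message).
#' @param path_gt,path_pred Path prefixes used for reported leaf paths.
#' @return A tibble with columns `path_gt`, `path_pred`, `value_gt`,
#'   `value_pred`, `status`.
#' @export
node_diff <- function(gt, pred, path_gt = "", path_pred = path_gt) {
  gt_empty <- is.null(gt) || (is.list(gt) && length(gt) == 0)
  pred_empty <- is.null(pred) || (is.list(pred) && length(pred) == 0)
  if (gt_empty && pred_empty) return(empty_diff())
  if (gt_empty) return(one_sided_diff(pred, path_pred, "pred"))
  if (pred_empty) return(one_sided_diff(gt, path_gt, "gt"))

  if (is_scalar_leaf(gt) && is_scalar_leaf(pred)) {
    status <- if (scalar_equal(gt, pred)) "accurate" else "alteration"
    return(diff_row(path_gt, path_pred, gt, pred, status))
  }
  if (is.atomic(gt)) gt <- as.list(gt)
  if (is.atomic(pred)) pred <- as.list(pred)

  gt_obj <- is.list(gt) && !is.null(names(gt))
  pred_obj <- is.list(pred) && !is.null(names(pred))
  gt_arr <- is.list(gt) && is.null(names(gt))
  pred_arr <- is.list(pred) && is.null(names(pred))

  if (gt_obj && pred_obj) {
    nms <- union(names(gt), names(pred))
    out <- lapply(nms, function(nm) {
      sub_gt <- if (nzchar(path_gt)) paste0(path_gt, ".", nm) else nm
      sub_pred <- if (nzchar(path_pred)) paste0(path_pred, ".", nm) else nm
      node_diff(gt[[nm]], pred[[nm]], sub_gt, sub_pred)
    })
    return(bind_rows(out))
  }
  if (gt_arr && pred_arr) {
    n <- max(length(gt), length(pred))
    cost <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        a <- if (i <= length(gt)) gt[[i]] else NULL
        b <- if (j <= length(pred)) pred[[j]] else NULL
        cost[i, j] <- node_distance(a, b)
      }
    }
    assign <- solve_assignment(cost)
    assign <- canonicalize_assignment(cost, assign)
    out <- lapply(seq_len(n), function(i) {
      j <- assign[i]
      a <- if (i <= length(gt)) gt[[i]] else NULL
      b <- if (j <= length(pred)) pred[[j]] else NULL
      node_diff(
        a, b,
        paste0(path_gt, "[", i - 1L, "]"),
        paste0(path_pred, "[", j - 1L, "]")
      )
    })
    return(bind_rows(out))
  }
  # structural mismatch (scalar vs container, object vs array): no shared
  # leaf paths, so both sides count in full
  bind_rows(
    one_sided_diff(gt, path_gt, "gt"),
    one_sided_diff(pred, path_pred, "pred")
  )
}

#' Nested edit distance between two messages
#'
#' A symmetric premetric on message trees: the number of leaf paths present
#' in exactly one tree plus the number of shared paths whose values differ,
#' with repeated sub-lists aligned by minimal-cost pairing. The distance to
#' the empty message equals the number of populated leaves.
#'
#' @param gt,pred Message trees; `NULL` denotes the empty message.
#' @return A non-negative count; `0` iff the trees have identical leaf sets.
#' @export
#' @examples
#' a <- parse_record('{"amount": {"mass": {"value": 5, "units": "GRAM"}}}')
#' b <- parse_record('{"amount": {"mass": {"value": 7, "units": "GRAM"}}}')
#' node_distance(a, b) # one altered leaf
#' node_distance(a, NULL) # two populated leaves
node_distance <- function(gt, pred) {
  gt_empty <- is.null(gt) || (is.list(gt) && length(gt) == 0)
  pred_empty <- is.null(pred) || (is.list(pred) && length(pred) == 0)
  if (gt_empty && pred_empty) return(0)
  if (gt_empty) return(n_leaves(pred))
  if (pred_empty) return(n_leaves(gt))
  if (is_scalar_leaf(gt) && is_scalar_leaf(pred)) {
    return(if (scalar_equal(gt, pred)) 0 else 1)
  }
  if (is.atomic(gt)) gt <- as.list(gt)
  if (is.atomic(pred)) pred <- as.list(pred)
  gt_named <- !is.null(names(gt))
  pred_named <- !is.null(names(pred))
  if (gt_named && pred_named) {
    nms <- union(names(gt), names(pred))
    return(sum(vapply(
      nms, function(nm) node_distance(gt[[nm]], pred[[nm]]), numeric(1)
    )))
  }
  if (!gt_named && !pred_named && is.list(gt) && is.list(pred)) {
    n <- max(length(gt), length(pred))
    cost <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        a <- if (i <= length(gt)) gt[[i]] else NULL
        b <- if (j <= length(pred)) pred[[j]] else NULL
        cost[i, j] <- node_distance(a, b)
      }
    }
    assign <- solve_assignment(cost)
    return(sum(cost[cbind(seq_len(n), assign)]))
  }
  # structural mismatch: no shared leaf paths
  n_leaves(gt) + n_leaves(pred)
}
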
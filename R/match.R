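# Padded bijective matching of message lists and failure-mode attribution.

#' Match two lists of messages by minimal total nested distance
#'
#' The shorter list is padded with empty messages so both lists have equal
#' size, and a bijection minimizing the summed [node_distance()] is found.
#' Each matched pair is attributed a failure mode: `ACCURATE` (distance 0),
#' `ALTERATION` (both real, distance > 0), `REMOVAL` (ground truth paired
#' with a pad) or `ADDITION` (prediction paired with a pad). Ties among
#' equal-cost bijections are broken deterministically, preferring the lower
#' prediction index for the lower ground-truth index.
#'
#' @param gt_list,pred_list Lists of message trees of a common message type.
#' @return A tibble with columns `gt_index`, `pred_index` (`NA` marks a
#'   pad), `distance` and `mode`.
#' @export
#' @examples
#' a <- parse_record('{"identifiers": [{"type": "NAME", "value": "THF"}]}')
#' b <- parse_record('{"identifiers": [{"type": "NAME", "value": "NaH"}]}')
#' match_messages(list(a), list(a, b))
match_messages <- function(gt_list, pred_list) {
  n_gt <- length(gt_list)
  n_pred <- length(pred_list)
  n <- max(n_gt, n_pred)
  if (n == 0L) {
    return(tibble(
      gt_index = integer(), pred_index = integer(),
      distance = numeric(), mode = character()
    ))
  }
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- if (i <= n_gt) gt_list[[i]] else NULL
      b <- if (j <= n_pred) pred_list[[j]] else NULL
      cost[i, j] <- node_distance(a, b)
    }
  }
  assign <- canonicalize_assignment(cost, solve_assignment(cost))
  tibble(
    gt_index = ifelse(seq_len(n) <= n_gt, seq_len(n), NA_integer_),
    pred_index = ifelse(assign <= n_pred, assign, NA_integer_),
    distance = cost[cbind(seq_len(n), assign)],
    mode = pmap_mode(seq_len(n) <= n_gt, assign <= n_pred, cost[cbind(seq_len(n), assign)])
  )
}

pmap_mode <- function(gt_real, pred_real, distance) {
  mode <- character(length(gt_real))
  mode[!pred_real] <- "REMOVAL"
  mode[!gt_real] <- "ADDITION"
  both <- gt_real & pred_real
  mode[both & distance == 0] <- "ACCURATE"
  mode[both & distance > 0] <- "ALTERATION"
  mode
}

#' Tally failure modes over matched message pairs
#'
#' @param pairs A tibble from [match_messages()].
#' @param message_type Label recorded in the output.
#' @return A one-row tibble with columns `message_type`, `accurate`,
#'   `removal`, `addition`, `alteration` and `total`; `total` counts
#'   ground-truth messages only (`accurate + removal + alteration`),
#'   additions being extra to ground truth.
#' @export
classify_messages <- function(pairs, message_type = "message") {
  tibble(
    message_type = message_type,
    accurate = sum(pairs$mode == "ACCURATE"),
    removal = sum(pairs$mode == "REMOVAL"),
    addition = sum(pairs$mode == "ADDITION"),
    alteration = sum(pairs$mode == "ALTERATION"),
    total = sum(pairs$mode != "ADDITION")
  )
}

# Field-type bucket for a leaf path, given the message type it belongs to.
leaf_bucket <- function(path, message_type) {
  if (message_type == "ReactionConditions") return(rep("condition", length(path)))
  if (message_type == "ReactionWorkup") return(rep("workup", length(path)))
  out <- rep("other", length(path))
  out[str_detect(path, "(^|\\.)identifiers\\[")] <- "identifiers"
  out[str_detect(path, "(^|\\.)amount\\.")] <- "amount"
  out[str_detect(path, "(^|\\.)reaction_role$")] <- "reaction role"
  out
}

#' Tally leaf-level failure modes for matched message pairs
#'
#' Leaf attribution inherits from the message-level assignment: for a
#' message marked `REMOVAL` every ground-truth leaf is a removal and for an
#' `ADDITION` every predicted leaf is an addition; for `ACCURATE` and
#' `ALTERATION` pairs each leaf is classified by the aligned diff of the two
#' trees. Leaves are bucketed by field type (identifiers, amount, reaction
#' role, condition, workup, other).
#'
#' @param gt_list,pred_list The matched lists of message trees.
#' @param pairs A tibble from [match_messages()] for these lists.
#' @param message_type One of `"Compound"`, `"ProductCompound"`,
#'   `"ReactionConditions"`, `"ReactionWorkup"` (controls bucketing).
#' @return A tibble with one row per field type: counts `accurate`,
#'   `removal`, `addition`, `alteration` and `total` (= accurate + removal +
#'   alteration).
#' @export
classify_leaves <- function(gt_list, pred_list, pairs, message_type = "Compound") {
  statuses <- list()
  for (r in seq_len(nrow(pairs))) {
    mode <- pairs$mode[r]
    gt <- if (!is.na(pairs$gt_index[r])) gt_list[[pairs$gt_index[r]]] else NULL
    pred <- if (!is.na(pairs$pred_index[r])) pred_list[[pairs$pred_index[r]]] else NULL
    if (mode == "REMOVAL") {
      d <- one_sided_diff(gt, "", "gt")
    } else if (mode == "ADDITION") {
      d <- one_sided_diff(pred, "", "pred")
    } else {
      d <- node_diff(gt, pred)
    }
    if (nrow(d) == 0) next
    path <- ifelse(is.na(d$path_gt), d$path_pred, d$path_gt)
    statuses[[length(statuses) + 1L]] <- tibble(
      field_type = leaf_bucket(path, message_type),
      status = d$status
    )
  }
  buckets <- leaf_buckets_for(message_type)
  if (length(statuses) == 0) {
    return(tibble(
      message_type = message_type, field_type = buckets,
      accurate = 0L, removal = 0L, addition = 0L, alteration = 0L, total = 0L
    ))
  }
  st <- bind_rows(statuses)
  out <- st %>%
    count(.data$field_type, .data$status) %>%
    tidyr::pivot_wider(
      names_from = "status", values_from = "n", values_fill = 0L
    )
  for (col in c("accurate", "removal", "addition", "alteration")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out <- out %>%
    mutate(
      message_type = message_type,
      total = .data$accurate + .data$removal + .data$alteration
    ) %>%
    select("message_type", "field_type", "accurate", "removal", "addition",
           "alteration", "total")
  # keep every expected bucket present, zero-filled
  missing <- setdiff(buckets, out$field_type)
  if (length(missing) > 0) {
    out <- bind_rows(out, tibble(
      message_type = message_type, field_type = missing,
      accurate = 0L, removal = 0L, addition = 0L, alteration = 0L, total = 0L
    ))
  }
  out[order(match(out$field_type, buckets)), ]
}

leaf_buckets_for <- function(message_type) {
  switch(message_type,
    "ReactionConditions" = "condition",
    "ReactionWorkup" = "workup",
    c("identifiers", "amount", "reaction role", "other")
  )
}

# Multiset of (type, value) identifier pairs of a compound-like message.
identifier_multiset <- function(node) {
  ids <- node$identifiers
  if (is.null(ids)) return(character(0))
  sort(map_chr(ids, function(id) {
    paste0(
      if (is.null(id$type)) "" else str_trim(as.character(id$type)), "\r",
      if (is.null(id$value)) "" else str_trim(as.character(id$value))
    )
  }))
}

# Multiset of amount-bucket leaves (index-stripped path plus value).
amount_multiset <- function(node, message_type) {
  leaves <- walk_leaves(node, concrete = "", general = "")
  if (length(leaves) == 0) return(character(0))
  path <- map_chr(leaves, "path")
  keep <- leaf_bucket(path, message_type) == "amount"
  if (!any(keep)) return(character(0))
  vals <- map_chr(leaves[keep], function(l) {
    v <- l$value
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) format(num, digits = 15) else str_trim(as.character(v))
  })
  sort(paste0(gsub("\\[[0-9]+\\]", "[]", path[keep]), "\r", vals))
}

#' Lenient equivalence for compound-like messages
#'
#' Two messages are leniently identical when their identifier multisets
#' (type/value pairs) and all amount-bearing leaves agree; every other leaf
#' (calculated yield, texture, isolated color, reaction role) is ignored.
#' This is the relaxed routine used to separate chemical entity/relation
#' errors from implicit-information errors.
#'
#' @param a,b Compound or ProductCompound message trees.
#' @param message_type Bucketing context, `"ProductCompound"` (default) or
#'   `"Compound"`.
#' @return `TRUE` or `FALSE`.
#' @export
lenient_equal <- function(a, b, message_type = "ProductCompound") {
  identical(identifier_multiset(a), identifier_multiset(b)) &&
    identical(amount_multiset(a, message_type), amount_multiset(b, message_type))
}
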
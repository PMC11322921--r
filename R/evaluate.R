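# Whole-reaction evaluation: message-level (Metric 1) and leaf-level
# (Metric 2) tallies with strict and lenient variants.

input_compounds <- function(record) {
  out <- list()
  for (inp in record$inputs) {
    for (comp in inp$components) out[[length(out) + 1L]] <- comp
  }
  out
}

product_compounds <- function(record) {
  out <- list()
  for (oc in record$outcomes) {
    for (p in oc$products) out[[length(out) + 1L]] <- p
  }
  out
}

workup_list <- function(record) {
  if (is.null(record$workups)) list() else record$workups
}

#' Evaluate a predicted reaction record against ground truth
#'
#' Compares two reaction records message type by message type: Compound
#' messages are pooled across all inputs, ProductCompound messages across
#' all outcomes, workups are matched as an ordered list, and conditions are
#' compared as one single message (so only `ACCURATE` or `ALTERATION` apply
#' to conditions). Produces both strict tallies and a lenient variant in
#' which an `ALTERATION` pair satisfying [lenient_equal()] is upgraded to
#' accurate; for input compounds the lenient routine additionally ignores
#' the reaction role.
#'
#' An unparseable prediction (`pred = NULL`) counts as the total removal of
#' all ground-truth messages (conditions, which cannot be removed, count as
#' altered).
#'
#' @param gt Ground-truth record (message tree).
#' @param pred Predicted record, or `NULL` if the prediction could not be
#'   parsed.
#' @return An object of class `ord_eval`: a list with tibbles `message`
#'   (per variant and message type) and `leaf` (per message type and field
#'   type), plus the per-type matched pairs for audit.
#' @export
#' @examples
#' cfg <- gen_config(n_reactions = 1, seed = 1)
#' rec <- gen_reaction(cfg, 1)$record
#' ev <- evaluate_reaction(rec, rec)
#' tidy(ev)
evaluate_reaction <- function(gt, pred) {
  types <- list(
    Compound = input_compounds,
    ProductCompound = product_compounds,
    ReactionWorkup = workup_list
  )
  message_rows <- list()
  leaf_rows <- list()
  pairs_out <- list()

  for (tp in names(types)) {
    gt_list <- types[[tp]](gt)
    pred_list <- if (is.null(pred)) list() else types[[tp]](pred)
    pairs <- match_messages(gt_list, pred_list)
    strict <- classify_messages(pairs, tp) %>% mutate(variant = "strict")
    # lenient upgrade for compound-like messages
    lenient <- strict
    if (tp %in% c("Compound", "ProductCompound") && nrow(pairs) > 0) {
      upgraded <- 0L
      alt <- which(pairs$mode == "ALTERATION")
      for (r in alt) {
        a <- gt_list[[pairs$gt_index[r]]]
        b <- pred_list[[pairs$pred_index[r]]]
        if (lenient_equal(a, b, tp)) upgraded <- upgraded + 1L
      }
      lenient$accurate <- lenient$accurate + upgraded
      lenient$alteration <- lenient$alteration - upgraded
    }
    lenient$variant <- "lenient"
    message_rows[[length(message_rows) + 1L]] <- bind_rows(strict, lenient)
    leaf_rows[[length(leaf_rows) + 1L]] <-
      classify_leaves(gt_list, pred_list, pairs, tp)
    pairs_out[[tp]] <- pairs
  }

  # conditions: one single message, never a list
  gt_cond <- gt$conditions
  pred_cond <- if (is.null(pred)) NULL else pred$conditions
  if (!is.null(gt_cond)) {
    d <- node_distance(gt_cond, pred_cond)
    mode <- if (d == 0) "ACCURATE" else "ALTERATION"
    cond_pairs <- tibble(
      gt_index = 1L, pred_index = if (is.null(pred_cond)) NA_integer_ else 1L,
      distance = d, mode = mode
    )
    cond_tally <- tibble(
      message_type = "ReactionConditions",
      accurate = as.integer(mode == "ACCURATE"),
      removal = 0L, addition = 0L,
      alteration = as.integer(mode == "ALTERATION"),
      total = 1L
    )
    ld <- node_diff(gt_cond, pred_cond)
    cond_leaf <- tibble(
      message_type = "ReactionConditions", field_type = "condition",
      accurate = sum(ld$status == "accurate"),
      removal = sum(ld$status == "removal"),
      addition = sum(ld$status == "addition"),
      alteration = sum(ld$status == "alteration")
    ) %>% mutate(total = .data$accurate + .data$removal + .data$alteration)
  } else {
    cond_pairs <- tibble(
      gt_index = integer(), pred_index = integer(),
      distance = numeric(), mode = character()
    )
    cond_tally <- tibble(
      message_type = "ReactionConditions", accurate = 0L, removal = 0L,
      addition = 0L, alteration = 0L, total = 0L
    )
    if (!is.null(pred_cond)) {
      ld <- node_diff(NULL, pred_cond)
      cond_leaf <- tibble(
        message_type = "ReactionConditions", field_type = "condition",
        accurate = 0L, removal = 0L, addition = sum(ld$status == "addition"),
        alteration = 0L, total = 0L
      )
    } else {
      cond_leaf <- tibble(
        message_type = "ReactionConditions", field_type = "condition",
        accurate = 0L, removal = 0L, addition = 0L, alteration = 0L, total = 0L
      )
    }
  }
  message_rows[[length(message_rows) + 1L]] <- bind_rows(
    cond_tally %>% mutate(variant = "strict"),
    cond_tally %>% mutate(variant = "lenient")
  )
  leaf_rows[[length(leaf_rows) + 1L]] <- cond_leaf
  pairs_out[["ReactionConditions"]] <- cond_pairs

  structure(
    list(
      message = bind_rows(message_rows) %>%
        select("variant", "message_type", "accurate", "removal", "addition",
               "alteration", "total"),
      leaf = bind_rows(leaf_rows),
      pairs = pairs_out
    ),
    class = "ord_eval"
  )
}

#' Evaluate a corpus of predictions against ground truth
#'
#' @param gt A data frame with columns `source_id` and `record`
#'   (list-column of message trees).
#' @param pred A data frame with columns `source_id` and `record`;
#'   predictions missing for a ground-truth id, or stored as `NULL`, count
#'   as total removals.
#' @return A tibble with columns `source_id` and `eval` (list-column of
#'   `ord_eval` objects).
#' @export
evaluate_records <- function(gt, pred) {
  stopifnot(is.data.frame(gt), is.data.frame(pred))
  idx <- match(gt$source_id, pred$source_id)
  evals <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    p <- if (is.na(idx[i])) NULL else pred$record[[idx[i]]]
    evals[[i]] <- evaluate_reaction(gt$record[[i]], p)
  }
  tibble(source_id = gt$source_id, eval = evals)
}

#' Aggregate per-reaction evaluations into report tables
#'
#' Sums message- and leaf-level tallies across reactions and appends
#' printed percentages (one decimal, half-up; additions over the same
#' ground-truth denominator). The leaf table is also pooled across Compound
#' and ProductCompound per field type, mirroring how field-level results
#' are conventionally reported.
#'
#' @param results A list of `ord_eval` objects, or a data frame with an
#'   `eval` list-column as returned by [evaluate_records()].
#' @return An object of class `ord_report` with tibbles `message` and
#'   `leaf`.
#' @export
aggregate_report <- function(results) {
  if (is.data.frame(results)) results <- results$eval
  if (length(results) == 0) {
    return(structure(
      list(
        message = tibble(
          variant = character(), message_type = character(),
          accurate = integer(), removal = integer(), addition = integer(),
          alteration = integer(), total = integer()
        ),
        leaf = tibble(
          message_group = character(), field_type = character(),
          accurate = integer(), removal = integer(), addition = integer(),
          alteration = integer(), total = integer()
        ),
        n_reactions = 0L
      ),
      class = "ord_report"
    ))
  }
  msg <- bind_rows(lapply(results, function(e) e$message)) %>%
    group_by(.data$variant, .data$message_type) %>%
    summarise(across(c("accurate", "removal", "addition", "alteration", "total"),
                     sum), .groups = "drop") %>%
    tally_percentages()
  leaf <- bind_rows(lapply(results, function(e) e$leaf)) %>%
    mutate(message_group = ifelse(
      .data$message_type %in% c("Compound", "ProductCompound"),
      "ProductCompound & Compound", .data$message_type
    )) %>%
    group_by(.data$message_group, .data$field_type) %>%
    summarise(across(c("accurate", "removal", "addition", "alteration", "total"),
                     sum), .groups = "drop") %>%
    tally_percentages()
  structure(
    list(message = msg, leaf = leaf, n_reactions = length(results)),
    class = "ord_report"
  )
}

#' @export
print.ord_report <- function(x, ...) {
  cat("ORD extraction evaluation over", x$n_reactions, "reactions\n\n")
  cat("Message level (Metric 1):\n")
  print(as.data.frame(x$message), row.names = FALSE)
  cat("\nLeaf field level (Metric 2):\n")
  print(as.data.frame(x$leaf), row.names = FALSE)
  invisible(x)
}

#' Tidy an evaluation or report into a tibble
#'
#' @param x An `ord_eval` or `ord_report` object.
#' @param level `"message"` (default) or `"leaf"`.
#' @param ... Unused.
#' @return A tibble of tallies.
#' @export
tidy.ord_eval <- function(x, level = c("message", "leaf"), ...) {
  level <- match.arg(level)
  x[[level]]
}

#' @rdname tidy.ord_eval
#' @export
tidy.ord_report <- function(x, level = c("message", "leaf"), ...) {
  level <- match.arg(level)
  x[[level]]
}

#' One-row summary of an evaluation report
#'
#' `message_mean_accuracy_pct` is the unweighted mean of the per-message-type
#' accuracies using the lenient variant for compound-like messages (the
#' headline message-level figure); `message_mean_accuracy_strict_pct` uses
#' strict tallies throughout; `leaf_mean_accuracy_pct` is the unweighted
#' mean over the pooled leaf-table rows. Means of one-decimal percentages
#' are reported at two decimals, half-up.
#'
#' @param x An `ord_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ord_report <- function(x, ...) {
  msg <- x$message
  strict <- msg[msg$variant == "strict", ]
  lenient <- msg[msg$variant == "lenient", ]
  tibble(
    n_reactions = x$n_reactions,
    message_mean_accuracy_pct =
      round_half_up(mean(lenient$accurate_pct, na.rm = TRUE), 2),
    message_mean_accuracy_strict_pct =
      round_half_up(mean(strict$accurate_pct, na.rm = TRUE), 2),
    leaf_mean_accuracy_pct =
      round_half_up(mean(x$leaf$accurate_pct, na.rm = TRUE), 2)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot failure-mode composition of a report
#'
#' Stacked bars of Accurate/Removal/Addition/Alteration counts per message
#' type (strict variant), the message-level view of extraction quality.
#'
#' @param object An `ord_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ord_report <- function(object, ...) {
  df <- object$message %>%
    filter(.data$variant == "strict") %>%
    tidyr::pivot_longer(
      c("accurate", "removal", "addition", "alteration"),
      names_to = "mode", values_to = "count"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$message_type, y = .data$count, fill = .data$mode
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "messages", fill = "failure mode") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
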
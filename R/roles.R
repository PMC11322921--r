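# Reaction role classification evaluation. Input compounds carry exactly
# one reaction_role; in patent-derived corpora only REACTANT, SOLVENT and
# CATALYST occur for inputs (products are always PRODUCT and are excluded).
# A popularity baseline assigns each compound its most frequent
# training-set role, breaking ties and unseen names uniformly at random.

ROLE_CLASSES <- c("REACTANT", "SOLVENT", "CATALYST")
CONFUSION_COLS <- c(ROLE_CLASSES, "MISSING", "ERROR")

compound_name <- function(comp) {
  for (id in comp$identifiers) {
    if (identical(id$type, "NAME") && !is.null(id$value)) {
      return(normalize_name(id$value))
    }
  }
  NA_character_
}

#' Build a role-frequency table from training records
#'
#' Counts, per compound name, how often each of the three input roles
#' (REACTANT, SOLVENT, CATALYST) occurs among input compounds of the
#' training corpus.
#'
#' @param training A data frame with a `record` list-column, or a plain
#'   list of records.
#' @return A tibble with columns `name`, `role`, `n`.
#' @export
build_popularity_table <- function(training) {
  records <- if (is.data.frame(training)) training$record else training
  rows <- list()
  for (rec in records) {
    for (comp in input_compounds(rec)) {
      role <- comp$reaction_role
      nm <- compound_name(comp)
      if (!is.null(role) && role %in% ROLE_CLASSES && !is.na(nm)) {
        rows[[length(rows) + 1L]] <- tibble(name = nm, role = role)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(name = character(), role = character(), n = integer()))
  }
  bind_rows(rows) %>% count(.data$name, .data$role)
}

#' Predict reaction roles by popularity
#'
#' For each name, the most frequent role in the frequency table; ties and
#' unseen names are resolved by a uniform draw (among the tied roles, or
#' among all three roles). Uses R's RNG: seed with `set.seed()` for
#' reproducible draws.
#'
#' @param names Character vector of compound names.
#' @param table A frequency tibble from [build_popularity_table()].
#' @return A character vector of roles.
#' @export
#' @examples
#' tab <- tibble::tibble(name = "THF", role = c("SOLVENT", "REACTANT"), n = c(10, 1))
#' popularity_predict("THF", tab)
popularity_predict <- function(names, table) {
  names <- normalize_name(names)
  out <- character(length(names))
  for (k in seq_along(names)) {
    sub <- table[table$name == names[k], ]
    if (nrow(sub) == 0) {
      out[k] <- ROLE_CLASSES[sample.int(length(ROLE_CLASSES), 1)]
    } else {
      top <- sub$role[sub$n == max(sub$n)]
      out[k] <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
    }
  }
  out
}

new_role_confusion <- function(counts) {
  structure(counts, class = c("role_confusion", "matrix", "array"))
}

empty_confusion <- function() {
  m <- matrix(
    0L, nrow = length(ROLE_CLASSES), ncol = length(CONFUSION_COLS),
    dimnames = list(true = ROLE_CLASSES, predicted = CONFUSION_COLS)
  )
  m
}

#' Confusion matrix of reaction role classification
#'
#' For every ground-truth input compound with a role in
#' \{REACTANT, SOLVENT, CATALYST\}, the matched predicted compound (via the
#' same bipartite matching used for message-level scoring) determines the
#' predicted column: `MISSING` when no predicted compound pairs with it,
#' `ERROR` when the paired compound's name differs (or it carries no usable
#' role), otherwise the predicted role. Row sums therefore equal the
#' per-role ground-truth compound counts.
#'
#' @param gt,pred Data frames with `source_id` and `record` list-columns.
#' @return A `role_confusion` object: an integer matrix with true roles as
#'   rows and \{REACTANT, SOLVENT, CATALYST, MISSING, ERROR\} as columns.
#' @export
role_confusion <- function(gt, pred) {
  cm <- empty_confusion()
  idx <- match(gt$source_id, pred$source_id)
  for (i in seq_len(nrow(gt))) {
    gt_comps <- input_compounds(gt$record[[i]])
    p <- if (is.na(idx[i])) NULL else pred$record[[idx[i]]]
    pred_comps <- if (is.null(p)) list() else input_compounds(p)
    pairs <- match_messages(gt_comps, pred_comps)
    for (r in seq_len(nrow(pairs))) {
      gi <- pairs$gt_index[r]
      if (is.na(gi)) next
      truth <- gt_comps[[gi]]$reaction_role
      if (is.null(truth) || !(truth %in% ROLE_CLASSES)) next
      pj <- pairs$pred_index[r]
      if (is.na(pj)) {
        cm[truth, "MISSING"] <- cm[truth, "MISSING"] + 1L
        next
      }
      pc <- pred_comps[[pj]]
      gt_name <- compound_name(truth_comp <- gt_comps[[gi]])
      pred_name <- compound_name(pc)
      if (is.na(pred_name) || is.na(gt_name) || pred_name != gt_name) {
        cm[truth, "ERROR"] <- cm[truth, "ERROR"] + 1L
        next
      }
      pred_role <- pc$reaction_role
      if (is.null(pred_role) || !(pred_role %in% ROLE_CLASSES)) {
        cm[truth, "ERROR"] <- cm[truth, "ERROR"] + 1L
      } else {
        cm[truth, pred_role] <- cm[truth, pred_role] + 1L
      }
    }
  }
  new_role_confusion(cm)
}

#' Confusion matrix of the popularity baseline
#'
#' Applies [popularity_predict()] to the names of the ground-truth input
#' compounds (so extraction is perfect by construction: the MISSING and
#' ERROR columns are zero) and tallies predicted against true roles.
#'
#' @param gt A data frame with a `record` list-column, or a list of records.
#' @param table A frequency tibble from [build_popularity_table()].
#' @return A `role_confusion` object.
#' @export
role_confusion_baseline <- function(gt, table) {
  records <- if (is.data.frame(gt)) gt$record else gt
  cm <- empty_confusion()
  for (rec in records) {
    for (comp in input_compounds(rec)) {
      truth <- comp$reaction_role
      nm <- compound_name(comp)
      if (is.null(truth) || !(truth %in% ROLE_CLASSES) || is.na(nm)) next
      pred <- popularity_predict(nm, table)
      cm[truth, pred] <- cm[truth, pred] + 1L
    }
  }
  new_role_confusion(cm)
}

#' Row-normalized percentages of a role confusion matrix
#'
#' @param cm A `role_confusion`.
#' @param digits Decimal places (half-up).
#' @return A numeric matrix of percentages normalized by the number of true
#'   instances per row.
#' @export
confusion_row_pct <- function(cm, digits = 1) {
  rs <- rowSums(cm)
  out <- matrix(
    NA_real_, nrow(cm), ncol(cm), dimnames = dimnames(cm)
  )
  for (i in seq_len(nrow(cm))) {
    if (rs[i] > 0) out[i, ] <- round_half_up(100 * cm[i, ] / rs[i], digits)
  }
  out
}

#' Macro-averaged F1 of reaction role classification
#'
#' Unweighted mean of per-role F1 over \{REACTANT, SOLVENT, CATALYST\}.
#' MISSING and ERROR outcomes count as false negatives of the true role and
#' as false positives of no role. A role with zero support (or an undefined
#' F1) contributes 0 to the macro average; an all-empty matrix gives `NA`.
#'
#' @param cm A `role_confusion`.
#' @return A number in `[0, 1]`, or `NA` for an empty matrix.
#' @export
macro_f1 <- function(cm) {
  if (sum(cm) == 0) return(NA_real_)
  f1 <- vapply(ROLE_CLASSES, function(r) {
    tp <- cm[r, r]
    fn <- sum(cm[r, ]) - tp
    fp <- sum(cm[setdiff(ROLE_CLASSES, r), r])
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' @export
print.role_confusion <- function(x, ...) {
  cat("Reaction role confusion matrix (rows: truth)\n")
  print(unclass(x))
  cat(sprintf("macro-F1: %.3f\n", macro_f1(x)))
  invisible(x)
}

#' Tidy a role confusion matrix
#'
#' @param x A `role_confusion`.
#' @param ... Unused.
#' @return A long tibble with `true`, `predicted`, `n` and `row_pct`.
#' @export
tidy.role_confusion <- function(x, ...) {
  pct <- confusion_row_pct(x)
  df <- expand.grid(
    true = rownames(x), predicted = colnames(x),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  df$n <- as.vector(unclass(x))
  df$row_pct <- as.vector(pct)
  as_tibble(df)
}

#' Plot a role confusion matrix
#'
#' Heatmap of row-normalized percentages with counts overlaid.
#'
#' @param object A `role_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.role_confusion <- function(object, ...) {
  df <- tidy.role_confusion(object)
  df$predicted <- factor(df$predicted, levels = CONFUSION_COLS)
  df$true <- factor(df$true, levels = rev(ROLE_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$true, fill = .data$row_pct
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue", na.value = "grey90"
    ) +
    ggplot2::labs(x = "predicted", y = "true role", fill = "% of row") +
    ggplot2::theme_minimal()
}
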
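# Compound-name recognition scoring: the set of compound names (entities)
# extracted from a procedure is compared against the names in the
# ground-truth record. Referencing tokens ("desired product", "compound 17")
# are names too.

#' Extract the compound names of a reaction record
#'
#' Collects every NAME-type identifier value from input compounds and
#' product compounds, trimmed with internal whitespace collapsed
#' (case-sensitive: chemical names are case-meaningful).
#'
#' @param record A reaction record (message tree).
#' @return A character vector (a multiset: duplicates preserved).
#' @export
extract_names <- function(record) {
  comps <- c(input_compounds(record), product_compounds(record))
  out <- character(0)
  for (comp in comps) {
    for (id in comp$identifiers) {
      if (identical(id$type, "NAME") && !is.null(id$value)) {
        out <- c(out, str_squish(as.character(id$value)))
      }
    }
  }
  out
}

normalize_name <- function(x) str_squish(as.character(x))

# Normalized Levenshtein distance in [0, 1].
name_distance <- function(a, b) {
  if (a == b) return(0)
  d <- as.numeric(adist(a, b))
  d / max(nchar(a), nchar(b), 1)
}

#' Compare extracted compound names against ground truth
#'
#' Names are paired by a minimum-total-cost matching where the cost of a
#' pair is the normalized string edit distance in `[0, 1]` and unmatched
#' names (pads of the shorter multiset) cost 1. Zero-cost pairs count as
#' accurate, matched non-identical names as alterations, unmatched
#' ground-truth names as removals and unmatched predictions as additions.
#' On cost ties, real-name pairings are preferred over pad pairings.
#'
#' @param gt,pred Character vectors (multisets) of compound names.
#' @return A one-row tibble: `accurate`, `removal`, `addition`,
#'   `alteration`, `total` (`= accurate + removal + alteration = |gt|`).
#' @export
#' @examples
#' compare_names(c("tryptophan methyl ester", "9"), "tryptophan methyl ester")
compare_names <- function(gt, pred) {
  gt <- normalize_name(gt)
  pred <- normalize_name(pred)
  n_gt <- length(gt)
  n_pred <- length(pred)
  n <- max(n_gt, n_pred)
  if (n == 0L) {
    return(tibble(
      accurate = 0L, removal = 0L, addition = 0L, alteration = 0L, total = 0L
    ))
  }
  eps <- 1e-9 # prefer real-real pairings on exact cost ties
  cost <- matrix(1, n, n)
  for (i in seq_len(min(n_gt, n))) {
    for (j in seq_len(min(n_pred, n))) {
      cost[i, j] <- name_distance(gt[i], pred[j]) - eps
    }
  }
  assign <- canonicalize_assignment(cost, solve_assignment(cost))
  acc <- 0L; rem <- 0L; add <- 0L; alt <- 0L
  for (i in seq_len(n)) {
    j <- assign[i]
    gt_real <- i <= n_gt
    pred_real <- j <= n_pred
    if (gt_real && pred_real) {
      if (gt[i] == pred[j]) acc <- acc + 1L else alt <- alt + 1L
    } else if (gt_real) {
      rem <- rem + 1L
    } else if (pred_real) {
      add <- add + 1L
    }
  }
  tibble(
    accurate = acc, removal = rem, addition = add, alteration = alt,
    total = acc + rem + alt
  )
}

#' Score name recognition over a corpus
#'
#' @param gt,pred Data frames with `source_id` and `record` list-columns;
#'   missing or `NULL` predictions contribute removals only.
#' @return A one-row tibble of summed name tallies with printed percentages
#'   ([tally_percentages()]).
#' @export
compare_names_corpus <- function(gt, pred) {
  idx <- match(gt$source_id, pred$source_id)
  rows <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    p <- if (is.na(idx[i])) NULL else pred$record[[idx[i]]]
    pred_names <- if (is.null(p)) character(0) else extract_names(p)
    rows[[i]] <- compare_names(extract_names(gt$record[[i]]), pred_names)
  }
  bind_rows(rows) %>%
    summarise(across(c("accurate", "removal", "addition", "alteration", "total"),
                     sum)) %>%
    tally_percentages()
}
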
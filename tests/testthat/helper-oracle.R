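# Shared test utilities: exhaustive assignment oracle and small fixture
# builders. The oracle enumerates all bijections, independent of the
# Hungarian solver it checks.

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, smaller + (smaller >= k))
    out <- rbind(out, block)
  }
  out
}

brute_force_min_cost <- function(cost) {
  n <- nrow(cost)
  perms <- all_permutations(n)
  costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  min(costs)
}

make_compound <- function(name, mass = NULL, volume = NULL, role = "REACTANT",
                          extra = NULL) {
  amount <- list()
  if (!is.null(mass)) amount$mass <- list(value = mass, units = "GRAM")
  if (!is.null(volume)) amount$volume <- list(value = volume, units = "MILLILITER")
  comp <- list(
    identifiers = list(list(type = "NAME", value = name)),
    amount = amount,
    reaction_role = role
  )
  if (length(amount) == 0) comp$amount <- NULL
  if (!is.null(extra)) comp <- utils::modifyList(comp, extra)
  comp
}

make_product <- function(name, yield = NULL, mass = NULL, texture = NULL,
                         color = NULL) {
  ms <- list()
  if (!is.null(yield)) {
    ms[[length(ms) + 1]] <- list(type = "YIELD", percentage = list(value = yield))
  }
  if (!is.null(mass)) {
    ms[[length(ms) + 1]] <- list(
      type = "AMOUNT", amount = list(mass = list(value = mass, units = "GRAM"))
    )
  }
  prod <- list(
    identifiers = list(list(type = "NAME", value = name)),
    reaction_role = "PRODUCT"
  )
  if (length(ms) > 0) prod$measurements <- ms
  if (!is.null(texture)) prod$texture <- list(type = texture)
  if (!is.null(color)) prod$isolated_color <- color
  prod
}

# perturbation schemes that keep the optimal matching unambiguous: adds and
# removes of one message type never co-occur in a record
recovery_schemes <- list(
  list(compound = c(alter = 1)),
  list(compound = c(remove = 1)),
  list(compound = c(add = 1)),
  list(compound = c(add = 1, alter = 1)),
  list(compound = c(remove = 1, alter = 1)),
  list(workup = c(alter = 1)),
  list(workup = c(remove = 1)),
  list(workup = c(add = 1, alter = 1)),
  list(workup = c(remove = 2)),
  list(product = c(alter = 1)),
  list(conditions = c(alter = 1)),
  list(compound = c(alter = 2), workup = c(add = 1)),
  list(compound = c(remove = 1), product = c(alter = 1),
       conditions = c(alter = 1)),
  list() # untouched record
)

# expected message-level tallies implied by a perturbation log
expected_message_tally <- function(gt_record, log) {
  totals <- c(
    Compound = length(ordbench:::input_compounds(gt_record)),
    ProductCompound = length(ordbench:::product_compounds(gt_record)),
    ReactionWorkup = length(ordbench:::workup_list(gt_record)),
    ReactionConditions = as.integer(!is.null(gt_record$conditions))
  )
  out <- list()
  for (tp in names(totals)) {
    sub <- log[log$message_type == tp, ]
    n_rm <- sum(sub$op == "remove")
    n_alt <- sum(sub$op == "alter")
    n_add <- sum(sub$op == "add")
    out[[tp]] <- tibble::tibble(
      message_type = tp,
      accurate = totals[[tp]] - n_rm - n_alt,
      removal = n_rm, addition = n_add, alteration = n_alt,
      total = totals[[tp]]
    )
  }
  dplyr::bind_rows(out)
}

# expected leaf-level tallies (summed over field types) implied by a log
expected_leaf_tally <- function(gt_record, log) {
  leaf_totals <- c(
    Compound = sum(vapply(ordbench:::input_compounds(gt_record),
                          ordbench:::n_leaves, integer(1)), 0L),
    ProductCompound = sum(vapply(ordbench:::product_compounds(gt_record),
                                 ordbench:::n_leaves, integer(1)), 0L),
    ReactionWorkup = sum(vapply(ordbench:::workup_list(gt_record),
                                ordbench:::n_leaves, integer(1)), 0L),
    ReactionConditions = ordbench:::n_leaves(gt_record$conditions)
  )
  out <- list()
  for (tp in names(leaf_totals)) {
    sub <- log[log$message_type == tp, ]
    rm_leaves <- sum(sub$n_leaves[sub$op == "remove"], 0L)
    add_leaves <- sum(sub$n_leaves[sub$op == "add"], 0L)
    n_alt <- sum(sub$op == "alter") # alterations touch exactly one leaf
    out[[tp]] <- tibble::tibble(
      message_type = tp,
      accurate = leaf_totals[[tp]] - rm_leaves - n_alt,
      removal = rm_leaves, addition = add_leaves, alteration = n_alt,
      total = leaf_totals[[tp]]
    )
  }
  dplyr::bind_rows(out)
}
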
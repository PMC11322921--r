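# Synthetic USPTO-style fixtures: (procedure text, reaction record) pairs
# rendered from patent-register templates, plus a perturbation engine that
# injects logged corruptions so every metric has a known-answer oracle.

default_lexicon <- function() {
  tibble(
    name = c(
      # solvent-class names
      "tetrahydrofuran", "dichloromethane", "ethyl acetate", "methanol",
      "ethanol", "toluene", "N,N-dimethylformamide", "acetonitrile",
      "diethyl ether", "1,4-dioxane",
      # catalyst-class names
      "palladium on carbon", "copper(I) iodide", "platinum(IV) oxide",
      "p-toluenesulfonic acid", "tetrakis(triphenylphosphine)palladium(0)",
      # reactant-class names
      "benzaldehyde", "aniline", "sodium borohydride", "4-bromotoluene",
      "methyl iodide", "potassium carbonate", "acetic anhydride",
      "benzyl chloride", "phenylboronic acid", "2-chloropyridine",
      "cyclohexanone", "triethylamine"
    ),
    class = c(
      rep("solvent", 10), rep("catalyst", 5), rep("reactant", 12)
    ),
    # per-name role distribution: roles are context-dependent, so even a
    # typical solvent occasionally serves as a reactant
    p_reactant = c(rep(0.07, 10), rep(0.10, 5), rep(0.92, 12)),
    p_solvent = c(rep(0.90, 10), rep(0.05, 5), rep(0.04, 12)),
    p_catalyst = c(rep(0.03, 10), rep(0.85, 5), rep(0.04, 12))
  )
}

product_pool <- c(
  "4-methylbenzanilide", "N-benzylaniline", "methyl 4-bromobenzoate",
  "1-phenylethanol", "2-phenylpyridine", "4-methoxybenzonitrile"
)

workup_templates <- tibble::tibble(
  type = c("FILTRATION", "EXTRACTION", "WASH", "CONCENTRATION",
           "DRY_WITH_MATERIAL", "DISTILLATION", "RECRYSTALLIZATION"),
  phrase = c(
    "The mixture was filtered through a pad of celite",
    "The aqueous layer was extracted with ethyl acetate",
    "The combined organic layers were washed with brine",
    "The solvent was removed under reduced pressure",
    "The organic phase was dried over anhydrous sodium sulfate",
    "The crude material was purified by distillation",
    "The solid was recrystallized from hot ethanol"
  )
)

texture_pool <- list(
  list(phrase = "as a white solid", texture = "SOLID", color = "white"),
  list(phrase = "as a yellow oil", texture = "OIL", color = "yellow"),
  list(phrase = "as colorless crystals", texture = "CRYSTAL", color = "colorless"),
  list(phrase = "as a pale-yellow powder", texture = "POWDER", color = "pale yellow"),
  list(phrase = "as an off-white foam", texture = "FOAM", color = "off-white")
)

#' Configuration of the synthetic fixture generator
#'
#' Defaults emulate short USPTO-style procedures: 1-4 input compounds with
#' mass/volume amounts and context-dependent reaction roles, a temperature
#' condition, 1-5 workups and a single product with a stated integer yield.
#'
#' @param n_reactions Number of reactions to generate.
#' @param seed Integer seed (mandatory; all generation is derived from it).
#' @param compounds_range Inclusive range of input compounds per reaction.
#' @param workup_range Inclusive range of workup steps.
#' @param yield_range Inclusive integer range of product yields (percent).
#' @param p_omit_product_name Probability that the procedure text refers to
#'   "the desired product" while the record keeps the product name
#'   (exercises implicit-information scrubbing).
#' @param p_texture Probability that the product reports texture and
#'   isolated color.
#' @param lexicon A tibble of compound names with per-name role
#'   probabilities; see `ordbench:::default_lexicon()` for the shape.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(n_reactions = 100, seed, compounds_range = c(1, 4),
                       workup_range = c(1, 5), yield_range = c(10, 99),
                       p_omit_product_name = 0, p_texture = 0.5,
                       lexicon = default_lexicon()) {
  if (missing(seed)) abort("seed is mandatory", class = "ordbench_config_error")
  stopifnot(
    p_omit_product_name >= 0, p_omit_product_name <= 1,
    p_texture >= 0, p_texture <= 1
  )
  structure(
    list(
      n_reactions = n_reactions, seed = as.integer(seed),
      compounds_range = compounds_range, workup_range = workup_range,
      yield_range = yield_range, p_omit_product_name = p_omit_product_name,
      p_texture = p_texture, lexicon = lexicon
    ),
    class = "gen_config"
  )
}

sample_range <- function(lo, hi) {
  if (lo >= hi) lo else sample(lo:hi, 1)
}

record_seed <- function(config, index) {
  (config$seed %% 100000L) * 10007L + index * 131L
}

draw_role <- function(lex_row) {
  sample(
    ROLE_CLASSES, 1,
    prob = c(lex_row$p_reactant, lex_row$p_solvent, lex_row$p_catalyst)
  )
}

make_compound <- function(name, role, amount_kind, value, units) {
  amount <- list()
  amount[[amount_kind]] <- list(value = value, units = units)
  list(
    identifiers = list(list(type = "NAME", value = name)),
    amount = amount,
    reaction_role = role
  )
}

format_amount <- function(value, units) {
  unit_txt <- c(
    GRAM = "g", MILLIGRAM = "mg", MILLILITER = "mL", LITER = "L",
    MILLIMOLE = "mmol", MOLE = "mol"
  )[[units]]
  paste0(format(value, trim = TRUE, scientific = FALSE), " ", unit_txt)
}

#' Generate one synthetic reaction
#'
#' Deterministic in `(config, index)`. The procedure text is rendered from
#' patent-register templates so that every compound name (and the integer
#' yield) appears verbatim in the text; with probability
#' `p_omit_product_name` the text instead says "the desired product", so
#' that [scrub_implicit()] removes exactly the product NAME identifier.
#' Names and amount values are distinct within a record, which keeps the
#' optimal matching unambiguous under small perturbations.
#'
#' @param config A [gen_config()].
#' @param index 1-based reaction index.
#' @return A list with `source_id`, `procedure_text`, `record` and
#'   `product_name_in_text` (logical).
#' @export
gen_reaction <- function(config, index) {
  with_local_seed(record_seed(config, index), {
    lex <- config$lexicon
    n_comp <- sample_range(config$compounds_range[1], config$compounds_range[2])

    # always one reactant-class lead compound; a solvent when room permits
    reactant_rows <- which(lex$class == "reactant")
    solvent_rows <- which(lex$class == "solvent")
    picked <- sample(reactant_rows, 1)
    if (n_comp >= 2) picked <- c(picked, sample(solvent_rows, 1))
    if (n_comp > length(picked)) {
      remaining <- setdiff(seq_len(nrow(lex)), picked)
      picked <- c(picked, sample(remaining, n_comp - length(picked)))
    }

    masses <- sample(5:5000, n_comp) / 100 # distinct, parse-canonical values
    volumes <- sample(2:400, n_comp) / 2
    comps <- list()
    phrases <- character(0)
    solvent_phrase <- NULL
    for (k in seq_len(n_comp)) {
      row <- lex[picked[k], ]
      role <- draw_role(row)
      if (row$class == "solvent") {
        value <- volumes[k]
        comp <- make_compound(row$name, role, "volume", value, "MILLILITER")
        txt <- paste0(row$name, " (", format_amount(value, "MILLILITER"), ")")
        if (is.null(solvent_phrase)) solvent_phrase <- txt else phrases <- c(phrases, txt)
      } else {
        value <- masses[k]
        comp <- make_compound(row$name, role, "mass", value, "GRAM")
        phrases <- c(phrases, paste0(row$name, " (", format_amount(value, "GRAM"), ")"))
      }
      comps[[k]] <- comp
    }

    # inputs: non-solvent compounds under "m1"; the solvent (if any) under "m2"
    is_solvent_comp <- map_lgl(comps, function(cp) !is.null(cp$amount$volume))
    first_solvent <- if (any(is_solvent_comp)) which(is_solvent_comp)[1] else NA_integer_
    inputs <- list()
    main <- comps[setdiff(seq_along(comps), first_solvent)]
    if (length(main) > 0) inputs[["m1"]] <- list(components = main)
    if (!is.na(first_solvent)) {
      inputs[[if (length(main) > 0) "m2" else "m1"]] <-
        list(components = comps[first_solvent])
    }

    temperature <- sample(c(-78, -40, -20, 0, 20, 25, 40, 60, 80, 100, 110, 120), 1)
    conditions <- list(
      temperature = list(setpoint = list(value = temperature, units = "CELSIUS"))
    )
    if (stats::runif(1) < 0.7) conditions$stirring <- list(type = "STIR")

    n_wk <- sample_range(config$workup_range[1], config$workup_range[2])
    wk_rows <- sample(nrow(workup_templates), n_wk)
    workups <- lapply(wk_rows, function(r) {
      list(type = workup_templates$type[r], details = workup_templates$phrase[r])
    })
    workup_text <- paste0(workup_templates$phrase[wk_rows], ".", collapse = " ")

    product_name <- switch(
      sample(3, 1),
      "the title compound",
      sprintf("compound %d", sample(100:999, 1)),
      sample(product_pool, 1)
    )
    yield <- as.numeric(sample_range(config$yield_range[1], config$yield_range[2]))
    prod_mass <- sample(5:5000, 1) / 100
    product <- list(
      identifiers = list(list(type = "NAME", value = product_name)),
      measurements = list(
        list(type = "YIELD", percentage = list(value = yield)),
        list(type = "AMOUNT",
             amount = list(mass = list(value = prod_mass, units = "GRAM")))
      ),
      reaction_role = "PRODUCT"
    )
    texture_phrase <- ""
    if (stats::runif(1) < config$p_texture) {
      tx <- texture_pool[[sample(length(texture_pool), 1)]]
      product$texture <- list(type = tx$texture)
      product$isolated_color <- tx$color
      texture_phrase <- paste0(" ", tx$phrase)
    }

    omit_name <- stats::runif(1) < config$p_omit_product_name
    product_in_text <- if (omit_name) "the desired product" else product_name

    mixture <- paste(phrases, collapse = " and ")
    opening <- if (!is.null(solvent_phrase)) {
      paste0("A solution of ", mixture, " in ", solvent_phrase)
    } else {
      paste0("A mixture of ", mixture)
    }
    text <- paste0(
      opening, " was stirred at ", temperature, " °C. ", workup_text,
      " The residue gave ", product_in_text, " (",
      format_amount(prod_mass, "GRAM"), ", ", yield, "%)", texture_phrase, "."
    )

    record <- list(
      inputs = inputs,
      conditions = conditions,
      workups = workups,
      outcomes = list(list(products = list(product))),
      notes = list(procedure_details = text)
    )
    list(
      source_id = sprintf("rxn-%05d", index),
      procedure_text = text,
      record = record,
      product_name_in_text = !omit_name
    )
  })
}

#' Generate a synthetic corpus
#'
#' @param config A [gen_config()].
#' @return A tibble with columns `source_id`, `procedure_text`, `record`
#'   (list-column) and `product_name_in_text`.
#' @export
#' @examples
#' corpus <- gen_corpus(gen_config(n_reactions = 3, seed = 7))
#' corpus$source_id
gen_corpus <- function(config) {
  if (config$n_reactions == 0) {
    return(tibble(
      source_id = character(), procedure_text = character(),
      record = list(), product_name_in_text = logical()
    ))
  }
  rows <- lapply(seq_len(config$n_reactions), function(i) gen_reaction(config, i))
  tibble(
    source_id = map_chr(rows, "source_id"),
    procedure_text = map_chr(rows, "procedure_text"),
    record = map(rows, "record"),
    product_name_in_text = map_lgl(rows, "product_name_in_text")
  )
}

empty_perturbation_log <- function() {
  tibble(
    message_type = character(), op = character(), path = character(),
    leaf = character(), before = character(), after = character(),
    n_leaves = integer()
  )
}

log_row <- function(message_type, op, path, leaf = NA_character_,
                    before = NA_character_, after = NA_character_,
                    n_leaves = NA_integer_) {
  tibble(
    message_type = message_type, op = op, path = path, leaf = leaf,
    before = before, after = after, n_leaves = n_leaves
  )
}

normalize_counts <- function(x) {
  out <- c(add = 0L, remove = 0L, alter = 0L)
  if (!is.null(x)) out[names(x)] <- as.integer(x)
  out
}

#' Inject logged corruptions into a reaction record
#'
#' Applies the requested numbers of message additions, removals and
#' alterations per message type at uniformly sampled eligible sites, and
#' returns both the corrupted record and a log of every edit - the oracle
#' against which the evaluation metrics are tested. Alterations change one
#' leaf to a fresh value guaranteed distinct from every other value in the
#' record, so the corrupted message stays closer to its origin than to any
#' other message and the optimal matching is unambiguous. Note that under
#' the padded-matching metric, an added and a removed message of the same
#' type in the same record pair up as a single alteration; for exact
#' metric recovery do not request both at once.
#'
#' @param record A reaction record.
#' @param counts A list with optional entries `compound`, `product`,
#'   `workup` (each a named vector with any of `add`, `remove`, `alter`)
#'   and `conditions` (with `alter`).
#' @param seed Integer seed.
#' @return A list: `record` (corrupted) and `log` (tibble with columns
#'   `message_type`, `op`, `path`, `leaf`, `before`, `after`, `n_leaves`).
#' @export
#' @examples
#' cfg <- gen_config(n_reactions = 1, seed = 3)
#' rec <- gen_reaction(cfg, 1)$record
#' out <- perturb(rec, list(workup = c(remove = 1)), seed = 9)
#' out$log
perturb <- function(record, counts, seed) {
  cc <- normalize_counts(counts$compound)
  pc <- normalize_counts(counts$product)
  wc <- normalize_counts(counts$workup)
  xc <- normalize_counts(counts$conditions)
  with_local_seed(seed, {
    logs <- list()
    fresh <- 0L
    next_fresh <- function() {
      fresh <<- fresh + 1L
      fresh
    }

    ## ---- input compounds ----
    sites <- list()
    for (nm in names(record$inputs)) {
      for (k in seq_along(record$inputs[[nm]]$components)) {
        sites[[length(sites) + 1L]] <- list(input = nm, idx = k)
      }
    }
    if (cc[["remove"]] + cc[["alter"]] > length(sites)) {
      abort("infeasible perturbation: not enough Compound messages",
            class = "ordbench_config_error")
    }
    chosen <- if (length(sites) > 0) {
      sample(length(sites), cc[["remove"]] + cc[["alter"]])
    } else integer(0)
    rm_sites <- chosen[seq_len(cc[["remove"]])]
    alt_sites <- setdiff(chosen, rm_sites)

    site_path <- function(s) {
      paste0('inputs["', s$input, '"].components[', s$idx - 1L, "]")
    }
    for (si in alt_sites) {
      s <- sites[[si]]
      comp <- record$inputs[[s$input]]$components[[s$idx]]
      res <- alter_compound(comp, next_fresh())
      record$inputs[[s$input]]$components[[s$idx]] <- res$node
      logs[[length(logs) + 1L]] <- log_row(
        "Compound", "alter", site_path(s), res$leaf, res$before, res$after
      )
    }
    for (si in rm_sites) {
      s <- sites[[si]]
      comp <- record$inputs[[s$input]]$components[[s$idx]]
      logs[[length(logs) + 1L]] <- log_row(
        "Compound", "remove", site_path(s), n_leaves = n_leaves(comp)
      )
    }
    # apply removals in descending index order per input
    if (length(rm_sites) > 0) {
      rm_list <- lapply(rm_sites, function(si) sites[[si]])
      for (nm in unique(map_chr(rm_list, "input"))) {
        idxs <- sort(unlist(lapply(rm_list, function(s) {
          if (s$input == nm) s$idx else NULL
        })), decreasing = TRUE)
        for (k in idxs) record$inputs[[nm]]$components[[k]] <- NULL
      }
    }
    for (a in seq_len(cc[["add"]])) {
      fid <- next_fresh()
      comp <- make_compound(
        sprintf("uncharacterized reagent %d", fid), "REACTANT",
        "mass", 900 + fid, "GRAM"
      )
      tgt <- sample(names(record$inputs), 1)
      record$inputs[[tgt]]$components[[
        length(record$inputs[[tgt]]$components) + 1L
      ]] <- comp
      logs[[length(logs) + 1L]] <- log_row(
        "Compound", "add",
        paste0('inputs["', tgt, '"].components[',
               length(record$inputs[[tgt]]$components) - 1L, "]"),
        n_leaves = n_leaves(comp)
      )
    }

    ## ---- product compounds ----
    psites <- list()
    for (oi in seq_along(record$outcomes)) {
      for (k in seq_along(record$outcomes[[oi]]$products)) {
        psites[[length(psites) + 1L]] <- list(oi = oi, idx = k)
      }
    }
    if (pc[["remove"]] + pc[["alter"]] > length(psites)) {
      abort("infeasible perturbation: not enough ProductCompound messages",
            class = "ordbench_config_error")
    }
    chosen <- if (length(psites) > 0) {
      sample(length(psites), pc[["remove"]] + pc[["alter"]])
    } else integer(0)
    rm_sites <- chosen[seq_len(pc[["remove"]])]
    alt_sites <- setdiff(chosen, rm_sites)
    ppath <- function(s) {
      paste0("outcomes[", s$oi - 1L, "].products[", s$idx - 1L, "]")
    }
    for (si in alt_sites) {
      s <- psites[[si]]
      prod <- record$outcomes[[s$oi]]$products[[s$idx]]
      res <- alter_product(prod, next_fresh())
      record$outcomes[[s$oi]]$products[[s$idx]] <- res$node
      logs[[length(logs) + 1L]] <- log_row(
        "ProductCompound", "alter", ppath(s), res$leaf, res$before, res$after
      )
    }
    for (si in rm_sites) {
      s <- psites[[si]]
      prod <- record$outcomes[[s$oi]]$products[[s$idx]]
      logs[[length(logs) + 1L]] <- log_row(
        "ProductCompound", "remove", ppath(s), n_leaves = n_leaves(prod)
      )
    }
    if (length(rm_sites) > 0) {
      rm_list <- lapply(rm_sites, function(si) psites[[si]])
      for (oi in unique(map_int(rm_list, function(s) as.integer(s$oi)))) {
        idxs <- sort(unlist(lapply(rm_list, function(s) {
          if (s$oi == oi) s$idx else NULL
        })), decreasing = TRUE)
        for (k in idxs) record$outcomes[[oi]]$products[[k]] <- NULL
      }
    }
    for (a in seq_len(pc[["add"]])) {
      fid <- next_fresh()
      prod <- list(
        identifiers = list(list(
          type = "NAME", value = sprintf("unexpected byproduct %d", fid)
        )),
        measurements = list(list(
          type = "AMOUNT",
          amount = list(mass = list(value = 900 + fid, units = "GRAM"))
        )),
        reaction_role = "PRODUCT"
      )
      record$outcomes[[1]]$products[[
        length(record$outcomes[[1]]$products) + 1L
      ]] <- prod
      logs[[length(logs) + 1L]] <- log_row(
        "ProductCompound", "add",
        paste0("outcomes[0].products[",
               length(record$outcomes[[1]]$products) - 1L, "]"),
        n_leaves = n_leaves(prod)
      )
    }

    ## ---- workups ----
    n_wk <- length(record$workups)
    if (wc[["remove"]] + wc[["alter"]] > n_wk) {
      abort("infeasible perturbation: not enough ReactionWorkup messages",
            class = "ordbench_config_error")
    }
    chosen <- if (n_wk > 0) sample(n_wk, wc[["remove"]] + wc[["alter"]]) else integer(0)
    rm_sites <- chosen[seq_len(wc[["remove"]])]
    alt_sites <- setdiff(chosen, rm_sites)
    used_types <- map_chr(record$workups, function(w) w$type %||% "")
    free_types <- setdiff(workup_templates$type, used_types)
    for (k in alt_sites) {
      wk <- record$workups[[k]]
      fid <- next_fresh()
      if (length(free_types) > 0 && stats::runif(1) < 0.5) {
        new_type <- free_types[1]
        free_types <- free_types[-1]
        logs[[length(logs) + 1L]] <- log_row(
          "ReactionWorkup", "alter", paste0("workups[", k - 1L, "]"),
          "type", wk$type, new_type
        )
        wk$type <- new_type
      } else {
        new_details <- paste0(wk$details, sprintf(" (repeated, step %d)", fid))
        logs[[length(logs) + 1L]] <- log_row(
          "ReactionWorkup", "alter", paste0("workups[", k - 1L, "]"),
          "details", wk$details, new_details
        )
        wk$details <- new_details
      }
      record$workups[[k]] <- wk
    }
    for (k in rm_sites) {
      logs[[length(logs) + 1L]] <- log_row(
        "ReactionWorkup", "remove", paste0("workups[", k - 1L, "]"),
        n_leaves = n_leaves(record$workups[[k]])
      )
    }
    if (length(rm_sites) > 0) {
      for (k in sort(rm_sites, decreasing = TRUE)) record$workups[[k]] <- NULL
    }
    for (a in seq_len(wc[["add"]])) {
      fid <- next_fresh()
      tp <- if (length(free_types) > 0) {
        out <- free_types[1]
        free_types <- free_types[-1]
        out
      } else "CUSTOM"
      wk <- list(type = tp, details = sprintf("Additional processing step %d", fid))
      record$workups[[length(record$workups) + 1L]] <- wk
      logs[[length(logs) + 1L]] <- log_row(
        "ReactionWorkup", "add",
        paste0("workups[", length(record$workups) - 1L, "]"),
        n_leaves = n_leaves(wk)
      )
    }

    ## ---- conditions ----
    if (xc[["alter"]] > 0) {
      if (is.null(record$conditions)) {
        abort("infeasible perturbation: no ReactionConditions message",
              class = "ordbench_config_error")
      }
      old <- record$conditions$temperature$setpoint$value
      new <- old + 500 + next_fresh()
      record$conditions$temperature$setpoint$value <- new
      logs[[length(logs) + 1L]] <- log_row(
        "ReactionConditions", "alter", "conditions",
        "temperature.setpoint.value", as.character(old), as.character(new)
      )
    }

    list(
      record = record,
      log = if (length(logs) == 0) empty_perturbation_log() else bind_rows(logs)
    )
  })
}

# one-leaf alteration of an input compound, guaranteed fresh values
alter_compound <- function(comp, fid) {
  choice <- sample(3, 1)
  if (choice == 1) {
    old <- comp$identifiers[[1]]$value
    new <- sprintf("%s (batch %d)", old, fid)
    comp$identifiers[[1]]$value <- new
    leaf <- "identifiers[0].value"
  } else if (choice == 2) {
    kind <- names(comp$amount)[1]
    old <- comp$amount[[kind]]$value
    new <- old + 1000 + fid
    comp$amount[[kind]]$value <- new
    leaf <- paste0("amount.", kind, ".value")
  } else {
    old <- comp$reaction_role
    new <- sample(setdiff(ROLE_CLASSES, old), 1)
    comp$reaction_role <- new
    leaf <- "reaction_role"
  }
  list(node = comp, leaf = leaf, before = as.character(old),
       after = as.character(new))
}

alter_product <- function(prod, fid) {
  choice <- sample(3, 1)
  if (choice == 1) {
    old <- prod$identifiers[[1]]$value
    new <- sprintf("%s (batch %d)", old, fid)
    prod$identifiers[[1]]$value <- new
    leaf <- "identifiers[0].value"
  } else if (choice == 2) {
    yi <- which(map_lgl(prod$measurements, function(m) identical(m$type, "YIELD")))
    if (length(yi) > 0) {
      old <- prod$measurements[[yi[1]]]$percentage$value
      new <- old + 1000 + fid
      prod$measurements[[yi[1]]]$percentage$value <- new
      leaf <- paste0("measurements[", yi[1] - 1L, "].percentage.value")
    } else {
      old <- prod$identifiers[[1]]$value
      new <- sprintf("%s (batch %d)", old, fid)
      prod$identifiers[[1]]$value <- new
      leaf <- "identifiers[0].value"
    }
  } else {
    ai <- which(map_lgl(prod$measurements, function(m) identical(m$type, "AMOUNT")))
    if (length(ai) > 0) {
      old <- prod$measurements[[ai[1]]]$amount$mass$value
      new <- old + 1000 + fid
      prod$measurements[[ai[1]]]$amount$mass$value <- new
      leaf <- paste0("measurements[", ai[1] - 1L, "].amount.mass.value")
    } else {
      old <- prod$identifiers[[1]]$value
      new <- sprintf("%s (batch %d)", old, fid)
      prod$identifiers[[1]]$value <- new
      leaf <- "identifiers[0].value"
    }
  }
  list(node = prod, leaf = leaf, before = as.character(old),
       after = as.character(new))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
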
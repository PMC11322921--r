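# Corpus preparation: admission, implicit-information scrubbing, prompt
# rendering, deduplication, token-length filtering and splitting.

DEFAULT_INSTRUCTION <- paste(
  "Extract the structured reaction record from the following organic",
  "synthesis procedure as a JSON object with inputs, conditions, workups",
  "and outcomes."
)

#' Default deterministic tokenizer
#'
#' Counts word tokens (runs of alphanumerics) plus individual punctuation
#' characters. A real subword tokenizer may be plugged into
#' [token_filter()] instead; counts are tokenizer-dependent.
#'
#' @param text Character vector.
#' @return Integer vector of token counts.
#' @export
count_tokens <- function(text) {
  str_count(text, "[A-Za-z0-9_]+|[^A-Za-z0-9_\\s]")
}

#' Admission rule for a corpus record
#'
#' A record is admitted iff every ReactionInput has a non-empty components
#' list (its chemical inputs are identifiable) and a non-empty procedure
#' paragraph is attached.
#'
#' @param record A reaction record (message tree).
#' @param procedure_text The associated procedure paragraph.
#' @return `TRUE` or `FALSE`.
#' @export
admit_record <- function(record, procedure_text) {
  if (is.null(procedure_text) || is.na(procedure_text) ||
      !nzchar(str_trim(procedure_text))) {
    return(FALSE)
  }
  inputs <- record$inputs
  if (length(inputs) == 0) return(FALSE)
  all(map_lgl(inputs, function(inp) length(inp$components) > 0))
}

#' Flag admitted records in a corpus
#'
#' @param corpus A data frame with columns `record` (list) and
#'   `procedure_text`.
#' @return The corpus tibble with a logical `admitted` column appended.
#' @export
admit_records <- function(corpus) {
  corpus %>%
    as_tibble() %>%
    mutate(admitted = map2(.data$record, .data$procedure_text, admit_record) %>%
             unlist())
}

yield_int_in_text <- function(value, text) {
  str_detect(text, regex(paste0("\\b", floor(as.numeric(value)), "\\b")))
}

name_in_text <- function(name, text) {
  str_detect(
    str_squish(text),
    fixed(str_squish(name), ignore_case = TRUE)
  )
}

# Scrub one record against its procedure text. Returns list(record, removed).
scrub_record <- function(record, procedure_text) {
  removed <- character(0)
  text <- procedure_text

  scrub_compound_names <- function(comps, base_path) {
    for (k in seq_along(comps)) {
      ids <- comps[[k]]$identifiers
      keep <- rep(TRUE, length(ids))
      for (q in seq_along(ids)) {
        id <- ids[[q]]
        if (identical(id$type, "NAME") && !is.null(id$value) &&
            !name_in_text(id$value, text)) {
          keep[q] <- FALSE
          removed <<- c(removed, paste0(
            base_path, "[", k - 1L, "].identifiers[", q - 1L, "]"
          ))
        }
      }
      if (!all(keep)) {
        ids <- ids[keep]
        if (length(ids) == 0) {
          comps[[k]]$identifiers <- NULL
        } else {
          comps[[k]]$identifiers <- ids
        }
      }
    }
    comps
  }

  for (nm in names(record$inputs)) {
    record$inputs[[nm]]$components <- scrub_compound_names(
      record$inputs[[nm]]$components,
      paste0('inputs["', nm, '"].components')
    )
  }
  for (oi in seq_along(record$outcomes)) {
    prods <- record$outcomes[[oi]]$products
    prods <- scrub_compound_names(
      prods, paste0("outcomes[", oi - 1L, "].products")
    )
    # calculated yields: drop YIELD measurements whose integer value is not
    # literally stated in the text
    for (k in seq_along(prods)) {
      ms <- prods[[k]]$measurements
      keep <- rep(TRUE, length(ms))
      for (q in seq_along(ms)) {
        m <- ms[[q]]
        if (identical(m$type, "YIELD") && !is.null(m$percentage$value) &&
            !yield_int_in_text(m$percentage$value, text)) {
          keep[q] <- FALSE
          removed <- c(removed, paste0(
            "outcomes[", oi - 1L, "].products[", k - 1L,
            "].measurements[", q - 1L, "]"
          ))
        }
      }
      if (!all(keep)) {
        ms <- ms[keep]
        if (length(ms) == 0) prods[[k]]$measurements <- NULL
        else prods[[k]]$measurements <- ms
      }
    }
    record$outcomes[[oi]]$products <- prods
  }
  list(record = record, removed = removed)
}

#' Scrub unlearnable implicit information from a corpus
#'
#' Two rules mirror how patent-derived records carry information that is
#' absent from the procedure paragraph and therefore unlearnable from it:
#' a NAME identifier whose value does not occur in the text (after
#' whitespace normalization, case-insensitively) is removed, and a YIELD
#' measurement whose integer percentage value is not stated in the text is
#' removed. Removals are logged by path. Scrubbing is idempotent.
#'
#' @param corpus A data frame with `record` and `procedure_text` columns.
#' @return The corpus tibble with `record` replaced by the scrubbed trees
#'   and a `scrubbed_paths` list-column of removed paths.
#' @export
scrub_implicit <- function(corpus) {
  res <- map2(corpus$record, corpus$procedure_text, scrub_record)
  corpus %>%
    as_tibble() %>%
    mutate(
      record = map(res, "record"),
      scrubbed_paths = map(res, "removed")
    )
}

read_template <- function(template = NULL) {
  if (is.null(template)) {
    template <- system.file("extdata", "prompt_template.txt", package = "ordbench")
  }
  if (file.exists(template)) {
    template <- paste(readLines(template, warn = FALSE), collapse = "\n")
  }
  for (ph in c("{instruction}", "{input}", "{output}")) {
    if (!grepl(ph, template, fixed = TRUE)) {
      abort(
        paste0("prompt template is missing the ", ph, " placeholder"),
        class = "ordbench_config_error"
      )
    }
  }
  template
}

#' Render prompt/completion examples from a corpus
#'
#' The procedure text and the record's canonical JSON serialization are
#' combined through an instruction template (Alpaca-style by default). The
#' prompt is the template up to the `{output}` placeholder with the
#' instruction and procedure text filled in; the completion is the
#' canonical JSON. Rendering is deterministic.
#'
#' @param corpus A data frame with `record` and `procedure_text` columns.
#' @param template Path to a template file or a template string containing
#'   `{instruction}`, `{input}` and `{output}` placeholders. `NULL` uses
#'   the packaged default.
#' @param instruction The instruction sentence.
#' @param tokenizer A function `character -> integer` used for
#'   `token_count`.
#' @return A tibble with columns `source_id` (if present in `corpus`),
#'   `prompt`, `completion`, `token_count` and `split` (initially
#'   `"none"`).
#' @export
render_prompts <- function(corpus, template = NULL,
                           instruction = DEFAULT_INSTRUCTION,
                           tokenizer = count_tokens) {
  tpl <- read_template(template)
  prefix <- sub("\\{output\\}[\\s\\S]*$", "", tpl, perl = TRUE)
  prompts <- map_chr(corpus$procedure_text, function(tx) {
    out <- sub("{instruction}", instruction, prefix, fixed = TRUE)
    sub("{input}", tx, out, fixed = TRUE)
  })
  completions <- map_chr(corpus$record, ord_serialize)
  out <- tibble(
    prompt = prompts,
    completion = completions,
    token_count = tokenizer(paste0(prompts, completions)),
    split = "none"
  )
  if ("source_id" %in% names(corpus)) {
    out <- bind_cols(tibble(source_id = corpus$source_id), out)
  }
  out
}

#' Deduplicate prompt/completion examples
#'
#' Keeps the first occurrence per prompt string (the dedup key is the
#' prompt only), preserving order otherwise. Duplicated prompts carrying a
#' different completion are logged in the `conflicts` attribute.
#'
#' @param examples A data frame with `prompt` and `completion` columns.
#' @return The deduplicated tibble, with attribute `conflicts` (a tibble of
#'   prompts whose duplicates disagreed on the completion).
#' @export
dedupe <- function(examples) {
  examples <- as_tibble(examples)
  first <- !duplicated(examples$prompt)
  kept <- examples[first, ]
  dup <- examples[!first, ]
  conflicts <- dup[
    dup$completion != kept$completion[match(dup$prompt, kept$prompt)],
    c("prompt", "completion")
  ]
  attr(kept, "conflicts") <- conflicts
  kept
}

#' Filter examples by token count
#'
#' @param examples A data frame with a `token_count` column.
#' @param limit Inclusive token limit (default 2048).
#' @return A list with tibbles `kept` (`token_count <= limit`) and
#'   `dropped`.
#' @export
token_filter <- function(examples, limit = 2048) {
  examples <- as_tibble(examples)
  keep <- examples$token_count <= limit
  list(kept = examples[keep, ], dropped = examples[!keep, ])
}

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assign train/validation/test splits
#'
#' Seeded shuffle followed by largest-remainder apportionment of the
#' normalized ratios, so the partition is disjoint, exhaustive and
#' reproducible, with sizes matching the ratios up to rounding.
#'
#' @param examples A data frame of examples.
#' @param ratios Named numeric ratios (default `8:1:1`
#'   train/validation/test); normalized to sum to one.
#' @param seed Integer seed for the shuffle.
#' @return The tibble with its `split` column filled in.
#' @export
split_examples <- function(examples,
                           ratios = c(train = 8, validation = 1, test = 1),
                           seed = 0L) {
  examples <- as_tibble(examples)
  n <- nrow(examples)
  if (n < length(ratios)) {
    abort("fewer examples than splits", class = "ordbench_config_error")
  }
  p <- ratios / sum(ratios)
  exact <- n * p
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_local_seed(seed, sample.int(n))
  split <- character(n)
  offset <- 0L
  for (k in seq_along(sizes)) {
    take <- perm[seq_len(sizes[k]) + offset]
    split[take] <- names(ratios)[k]
    offset <- offset + sizes[k]
  }
  examples$split <- split
  examples
}

#' Corpus preparation report
#'
#' Stage counts through the pipeline with the headline retention
#' percentage, `100 * n_within_limit / n_unique` at one decimal (half-up);
#' a zero denominator is reported as `NA`.
#'
#' @param n_in,n_admitted,n_unique,n_within_limit Non-increasing stage
#'   counts.
#' @param seed The split seed, recorded for reproducibility.
#' @return A one-row tibble.
#' @export
#' @examples
#' prep_report(1500000, 1400000, 1339260, 1300613)$retention_pct # 97.1
prep_report <- function(n_in, n_admitted, n_unique, n_within_limit,
                        seed = NA_integer_) {
  counts <- c(n_in, n_admitted, n_unique, n_within_limit)
  if (any(counts < 0) || any(diff(counts) > 0)) {
    abort("stage counts must be non-negative and non-increasing",
          class = "ordbench_config_error")
  }
  tibble(
    n_in = n_in, n_admitted = n_admitted, n_unique = n_unique,
    n_within_limit = n_within_limit,
    admission_pct = pct_half_up(n_admitted, n_in),
    retention_pct = pct_half_up(n_within_limit, n_unique),
    split_seed = seed
  )
}

#' Run the full corpus preparation pipeline
#'
#' Admission, scrubbing, prompt rendering, deduplication, token filtering
#' and splitting, in that order, with a [prep_report()] of the stage
#' counts.
#'
#' @param corpus A data frame with `source_id`, `procedure_text` and
#'   `record` columns.
#' @inheritParams render_prompts
#' @inheritParams token_filter
#' @inheritParams split_examples
#' @return A list: `examples` (the prepared tibble with split labels),
#'   `report` (one-row tibble), `scrub_log` (tibble of removed paths) and
#'   `dropped` (over-limit examples).
#' @export
prep_corpus <- function(corpus, template = NULL,
                        instruction = DEFAULT_INSTRUCTION,
                        tokenizer = count_tokens, limit = 2048,
                        ratios = c(train = 8, validation = 1, test = 1),
                        seed = 0L) {
  n_in <- nrow(corpus)
  admitted <- admit_records(corpus) %>% filter(.data$admitted)
  scrubbed <- scrub_implicit(admitted)
  examples <- render_prompts(scrubbed, template, instruction, tokenizer)
  unique_ex <- dedupe(examples)
  filtered <- token_filter(unique_ex, limit)
  examples_out <- split_examples(filtered$kept, ratios, seed)
  scrub_log <- tibble(
    source_id = rep(scrubbed$source_id, lengths(scrubbed$scrubbed_paths)),
    path = unlist(scrubbed$scrubbed_paths, use.names = FALSE)
  )
  list(
    examples = examples_out,
    report = prep_report(
      n_in, nrow(admitted), nrow(unique_ex), nrow(filtered$kept), seed
    ),
    scrub_log = scrub_log,
    dropped = filtered$dropped
  )
}
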
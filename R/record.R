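#' Parse an ORD-flavored JSON reaction record
#'
#' Parses JSON text into a message tree (nested named lists). Explicit nulls
#' are stripped so that "populated" is well defined: a field is populated iff
#' it is present in the tree. Unknown fields are retained (and later flagged
#' by [validate_record()]); malformed JSON raises a parse-failure condition
#' of class `ordbench_parse_error`, distinct from a validation failure.
#'
#' @param json_text A length-one character vector of JSON.
#' @param spec A schema tibble from [ord_schema()]; kept for interface
#'   symmetry (parsing itself is schema-free).
#' @return The message tree: a nested list in which JSON objects are named
#'   lists, arrays are unnamed lists and scalars are length-one vectors.
#' @export
#' @examples
#' rec <- parse_record('{"workups": [{"type": "FILTRATION"}]}')
#' leaf_fields(rec)
parse_record <- function(json_text, spec = ord_schema()) {
  node <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) {
      abort(
        paste0("malformed JSON: ", conditionMessage(e)),
        class = "ordbench_parse_error"
      )
    }
  )
  strip_nulls(node)
}

strip_nulls <- function(x) {
  # canonical scalar form: JSON numbers are doubles, so whole-number values
  # round-trip identically
  if (is.integer(x)) return(as.numeric(x))
  if (!is.list(x)) return(x)
  x <- x[!map_lgl(x, is.null)]
  out <- lapply(x, strip_nulls)
  # preserve object-ness of empty named lists
  if (length(out) == 0 && !is.null(names(x))) names(out) <- character(0)
  out
}

#' Serialize a reaction record to canonical JSON
#'
#' The canonical form is compact JSON with scalars unboxed and full numeric
#' precision, so that `parse_record(ord_serialize(x))` reproduces the tree.
#'
#' @param record A message tree as returned by [parse_record()].
#' @return A length-one character vector of JSON.
#' @export
ord_serialize <- function(record) {
  as.character(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA, null = "null"))
}

is_json_object <- function(x) is.list(x) && !is.null(names(x))
is_json_array <- function(x) is.list(x) && is.null(names(x)) && length(x) > 0
is_scalar_leaf <- function(x) is.atomic(x) && length(x) == 1

# Depth-first walk producing one row per populated leaf. Map fields (per the
# schema) get quoted keys in the concrete path; repeated fields get
# zero-based bracketed indices.
walk_leaves <- function(x, concrete = "", general = "", spec = NULL) {
  if (is.null(x)) return(NULL)
  if (is_scalar_leaf(x)) {
    return(list(list(path = concrete, general = general, value = x)))
  }
  if (is.atomic(x)) { # atomic vector of length != 1: treat as scalar array
    x <- as.list(x)
  }
  if (length(x) == 0) return(NULL)
  rows <- list()
  if (!is.null(names(x))) {
    kind <- if (!is.null(spec) && nzchar(general)) schema_kind(spec, general) else NA_character_
    is_map <- identical(kind, "map-of-message")
    for (nm in names(x)) {
      if (is_map) {
        sub_c <- paste0(concrete, '["', nm, '"]')
        sub_g <- paste0(general, ".*")
      } else {
        sub_c <- if (nzchar(concrete)) paste0(concrete, ".", nm) else nm
        sub_g <- if (nzchar(general)) paste0(general, ".", nm) else nm
      }
      rows <- c(rows, walk_leaves(x[[nm]], sub_c, sub_g, spec))
    }
  } else {
    for (i in seq_along(x)) {
      sub_c <- paste0(concrete, "[", i - 1L, "]")
      sub_g <- paste0(general, "[]")
      rows <- c(rows, walk_leaves(x[[i]], sub_c, sub_g, spec))
    }
  }
  rows
}

#' Enumerate the populated leaf fields of a message tree
#'
#' Returns a deterministic, depth-first, index-ordered enumeration of the
#' populated scalar fields. Leaf paths use dotted names with zero-based
#' bracketed list indices and quoted map keys, e.g.
#' `inputs["m1"].components[0].identifiers[0].value`.
#'
#' @param node A message tree ([parse_record()]).
#' @param spec Schema tibble used to recognize map fields for path quoting.
#' @return A tibble with columns `path`, `general` (the schema form of the
#'   path) and `value` (list-column of scalars).
#' @export
leaf_fields <- function(node, spec = ord_schema()) {
  rows <- walk_leaves(node, spec = spec)
  if (length(rows) == 0) {
    return(tibble(path = character(), general = character(), value = list()))
  }
  tibble(
    path = map_chr(rows, "path"),
    general = map_chr(rows, "general"),
    value = map(rows, "value")
  )
}

n_leaves <- function(node) {
  if (is.null(node)) return(0L)
  if (is_scalar_leaf(node)) return(1L)
  if (is.atomic(node)) return(length(node))
  if (length(node) == 0) return(0L)
  sum(vapply(node, n_leaves, integer(1)))
}

#' Validate a record against the schema vocabulary
#'
#' Syntactic validation in the ORD sense: every populated leaf must sit at a
#' known schema path, enums must take an admitted vocabulary string
#' (case-sensitive exact match) and scalars must have the declared type.
#' Validation reports violations rather than throwing; an empty report means
#' the record is a syntactically valid instance of the modeled subset.
#'
#' @param node A message tree ([parse_record()]).
#' @param spec Schema tibble from [ord_schema()].
#' @return A tibble with one row per violation: `path`, `violation` (one of
#'   `"out-of-vocabulary enum"`, `"wrong scalar type"`, `"unknown field"`)
#'   and `value` (offending value, as character).
#' @export
#' @examples
#' bad <- parse_record('{"workups": [{"type": "SHAKEN_VIGOROUSLY"}]}')
#' validate_record(bad)
validate_record <- function(node, spec = ord_schema()) {
  leaves <- leaf_fields(node, spec)
  rows <- list()
  for (i in seq_len(nrow(leaves))) {
    g <- leaves$general[i]
    v <- leaves$value[[i]]
    kind <- schema_kind(spec, g)
    if (is.na(kind)) {
      rows[[length(rows) + 1L]] <- list(
        path = leaves$path[i], violation = "unknown field",
        value = as.character(v)
      )
    } else if (kind == "enum") {
      vocab <- schema_enum(spec, g)
      if (!is.character(v) || !(v %in% vocab)) {
        rows[[length(rows) + 1L]] <- list(
          path = leaves$path[i], violation = "out-of-vocabulary enum",
          value = as.character(v)
        )
      }
    } else if (kind == "scalar-number") {
      if (!is.numeric(v)) {
        rows[[length(rows) + 1L]] <- list(
          path = leaves$path[i], violation = "wrong scalar type",
          value = as.character(v)
        )
      }
    } else if (kind == "scalar-string") {
      if (!is.character(v)) {
        rows[[length(rows) + 1L]] <- list(
          path = leaves$path[i], violation = "wrong scalar type",
          value = as.character(v)
        )
      }
    } else {
      # a leaf where the schema expects a sub-message
      rows[[length(rows) + 1L]] <- list(
        path = leaves$path[i], violation = "wrong scalar type",
        value = as.character(v)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(path = character(), violation = character(), value = character()))
  }
  bind_rows(lapply(rows, as_tibble))
}

#' Is a record syntactically valid?
#'
#' @inheritParams validate_record
#' @return `TRUE` iff [validate_record()] reports no violations.
#' @export
is_valid_record <- function(node, spec = ord_schema()) {
  nrow(validate_record(node, spec)) == 0
}
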
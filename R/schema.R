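#' Load a schema vocabulary
#'
#' Reads a declarative description of the modeled ORD subset: one row per
#' field path, with its kind (scalar, enum, message, repeated-message or
#' map-of-message) and, for enums, the admitted vocabulary. The default file
#' shipped with the package covers the fields exercised by the four
#' chemically important Reaction members: `inputs`, `conditions`, `workups`
#' and `outcomes`.
#'
#' Schema paths use dotted field names, `[]` to mark a repeated field and
#' `.*` to mark the children of a map field, e.g.
#' `inputs.*.components[].identifiers[].value`.
#'
#' @param path Path to a schema JSON file. `NULL` (default) loads the
#'   packaged `ord_schema_subset.json`.
#' @return A tibble with columns `path`, `kind` and `enum` (list-column of
#'   character vocabularies, `NULL` for non-enum fields), carrying the schema
#'   name/version as attributes.
#' @export
#' @examples
#' sch <- ord_schema()
#' sch[sch$kind == "enum", ]
ord_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ord_schema_subset.json", package = "ordbench")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fields <- raw$fields
  spec <- tibble(
    path = map_chr(fields, "path"),
    kind = map_chr(fields, "kind"),
    enum = map(fields, function(f) {
      if (is.null(f$enum)) NULL else unlist(f$enum, use.names = FALSE)
    })
  )
  if (anyDuplicated(spec$path) > 0) {
    abort("schema paths must be unique", class = "ordbench_schema_error")
  }
  bad_enum <- spec$kind == "enum" & !map_lgl(spec$enum, function(v) length(v) > 0)
  if (any(bad_enum)) {
    abort(
      paste0("enum field without vocabulary: ", spec$path[bad_enum][1]),
      class = "ordbench_schema_error"
    )
  }
  attr(spec, "schema_name") <- raw$schema_name
  attr(spec, "schema_version") <- raw$schema_version
  spec
}

# Generalize a concrete leaf path (with quoted map keys and numeric indices)
# to the schema path form: inputs["m1"].components[0].x -> inputs.*.components[].x
generalize_path <- function(path) {
  out <- gsub('\\["([^"]|\\\\")*"\\]', ".*", path)
  gsub("\\[[0-9]+\\]", "[]", out)
}

schema_kind <- function(spec, general_path) {
  i <- match(general_path, spec$path)
  if (is.na(i)) NA_character_ else spec$kind[i]
}

schema_enum <- function(spec, general_path) {
  i <- match(general_path, spec$path)
  if (is.na(i)) NULL else spec$enum[[i]]
}
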
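# Heuristic repair of malformed JSON completions.
#
# Model completions occasionally come back as almost-JSON: a missing quote,
# a dangling comma, an unbalanced bracket. Rather than patching the string
# in place, repair is implemented as a forgiving recursive-descent parser
# that consumes the malformed text into an R structure while logging every
# fix it had to apply, then re-serializes canonically. Valid JSON is a fixed
# point: it is returned byte-identical with an empty action log.

rp_state <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$n <- length(env$chars)
  env$pos <- 1L
  env$actions <- list()
  env
}

rp_log <- function(st, action) {
  st$actions[[length(st$actions) + 1L]] <- list(position = st$pos, action = action)
}

rp_eof <- function(st) st$pos > st$n
rp_peek <- function(st) if (rp_eof(st)) NA_character_ else st$chars[st$pos]
rp_advance <- function(st) st$pos <- st$pos + 1L

rp_skip_ws <- function(st) {
  while (!rp_eof(st) && grepl("^[ \t\r\n]$", st$chars[st$pos])) rp_advance(st)
}

# String body starting after the opening quote; closes at an unescaped
# quote, or (with an insert-quote fix) at a newline or end of text.
rp_parse_string <- function(st) {
  buf <- character(0)
  while (!rp_eof(st)) {
    ch <- rp_peek(st)
    if (ch == "\\") {
      buf <- c(buf, ch)
      rp_advance(st)
      if (!rp_eof(st)) {
        buf <- c(buf, rp_peek(st))
        rp_advance(st)
      }
      next
    }
    if (ch == '"') {
      rp_advance(st)
      return(rp_unescape(paste0(buf, collapse = "")))
    }
    if (ch == "\n") {
      rp_log(st, "insert-quote")
      rp_advance(st)
      return(rp_unescape(paste0(buf, collapse = "")))
    }
    buf <- c(buf, ch)
    rp_advance(st)
  }
  rp_log(st, "insert-quote")
  rp_unescape(paste0(buf, collapse = ""))
}

rp_unescape <- function(s) {
  out <- tryCatch(
    jsonlite::fromJSON(paste0('["', s, '"]'))[[1]],
    error = function(e) s
  )
  out
}

# A bare (unquoted) token: read until a structural delimiter. A trailing
# orphan quote (the residue of a deleted opening quote) is consumed.
rp_parse_bare <- function(st, stop_chars) {
  buf <- character(0)
  while (!rp_eof(st)) {
    ch <- rp_peek(st)
    if (ch %in% stop_chars) break
    if (ch == '"') { # orphan closing quote
      rp_advance(st)
      rp_log(st, "truncate-garbage")
      break
    }
    buf <- c(buf, ch)
    rp_advance(st)
  }
  str_trim(paste0(buf, collapse = ""))
}

rp_bare_value <- function(st) {
  tok <- rp_parse_bare(st, c(",", "}", "]", ":", "\n"))
  if (tok == "") return(NULL)
  if (tok %in% c("true", "false")) return(tok == "true")
  if (tok == "null") return(NULL)
  if (grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", tok)) {
    return(as.numeric(tok))
  }
  rp_log(st, "insert-quote")
  gsub('"', "", tok, fixed = TRUE)
}

rp_parse_value <- function(st, depth = 0) {
  if (depth > 200) abort("repair: nesting too deep", class = "ordbench_repair_error")
  rp_skip_ws(st)
  if (rp_eof(st)) return(NULL)
  ch <- rp_peek(st)
  if (ch == "{") {
    rp_advance(st)
    return(rp_parse_object(st, depth + 1))
  }
  if (ch == "[") {
    rp_advance(st)
    return(rp_parse_array(st, depth + 1))
  }
  if (ch == '"') {
    rp_advance(st)
    return(rp_parse_string(st))
  }
  rp_bare_value(st)
}

rp_parse_object <- function(st, depth) {
  vals <- list()
  nms <- character(0)
  repeat {
    pos_before <- st$pos
    rp_skip_ws(st)
    if (rp_eof(st)) {
      rp_log(st, "insert-bracket")
      break
    }
    ch <- rp_peek(st)
    if (ch == "}") {
      rp_advance(st)
      break
    }
    if (ch == "]") { # stray closer from a swallowed bracket upstream
      rp_advance(st)
      rp_log(st, "insert-bracket")
      break
    }
    if (ch == ",") {
      rp_advance(st)
      rp_skip_ws(st)
      if (rp_eof(st) || rp_peek(st) %in% c("}", "]")) {
        rp_log(st, "delete-trailing-comma")
      }
      next
    }
    # key
    if (ch == '"') {
      rp_advance(st)
      key <- rp_parse_string(st)
    } else {
      key <- rp_parse_bare(st, c(":", ",", "{", "}", "[", "]", "\n"))
      key <- gsub('"', "", key, fixed = TRUE)
      rp_log(st, "insert-quote")
    }
    rp_skip_ws(st)
    if (!rp_eof(st) && rp_peek(st) == ":") {
      rp_advance(st)
    } else {
      rp_log(st, "insert-colon")
    }
    val <- rp_parse_value(st, depth + 1)
    if (!is.null(val)) { # null-valued members are stripped, like at parse
      vals[[length(vals) + 1L]] <- val
      nms <- c(nms, key)
    }
    rp_skip_ws(st)
    if (!rp_eof(st) && !(rp_peek(st) %in% c(",", "}", "]"))) {
      rp_log(st, "insert-comma")
    }
    if (st$pos == pos_before) rp_advance(st) # guarantee progress
  }
  names(vals) <- nms
  if (length(vals) == 0) names(vals) <- character(0)
  vals
}

rp_parse_array <- function(st, depth) {
  vals <- list()
  repeat {
    pos_before <- st$pos
    rp_skip_ws(st)
    if (rp_eof(st)) {
      rp_log(st, "insert-bracket")
      break
    }
    ch <- rp_peek(st)
    if (ch == "]") {
      rp_advance(st)
      break
    }
    if (ch == "}") {
      rp_advance(st)
      rp_log(st, "insert-bracket")
      break
    }
    if (ch == ",") {
      rp_advance(st)
      rp_skip_ws(st)
      if (rp_eof(st) || rp_peek(st) %in% c("}", "]")) {
        rp_log(st, "delete-trailing-comma")
      }
      next
    }
    if (ch == ":") { # garbage separator, skip
      rp_advance(st)
      rp_log(st, "truncate-garbage")
      next
    }
    val <- rp_parse_value(st, depth + 1)
    if (!is.null(val)) vals[[length(vals) + 1L]] <- val
    if (st$pos == pos_before) rp_advance(st)
  }
  vals
}

#' Repair malformed JSON text
#'
#' Syntactically valid input is returned byte-identical with an empty
#' action log. Otherwise the text is re-parsed forgivingly — inserting
#' missing quotes, commas, colons and brackets, deleting trailing commas
#' and skipping trailing garbage — and re-serialized as canonical JSON.
#' Failure (no parse achieved) is a result state, never an error.
#'
#' @param text A length-one character vector.
#' @return A list of class `repair_result`: `repaired_text`, `actions`
#'   (tibble with `position` and `action`), `success` (`TRUE` iff
#'   `repaired_text` parses as JSON).
#' @export
#' @examples
#' repair_json('{"type": NAME}')$repaired_text
repair_json <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty_actions <- tibble(position = integer(), action = character())
  if (jsonlite::validate(text)) {
    return(structure(
      list(repaired_text = text, actions = empty_actions, success = TRUE),
      class = "repair_result"
    ))
  }
  st <- rp_state(text)
  value <- tryCatch(rp_parse_value(st), error = function(e) NULL)
  if (is.null(value)) {
    return(structure(
      list(repaired_text = text, actions = empty_actions, success = FALSE),
      class = "repair_result"
    ))
  }
  rp_skip_ws(st)
  if (!rp_eof(st)) rp_log(st, "truncate-garbage")
  repaired <- ord_serialize(value)
  actions <- tibble(
    position = map_int(st$actions, function(a) as.integer(a$position)),
    action = map_chr(st$actions, "action")
  )
  structure(
    list(
      repaired_text = repaired,
      actions = actions,
      success = jsonlite::validate(repaired)
    ),
    class = "repair_result"
  )
}

#' @export
print.repair_result <- function(x, ...) {
  cat(
    "JSON repair:", if (x$success) "success" else "FAILED",
    "|", nrow(x$actions), "edit(s)\n"
  )
  if (nrow(x$actions) > 0) print(as.data.frame(x$actions), row.names = FALSE)
  invisible(x)
}
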
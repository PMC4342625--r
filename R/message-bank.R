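# The message bank: the full set of feedback texts keyed by
# (determinant, answer pattern, stage or "*"). Externalized as JSON so
# wording can be revised without touching code.

#' Load a message bank
#'
#' Reads a message bank from a JSON array of
#' `{id, determinant, pattern, stage, template}` records. The default bank
#' shipped with the package covers every legal (determinant, answer) pair of
#' the diagnostic questionnaire, all five stage-specific introductions, the
#' personal-feedback blocks and the progress variants. Templates may contain
#' `{steps}`, `{goal}`, `{previous}`, `{current}` and `{delta}` placeholders.
#'
#' @param path path to a bank JSON file; defaults to the bank shipped in
#'   `inst/extdata/message_bank.json`.
#' @return A `message_bank`: a data frame with columns `id`, `determinant`,
#'   `pattern`, `stage`, `template`.
#' @examples
#' bank <- load_message_bank()
#' nrow(bank)
#' @export
load_message_bank <- function(path = NULL) {
  path <- path %||% system.file("extdata", "message_bank.json",
                                package = "steptailor", mustWork = TRUE)
  entries <- jsonlite::fromJSON(path)
  required <- c("id", "determinant", "pattern", "stage", "template")
  if (!is.data.frame(entries) || !all(required %in% names(entries))) {
    stopf("message bank must be a JSON array with fields %s",
          paste(required, collapse = ", "))
  }
  if (anyDuplicated(entries$id)) {
    stopf("duplicate message identifiers in bank: %s",
          paste(unique(entries$id[duplicated(entries$id)]), collapse = ", "))
  }
  structure(entries[required], class = c("message_bank", "data.frame"))
}

# Resolve one (determinant, pattern, stage) key to a message id.
# Stage-specific entries beat wildcard ("*") entries.
lookup_messages <- function(bank, determinant, pattern, stage) {
  hit <- bank$determinant == determinant & bank$pattern == pattern &
    (bank$stage == "*" | bank$stage == stage)
  if (!any(hit)) {
    stopf("no message for determinant `%s`, answer `%s` (stage %s)",
          determinant, pattern, stage)
  }
  ids <- bank$id[hit]
  specific <- bank$stage[hit] != "*"
  if (any(specific)) ids[specific][1] else ids[1]
}

# Render message ids against a placeholder environment (deterministic).
render_message <- function(bank, ids, env) {
  idx <- match(ids, bank$id)
  if (anyNA(idx)) {
    stopf("unknown message identifier(s): %s",
          paste(ids[is.na(idx)], collapse = ", "))
  }
  out <- vapply(bank$template[idx], function(tpl) {
    as.character(glue::glue_data(env, tpl, .open = "{", .close = "}"))
  }, character(1), USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' @export
print.message_bank <- function(x, ...) {
  cat("<message_bank>", nrow(x), "messages,",
      length(unique(x$determinant)), "determinants\n")
  print(table(x$determinant))
  invisible(x)
}
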
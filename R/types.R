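#' Event type system
#'
#' The nine Genia event types handled by the package, grouped into the three
#' usual classes: single-theme events (SVT), Binding (BIN, up to two protein
#' themes) and regulation events (REG, whose theme and optional cause may be
#' proteins or other events).  Event types introduced only in the 2013
#' edition of the shared task are recognized on input but rejected with a
#' warning.
#'
#' @format `EVENT_TYPES` is a character vector of length 9; `EVENT_CLASSES`
#'   a named character vector mapping each type to `"SVT"`, `"BIN"` or
#'   `"REG"`.
#' @name type-system
NULL

#' @rdname type-system
#' @export
EVENT_TYPES <- c(
  "Gene_expression", "Transcription", "Protein_catabolism",
  "Phosphorylation", "Localization",
  "Binding",
  "Regulation", "Positive_regulation", "Negative_regulation"
)

#' @rdname type-system
#' @export
EVENT_CLASSES <- c(
  Gene_expression = "SVT", Transcription = "SVT", Protein_catabolism = "SVT",
  Phosphorylation = "SVT", Localization = "SVT",
  Binding = "BIN",
  Regulation = "REG", Positive_regulation = "REG", Negative_regulation = "REG"
)

REG_TYPES <- names(EVENT_CLASSES)[EVENT_CLASSES == "REG"]

# Label set Y of the pair classifier: the nine types plus None, in the fixed
# order used for deterministic argmax tie-breaking (None last).
LABEL_SET <- c(EVENT_TYPES, "None")

# Types defined only in the 2013 task; not modelled, rejected with a warning.
TYPES_2013_ONLY <- c(
  "Protein_modification", "Ubiquitination", "Acetylation", "Deacetylation"
)

new_entity <- function(id, kind, begin, end, surface,
                       sent = NA_integer_, head_tok = NA_integer_,
                       tok_from = NA_integer_, tok_to = NA_integer_) {
  list(id = id, kind = kind, begin = begin, end = end, surface = surface,
       sent = sent, head_tok = head_tok, tok_from = tok_from, tok_to = tok_to)
}

new_event <- function(id, type, trigger_id, theme_id, theme_is_event,
                      theme2_id = NA_character_, cause_id = NA_character_,
                      cause_is_event = FALSE) {
  list(id = id, type = type, trigger_id = trigger_id,
       theme_id = theme_id, theme_is_event = theme_is_event,
       theme2_id = theme2_id, cause_id = cause_id,
       cause_is_event = cause_is_event)
}

# Topological order of a flat event list (arguments before the events using
# them).  Errors on cycles.
topo_order_events <- function(events) {
  n <- length(events)
  if (n == 0L) return(integer(0))
  ids <- vapply(events, `[[`, "", "id")
  idx <- stats::setNames(seq_len(n), ids)
  deps <- lapply(events, function(e) {
    d <- character(0)
    if (isTRUE(e$theme_is_event)) d <- c(d, e$theme_id)
    if (isTRUE(e$cause_is_event) && !is.na(e$cause_id)) d <- c(d, e$cause_id)
    d
  })
  order <- integer(0)
  state <- integer(n)  # 0 unseen, 1 on stack, 2 done
  visit <- function(i) {
    if (state[i] == 2L) return(invisible(NULL))
    if (state[i] == 1L) stop("cycle in event argument graph", call. = FALSE)
    state[i] <<- 1L
    for (d in deps[[i]]) {
      j <- idx[[d]]
      if (is.null(j)) stop("dangling event argument id: ", d, call. = FALSE)
      visit(j)
    }
    state[i] <<- 2L
    order <<- c(order, i)
    invisible(NULL)
  }
  for (i in seq_len(n)) visit(i)
  order
}

events_are_acyclic <- function(events) {
  !inherits(try(topo_order_events(events), silent = TRUE), "try-error")
}

# Canonical, id-free representation of an event set: recursively expanded
# tuples, sorted.  Used for round-trip comparison and by tests.
canonical_events <- function(events, entities) {
  ev_by_id <- stats::setNames(events, vapply(events, `[[`, "", "id"))
  ent_span <- function(id) {
    e <- entities[[id]]
    paste0("[", e$begin, ",", e$end, ")")
  }
  expand <- function(id, is_event) {
    if (!is_event) return(ent_span(id))
    e <- ev_by_id[[id]]
    trig <- ent_span(e$trigger_id)
    th <- expand(e$theme_id, isTRUE(e$theme_is_event))
    parts <- c(e$type, trig, paste0("Theme=", th))
    if (!is.na(e$theme2_id)) {
      th2 <- ent_span(e$theme2_id)
      # themes of a Binding are unordered
      pair <- sort(c(th, th2))
      parts <- c(e$type, trig, paste0("Theme=", pair[1]),
                 paste0("Theme2=", pair[2]))
    }
    if (!is.na(e$cause_id))
      parts <- c(parts, paste0("Cause=", expand(e$cause_id,
                                                isTRUE(e$cause_is_event))))
    paste0("{", paste(parts, collapse = " "), "}")
  }
  sort(vapply(events, function(e) expand(e$id, TRUE), ""))
}
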
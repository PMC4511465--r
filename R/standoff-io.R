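#' Read a standoff-annotated document
#'
#' Reads one document of a BioNLP-GE style corpus: the plain text (`.txt`),
#' gold protein entities (`.a1`), optional gold triggers and events (`.a2`)
#' and the per-sentence dependency/POS token table.  Character offsets are
#' 0-based half-open into the document text, which is never normalized.
#'
#' The token table is a TSV with columns
#' `sent_idx  tok_idx  surface  begin  end  pos  head  deprel`
#' (one row per fine-grained token; `sent_idx`/`tok_idx` are 1-based and
#' `head` is the 1-based `tok_idx` of the governing token within the same
#' sentence, 0 for the root).
#'
#' @param txt_path path to the `.txt` file.
#' @param a1_path path to the `.a1` file (gold proteins).
#' @param a2_path path to the `.a2` file, or `NULL`/missing file for
#'   unannotated documents (prediction time).
#' @param tok_path path to the token table TSV.
#' @return a `standoff_document`: a list with `doc_id`, `text`, `tokens`
#'   (fine-token data frame), `sentences`, `entities` (named list: proteins
#'   and gold triggers), `proteins` (ids), and `gold_events`.
#' @seealso [write_a2()], [read_standoff_corpus()]
#' @export
read_standoff_document <- function(txt_path, a1_path, a2_path = NULL,
                                   tok_path = NULL) {
  if (!file.exists(txt_path)) stop_data("missing text file: ", txt_path)
  if (!file.exists(a1_path)) stop_data("missing a1 file: ", a1_path)
  text <- readChar(txt_path, file.info(txt_path)$size, useBytes = FALSE)
  doc_id <- sub("\\.txt$", "", basename(txt_path))

  entities <- list()
  proteins <- character(0)
  for (line in read_lines0(a1_path)) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_data("malformed a1 line in ", a1_path, ": ", line)
    ann <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    begin <- as.integer(ann[2]); end <- as.integer(ann[3])
    check_span(begin, end, text, a1_path, line)
    surf <- substr(text, begin + 1L, end)
    if (!identical(surf, f[3]))
      stop_data("surface mismatch in ", a1_path, ": ", line,
                " (text has '", surf, "')")
    entities[[f[1]]] <- new_entity(f[1], "protein", begin, end, surf)
    proteins <- c(proteins, f[1])
  }

  gold_events <- list()
  if (!is.null(a2_path) && file.exists(a2_path)) {
    res <- parse_a2(read_lines0(a2_path), text, entities, a2_path)
    entities <- res$entities
    gold_events <- res$events
  }

  tokens <- NULL
  if (!is.null(tok_path)) {
    if (!file.exists(tok_path)) stop_data("missing token table: ", tok_path)
    tokens <- utils::read.table(
      tok_path, sep = "\t", quote = "", comment.char = "",
      col.names = c("sent_idx", "tok_idx", "surface", "begin", "end",
                    "pos", "head", "deprel"),
      colClasses = c("integer", "integer", "character", "integer",
                     "integer", "character", "integer", "character"),
      stringsAsFactors = FALSE)
    bad <- tokens$begin < 0L | tokens$end > nchar(text) |
      tokens$begin >= tokens$end
    if (any(bad))
      stop_data("token span outside text in ", tok_path, " (row ",
                which(bad)[1], ")")
  }

  doc <- structure(
    list(doc_id = doc_id, text = text, tokens = tokens,
         sentences = NULL, entities = entities, proteins = proteins,
         gold_events = gold_events),
    class = "standoff_document")
  if (!is.null(tokens)) doc <- preprocess_document(doc)
  doc
}

parse_a2 <- function(lines, text, entities, path) {
  events_raw <- list()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- f[1]
    if (startsWith(id, "T")) {
      ann <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      type <- ann[1]
      if (type %in% TYPES_2013_ONLY) {
        warning("ignoring trigger of unmodelled 2013-only type ", type,
                " in ", path, call. = FALSE)
        next
      }
      begin <- as.integer(ann[2]); end <- as.integer(ann[3])
      check_span(begin, end, text, path, line)
      surf <- substr(text, begin + 1L, end)
      entities[[id]] <- new_entity(id, "candidate", begin, end, surf)
    } else if (startsWith(id, "E")) {
      parts <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      kv <- strsplit(parts, ":", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, `[`, "", 2L)
      type <- keys[1]
      if (type %in% TYPES_2013_ONLY) {
        warning("ignoring event of unmodelled 2013-only type ", type,
                " in ", path, call. = FALSE)
        next
      }
      if (!type %in% EVENT_TYPES)
        stop_data("unknown event type '", type, "' in ", path, ": ", line)
      extra <- setdiff(keys[-1], c("Theme", "Theme2", "Cause"))
      if (length(extra))
        stop_data("unsupported argument key(s) ", paste(extra, collapse = ","),
                  " in ", path, ": ", line)
      events_raw[[id]] <- list(id = id, type = type, trigger = vals[1],
                               theme = vals[keys == "Theme"][1],
                               theme2 = if (any(keys == "Theme2"))
                                 vals[keys == "Theme2"][1] else NA_character_,
                               cause = if (any(keys == "Cause"))
                                 vals[keys == "Cause"][1] else NA_character_,
                               line = line)
    }
  }

  events <- list()
  for (r in events_raw) {
    if (is.na(r$theme))
      stop_data("event without Theme in ", path, ": ", r$line)
    resolve <- function(ref) {
      if (startsWith(ref, "E")) {
        if (is.null(events_raw[[ref]]))
          stop_data("dangling argument id ", ref, " in ", path, ": ", r$line)
        list(id = ref, is_event = TRUE)
      } else {
        if (is.null(entities[[ref]]))
          stop_data("dangling argument id ", ref, " in ", path, ": ", r$line)
        list(id = ref, is_event = FALSE)
      }
    }
    if (is.null(entities[[r$trigger]]))
      stop_data("dangling trigger id ", r$trigger, " in ", path, ": ", r$line)
    th <- resolve(r$theme)
    th2 <- NA_character_
    if (!is.na(r$theme2)) {
      t2 <- resolve(r$theme2)
      if (t2$is_event)
        stop_data("Theme2 must be an entity in ", path, ": ", r$line)
      th2 <- t2$id
    }
    cid <- NA_character_; cev <- FALSE
    if (!is.na(r$cause)) {
      cv <- resolve(r$cause)
      cid <- cv$id; cev <- cv$is_event
    }
    events[[r$id]] <- new_event(r$id, r$type, r$trigger,
                                th$id, th$is_event, th2, cid, cev)
  }
  events <- unname(events)
  # validates acyclicity (errors on cyclic gold annotation)
  topo_order_events(events)
  list(entities = entities, events = events)
}

#' Read a directory of standoff documents
#'
#' Expects, for each document basename `D`, files `D.txt`, `D.a1`,
#' `D.tok.tsv` and optionally `D.a2`.
#'
#' @param dir corpus directory.
#' @param with_a2 read gold annotations when present (default `TRUE`).
#' @return a `standoff_corpus`: a named list of `standoff_document`s.
#' @export
read_standoff_corpus <- function(dir, with_a2 = TRUE) {
  if (!dir.exists(dir)) stop_data("corpus directory not found: ", dir)
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    a2 <- paste0(base, ".a2")
    read_standoff_document(tp, paste0(base, ".a1"),
                           if (with_a2 && file.exists(a2)) a2 else NULL,
                           paste0(base, ".tok.tsv"))
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  structure(docs, class = "standoff_corpus")
}

#' Serialize events to a2 text
#'
#' Trigger lines come first (one per distinct trigger entity, ids continuing
#' after the document's `.a1` ids), then event lines in topological order of
#' the argument DAG so that every referenced event is defined before use.
#' Re-reading the output reproduces the same canonical event set.
#'
#' @param events list of events (as stored in a `standoff_document`, or as
#'   returned by [predict.event_model()]); entity references must resolve in
#'   `entities`.
#' @param document the `standoff_document` the events belong to.
#' @param entities optional entity registry overriding `document$entities`
#'   (used for predicted trigger entities).
#' @return a single string of a2 lines (possibly empty).
#' @export
write_a2 <- function(events, document, entities = NULL) {
  if (is.null(entities)) entities <- document$entities
  if (length(events) == 0L) return("")
  ord <- topo_order_events(events)
  events <- events[ord]

  # assign fresh ids: triggers continue after a1 T ids, events E1..
  a1_max <- max(c(0L, as.integer(sub("^T", "", document$proteins))))
  tmap <- list()  # old entity id -> new T id
  lines <- character(0)
  next_t <- a1_max
  for (e in events) {
    tid <- e$trigger_id
    if (is.null(entities[[tid]]))
      stop_data("unresolvable trigger entity ", tid)
    if (!tid %in% names(tmap)) {
      next_t <- next_t + 1L
      new_id <- paste0("T", next_t)
      tmap[[tid]] <- new_id
      ent <- entities[[tid]]
      lines <- c(lines, paste0(new_id, "\t", e$type, " ", ent$begin, " ",
                               ent$end, "\t", ent$surface))
    }
  }
  emap <- list()
  k <- 0L
  ref <- function(id, is_event) {
    if (is_event) {
      v <- emap[[id]]
      if (is.null(v)) stop_data("unresolvable event argument ", id)
      v
    } else {
      if (startsWith(id, "T") && !is.null(entities[[id]]) &&
          entities[[id]]$kind == "protein") id
      else if (!is.null(tmap[[id]])) tmap[[id]]
      else stop_data("unresolvable entity argument ", id)
    }
  }
  for (e in events) {
    k <- k + 1L
    eid <- paste0("E", k)
    emap[[e$id]] <- eid
    args <- paste0(e$type, ":", tmap[[e$trigger_id]], " Theme:",
                   ref(e$theme_id, isTRUE(e$theme_is_event)))
    if (!is.na(e$theme2_id))
      args <- paste0(args, " Theme2:", ref(e$theme2_id, FALSE))
    if (!is.na(e$cause_id))
      args <- paste0(args, " Cause:", ref(e$cause_id, isTRUE(e$cause_is_event)))
    lines <- c(lines, paste0(eid, "\t", args))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

check_span <- function(begin, end, text, path, line) {
  if (is.na(begin) || is.na(end) || begin < 0L || end > nchar(text) ||
      begin >= end)
    stop_data("character offset outside text in ", path, ": ", line)
}

read_lines0 <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x[nzchar(x)]
}
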
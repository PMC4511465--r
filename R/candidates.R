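#' Build a trigger gazetteer from gold annotations
#'
#' The gazetteer is the set of distinct stemmed fine-token sequences
#' observed as gold event triggers in the training corpus.  Stemming the
#' entries generalizes the lexicon across inflections; pure-punctuation
#' sequences are never admitted.
#'
#' @param corpus a `standoff_corpus` (documents must carry gold events).
#' @return a `gazetteer`: list with `entries` (character vector of
#'   space-joined stem sequences) and `max_len` (longest entry in tokens).
#' @export
build_gazetteer <- function(corpus) {
  entries <- character(0)
  for (doc in corpus) {
    if (!length(doc$gold_events)) next
    trig_ids <- unique(vapply(doc$gold_events, `[[`, "", "trigger_id"))
    for (tid in trig_ids) {
      ent <- doc$entities[[tid]]
      if (is.na(ent$sent)) next
      s <- doc$sentences[[sent_pos(doc, ent$sent)]]
      stems <- s$fine$stem[ent$tok_from:ent$tok_to]
      key <- paste(stems, collapse = " ")
      if (grepl("[[:alnum:]]", key)) entries <- c(entries, key)
    }
  }
  entries <- sort(unique(entries))
  if (!length(entries))
    stop_data("no gold events in corpus: cannot build a gazetteer")
  structure(list(entries = entries,
                 max_len = max(lengths(strsplit(entries, " ", fixed = TRUE)))),
            class = "gazetteer")
}

sent_pos <- function(doc, sent_index) {
  which(vapply(doc$sentences, `[[`, 0L, "index") == sent_index)[1]
}

#' Extract trigger candidates from a sentence
#'
#' Greedy longest-match scan of the sentence's stemmed fine tokens against
#' the gazetteer.  At each start position only the longest matching entry is
#' emitted, but scanning resumes at the next token, so shorter entries
#' nested inside a longer match (e.g. "expression" inside "biallelic
#' expression") are also produced.  Tokens fully inside a protein span never
#' become single-token candidates.
#'
#' @param sentence preprocessed sentence.
#' @param gazetteer from [build_gazetteer()].
#' @param text document text (for candidate surfaces); optional.
#' @return list of candidate entities (kind `"candidate"`), possibly empty,
#'   with deterministic ids.
#' @export
extract_candidates <- function(sentence, gazetteer, text = NULL) {
  fine <- sentence$fine
  n <- nrow(fine)
  out <- list()
  for (i in seq_len(n)) {
    max_l <- min(gazetteer$max_len, n - i + 1L)
    for (len in rev(seq_len(max_l))) {
      key <- paste(fine$stem[i:(i + len - 1L)], collapse = " ")
      if (!key %in% gazetteer$entries) next
      if (len == 1L &&
          (fine$fsurf[i] == "PROT" || !grepl("[[:alnum:]]", fine$surface[i])))
        break
      b <- fine$begin[i]; e <- fine$end[i + len - 1L]
      surf <- if (is.null(text)) paste(fine$surface[i:(i + len - 1L)],
                                       collapse = " ")
              else substr(text, b + 1L, e)
      id <- sprintf("C%d.%d.%d", sentence$index, i, len)
      ent <- new_entity(id, "candidate", b, e, surf, sent = sentence$index,
                        tok_from = i, tok_to = i + len - 1L)
      ent$head_tok <- select_head_token(ent, sentence)
      out[[length(out) + 1L]] <- ent
      break  # longest match only at this start position
    }
  }
  out
}

#' Head token of a multi-token entity
#'
#' The representative token used for dependency-based features: the unique
#' entity token whose dependency head lies outside the entity; when there is
#' no such token or several, the rightmost non-punctuation token.
#'
#' @param ent entity with `tok_from`/`tok_to` set.
#' @param sentence preprocessed sentence.
#' @return row index into `sentence$fine`.
#' @export
select_head_token <- function(ent, sentence) {
  fine <- sentence$fine
  rng <- ent$tok_from:ent$tok_to
  if (length(rng) == 1L) return(rng)
  inside <- fine$tok_idx[rng]
  external <- vapply(rng, function(i) {
    h <- fine$head[i]
    h == 0L || !(h %in% inside)
  }, TRUE)
  if (sum(external) == 1L) return(rng[external])
  word <- rng[grepl("[[:alnum:]]", fine$surface[rng])]
  if (length(word)) max(word) else max(rng)
}
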
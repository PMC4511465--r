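# Fixtures are built in code at test time; nothing binary ships with the
# package.  Expensive objects (generated corpora, trained models) are cached
# per test run.

.cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# --- generic in-code document writer --------------------------------------
# sentences: list of list(tokens = data.frame(surface, pos, head, deprel,
# glue), proteins = token indices, a2 = function(begins, ends, tids) ->
# character lines).  Returns a read standoff_document.
write_fixture_doc <- function(doc_id, sentences, dir = tempfile("fix")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  text <- ""
  tok_lines <- character(0)
  a1 <- character(0)
  a2 <- character(0)
  n_t <- 0L
  offset <- 0L
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    tok <- s$tokens
    n <- nrow(tok)
    begins <- integer(n); ends <- integer(n)
    for (i in seq_len(n)) {
      glue <- isTRUE(tok$glue[i])
      if (nzchar(text) && !glue) { text <- paste0(text, " ") }
      begins[i] <- nchar(text)
      text <- paste0(text, tok$surface[i])
      ends[i] <- nchar(text)
    }
    tok_lines <- c(tok_lines, sprintf("%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s",
                                      si, seq_len(n), tok$surface, begins,
                                      ends, tok$pos, tok$head, tok$deprel))
    tids <- character(n)
    for (pt in s$proteins %||% integer(0)) {
      n_t <- n_t + 1L
      tids[pt] <- paste0("T", n_t)
      a1 <- c(a1, sprintf("T%d\tProtein %d %d\t%s", n_t, begins[pt],
                          ends[pt], tok$surface[pt]))
    }
    if (!is.null(s$a2)) a2 <- c(a2, s$a2(begins, ends, tids))
    offset <- nchar(text)
  }
  base <- file.path(dir, doc_id)
  writeLines(text, paste0(base, ".txt"), useBytes = TRUE)
  writeLines(a1, paste0(base, ".a1"), useBytes = TRUE)
  writeLines(a2, paste0(base, ".a2"), useBytes = TRUE)
  writeLines(tok_lines, paste0(base, ".tok.tsv"), useBytes = TRUE)
  read_standoff_document(paste0(base, ".txt"), paste0(base, ".a1"),
                         paste0(base, ".a2"), paste0(base, ".tok.tsv"))
}

tokdf <- function(...) {
  rows <- list(...)
  data.frame(surface = vapply(rows, `[[`, "", 1L),
             pos = vapply(rows, `[[`, "", 2L),
             head = as.integer(vapply(rows, `[[`, "", 3L)),
             deprel = vapply(rows, `[[`, "", 4L),
             glue = vapply(rows, function(r)
               length(r) > 4L && r[5] == "g", TRUE),
             stringsAsFactors = FALSE)
}

# --- the worked example sentence ------------------------------------------
# "Transcriptional regulation of the IL-2 promoter requires the recruitment
#  of NF-kappaB and upregulation of LPS-activated Tax-expression ." plus a
# second sentence carrying the knowledge-base protein c-Rel.
figure_fixture <- function() cached("figure_fixture", {
  s1 <- tokdf(
    c("Transcriptional", "JJ", "2", "AMOD"),
    c("regulation", "NN", "7", "NSUBJ"),
    c("of", "IN", "2", "PREP"),
    c("the", "DT", "6", "DET"),
    c("IL-2", "NN", "6", "NN"),
    c("promoter", "NN", "2", "PREP_OF"),
    c("requires", "VBZ", "0", "ROOT"),
    c("the", "DT", "9", "DET"),
    c("recruitment", "NN", "7", "DOBJ"),
    c("of", "IN", "9", "PREP"),
    c("NF-kappaB", "NN", "9", "PREP_OF"),
    c("and", "CC", "7", "CC"),
    c("upregulation", "NN", "7", "CONJ"),
    c("of", "IN", "13", "PREP"),
    c("LPS", "NN", "17", "NN"),
    c("-", "HYPH", "17", "PUNCT", "g"),
    c("activated", "JJ", "20", "AMOD", "g"),
    c("Tax", "NN", "20", "NN"),
    c("-", "HYPH", "20", "PUNCT", "g"),
    c("expression", "NN", "13", "PREP_OF", "g"),
    c(".", ".", "7", "PUNCT"))
  s2 <- tokdf(
    c("c-Rel", "NN", "3", "NSUBJ"),
    c("was", "VBD", "3", "AUX"),
    c("detected", "VBN", "0", "ROOT"),
    c(".", ".", "3", "PUNCT"))
  write_fixture_doc("figdoc", list(
    list(tokens = s1, proteins = c(5L, 11L, 15L, 18L)),
    list(tokens = s2, proteins = 1L)))
})

# candidate entity over fine tokens [from, to] of a fixture sentence
fixture_candidate <- function(doc, sent, from, to = from) {
  s <- doc$sentences[[sent]]
  ent <- list(id = sprintf("C%d.%d.%d", sent, from, to - from + 1L),
              kind = "candidate",
              begin = s$fine$begin[from], end = s$fine$end[to],
              surface = substr(doc$text, s$fine$begin[from] + 1L,
                               s$fine$end[to]),
              sent = sent, tok_from = from, tok_to = to)
  ent$head_tok <- select_head_token(ent, s)
  ent
}

# --- Figure-1-style document: two Binding events sharing one trigger ------
fig1_fixture <- function() cached("fig1_fixture", {
  s1 <- tokdf(
    c("The", "DT", "2", "DET"),
    c("recruit", "NN", "9", "NSUBJ"),
    c("of", "IN", "2", "PREP"),
    c("Tax", "NN", "2", "PREP_OF"),
    c("to", "IN", "2", "PREP"),
    c("CBP", "NN", "2", "PREP_TO"),
    c("and", "CC", "6", "CC"),
    c("p300", "NN", "6", "CONJ"),
    c("occurred", "VBD", "0", "ROOT"),
    c(".", ".", "9", "PUNCT"))
  write_fixture_doc("fig1doc", list(list(
    tokens = s1, proteins = c(4L, 6L, 8L),
    a2 = function(b, e, tids) c(
      sprintf("T4\tBinding %d %d\trecruit", b[2], e[2]),
      "E1\tBinding:T4 Theme:T1 Theme2:T2",
      "E2\tBinding:T4 Theme:T1 Theme2:T3"))))
})

# --- independent oracles ---------------------------------------------------

# breadth-first shortest-path distance on an undirected edge list
bfs_distance <- function(n, edges, from, to) {
  if (from == to) return(0L)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      if (w == to) return(dist[w])
      queue <- c(queue, w)
    }
  }
  NA_integer_
}

# Literal line-by-line simulation of the recursive agenda extraction, kept
# independent of the package implementation.  `score_fun(cand, arg, is_ev)`
# must return list(shat, yhat).  Returns sorted "trigger|argument|type"
# triples (event themes identified by the inner trigger entity).
oracle_extract <- function(cands, prots, score_fun) {
  pairs <- list()
  mk <- function(ci, arg, is_ev) {
    sc <- score_fun(cands[[ci]], arg, is_ev)
    list(ci = ci, arg = arg, is_ev = is_ev, s = sc$shat, y = sc$yhat)
  }
  for (ci in seq_along(cands))
    for (p in prots) pairs[[length(pairs) + 1L]] <- mk(ci, p, FALSE)
  events <- list()   # list(trig =, arg =, type =)
  expanded <- character(0)
  label_order <- c(EVENT_TYPES, "None")
  while (length(pairs)) {
    s <- vapply(pairs, `[[`, 0, "s")
    cb <- vapply(pairs, function(p) cands[[p$ci]]$begin, 0L)
    ab <- vapply(pairs, function(p) p$arg$begin, 0L)
    yo <- match(vapply(pairs, `[[`, "", "y"), label_order)
    k <- order(-s, cb, ab, yo)[1]
    p <- pairs[[k]]
    pairs[[k]] <- NULL
    if (p$y == "None") next
    trig <- cands[[p$ci]]
    events[[length(events) + 1L]] <- list(trig = trig$id, arg = p$arg$id,
                                          type = p$y)
    if (!trig$id %in% expanded) {
      expanded <- c(expanded, trig$id)
      for (ci2 in seq_along(cands))
        if (cands[[ci2]]$id != trig$id)
          pairs[[length(pairs) + 1L]] <- mk(ci2, trig, TRUE)
    }
    # censor: drop pairs whose acceptance closes a cycle, using a freshly
    # computed transitive closure of trigger -> argument entity edges
    anc <- transitive_reach(events)
    keep <- vapply(pairs, function(q) {
      if (!q$is_ev) return(TRUE)
      ci_id <- cands[[q$ci]]$id
      !(ci_id %in% (anc[[q$arg$id]] %||% character(0)))
    }, TRUE)
    pairs <- pairs[keep]
  }
  sort(vapply(events, function(e) paste(e$trig, e$arg, e$type, sep = "|"),
              ""))
}

# descendants of every node under trigger -> argument edges
transitive_reach <- function(events) {
  out <- list()
  froms <- vapply(events, `[[`, "", "trig")
  tos <- vapply(events, `[[`, "", "arg")
  for (n in unique(froms)) {
    seen <- character(0)
    frontier <- n
    repeat {
      nxt <- setdiff(tos[froms %in% frontier], seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    out[[n]] <- seen
  }
  out
}

# canonical triples from the implementation's event list
core_triples <- function(res) {
  evs <- res$events
  if (!length(evs)) return(character(0))
  ids <- vapply(evs, `[[`, "", "id")
  sort(vapply(evs, function(e) {
    arg <- if (isTRUE(e$theme_is_event))
      evs[[match(e$theme_id, ids)]]$trigger_id else e$theme_id
    paste(e$trigger_id, arg, e$type, sep = "|")
  }, ""))
}

# small entity helpers for mock inference tests
mock_entity <- function(id, begin, kind = "candidate") {
  list(id = id, kind = kind, begin = begin, end = begin + 5L,
       surface = id, sent = 1L, head_tok = 1L, tok_from = 1L, tok_to = 1L)
}

# --- shared generated corpora / models -------------------------------------

separable_corpus_dir <- function() cached("sep_dir", {
  cfg <- corpus_config(seed = 101, n_documents = 40, sentences_per_doc = 5,
                       p_reg_nested = 0.5, p_binding_multitheme = 0.4,
                       noise = 0)
  d <- file.path(tempdir(), "eventpairs-sep200")
  make_separable_corpus(cfg, d)
  d
})

separable_corpus <- function() cached("sep_corpus",
  read_standoff_corpus(separable_corpus_dir()))

separable_model <- function() cached("sep_model",
  event_model(separable_corpus(), seed = 5))

small_corpus <- function() cached("small_corpus", {
  cfg <- corpus_config(seed = 31, n_documents = 12, sentences_per_doc = 4,
                       noise = 0.15)
  d <- file.path(tempdir(), "eventpairs-small")
  generate_corpus(cfg, d)
  read_standoff_corpus(d)
})

small_model <- function() cached("small_model",
  suppressWarnings(event_model(small_corpus(),
                               cpos_grid = c(0.1, 1, 10),
                               cneg_grid = c(0.1, 1),
                               folds = 3, seed = 2)))
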
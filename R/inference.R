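# Score-ordered recursive extraction of (trigger, theme) events.
#
# The agenda starts from all (candidate, protein) pairs; whenever a pair is
# popped and labeled as an event, new (candidate, trigger-entity) pairs are
# created so that nested regulation events can be found, and pending pairs
# whose acceptance would close a cycle are censored.  Each pair is popped at
# most once and the extracted event set is a DAG at every step.

# `score_fun(cand, arg_ent, arg_is_event)` must return list(shat=, yhat=).
# Pair creation, popping order (max score; ties by candidate offset then
# argument offset then label order) and censoring are all deterministic.
extract_events_core <- function(cands, prot_ents, score_fun) {
  events <- list()
  if (!length(cands)) return(list(events = events, pairs = NULL, pops = 0L))

  pair_cand <- integer(0)     # index into cands
  pair_arg <- character(0)    # entity id
  pair_arg_ev <- logical(0)   # argument stands for extracted event(s)
  pair_s <- numeric(0)
  pair_y <- character(0)
  pair_pending <- logical(0)
  arg_ents <- list()          # id -> entity

  add_pair <- function(ci, arg_ent, is_ev) {
    sc <- score_fun(cands[[ci]], arg_ent, is_ev)
    pair_cand <<- c(pair_cand, ci)
    pair_arg <<- c(pair_arg, arg_ent$id)
    pair_arg_ev <<- c(pair_arg_ev, is_ev)
    pair_s <<- c(pair_s, sc$shat)
    pair_y <<- c(pair_y, sc$yhat)
    pair_pending <<- c(pair_pending, TRUE)
    arg_ents[[arg_ent$id]] <<- arg_ent
  }

  for (ci in seq_along(cands))
    for (p in prot_ents) add_pair(ci, p, FALSE)

  # entity-level argument edges of the event DAG: trigger id -> argument id
  edge_from <- character(0); edge_to <- character(0)
  descendants <- function(id) {
    seen <- character(0); frontier <- id
    while (length(frontier)) {
      nxt <- edge_to[edge_from %in% frontier]
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }

  trigger_expanded <- character(0)  # trigger ids whose pairs were created
  ev_by_trigger <- list()           # trigger id -> first event index
  cand_begin <- vapply(cands, `[[`, 0L, "begin")
  pops <- 0L
  max_pops <- length(cands) * (length(prot_ents) + length(cands))

  while (any(pair_pending)) {
    pend <- which(pair_pending)
    s <- pair_s[pend]
    top <- pend[s == max(s)]
    if (length(top) > 1L) {
      ab <- vapply(top, function(i) arg_ents[[pair_arg[i]]]$begin, 0L)
      o <- order(cand_begin[pair_cand[top]], ab,
                 match(pair_y[top], LABEL_SET))
      top <- top[o]
    }
    i <- top[1]
    pair_pending[i] <- FALSE
    pops <- pops + 1L
    if (pops > max_pops) stop("agenda exceeded its pair budget")  # nocov
    yhat <- pair_y[i]
    if (yhat == "None") next

    ca <- cands[[pair_cand[i]]]
    arg_id <- pair_arg[i]
    theme_is_event <- pair_arg_ev[i]
    theme_id <- arg_id
    if (theme_is_event) {
      k <- ev_by_trigger[[arg_id]]
      theme_id <- events[[k]]$id
    }
    eid <- sprintf("X%d", length(events) + 1L)
    events[[length(events) + 1L]] <-
      new_event(eid, yhat, ca$id, theme_id, theme_is_event)
    edge_from <- c(edge_from, ca$id)
    edge_to <- c(edge_to, arg_id)
    if (is.null(ev_by_trigger[[ca$id]]))
      ev_by_trigger[[ca$id]] <- length(events)

    # create pairs with the new trigger entity as argument (once per entity)
    if (!ca$id %in% trigger_expanded) {
      trigger_expanded <- c(trigger_expanded, ca$id)
      for (ci in seq_along(cands))
        if (!identical(cands[[ci]]$id, ca$id)) add_pair(ci, ca, TRUE)
    }
    # censor pending pairs that would close a cycle
    for (j in which(pair_pending & pair_arg_ev)) {
      t_id <- pair_arg[j]
      ci_id <- cands[[pair_cand[j]]]$id
      if (ci_id %in% descendants(t_id)) pair_pending[j] <- FALSE
    }
  }

  pairs <- NULL
  if (length(pair_cand)) {
    pairs <- data.frame(
      cand_id = vapply(pair_cand, function(ci) cands[[ci]]$id, ""),
      cand_begin = cand_begin[pair_cand],
      cand_end = vapply(pair_cand, function(ci) cands[[ci]]$end, 0L),
      arg_id = pair_arg,
      arg_is_event = pair_arg_ev,
      yhat = pair_y,
      shat = pair_s,
      stringsAsFactors = FALSE)
  }
  list(events = events, pairs = pairs, pops = pops,
       cand_index = stats::setNames(seq_along(cands),
                                    vapply(cands, `[[`, "", "id")))
}

#' Extract events from one sentence
#'
#' Runs the recursive agenda extraction with a trained model's pair scorers:
#' all (candidate, protein) pairs are scored, the highest-scoring pair is
#' repeatedly popped, non-None pairs become events, new pairs targeting the
#' fresh trigger entity are added (so regulation events can nest) and
#' pending pairs that would create cycles are censored.
#'
#' @param model a fitted [event_model()].
#' @param document a preprocessed `standoff_document`.
#' @param sentence one element of `document$sentences`.
#' @param delta decision threshold added to the None score; larger values
#'   extract fewer events.
#' @return list with `events`, the candidate `entities` used, and the
#'   scored `pairs` log.
#' @export
extract_events <- function(model, document, sentence, delta = 0) {
  cands <- extract_candidates(sentence, model$gazetteer, document$text)
  prot_ents <- document$entities[sentence$proteins]
  score_fun <- function(cand, arg, is_ev)
    score_pair(model, cand, arg, sentence, arg_is_event = is_ev,
               delta = delta)
  res <- extract_events_core(cands, prot_ents, score_fun)
  list(events = res$events,
       entities = stats::setNames(cands, vapply(cands, `[[`, "", "id")),
       pairs = res$pairs)
}
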
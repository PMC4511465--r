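# Post-processing: secondary arguments for extracted events.  Binding
# singletons sharing a trigger may be fused into two-theme events; REG
# events may receive one optional cause (protein or event), attached
# incrementally under acyclicity constraints.

score_aux <- function(aux, fv) {
  if (isTRUE(aux$always)) return(1)
  idx <- match(fv, aux$vocab)
  idx <- idx[!is.na(idx)]
  sum(aux$w[idx]) + aux$b
}

#' Binding theme fusion
#'
#' For every trigger shared by two or more single-theme Binding events, all
#' unordered theme pairs are scored by the binary fusion classifier;
#' accepted merges create a two-theme event and remove both source
#' singletons.  Conflicting accepted merges are resolved greedily by
#' descending classifier score, each singleton being consumed at most once.
#' Events that referenced a consumed singleton are re-pointed to the merged
#' event.  Idempotent; identity when the fusion classifier is absent.
#'
#' @param events extracted events of one sentence.
#' @param cand_entities candidate entity registry of the sentence.
#' @param sentence preprocessed sentence.
#' @param model fitted `event_model` (its `$fusion` component is used).
#' @return the post-processed event list.
#' @export
binding_fusion <- function(events, cand_entities, sentence, model) {
  aux <- model$fusion
  if (is.null(aux) || !length(events)) return(events)
  is_singleton <- vapply(events, function(e)
    e$type == "Binding" && is.na(e$theme2_id) && !isTRUE(e$theme_is_event),
    TRUE)
  if (sum(is_singleton) < 2L) return(events)
  prot <- sentence$protein_entities
  trig_of <- vapply(events, `[[`, "", "trigger_id")

  combos <- list()
  for (tid in unique(trig_of[is_singleton])) {
    grp <- which(is_singleton & trig_of == tid)
    if (length(grp) < 2L) next
    trig_ent <- cand_entities[[tid]]
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (a >= b) next
      i <- grp[a]; j <- grp[b]
      ea <- prot[[events[[i]]$theme_id]]
      eb <- prot[[events[[j]]$theme_id]]
      fv <- triple_feature_vector(trig_ent, ea, eb, sentence, model$hyper,
                                  model$kb)
      combos[[length(combos) + 1L]] <-
        list(i = i, j = j, score = score_aux(aux, fv),
             key = c(ea$begin, eb$begin))
    }
  }
  if (!length(combos)) return(events)
  acc <- combos[vapply(combos, `[[`, 0, "score") > 0]
  if (!length(acc)) return(events)
  ord <- order(-vapply(acc, `[[`, 0, "score"),
               vapply(acc, function(x) x$key[1], 0L),
               vapply(acc, function(x) x$key[2], 0L))
  acc <- acc[ord]

  consumed <- logical(length(events))
  remap <- list()  # consumed singleton id -> merged event id
  merged <- list()
  n_new <- 0L
  for (m in acc) {
    if (consumed[m$i] || consumed[m$j]) next
    consumed[m$i] <- TRUE; consumed[m$j] <- TRUE
    ei <- events[[m$i]]; ej <- events[[m$j]]
    th <- c(ei$theme_id, ej$theme_id)
    tb <- c(prot[[th[1]]]$begin, prot[[th[2]]]$begin)
    th <- th[order(tb)]
    n_new <- n_new + 1L
    nid <- sprintf("F%d", n_new)
    merged[[n_new]] <- new_event(nid, "Binding", ei$trigger_id,
                                 th[1], FALSE, theme2_id = th[2])
    remap[[ei$id]] <- nid
    remap[[ej$id]] <- nid
  }
  out <- c(events[!consumed], merged)
  # re-point event-valued references to consumed singletons
  lapply(out, function(e) {
    if (isTRUE(e$theme_is_event) && !is.null(remap[[e$theme_id]]))
      e$theme_id <- remap[[e$theme_id]]
    if (isTRUE(e$cause_is_event) && !is.na(e$cause_id) &&
        !is.null(remap[[e$cause_id]]))
      e$cause_id <- remap[[e$cause_id]]
    e
  })
}

#' Regulation cause assignment
#'
#' For each extracted regulation event, candidate causes are the sentence's
#' proteins and the other extracted events (excluding the event's own
#' theme).  Triples (trigger, theme, cause) are scored by the binary cause
#' classifier; accepted causes are attached incrementally in descending
#' score order, each event receiving at most one cause, and attachments
#' that would close a cycle in the event graph are censored.
#'
#' @inheritParams binding_fusion
#' @param doc the document (for protein entities).
#' @return the post-processed event list.
#' @export
assign_causes <- function(events, cand_entities, sentence, doc, model) {
  aux <- model$cause
  if (is.null(aux) || !length(events)) return(events)
  reg <- which(vapply(events, function(e) e$type %in% REG_TYPES, TRUE))
  if (!length(reg)) return(events)
  prot <- sentence$protein_entities
  ev_ids <- vapply(events, `[[`, "", "id")

  cand_list <- list()
  for (i in reg) {
    e <- events[[i]]
    trig_ent <- cand_entities[[e$trigger_id]]
    theme_ent <- if (isTRUE(e$theme_is_event)) {
      inner <- events[[match(e$theme_id, ev_ids)]]
      cand_entities[[inner$trigger_id]]
    } else prot[[e$theme_id]]
    # protein causes
    for (pid in sentence$proteins) {
      if (!isTRUE(e$theme_is_event) && identical(pid, e$theme_id)) next
      fv <- triple_feature_vector(trig_ent, theme_ent, prot[[pid]],
                                  sentence, model$hyper, model$kb,
                                  a_is_event = isTRUE(e$theme_is_event))
      cand_list[[length(cand_list) + 1L]] <-
        list(ev = i, cause_id = pid, is_event = FALSE,
             score = score_aux(aux, fv), begin = prot[[pid]]$begin)
    }
    # event causes
    for (j in seq_along(events)) {
      e2 <- events[[j]]
      if (j == i) next
      if (isTRUE(e$theme_is_event) && identical(e2$id, e$theme_id)) next
      ent2 <- cand_entities[[e2$trigger_id]]
      fv <- triple_feature_vector(trig_ent, theme_ent, ent2, sentence,
                                  model$hyper, model$kb,
                                  a_is_event = isTRUE(e$theme_is_event),
                                  b_is_event = TRUE)
      cand_list[[length(cand_list) + 1L]] <-
        list(ev = i, cause_id = e2$id, is_event = TRUE,
             score = score_aux(aux, fv), begin = ent2$begin)
    }
  }
  if (!length(cand_list)) return(events)
  acc <- cand_list[vapply(cand_list, `[[`, 0, "score") > 0]
  if (!length(acc)) return(events)
  acc <- acc[order(-vapply(acc, `[[`, 0, "score"),
                   vapply(acc, `[[`, 0L, "ev"),
                   vapply(acc, `[[`, 0L, "begin"))]
  for (m in acc) {
    e <- events[[m$ev]]
    if (!is.na(e$cause_id)) next  # one cause per event
    e$cause_id <- m$cause_id
    e$cause_is_event <- m$is_event
    trial <- events
    trial[[m$ev]] <- e
    if (events_are_acyclic(trial)) events <- trial  # else censored
  }
  events
}

#' Train the post-processing classifiers
#'
#' Fusion training pairs come from gold multi-theme Bindings (positives)
#' against co-trigger Binding theme pairs not merged in gold (negatives);
#' cause training triples from gold regulation causes against the other
#' same-sentence candidates.  Both use the same cost-grid machinery as the
#' main pair model.  A classifier with no gold positives is disabled
#' (identity post-processing); one with positives but no negatives accepts
#' everything.
#'
#' @param corpus training corpus with gold events.
#' @param gazetteer,hyper,kb,seed as in [event_model()].
#' @param cpos_grid,cneg_grid cost grids.
#' @param fold_of_doc named fold assignment (document id -> fold).
#' @return list with `fusion` and `cause` classifiers (or `NULL`s).
#' @export
train_postprocessors <- function(corpus, gazetteer, hyper, kb, seed,
                                 cpos_grid, cneg_grid, fold_of_doc) {
  fus_fv <- list(); fus_y <- logical(0); fus_doc <- character(0)
  cau_fv <- list(); cau_y <- logical(0); cau_doc <- character(0)

  for (doc in corpus) {
    ev_by_id <- stats::setNames(doc$gold_events,
                                vapply(doc$gold_events, `[[`, "", "id"))
    by_sent <- split(doc$gold_events, vapply(doc$gold_events, function(e)
      doc$entities[[e$trigger_id]]$sent, 0L))
    for (sk in names(by_sent)) {
      s <- doc$sentences[[sent_pos(doc, as.integer(sk))]]
      evs <- by_sent[[sk]]

      # --- fusion examples
      bind <- evs[vapply(evs, function(e) e$type == "Binding", TRUE)]
      if (length(bind)) {
        trig_of <- vapply(bind, `[[`, "", "trigger_id")
        for (tid in unique(trig_of)) {
          grp <- bind[trig_of == tid]
          themes <- unique(unlist(lapply(grp, function(e)
            c(e$theme_id, if (!is.na(e$theme2_id)) e$theme2_id))))
          if (length(themes) < 2L) next
          gold_merges <- vapply(grp, function(e)
            if (!is.na(e$theme2_id))
              paste(sort(c(e$theme_id, e$theme2_id)), collapse = "|")
            else NA_character_, "")
          gold_merges <- gold_merges[!is.na(gold_merges)]
          trig_ent <- doc$entities[[tid]]
          for (a in seq_along(themes)) for (b in seq_along(themes)) {
            if (a >= b) next
            key <- paste(sort(c(themes[a], themes[b])), collapse = "|")
            fv <- triple_feature_vector(trig_ent,
                                        doc$entities[[themes[a]]],
                                        doc$entities[[themes[b]]],
                                        s, hyper, kb)
            fus_fv[[length(fus_fv) + 1L]] <- fv
            fus_y <- c(fus_y, key %in% gold_merges)
            fus_doc <- c(fus_doc, doc$doc_id)
          }
        }
      }

      # --- cause examples
      regs <- evs[vapply(evs, function(e) e$type %in% REG_TYPES, TRUE)]
      trig_ids <- unique(vapply(evs, `[[`, "", "trigger_id"))
      for (e in regs) {
        trig_ent <- doc$entities[[e$trigger_id]]
        theme_ent <- if (isTRUE(e$theme_is_event))
          doc$entities[[ev_by_id[[e$theme_id]]$trigger_id]]
        else doc$entities[[e$theme_id]]
        gold_cause <- if (is.na(e$cause_id)) NA_character_
          else if (isTRUE(e$cause_is_event))
            ev_by_id[[e$cause_id]]$trigger_id
          else e$cause_id
        cand_ids <- c(s$proteins, setdiff(trig_ids, e$trigger_id))
        cand_ids <- setdiff(cand_ids, theme_ent$id)
        for (cid in cand_ids) {
          cent <- doc$entities[[cid]]
          is_ev <- cent$kind != "protein"
          fv <- triple_feature_vector(trig_ent, theme_ent, cent, s, hyper,
                                      kb,
                                      a_is_event = isTRUE(e$theme_is_event),
                                      b_is_event = is_ev)
          cau_fv[[length(cau_fv) + 1L]] <- fv
          cau_y <- c(cau_y, identical(cid, gold_cause))
          cau_doc <- c(cau_doc, doc$doc_id)
        }
      }
    }
  }

  list(fusion = fit_aux(fus_fv, fus_y, fus_doc, cpos_grid, cneg_grid,
                        fold_of_doc, seed),
       cause = fit_aux(cau_fv, cau_y, cau_doc, cpos_grid, cneg_grid,
                       fold_of_doc, seed))
}

fit_aux <- function(fvecs, y, docs, cpos_grid, cneg_grid, fold_of_doc,
                    seed) {
  if (!length(fvecs) || !any(y)) return(NULL)     # disabled
  if (all(y)) return(list(always = TRUE))         # no negatives observed
  fm <- features_to_matrix(fvecs)
  folds <- fold_of_doc[docs]
  folds[is.na(folds)] <- 1L
  sel <- if (length(unique(folds)) > 1L)
    select_costs(fm$X, y, folds, cpos_grid, cneg_grid, seed)
  else list(cpos = 1, cneg = 1, f1 = NA_real_)
  fit <- fit_binary_svm(fm$X, y, sel$cpos, sel$cneg, seed)
  list(vocab = fm$vocab, w = fit$w, b = fit$b, cpos = sel$cpos,
       cneg = sel$cneg, cv_f1 = sel$f1)
}
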
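# Scoring predictions against gold: approximate-span & recursive matching,
# per-type/class F-scores, pair-level precision-recall curves.

# Extended gold trigger span: the gold span widened by one fine token on
# each side (the "approximate span" dialect; exact-span matching is the
# config-switchable alternative).
extended_span <- function(ent, doc) {
  sp <- sent_pos(doc, ent$sent)
  if (is.na(sp) || !length(sp)) return(c(ent$begin, ent$end))
  fine <- doc$sentences[[sp]]$fine
  hit <- which(fine$begin < ent$end & fine$end > ent$begin)
  if (!length(hit)) return(c(ent$begin, ent$end))
  lo <- max(1L, min(hit) - 1L)
  hi <- min(nrow(fine), max(hit) + 1L)
  c(fine$begin[lo], fine$end[hi])
}

#' Match predicted events against gold events
#'
#' A predicted event matches a gold event iff the types are equal, the
#' predicted trigger span lies within the gold trigger span extended by one
#' fine token on each side (`mode = "approximate"`; `"exact"` requires span
#' equality), and the arguments match recursively: protein arguments by
#' entity identity, event arguments by a matching event under the same
#' criteria, Binding themes as an unordered pair, causes both absent or
#' both matching.  Matching is resolved as a greatest fixpoint over the
#' nesting structure, followed by a greedy one-to-one assignment (most
#' specific gold type first, then offsets).
#'
#' @param gold_events,gold_entities gold side (from a `standoff_document`).
#' @param pred_events,pred_entities predicted side.
#' @param doc the document (token layer used for span extension).
#' @param mode `"approximate"` or `"exact"`.
#' @return list with `pairs` (matched index pairs), `fp`, `fn` index
#'   vectors, and the gold/pred types.
#' @export
match_events <- function(gold_events, gold_entities, pred_events,
                         pred_entities, doc, mode = "approximate") {
  ng <- length(gold_events); np <- length(pred_events)
  gold_types <- vapply(gold_events, `[[`, "", "type")
  pred_types <- vapply(pred_events, `[[`, "", "type")
  if (ng == 0L || np == 0L)
    return(list(pairs = cbind(pred = integer(0), gold = integer(0)),
                fp = seq_len(np), fn = seq_len(ng),
                gold_types = gold_types, pred_types = pred_types))

  gid <- vapply(gold_events, `[[`, "", "id")
  pid <- vapply(pred_events, `[[`, "", "id")

  trig_ok <- matrix(FALSE, np, ng)
  for (j in seq_len(ng)) {
    gt <- gold_entities[[gold_events[[j]]$trigger_id]]
    xs <- if (mode == "approximate") extended_span(gt, doc)
          else c(gt$begin, gt$end)
    for (i in seq_len(np)) {
      if (pred_types[i] != gold_types[j]) next
      pt <- pred_entities[[pred_events[[i]]$trigger_id]]
      trig_ok[i, j] <- if (mode == "approximate")
        pt$begin >= xs[1] && pt$end <= xs[2]
      else pt$begin == gt$begin && pt$end == gt$end
    }
  }

  M <- trig_ok
  repeat {
    M2 <- M
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      if (!M[i, j]) next
      pe <- pred_events[[i]]; ge <- gold_events[[j]]
      ok <- args_match(pe, ge, M, pid, gid)
      if (!ok) M2[i, j] <- FALSE
    }
    if (identical(M2, M)) break
    M <- M2
  }

  # greedy one-to-one: most specific first (fixed type order), then offsets
  cand <- which(M, arr.ind = TRUE)
  if (nrow(cand)) {
    gb <- vapply(gold_events, function(e)
      gold_entities[[e$trigger_id]]$begin, 0L)
    pb <- vapply(pred_events, function(e)
      pred_entities[[e$trigger_id]]$begin, 0L)
    o <- order(match(gold_types[cand[, 2]], LABEL_SET),
               gb[cand[, 2]], pb[cand[, 1]])
    cand <- cand[o, , drop = FALSE]
  }
  used_p <- logical(np); used_g <- logical(ng)
  pairs <- matrix(0L, 0L, 2L, dimnames = list(NULL, c("pred", "gold")))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  list(pairs = pairs, fp = which(!used_p), fn = which(!used_g),
       gold_types = gold_types, pred_types = pred_types)
}

args_match <- function(pe, ge, M, pid, gid) {
  ev_ok <- function(p_id, g_id) {
    i <- match(p_id, pid); j <- match(g_id, gid)
    !is.na(i) && !is.na(j) && M[i, j]
  }
  one <- function(p_ref, p_is_ev, g_ref, g_is_ev) {
    if (isTRUE(g_is_ev) != isTRUE(p_is_ev)) return(FALSE)
    if (isTRUE(g_is_ev)) ev_ok(p_ref, g_ref) else identical(p_ref, g_ref)
  }
  # themes: unordered for two-theme Bindings
  if (!is.na(ge$theme2_id) || !is.na(pe$theme2_id)) {
    if (is.na(ge$theme2_id) || is.na(pe$theme2_id)) return(FALSE)
    gset <- sort(c(ge$theme_id, ge$theme2_id))
    pset <- sort(c(pe$theme_id, pe$theme2_id))
    if (!identical(gset, pset)) return(FALSE)
  } else {
    if (!one(pe$theme_id, pe$theme_is_event,
             ge$theme_id, ge$theme_is_event)) return(FALSE)
  }
  # cause: both absent or both matching
  if (is.na(ge$cause_id) != is.na(pe$cause_id)) return(FALSE)
  if (!is.na(ge$cause_id) &&
      !one(pe$cause_id, pe$cause_is_event, ge$cause_id, ge$cause_is_event))
    return(FALSE)
  TRUE
}

#' Evaluate predictions against gold annotation
#'
#' Runs [match_events()] per document and aggregates true/false
#' positives/negatives into per-type precision, recall and F1, plus
#' micro-aggregated totals for the SVT, BIN and REG classes and overall
#' (`ALL`).  `F1 = 2PR/(P+R)` with `0/0` counted as 0.
#'
#' @param corpus gold corpus.
#' @param predictions an `event_predictions` object (or a corpus read back
#'   from predicted a2 files).
#' @param mode `"approximate"` (default) or `"exact"` span matching.
#' @return an `event_eval` object with a per-type/class table.
#' @export
evaluate_events <- function(corpus, predictions, mode = "approximate") {
  tp <- fp <- fn <- stats::setNames(integer(length(EVENT_TYPES)),
                                    EVENT_TYPES)
  for (p in predictions) {
    doc <- corpus[[p$doc_id]]
    if (is.null(doc)) stop_data("predictions refer to unknown document ",
                                p$doc_id)
    m <- match_events(doc$gold_events, doc$entities, p$events, p$entities,
                      doc, mode)
    for (r in seq_len(nrow(m$pairs)))
      tp[m$gold_types[m$pairs[r, 2]]] <-
        tp[m$gold_types[m$pairs[r, 2]]] + 1L
    for (i in m$fp) fp[m$pred_types[i]] <- fp[m$pred_types[i]] + 1L
    for (j in m$fn) fn[m$gold_types[j]] <- fn[m$gold_types[j]] + 1L
  }
  gold_only <- setdiff(names(corpus),
                       vapply(predictions, `[[`, "", "doc_id"))
  for (d in gold_only)
    for (e in corpus[[d]]$gold_events) fn[e$type] <- fn[e$type] + 1L

  prf <- function(tp, fp, fn) {
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  }
  rows <- list()
  for (t in EVENT_TYPES)
    rows[[t]] <- c(tp = tp[[t]], fp = fp[[t]], fn = fn[[t]],
                   prf(tp[[t]], fp[[t]], fn[[t]]))
  for (cl in c("SVT", "BIN", "REG")) {
    ts <- names(EVENT_CLASSES)[EVENT_CLASSES == cl]
    rows[[paste(cl, "TOTAL")]] <- c(tp = sum(tp[ts]), fp = sum(fp[ts]),
                                    fn = sum(fn[ts]),
                                    prf(sum(tp[ts]), sum(fp[ts]),
                                        sum(fn[ts])))
  }
  rows[["ALL TOTAL"]] <- c(tp = sum(tp), fp = sum(fp), fn = sum(fn),
                           prf(sum(tp), sum(fp), sum(fn)))
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(type = rownames(tab), tab)
  rownames(tab) <- NULL
  structure(list(table = tab, mode = mode), class = "event_eval")
}

#' @export
print.event_eval <- function(x, ...) {
  cat("Event-level evaluation (", x$mode, " span & recursive matching)\n",
      sep = "")
  tab <- x$table
  tab$precision <- round(tab$precision, 4)
  tab$recall <- round(tab$recall, 4)
  tab$f1 <- round(tab$f1, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Cross-validated pair confusion matrix
#'
#' The confusion matrix over the pair label set (the nine event types plus
#' None), computed as the sum of confusion matrices on left-out documents
#' during the cross-validation run inside [event_model()]; rows are
#' predicted labels, columns true labels.
#'
#' @param model fitted `event_model`.
#' @return integer matrix, predicted x true.
#' @export
cv_confusion <- function(model) model$cv_confusion

#' Precision-recall curve over the None threshold
#'
#' Re-runs (trigger, theme) pair extraction — before any post-processing —
#' for each value of the None-score shift `delta` and computes pair-level
#' precision and recall against the gold pair decomposition.  Increasing
#' `delta` makes the extractor more conservative, so recall is
#' non-increasing along the sweep.
#'
#' @param model fitted `event_model`.
#' @param corpus gold corpus to sweep on.
#' @param deltas numeric vector of threshold shifts.
#' @return data frame with `delta`, `precision`, `recall`, `f1`.
#' @export
pr_curve <- function(model, corpus, deltas = seq(-2, 2, by = 0.5)) {
  gold <- lapply(corpus, gold_pair_set)
  out <- lapply(deltas, function(d) {
    preds <- predict(model, corpus, delta = d, postprocess = FALSE)
    tp <- fp <- fn <- 0L
    for (p in preds) {
      g <- gold[[p$doc_id]]
      pp <- pred_pair_set(p)
      m <- match_pairs(g, pp)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    prec <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(delta = d, precision = prec, recall = rec, f1 = f1)
  })
  do.call(rbind, out)
}

# Gold (trigger span, argument key, type) records of one document.
gold_pair_set <- function(doc) {
  keys <- gold_pair_keys(doc)
  ev_by_id <- stats::setNames(doc$gold_events,
                              vapply(doc$gold_events, `[[`, "", "id"))
  rows <- list()
  for (k in names(keys$protein_pairs)) {
    ids <- strsplit(k, "|", fixed = TRUE)[[1]]
    t <- doc$entities[[ids[1]]]
    rows[[length(rows) + 1L]] <- list(tb = t$begin, te = t$end,
                                      arg = ids[2], arg_span = NULL,
                                      type = keys$protein_pairs[[k]])
  }
  for (k in names(keys$event_pairs)) {
    ids <- strsplit(k, "|", fixed = TRUE)[[1]]
    t <- doc$entities[[ids[1]]]
    a <- doc$entities[[ids[2]]]
    rows[[length(rows) + 1L]] <- list(tb = t$begin, te = t$end,
                                      arg = NA_character_,
                                      arg_span = c(a$begin, a$end),
                                      type = keys$event_pairs[[k]])
  }
  rows
}

# Predicted pair records from pre-postprocessing events.
pred_pair_set <- function(p) {
  ev_ids <- vapply(p$events, `[[`, "", "id")
  rows <- list()
  for (e in p$events) {
    t <- p$entities[[e$trigger_id]]
    if (isTRUE(e$theme_is_event)) {
      inner <- p$events[[match(e$theme_id, ev_ids)]]
      a <- p$entities[[inner$trigger_id]]
      rows[[length(rows) + 1L]] <- list(tb = t$begin, te = t$end,
                                        arg = NA_character_,
                                        arg_span = c(a$begin, a$end),
                                        type = e$type)
    } else {
      rows[[length(rows) + 1L]] <- list(tb = t$begin, te = t$end,
                                        arg = e$theme_id, arg_span = NULL,
                                        type = e$type)
    }
  }
  rows
}

match_pairs <- function(gold, pred) {
  used <- logical(length(gold))
  tp <- 0L
  for (pp in pred) {
    hit <- 0L
    for (j in seq_along(gold)) {
      if (used[j]) next
      g <- gold[[j]]
      if (g$type != pp$type) next
      if (!(pp$tb <= g$tb && pp$te >= g$te)) next  # candidate covers trigger
      ok <- if (is.null(g$arg_span)) identical(g$arg, pp$arg)
      else !is.null(pp$arg_span) &&
        pp$arg_span[1] <= g$arg_span[1] && pp$arg_span[2] >= g$arg_span[2]
      if (ok) { hit <- j; break }
    }
    if (hit > 0L) { used[hit] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = length(pred) - tp, fn = sum(!used))
}
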
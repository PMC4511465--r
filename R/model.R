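#' Assemble labeled training pairs
#'
#' Builds, for every sentence, the base pair set (candidate x protein) and
#' the gold-enriched pair set (candidate x gold event trigger) used to train
#' the regulation and None scorers.  Labels come from the gold annotation:
#' a pair is labeled with an event type when a gold event links a trigger
#' covered by the candidate to that argument (a Binding with two themes
#' contributes one pair per theme), and `None` otherwise.  No model
#' predictions are ever used at training time.
#'
#' @param corpus training `standoff_corpus` with gold events.
#' @param gazetteer from [build_gazetteer()].
#' @param hyper list with `k_cand`, `k_arg`, `path_max`, `prune`.
#' @param kb optional protein knowledge table.
#' @return list with `pairs` (each: `doc`, `sent`, `cand`, `arg`,
#'   `arg_is_event`, `label`, `fv`) and `n_skipped` gold events whose
#'   trigger no candidate covers.
#' @export
build_training_pairs <- function(corpus, gazetteer, hyper, kb = NULL) {
  pairs <- list()
  n_skipped <- 0L
  for (doc in corpus) {
    gold <- gold_pair_keys(doc)
    for (s in doc$sentences) {
      cands <- extract_candidates(s, gazetteer, doc$text)
      if (!length(cands)) next
      sent_triggers <- gold$triggers[vapply(gold$triggers, function(t)
        !is.na(t$sent) && t$sent == s$index, TRUE)]

      # which gold trigger (id) does each candidate match?
      cand_match <- vapply(cands, function(ca) {
        match_gold_trigger(ca, sent_triggers)
      }, "")

      for (ca_i in seq_along(cands)) {
        ca <- cands[[ca_i]]
        tmatch <- cand_match[ca_i]
        for (pid in s$proteins) {
          key <- paste0(tmatch, "|", pid)
          lab <- if (nzchar(tmatch) && !is.null(gold$protein_pairs[[key]]))
            gold$protein_pairs[[key]] else "None"
          arg <- doc$entities[[pid]]
          pairs[[length(pairs) + 1L]] <- list(
            doc = doc$doc_id, sent = s$index, cand = ca, arg = arg,
            arg_is_event = FALSE, label = lab,
            fv = pair_feature_vector(ca, arg, s, hyper, kb, FALSE))
        }
        # enriched pairs: gold event triggers as arguments
        for (tid in names(gold$event_trigger_ids)) {
          trig <- doc$entities[[tid]]
          if (is.na(trig$sent) || trig$sent != s$index) next
          if (trig$begin == ca$begin && trig$end == ca$end) next
          key <- paste0(tmatch, "|", tid)
          lab <- if (nzchar(tmatch) && !is.null(gold$event_pairs[[key]]))
            gold$event_pairs[[key]] else "None"
          pairs[[length(pairs) + 1L]] <- list(
            doc = doc$doc_id, sent = s$index, cand = ca, arg = trig,
            arg_is_event = TRUE, label = lab,
            fv = pair_feature_vector(ca, trig, s, hyper, kb, TRUE))
        }
      }

      # recall check: every gold trigger of this sentence must be covered
      for (t in sent_triggers) {
        covered <- any(vapply(cands, function(ca)
          ca$begin <= t$begin && ca$end >= t$end, TRUE))
        if (!covered) {
          n_skipped <- n_skipped + 1L
          message("gold trigger '", t$surface, "' (", doc$doc_id,
                  ") not covered by any candidate; event skipped")
        }
      }
    }
  }
  list(pairs = pairs, n_skipped = n_skipped)
}

# Decompose a document's gold events into pair labels.
# protein_pairs: "Tid_trigger|Tid_protein" -> type (theme and theme_2)
# event_pairs:   "Tid_trigger|Tid_inner_trigger" -> type
gold_pair_keys <- function(doc) {
  ev_by_id <- stats::setNames(doc$gold_events,
                              vapply(doc$gold_events, `[[`, "", "id"))
  protein_pairs <- list(); event_pairs <- list()
  event_trigger_ids <- list()
  put <- function(map, key, type) {
    old <- map[[key]]
    if (is.null(old) ||
        match(type, LABEL_SET) < match(old, LABEL_SET)) map[[key]] <- type
    map
  }
  for (e in doc$gold_events) {
    event_trigger_ids[[e$trigger_id]] <- TRUE
    if (isTRUE(e$theme_is_event)) {
      inner <- ev_by_id[[e$theme_id]]
      key <- paste0(e$trigger_id, "|", inner$trigger_id)
      event_pairs <- put(event_pairs, key, e$type)
    } else {
      protein_pairs <- put(protein_pairs,
                           paste0(e$trigger_id, "|", e$theme_id), e$type)
    }
    if (!is.na(e$theme2_id))
      protein_pairs <- put(protein_pairs,
                           paste0(e$trigger_id, "|", e$theme2_id), e$type)
  }
  trig_ids <- names(event_trigger_ids)
  triggers <- doc$entities[trig_ids]
  list(protein_pairs = protein_pairs, event_pairs = event_pairs,
       event_trigger_ids = event_trigger_ids, triggers = triggers)
}

# Gold trigger id matched by a candidate: exact span first, else the
# smallest gold trigger contained in the candidate span; "" if none.
match_gold_trigger <- function(ca, triggers) {
  if (!length(triggers)) return("")
  tb <- vapply(triggers, `[[`, 0L, "begin")
  te <- vapply(triggers, `[[`, 0L, "end")
  ids <- vapply(triggers, `[[`, "", "id")
  exact <- which(tb == ca$begin & te == ca$end)
  if (length(exact)) return(ids[exact[1]])
  cover <- which(tb >= ca$begin & te <= ca$end)
  if (!length(cover)) return("")
  ids[cover[order(te[cover] - tb[cover])][1]]
}

#' Fit a recursive pairwise event extraction model
#'
#' The single entry point for training.  From a gold-annotated standoff
#' corpus it builds the trigger gazetteer, assembles labeled
#' (candidate, argument) pairs, and fits one cost-asymmetric one-vs-rest
#' linear SVM per label in \{nine event types\} U \{None\}; the per-type
#' costs (C+, C-) are selected on a grid by document-level cross-validation
#' maximizing the type's binary F-score in isolation.  Binary
#' post-classifiers for Binding theme fusion and Regulation cause
#' assignment are trained from the same gold annotation.
#'
#' @param corpus a `standoff_corpus` with gold events (from
#'   [read_standoff_corpus()] or [generate_corpus()]).
#' @param candidate_window,argument_window token window half-widths for
#'   candidate and argument features (defaults 2 and 1).
#' @param path_threshold maximum dependency path length, in edges, for walk
#'   features (default 4).
#' @param prune dependency labels removed before path search.
#' @param cpos_grid,cneg_grid candidate values for the positive/negative
#'   class costs.
#' @param folds number of document-level cross-validation folds.
#' @param seed integer seed for fold assignment and solver shuffling,
#'   recorded in the model.
#' @param kb optional protein knowledge table ([read_protein_kb()]).
#' @param postprocessors train the Binding-fusion and Regulation-cause
#'   classifiers (default `TRUE`).
#' @return an object of class `event_model`.
#' @seealso [predict.event_model()], [pr_curve()], [evaluate_events()]
#' @export
event_model <- function(corpus,
                        candidate_window = 2L, argument_window = 1L,
                        path_threshold = 4L, prune = c("punct", "det"),
                        cpos_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                        cneg_grid = c(0.001, 0.01, 0.05, 0.1, 1, 10),
                        folds = 5L, seed = 1L, kb = NULL,
                        postprocessors = TRUE) {
  if (!length(corpus)) stop_data("empty training corpus")
  hyper <- list(k_cand = as.integer(candidate_window),
                k_arg = as.integer(argument_window),
                path_max = as.integer(path_threshold), prune = prune)
  gaz <- build_gazetteer(corpus)
  tp <- build_training_pairs(corpus, gaz, hyper, kb)
  pairs <- tp$pairs
  if (!length(pairs)) stop_data("no training pairs could be built")

  fm <- features_to_matrix(lapply(pairs, `[[`, "fv"))
  X <- fm$X; vocab <- fm$vocab
  labels <- vapply(pairs, `[[`, "", "label")
  docs_of <- vapply(pairs, `[[`, "", "doc")
  arg_ev <- vapply(pairs, `[[`, TRUE, "arg_is_event")

  doc_ids <- names(corpus)
  fold_of_doc <- with_seed(seed,
    stats::setNames(sample(rep_len(seq_len(folds), length(doc_ids))),
                    doc_ids))
  row_fold <- fold_of_doc[docs_of]

  scorers <- list()
  for (k in LABEL_SET) {
    y <- labels == k
    if (!any(y)) {
      if (k != "None")
        warning("no training example for type ", k, "; type dropped",
                call. = FALSE)
      next
    }
    sel <- select_costs(X, y, row_fold, cpos_grid, cneg_grid, seed)
    fit <- fit_binary_svm(X, y, sel$cpos, sel$cneg, seed)
    scorers[[k]] <- list(w = fit$w, b = fit$b, cpos = sel$cpos,
                         cneg = sel$cneg, cv_f1 = sel$f1)
  }
  if (is.null(scorers[["None"]]))
    stop_data("training corpus has no None pairs; cannot fit a None scorer")

  model <- structure(
    list(gazetteer = gaz, vocab = vocab, scorers = scorers, hyper = hyper,
         folds = folds, fold_of_doc = fold_of_doc, seed = seed, kb = kb,
         fusion = NULL, cause = NULL, cv_confusion = NULL,
         n_pairs = length(pairs), n_skipped = tp$n_skipped),
    class = "event_model")

  model$cv_confusion <- cv_confusion_matrix(model, X, labels, arg_ev,
                                            row_fold)
  if (postprocessors) {
    pp <- train_postprocessors(corpus, gaz, hyper, kb, seed,
                               cpos_grid, cneg_grid, fold_of_doc)
    model$fusion <- pp$fusion
    model$cause <- pp$cause
  }
  model
}

# Sum of per-fold confusion matrices (predicted x true) on left-out pairs,
# refitting every scorer per fold at the selected costs.
cv_confusion_matrix <- function(model, X, labels, arg_ev, row_fold) {
  cm <- matrix(0L, nrow = length(LABEL_SET), ncol = length(LABEL_SET),
               dimnames = list(predicted = LABEL_SET, true = LABEL_SET))
  for (fd in sort(unique(row_fold))) {
    tr <- row_fold != fd; te <- !tr
    if (!any(te) || !any(tr)) next
    S <- matrix(-Inf, nrow = sum(te), ncol = length(LABEL_SET),
                dimnames = list(NULL, LABEL_SET))
    for (k in names(model$scorers)) {
      sc <- model$scorers[[k]]
      fit <- fit_binary_svm(X[tr, , drop = FALSE], labels[tr] == k,
                            sc$cpos, sc$cneg, model$seed)
      S[, k] <- svm_decision(fit, X[te, , drop = FALSE])
    }
    S[arg_ev[te], setdiff(colnames(S), c(REG_TYPES, "None"))] <- -Inf
    pred <- LABEL_SET[apply(S, 1L, which.max)]
    for (i in seq_along(pred))
      cm[pred[i], labels[te][i]] <- cm[pred[i], labels[te][i]] + 1L
  }
  cm
}

#' Score one (candidate, argument) pair
#'
#' Computes the per-label linear scores `s_k = w_k . x + b_k`, masks
#' non-regulation event types to `-Inf` when the argument is an event, adds
#' `delta` to the None score, and returns the argmax decision with its
#' score.  Ties break deterministically in the fixed label order, None
#' last.
#'
#' @param model fitted `event_model`.
#' @param cand,arg candidate and argument entities.
#' @param sentence preprocessed sentence containing both.
#' @param arg_is_event whether the argument stands for extracted event(s).
#' @param delta shift added to the None score.
#' @return list with `scores` (named numeric over the label set), `shat`
#'   and `yhat`.
#' @export
score_pair <- function(model, cand, arg, sentence, arg_is_event = FALSE,
                       delta = 0) {
  fv <- pair_feature_vector(cand, arg, sentence, model$hyper, model$kb,
                            arg_is_event)
  idx <- match(fv, model$vocab)
  idx <- idx[!is.na(idx)]
  s <- vapply(model$scorers, function(sc) sum(sc$w[idx]) + sc$b, 0)
  full <- stats::setNames(rep(-Inf, length(LABEL_SET)), LABEL_SET)
  full[names(s)] <- s
  if (!is.na(full["None"])) full["None"] <- full["None"] + delta
  if (arg_is_event)
    full[setdiff(LABEL_SET, c(REG_TYPES, "None"))] <- -Inf
  best <- which.max(full)  # first max in fixed label order, None last
  list(scores = full, shat = unname(full[best]),
       yhat = names(full)[best])
}

#' @export
print.event_model <- function(x, ...) {
  cat("Recursive pairwise event extraction model\n")
  cat("  gazetteer entries :", length(x$gazetteer$entries), "\n")
  cat("  feature vocabulary:", length(x$vocab), "\n")
  cat("  training pairs    :", x$n_pairs, "\n")
  cat("  scorers           :", paste(names(x$scorers), collapse = ", "),
      "\n")
  cat("  windows (cand/arg):", x$hyper$k_cand, "/", x$hyper$k_arg,
      "; path threshold:", x$hyper$path_max, "\n")
  cat("  post-processors   : fusion",
      if (is.null(x$fusion)) "off" else "on", ", cause",
      if (is.null(x$cause)) "off" else "on", "\n")
  invisible(x)
}

#' @export
summary.event_model <- function(object, ...) {
  sc <- object$scorers
  tab <- data.frame(
    type = names(sc),
    cpos = vapply(sc, `[[`, 0, "cpos"),
    cneg = vapply(sc, `[[`, 0, "cneg"),
    cv_f1 = round(vapply(sc, `[[`, 0, "cv_f1"), 4),
    row.names = NULL)
  structure(list(costs = tab, confusion = object$cv_confusion,
                 n_pairs = object$n_pairs), class = "summary.event_model")
}

#' @export
print.summary.event_model <- function(x, ...) {
  cat("Selected costs and cross-validated F-scores (per type, in",
      "isolation):\n")
  print(x$costs, row.names = FALSE)
  cat("\nCross-validated pair confusion matrix (predicted x true):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
coef.event_model <- function(object, type = NULL, ...) {
  if (is.null(type)) {
    sapply(object$scorers, function(sc)
      stats::setNames(c(sc$w, sc$b), c(object$vocab, "(bias)")))
  } else {
    sc <- object$scorers[[type]]
    if (is.null(sc)) stop_config("no scorer for type ", type)
    stats::setNames(c(sc$w, sc$b), c(object$vocab, "(bias)"))
  }
}

#' Extract events from a corpus
#'
#' Runs per-sentence recursive extraction and post-processing (Binding
#' theme fusion, Regulation cause assignment) over every document and
#' returns the predicted event sets; deterministic given the model.
#'
#' @param object fitted `event_model`.
#' @param corpus a `standoff_corpus` (gold annotations, if present, are
#'   ignored).
#' @param delta None-score decision threshold (default 0).
#' @param postprocess apply Binding fusion and cause assignment.
#' @param ... unused.
#' @return an `event_predictions` object: per document, a list with
#'   `events`, `entities` (protein + predicted trigger entities) and the
#'   scored pair log.  Write to disk with [write_predictions()].
#' @export
predict.event_model <- function(object, corpus, delta = 0,
                                postprocess = TRUE, ...) {
  out <- lapply(corpus, function(doc) {
    events <- list()
    entities <- doc$entities[doc$proteins]
    pair_logs <- list()
    n_ev <- 0L
    for (s in doc$sentences) {
      res <- extract_events(object, doc, s, delta = delta)
      evs <- res$events
      if (postprocess && length(evs)) {
        evs <- binding_fusion(evs, res$entities, s, object)
        evs <- assign_causes(evs, res$entities, s, doc, object)
      }
      # renumber into the document event space
      if (length(evs)) {
        idmap <- stats::setNames(
          sprintf("P%d", n_ev + seq_along(evs)),
          vapply(evs, `[[`, "", "id"))
        evs <- lapply(evs, function(e) {
          e$id <- idmap[[e$id]]
          if (isTRUE(e$theme_is_event)) e$theme_id <- idmap[[e$theme_id]]
          if (isTRUE(e$cause_is_event)) e$cause_id <- idmap[[e$cause_id]]
          e
        })
        n_ev <- n_ev + length(evs)
        events <- c(events, evs)
        entities <- c(entities, res$entities)
      }
      if (!is.null(res$pairs)) pair_logs[[length(pair_logs) + 1L]] <- res$pairs
    }
    list(doc_id = doc$doc_id, events = events, entities = entities,
         pairs = if (length(pair_logs)) do.call(rbind, pair_logs) else NULL)
  })
  structure(out, class = "event_predictions")
}

#' Write predictions as a2 files
#'
#' One `.a2` file per document, deterministic bytes.
#'
#' @param predictions an `event_predictions` object.
#' @param corpus the corpus the predictions were made on.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_predictions <- function(predictions, corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in predictions) {
    doc <- corpus[[p$doc_id]]
    path <- file.path(dir, paste0(p$doc_id, ".a2"))
    cat(write_a2(p$events, doc, entities = p$entities), file = path, sep = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @export
print.event_predictions <- function(x, ...) {
  n <- sum(vapply(x, function(p) length(p$events), 0L))
  cat("Event predictions for", length(x), "document(s):", n, "event(s)\n")
  invisible(x)
}
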
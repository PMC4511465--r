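gold_as_predictions <- function(corp) {
  structure(lapply(corp, function(doc)
    list(doc_id = doc$doc_id, events = doc$gold_events,
         entities = doc$entities, pairs = NULL)),
    class = "event_predictions")
}

test_that("gold evaluated against itself scores 1 for every type present", {
  corp <- small_corpus()
  ev <- evaluate_events(corp, gold_as_predictions(corp))
  tab <- ev$table
  present <- tab$tp + tab$fn > 0
  expect_true(all(tab$f1[present] == 1))
  expect_equal(sum(tab$fp), 0)
  # micro totals: ALL TP equals the per-type sum
  expect_equal(tab$tp[tab$type == "ALL TOTAL"],
               sum(tab$tp[tab$type %in% EVENT_TYPES]))
})

test_that("approximate matching tolerates one-token trigger widening", {
  doc <- fig1_fixture()
  corp <- structure(list(fig1doc = doc), class = "standoff_corpus")
  # widen the predicted trigger one token to the left ("The recruit")
  wide <- fixture_candidate(doc, 1L, 1L, 2L)
  ents <- doc$entities
  ents[[wide$id]] <- wide
  evs <- lapply(doc$gold_events, function(e) { e$trigger_id <- wide$id; e })
  pred <- structure(list(list(doc_id = "fig1doc", events = evs,
                              entities = ents, pairs = NULL)),
                    class = "event_predictions")
  approx <- evaluate_events(corp, pred, mode = "approximate")
  exact <- evaluate_events(corp, pred, mode = "exact")
  expect_equal(approx$table$f1[approx$table$type == "Binding"], 1)
  expect_equal(exact$table$f1[exact$table$type == "Binding"], 0)
})

test_that("a nested event with a wrong inner event cannot match", {
  corp <- small_corpus()
  # find a doc with a nested gold event and corrupt the inner event's type
  for (doc in corp) {
    nested <- which(vapply(doc$gold_events, function(e)
      isTRUE(e$theme_is_event), TRUE))
    if (!length(nested)) next
    outer <- doc$gold_events[[nested[1]]]
    evs <- doc$gold_events
    ids <- vapply(evs, `[[`, "", "id")
    k <- match(outer$theme_id, ids)
    wrong_type <- setdiff(EVENT_TYPES, evs[[k]]$type)[1]
    evs[[k]]$type <- wrong_type
    pred <- structure(list(list(doc_id = doc$doc_id, events = evs,
                                entities = doc$entities, pairs = NULL)),
                      class = "event_predictions")
    sub <- structure(corp[doc$doc_id], class = "standoff_corpus")
    m <- match_events(doc$gold_events, doc$entities, evs, doc$entities,
                      doc)
    # the outer event is unmatched because its inner argument is wrong
    matched_gold <- m$pairs[, "gold"]
    expect_false(nested[1] %in% matched_gold)
    break
  }
})

test_that("planted errors are tallied exactly", {
  corp <- small_corpus()
  doc_id <- names(corp)[[1]]
  doc <- corp[[doc_id]]
  gold_n <- length(doc$gold_events)
  skip_if(gold_n < 2L)
  # drop one gold event (a false negative) and plant one spurious event
  evs <- doc$gold_events
  drop_idx <- which(!vapply(evs, function(e) {
    any(vapply(evs, function(o)
      (isTRUE(o$theme_is_event) && o$theme_id == e$id) ||
        (isTRUE(o$cause_is_event) && !is.na(o$cause_id) &&
           o$cause_id == e$id), TRUE))
  }, TRUE))[1]  # an event nothing else depends on
  dropped <- evs[[drop_idx]]
  evs <- evs[-drop_idx]
  spur <- dropped
  spur$id <- "Xspur"
  spur$type <- setdiff(EVENT_TYPES, dropped$type)[1]
  evs <- c(evs, list(spur))
  pred <- structure(list(list(doc_id = doc_id, events = evs,
                              entities = doc$entities, pairs = NULL)),
                    class = "event_predictions")
  sub <- structure(corp[doc_id], class = "standoff_corpus")
  tab <- evaluate_events(sub, pred)$table
  expect_equal(tab$fn[tab$type == dropped$type], 1)
  expect_equal(tab$fp[tab$type == spur$type], 1)
  expect_equal(tab$tp[tab$type == "ALL TOTAL"], gold_n - 1)
})

test_that("the matcher ignores event-id renaming", {
  doc <- fig1_fixture()
  evs <- doc$gold_events
  evs <- lapply(seq_along(evs), function(i) {
    e <- evs[[i]]; e$id <- paste0("Z", 9 - i); e
  })
  m <- match_events(doc$gold_events, doc$entities, evs, doc$entities, doc)
  expect_identical(nrow(m$pairs), 2L)
  expect_length(m$fp, 0L)
  expect_length(m$fn, 0L)
})

test_that("simple count arithmetic: one correct, one spurious", {
  doc <- fig1_fixture()
  evs <- doc$gold_events[1]
  spur <- doc$gold_events[[2]]
  spur$type <- "Regulation"  # wrong type: cannot match gold Binding
  spur$theme2_id <- NA_character_
  evs <- c(evs, list(spur))
  pred <- structure(list(list(doc_id = "fig1doc", events = evs,
                              entities = doc$entities, pairs = NULL)),
                    class = "event_predictions")
  corp <- structure(list(fig1doc = doc), class = "standoff_corpus")
  tab <- evaluate_events(corp, pred)$table
  all_row <- tab[tab$type == "ALL TOTAL", ]
  expect_equal(all_row$precision, 0.5)
  expect_equal(all_row$recall, 0.5)
  expect_equal(all_row$f1, 0.5)
})
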
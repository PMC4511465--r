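hyper0 <- list(k_cand = 2L, k_arg = 1L, path_max = 4L,
               prune = c("punct", "det"))

test_that("pairs with no gold events are labeled None", {
  s <- tokdf(c("The", "DT", "2", "DET"),
             c("expression", "NN", "5", "NSUBJ"),
             c("of", "IN", "2", "PREP"),
             c("Tax", "NN", "2", "PREP_OF"),
             c("rose", "VBD", "0", "ROOT"),
             c(".", ".", "5", "PUNCT"))
  doc <- write_fixture_doc("nolab", list(list(tokens = s, proteins = 4L)))
  corp <- structure(list(nolab = doc), class = "standoff_corpus")
  gaz <- structure(list(entries = c("express", "rose"), max_len = 1L),
                   class = "gazetteer")
  tp <- build_training_pairs(corp, gaz, hyper0)
  expect_length(tp$pairs, 2L)  # 2 candidates x 1 protein
  expect_true(all(vapply(tp$pairs, `[[`, "", "label") == "None"))
})

test_that("gold events label their pairs; nesting enriches the pair set", {
  corp <- separable_corpus()
  gaz <- build_gazetteer(corp)
  tp <- build_training_pairs(corp, gaz, hyper0)
  labs <- vapply(tp$pairs, `[[`, "", "label")
  ev_arg <- vapply(tp$pairs, `[[`, TRUE, "arg_is_event")
  expect_true(sum(labs != "None") > 0)
  # event-argument pairs may only be labeled REG types or None
  expect_true(all(labs[ev_arg] %in%
                    c("Regulation", "Positive_regulation",
                      "Negative_regulation", "None")))
  # nested gold: at least one enriched pair with a REG label exists
  expect_true(any(labs[ev_arg] != "None"))
  expect_identical(tp$n_skipped, 0L)
})

test_that("a separable corpus admits training F-score 1 at a grid point", {
  corp <- separable_corpus()
  m <- separable_model()
  gaz <- m$gazetteer
  tp <- build_training_pairs(corp, gaz, m$hyper)
  fm <- eventpairs:::features_to_matrix(lapply(tp$pairs, `[[`, "fv"))
  labs <- vapply(tp$pairs, `[[`, "", "label")
  for (k in unique(labs)) {
    fit <- eventpairs:::fit_binary_svm(fm$X, labs == k, 10, 1)
    pred <- eventpairs:::svm_decision(fit, fm$X) > 0
    expect_equal(eventpairs:::binary_f1(pred, labs == k), 1,
                 info = k)
  }
})

test_that("refitting with the same data and seed selects identical costs", {
  corp <- small_corpus()
  m1 <- small_model()
  m2 <- suppressWarnings(event_model(corp, cpos_grid = c(0.1, 1, 10),
                                     cneg_grid = c(0.1, 1), folds = 3,
                                     seed = 2))
  expect_identical(
    lapply(m1$scorers, function(s) c(s$cpos, s$cneg)),
    lapply(m2$scorers, function(s) c(s$cpos, s$cneg)))
  expect_identical(m1$scorers$None$w, m2$scorers$None$w)
})

test_that("scoring masks non-REG labels for event arguments", {
  m <- small_model()
  doc <- s <- cands <- NULL
  for (d in small_corpus()) {
    for (snt in d$sentences) {
      cs <- extract_candidates(snt, m$gazetteer, d$text)
      if (length(cs) >= 2L && length(snt$proteins)) {
        doc <- d; s <- snt; cands <- cs
        break
      }
    }
    if (!is.null(doc)) break
  }
  expect_false(is.null(doc))  # the generator produces such sentences
  prot <- doc$entities[[s$proteins[1]]]
  sc_p <- score_pair(m, cands[[1]], prot, s, arg_is_event = FALSE)
  # every fitted scorer yields a finite score (dropped types score -Inf)
  expect_true(all(is.finite(sc_p$scores[names(m$scorers)])))
  sc_e <- score_pair(m, cands[[1]], cands[[2]], s, arg_is_event = TRUE)
  masked <- setdiff(EVENT_TYPES,
                    c("Regulation", "Positive_regulation",
                      "Negative_regulation"))
  expect_true(all(sc_e$scores[masked] == -Inf))
  expect_true(sc_e$yhat %in% c("Regulation", "Positive_regulation",
                               "Negative_regulation", "None"))
  # shat equals the exhaustive maximum of the per-label scores
  expect_identical(sc_p$shat, max(sc_p$scores))
  expect_identical(sc_p$yhat, names(which.max(sc_p$scores)))
})

test_that("an all-None corpus cannot be fitted", {
  s <- tokdf(c("Tax", "NN", "2", "NSUBJ"), c("rose", "VBD", "0", "ROOT"),
             c(".", ".", "2", "PUNCT"))
  doc <- write_fixture_doc("allnone", list(list(tokens = s, proteins = 1L)))
  corp <- structure(list(allnone = doc), class = "standoff_corpus")
  expect_error(event_model(corp), "no gold events")
})

test_that("the model object carries its reproducibility metadata", {
  m <- small_model()
  expect_identical(m$seed, 2)
  expect_true(all(names(m$fold_of_doc) %in% names(small_corpus())))
  s <- summary(m)
  expect_s3_class(s, "summary.event_model")
  expect_true(all(c("type", "cpos", "cneg", "cv_f1") %in% names(s$costs)))
  cm <- cv_confusion(m)
  expect_identical(dim(cm), c(10L, 10L))
  # column sums equal true pair-label counts
  expect_identical(sum(cm), as.integer(m$n_pairs))
})
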
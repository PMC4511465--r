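test_that("a minimal document reads: one protein, no events", {
  dir <- tempfile()
  dir.create(dir)
  writeLines("Tax was detected .", file.path(dir, "d.txt"))
  writeLines("T1\tProtein 0 3\tTax", file.path(dir, "d.a1"))
  writeLines(sprintf("1\t%d\t%s\t%d\t%d\t%s\t%d\t%s",
                     1:4, c("Tax", "was", "detected", "."),
                     c(0L, 4L, 8L, 17L), c(3L, 7L, 16L, 18L),
                     c("NN", "VBD", "VBN", "."), c(3L, 3L, 0L, 3L),
                     c("NSUBJ", "AUX", "ROOT", "PUNCT")),
             file.path(dir, "d.tok.tsv"))
  doc <- read_standoff_document(file.path(dir, "d.txt"),
                                file.path(dir, "d.a1"),
                                tok_path = file.path(dir, "d.tok.tsv"))
  expect_length(doc$proteins, 1L)
  expect_length(doc$gold_events, 0L)
  expect_identical(doc$entities$T1$surface, "Tax")
  expect_identical(doc$entities$T1$sent, 1L)
})

test_that("two Binding events can share one trigger entity", {
  doc <- fig1_fixture()
  expect_length(doc$gold_events, 2L)
  trig <- unique(vapply(doc$gold_events, `[[`, "", "trigger_id"))
  expect_length(trig, 1L)
  expect_identical(doc$entities[[trig]]$surface, "recruit")
  th2 <- sort(vapply(doc$gold_events, function(e)
    doc$entities[[e$theme2_id]]$surface, ""))
  expect_identical(th2, c("CBP", "p300"))
  expect_true(all(vapply(doc$gold_events, function(e)
    doc$entities[[e$theme_id]]$surface, "") == "Tax"))
})

test_that("malformed corpora raise informative errors", {
  dir <- tempfile()
  dir.create(dir)
  writeLines("Tax binds CBP .", file.path(dir, "d.txt"))
  # offset outside the text
  writeLines("T1\tProtein 0 99\tTax", file.path(dir, "bad1.a1"))
  expect_error(read_standoff_document(file.path(dir, "d.txt"),
                                      file.path(dir, "bad1.a1")),
               "offset outside text")
  # surface mismatch
  writeLines("T1\tProtein 0 3\tCBP", file.path(dir, "bad2.a1"))
  expect_error(read_standoff_document(file.path(dir, "d.txt"),
                                      file.path(dir, "bad2.a1")),
               "surface mismatch")
  # dangling argument id
  writeLines("T1\tProtein 0 3\tTax", file.path(dir, "d.a1"))
  writeLines(c("T2\tBinding 4 9\tbinds", "E1\tBinding:T2 Theme:T9"),
             file.path(dir, "d.a2"))
  expect_error(read_standoff_document(file.path(dir, "d.txt"),
                                      file.path(dir, "d.a1"),
                                      file.path(dir, "d.a2")),
               "dangling")
  # cyclic gold events
  writeLines(c("T2\tPositive_regulation 4 9\tbinds",
               "E1\tPositive_regulation:T2 Theme:E2",
               "E2\tPositive_regulation:T2 Theme:E1"),
             file.path(dir, "cyc.a2"))
  expect_error(read_standoff_document(file.path(dir, "d.txt"),
                                      file.path(dir, "d.a1"),
                                      file.path(dir, "cyc.a2")),
               "cycle")
})

test_that("2013-only event types are rejected with a warning", {
  dir <- tempfile()
  dir.create(dir)
  writeLines("Tax acetylation occurs .", file.path(dir, "d.txt"))
  writeLines("T1\tProtein 0 3\tTax", file.path(dir, "d.a1"))
  writeLines(c("T2\tAcetylation 4 15\tacetylation",
               "E1\tAcetylation:T2 Theme:T1"),
             file.path(dir, "d.a2"))
  w <- testthat::capture_warnings(
    doc <- read_standoff_document(file.path(dir, "d.txt"),
                                  file.path(dir, "d.a1"),
                                  file.path(dir, "d.a2")))
  expect_true(all(grepl("2013-only", w)))
  expect_gte(length(w), 1L)
  expect_length(doc$gold_events, 0L)
})

test_that("write_a2 is empty for no events and counts lines for one", {
  doc <- fig1_fixture()
  expect_identical(write_a2(list(), doc), "")
  one <- doc$gold_events[1]
  lines <- strsplit(write_a2(one, doc), "\n")[[1]]
  expect_length(lines, 2L)  # exactly one trigger line + one event line
  expect_match(lines[1], "^T\\d+\tBinding \\d+ \\d+\trecruit$")
  expect_match(lines[2], "^E1\tBinding:T\\d+ Theme:T1 Theme2:T2$")
})

test_that("nested event lines are emitted in topological order", {
  corp <- small_corpus()
  found <- FALSE
  for (doc in corp) {
    nested <- vapply(doc$gold_events, function(e)
      isTRUE(e$theme_is_event), TRUE)
    if (!any(nested)) next
    found <- TRUE
    lines <- strsplit(write_a2(doc$gold_events, doc), "\n")[[1]]
    elines <- grep("^E", lines, value = TRUE)
    seen <- character(0)
    for (l in elines) {
      id <- sub("\t.*", "", l)
      refs <- regmatches(l, gregexpr("(Theme|Cause):(E\\d+)", l))[[1]]
      for (r in refs) expect_true(sub(".*:", "", r) %in% seen)
      seen <- c(seen, id)
    }
  }
  expect_true(found)
})

test_that("read-write-read is a fixed point modulo id renaming", {
  for (corp in list(separable_corpus(), small_corpus())) {
    for (doc in corp) {
      a2 <- write_a2(doc$gold_events, doc)
      res <- eventpairs:::parse_a2(
        strsplit(a2, "\n")[[1]], doc$text,
        doc$entities[doc$proteins], "roundtrip")
      expect_identical(
        eventpairs:::canonical_events(res$events, res$entities),
        eventpairs:::canonical_events(doc$gold_events, doc$entities))
    }
  }
})
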
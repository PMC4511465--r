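test_that("candidate features reproduce the documented indicator strings", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  reg <- fixture_candidate(doc, 1L, 2L)        # "regulation"
  f <- candidate_features(reg, s1, k_window = 2L)
  expect_true("cand:stem=regul" %in% f)
  expect_true("cand:parent=NSUBJ←requir/VBZ" %in% f)
  expect_true("cand:pos=NN" %in% f)
  upreg <- fixture_candidate(doc, 1L, 13L)     # "upregulation"
  f2 <- candidate_features(upreg, s1, k_window = 2L)
  expect_true("cand:prefix=up" %in% f2)
})

test_that("boundary windows emit explicit padding features", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  first <- fixture_candidate(doc, 1L, 1L)      # sentence-initial token
  f <- candidate_features(first, s1, k_window = 2L)
  expect_true("cand:win_stem[-2]=<PAD>" %in% f)
  expect_true("cand:win_stem[-1]=<PAD>" %in% f)
  expect_true("cand:win_pos[-1]=<PAD>" %in% f)
})

test_that("argument features flag proteins and carry KB labels", {
  doc <- figure_fixture()
  kb <- read_protein_kb(system.file("extdata", "protein_kb_synthetic.tsv",
                                    package = "eventpairs"))
  s2 <- doc$sentences[[2]]
  crel <- doc$entities[[Filter(function(id)
    doc$entities[[id]]$surface == "c-Rel", doc$proteins)[[1]]]]
  f <- argument_features(crel, s2, k_window = 1L, kb = kb)
  expect_true("arg:is_protein" %in% f)
  expect_true("arg:pos=NN" %in% f)
  expect_true(all(c("arg:kb=association", "arg:kb=physical association")
                  %in% f))
  # event-valued arguments lack the protein flag
  reg <- fixture_candidate(doc, 1L, 2L)
  f2 <- argument_features(reg, doc$sentences[[1]], is_event = TRUE)
  expect_false("arg:is_protein" %in% f2)
})

test_that("pruned shortest paths agree with a breadth-first oracle", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  # same head -> empty path
  p0 <- dependency_path(2L, 2L, s1)
  expect_identical(nrow(p0$edges), 0L)
  # regulation -> IL-2 runs through promoter, two edges
  il2 <- which(s1$fine$surface == "IL-2")
  p <- dependency_path(2L, il2, s1)
  expect_identical(p$nodes, c(2L, 6L, il2))
  # oracle comparison on random graphs
  set.seed(99)
  for (rep in 1:25) {
    n <- 10L
    heads <- c(0L, vapply(2:n, function(i)
      if (stats::runif(1) < 0.2) 0L else sample(seq_len(i - 1L), 1L), 0L))
    fine <- data.frame(tok_idx = 1:n, surface = letters[1:n],
                       begin = (0:(n - 1L)) * 2L, end = (0:(n - 1L)) * 2L + 1L,
                       pos = "NN", head = heads, deprel = "DEP",
                       fsurf = letters[1:n], stem = letters[1:n],
                       fstem = letters[1:n])
    g <- igraph::make_empty_graph(n = n)
    el <- rbind(heads[heads > 0], which(heads > 0))
    g <- igraph::add_edges(g, as.vector(el),
                           attr = list(label = rep("DEP", ncol(el))))
    sent <- list(fine = fine, graph = g)
    from <- sample(n, 1L); to <- sample(n, 1L)
    d <- bfs_distance(n, t(el), from, to)
    p <- dependency_path(from, to, sent, prune = character(0),
                         max_len = 99L)
    if (is.na(d)) expect_null(p)
    else expect_identical(length(p$nodes) - 1L, d)
  }
})

test_that("paths over the length threshold are absent, not errors", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  il2 <- which(s1$fine$surface == "IL-2")
  expect_null(dependency_path(2L, il2, s1, max_len = 1L))
})

test_that("walk features match the documented V-walk/E-walk encoding", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  reg <- fixture_candidate(doc, 1L, 2L)
  il2_tok <- which(s1$fine$surface == "IL-2")
  il2 <- doc$entities[[Filter(function(id)
    doc$entities[[id]]$surface == "IL-2", doc$proteins)[[1]]]]
  path <- dependency_path(reg$head_tok, il2$head_tok, s1)
  f <- joint_features(reg, il2, s1, path)
  expect_true("joint:vwalk_stem=regul PREP_OF ←promot" %in% f)
  expect_true("joint:vwalk_stem=promot NN ←PROT" %in% f)
  # POS and stem walk variants come in equal numbers
  expect_identical(sum(grepl("vwalk_stem", f)), sum(grepl("vwalk_pos", f)))
  expect_identical(sum(grepl("ewalk_stem", f)), sum(grepl("ewalk_pos", f)))
  # E-walks use START/END sentinels
  expect_true(any(grepl("^joint:ewalk_stem=START regul ", f)))
  expect_true(any(grepl(" PROT END$", f)))
  # empty path -> no walk features
  f0 <- joint_features(reg, il2, s1, NULL)
  expect_false(any(grepl("walk", f0)))
})

test_that("entities sharing a coarse token emit the ARG-<stem> feature", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  expr <- fixture_candidate(doc, 1L, 20L)      # "expression"
  tax <- doc$entities[[Filter(function(id)
    doc$entities[[id]]$surface == "Tax", doc$proteins)[[1]]]]
  path <- dependency_path(expr$head_tok, tax$head_tok, s1)
  f <- joint_features(expr, tax, s1, path)
  expect_true("joint:shared=ARG-express" %in% f)
  # embedded-entity candidate features see the masked coarse token
  fc <- candidate_features(expr, s1)
  expect_true("cand:coarse=PROT-expression" %in% fc)
  expect_true("cand:coarse_stem=PROT-express" %in% fc)
})

test_that("feature extraction is pure: identical inputs, identical output", {
  doc <- figure_fixture()
  s1 <- doc$sentences[[1]]
  reg <- fixture_candidate(doc, 1L, 2L)
  expect_identical(candidate_features(reg, s1), candidate_features(reg, s1))
})
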
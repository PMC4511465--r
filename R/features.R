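# Sparse binary feature extraction for (trigger, argument) pair
# classification.  Every feature is a named indicator; a feature vector is a
# character vector of names, namespaced by group ("cand:", "arg:", "joint:").
# Extraction is a pure function of (sentence, entities, hyperparameters).

ARROW_L <- "←"  # dependency arrow pointing at the dependent
ARROW_R <- "→"

#' Candidate-entity features
#'
#' Lexical, affix, dependency-parent/child and token-window indicators for a
#' trigger candidate, computed on protein-masked surfaces: head-token stem,
#' stem with `-`/`/` stripped, substring after `-`, head POS, separator
#' position flags, special prefixes (`over`, `up`, `down`, `co`),
#' parent/child `(dep-tag, stem/POS)` conjunctions, stems and POS of the
#' `k_window` tokens on each side (with explicit padding at sentence
#' boundaries), separator presence in the window, a sentence-level `mRNA`
#' flag, and the masked coarse token when the entity is embedded in a larger
#' coarse token.
#'
#' @param ent candidate entity (with `head_tok`, `tok_from`, `tok_to`).
#' @param sentence preprocessed sentence of the entity.
#' @param k_window window half-width in tokens (default 2).
#' @return character vector of feature names.
#' @export
candidate_features <- function(ent, sentence, k_window = 2L) {
  fine <- sentence$fine
  h <- ent$head_tok
  if (is.na(h)) stop("candidate entity without head token")
  f <- character(0)
  add <- function(x) f <<- c(f, x)

  hs <- fine$fsurf[h]
  add(paste0("cand:stem=", fine$fstem[h]))
  strip <- gsub("^[-/]+|[-/]+$", "", hs)
  if (nzchar(strip) && !identical(strip, hs))
    add(paste0("cand:stem_strip=", feature_stem(strip)))
  if (grepl("-", hs, fixed = TRUE)) {
    post <- tolower(sub(".*-", "", hs))
    if (nzchar(post)) add(paste0("cand:post_hyphen=", post))
  }
  add(paste0("cand:pos=", fine$pos[h]))

  first_s <- fine$surface[ent$tok_from]
  last_s <- fine$surface[ent$tok_to]
  prev_s <- if (ent$tok_from > 1L) fine$surface[ent$tok_from - 1L] else ""
  next_s <- if (ent$tok_to < nrow(fine)) fine$surface[ent$tok_to + 1L] else ""
  if (prev_s %in% c("-", "/") || grepl("^[-/]", first_s))
    add("cand:first_after_sep")
  if (next_s %in% c("-", "/") || grepl("[-/]$", last_s))
    add("cand:last_before_sep")

  lh <- tolower(hs)
  for (pre in c("over", "up", "down", "co"))
    if (startsWith(lh, pre)) add(paste0("cand:prefix=", pre))

  add(dep_neighbour_features("cand", h, fine))
  add(window_features("cand", ent, fine, k_window, with_sep = TRUE))
  if (any(grepl("mRNA", fine$surface, fixed = TRUE))) add("cand:sent_mRNA")
  add(coarse_embed_features("cand", ent, sentence))
  unique(f)
}

#' Argument features
#'
#' A reduced version of the candidate feature set for the argument side of a
#' pair: an is-protein flag, head POS, optional interaction labels from a
#' local protein knowledge table, token-window stems/POS, and the dependency
#' parent conjunction.  Event-valued arguments (trigger entities of already
#' extracted events) simply lack the is-protein flag, which is what lets the
#' classifier honour the constraint that only regulation events take event
#' arguments.
#'
#' @param ent argument entity (protein or trigger entity).
#' @param sentence preprocessed sentence.
#' @param k_window window half-width (default 1).
#' @param kb optional protein knowledge table from [read_protein_kb()].
#' @param is_event `TRUE` when the argument stands for an extracted event.
#' @return character vector of feature names.
#' @export
argument_features <- function(ent, sentence, k_window = 1L, kb = NULL,
                              is_event = FALSE) {
  fine <- sentence$fine
  h <- ent$head_tok
  f <- character(0)
  if (!is_event && identical(ent$kind, "protein")) f <- c(f, "arg:is_protein")
  f <- c(f, paste0("arg:pos=", fine$pos[h]))
  if (!is.null(kb) && identical(ent$kind, "protein")) {
    labs <- kb[[ent$surface]]
    if (!is.null(labs)) f <- c(f, paste0("arg:kb=", labs))
  }
  f <- c(f, window_features("arg", ent, fine, k_window, with_sep = FALSE))
  p <- fine$head[h]
  if (p > 0L) {
    pi <- match(p, fine$tok_idx)
    f <- c(f, paste0("arg:parent=", fine$deprel[h], ARROW_L,
                     fine$fstem[pi], "/", fine$pos[pi]))
  }
  unique(f)
}

dep_neighbour_features <- function(ns, h, fine) {
  f <- character(0)
  p <- fine$head[h]
  if (p > 0L) {
    pi <- match(p, fine$tok_idx)
    f <- c(f, paste0(ns, ":parent=", fine$deprel[h], ARROW_L,
                     fine$fstem[pi], "/", fine$pos[pi]))
  }
  kids <- which(fine$head == fine$tok_idx[h])
  for (ci in kids)
    f <- c(f, paste0(ns, ":child=", fine$deprel[ci], ARROW_R,
                     fine$fstem[ci], "/", fine$pos[ci]))
  f
}

window_features <- function(ns, ent, fine, k, with_sep) {
  f <- character(0)
  n <- nrow(fine)
  offs <- c(-(k:1), 1:k)
  for (o in offs) {
    i <- if (o < 0L) ent$tok_from + o else ent$tok_to + o
    tag <- sprintf("[%+d]", o)
    if (i < 1L || i > n) {
      f <- c(f, paste0(ns, ":win_stem", tag, "=<PAD>"),
             paste0(ns, ":win_pos", tag, "=<PAD>"))
      if (with_sep) f <- c(f, paste0(ns, ":win_sep", tag, "=NONE"))
    } else {
      f <- c(f, paste0(ns, ":win_stem", tag, "=", fine$fstem[i]),
             paste0(ns, ":win_pos", tag, "=", fine$pos[i]))
      if (with_sep) {
        sep <- if (grepl("[-/]", fine$surface[i])) "hyphen" else "NONE"
        f <- c(f, paste0(ns, ":win_sep", tag, "=", sep))
      }
    }
  }
  f
}

coarse_embed_features <- function(ns, ent, sentence) {
  fine <- sentence$fine
  h <- ent$head_tok
  tb <- fine$begin[h]; te <- fine$end[h]
  co <- sentence$coarse
  i <- which(co$begin <= tb & co$end >= te &
               (co$end - co$begin) > (te - tb))
  if (!length(i)) return(character(0))
  i <- i[1]
  full <- co$fsurf[i]
  # variant with the entity's own piece stemmed: PROT-expression -> PROT-express
  rel_b <- tb - co$begin[i]; rel_e <- te - co$begin[i]
  raw <- co$surface[i]
  piece <- substr(raw, rel_b + 1L, rel_e)
  stem_var <- paste0(mask_piece(substr(raw, 1L, rel_b), co$begin[i], sentence),
                     feature_stem(piece),
                     mask_piece(substr(raw, rel_e + 1L, nchar(raw)),
                                co$begin[i] + rel_e, sentence))
  c(paste0(ns, ":coarse=", full), paste0(ns, ":coarse_stem=", stem_var))
}

# Apply protein masking to a substring of the document given its offset.
mask_piece <- function(s, begin0, sentence) {
  if (!nzchar(s)) return(s)
  tok <- data.frame(surface = s, begin = begin0, end = begin0 + nchar(s))
  ents <- sentence$protein_entities
  if (is.null(ents)) return(s)
  substitute_proteins(tok, ents)$fsurf
}

#' Pruned shortest dependency path
#'
#' Undirected shortest path between two token positions in the sentence's
#' dependency graph, after removing uninformative edge types (`punct` and
#' `det` by default).  Paths longer than `max_len` edges, and pairs left
#' disconnected by pruning, yield `NULL` (walk features are then simply
#' absent, which is not an error).
#'
#' @param h_a,h_b token positions (row indices into `sentence$fine`).
#' @param sentence preprocessed sentence.
#' @param prune dependency labels to remove before the search.
#' @param max_len maximum path length in edges (default 4).
#' @return `NULL`, or a list with `nodes` (token positions) and `edges`
#'   (data frame `label`, `down`; `down` is `TRUE` when the edge runs from
#'   `nodes[i]` as head to `nodes[i+1]` as dependent).
#' @export
dependency_path <- function(h_a, h_b, sentence, prune = c("punct", "det"),
                            max_len = 4L) {
  if (h_a == h_b)
    return(list(nodes = h_a,
                edges = data.frame(label = character(0), down = logical(0))))
  g <- sentence$graph
  labs <- igraph::edge_attr(g, "label")
  if (length(labs)) {
    drop <- which(tolower(labs) %in% tolower(prune))
    if (length(drop)) g <- igraph::delete_edges(g, drop)
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = h_a, to = h_b, mode = "all",
                           output = "vpath"))
  nodes <- as.integer(sp$vpath[[1]])
  if (length(nodes) < 2L) return(NULL)            # disconnected
  if (length(nodes) - 1L > max_len) return(NULL)  # over threshold
  fine <- sentence$fine
  lab <- character(length(nodes) - 1L)
  down <- logical(length(nodes) - 1L)
  for (i in seq_len(length(nodes) - 1L)) {
    a <- nodes[i]; b <- nodes[i + 1L]
    if (fine$head[b] == fine$tok_idx[a]) {        # a governs b
      lab[i] <- fine$deprel[b]; down[i] <- TRUE
    } else {                                      # b governs a
      lab[i] <- fine$deprel[a]; down[i] <- FALSE
    }
  }
  list(nodes = nodes, edges = data.frame(label = lab, down = down))
}

#' Joint (pairwise) features
#'
#' Dependency-path walk features between a candidate and an argument —
#' V-walks `(token, dep-tag, token)` per edge and E-walks
#' `(dep-tag, token, dep-tag)` per node with `START`/`END` sentinels, each
#' in a stem and a POS variant, bag-of-words — plus a
#' proteins-on-the-token-sequence-between flag and a shared-coarse-token
#' feature (`ARG-<stem>` style).  With no path (absent or over threshold)
#' only the non-path features are emitted.
#'
#' @param cand candidate entity.
#' @param arg argument entity.
#' @param sentence preprocessed sentence.
#' @param path result of [dependency_path()] (possibly `NULL`).
#' @param ns namespace prefix (default `"joint"`).
#' @return character vector of feature names.
#' @export
joint_features <- function(cand, arg, sentence, path, ns = "joint") {
  fine <- sentence$fine
  f <- character(0)
  # proteins strictly between the two entities
  lo <- min(cand$tok_to, arg$tok_to) + 1L
  hi <- max(cand$tok_from, arg$tok_from) - 1L
  if (lo <= hi && any(grepl("PROT", fine$fsurf[lo:hi], fixed = TRUE)))
    f <- c(f, paste0(ns, ":prot_between"))
  # shared coarse token
  co <- sentence$coarse
  hc <- cand$head_tok; ha <- arg$head_tok
  same <- which(co$begin <= fine$begin[hc] & co$end >= fine$end[hc] &
                  co$begin <= fine$begin[ha] & co$end >= fine$end[ha])
  if (length(same))
    f <- c(f, paste0(ns, ":shared=ARG-", fine$fstem[hc]))
  if (!is.null(path) && nrow(path$edges) > 0L) {
    f <- c(f, walk_features(ns, path, fine$fstem, "vwalk_stem", "ewalk_stem"),
           walk_features(ns, path, fine$pos, "vwalk_pos", "ewalk_pos"))
  }
  unique(f)
}

# V-walk: downward edge prints "head DEP <-dependent" (arrow attached to the
# dependent); upward edge prints "dep DEP -> head".  E-walk labels carry the
# traversal direction; terminal walks use START/END sentinels.
walk_features <- function(ns, path, toks, vname, ename) {
  nodes <- path$nodes; ed <- path$edges
  L <- nrow(ed)
  v <- character(L)
  labdir <- character(L)
  for (i in seq_len(L)) {
    a <- toks[nodes[i]]; b <- toks[nodes[i + 1L]]
    if (ed$down[i]) {
      v[i] <- paste0(a, " ", ed$label[i], " ", ARROW_L, b)
      labdir[i] <- paste0(ed$label[i], ARROW_R)
    } else {
      v[i] <- paste0(a, " ", ed$label[i], " ", ARROW_R, " ", b)
      labdir[i] <- paste0(ed$label[i], ARROW_L)
    }
  }
  ew <- character(L + 1L)
  left <- c("START", labdir)
  right <- c(labdir, "END")
  for (i in seq_len(L + 1L))
    ew[i] <- paste(left[i], toks[nodes[i]], right[i])
  c(paste0(ns, ":", vname, "=", v), paste0(ns, ":", ename, "=", ew))
}

#' Read a protein interaction lookup table
#'
#' A packaged TSV snapshot standing in for live knowledge-base queries:
#' `protein_surface<TAB>label1;label2`.  Lookup of an unknown protein yields
#' no labels.  A small synthetic table ships in
#' `inst/extdata/protein_kb_synthetic.tsv`.
#'
#' @param path TSV path.
#' @return named list: surface string -> character vector of labels.
#' @export
read_protein_kb <- function(path) {
  if (!file.exists(path)) stop_data("protein KB not found: ", path)
  lines <- read_lines0(path)
  kb <- list()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 2L)
      kb[[f[1]]] <- strsplit(f[2], ";", fixed = TRUE)[[1]]
  }
  kb
}

# Full feature vector of a (candidate, argument) pair.
pair_feature_vector <- function(cand, arg, sentence, hyper, kb = NULL,
                                arg_is_event = FALSE) {
  path <- dependency_path(cand$head_tok, arg$head_tok, sentence,
                          prune = hyper$prune, max_len = hyper$path_max)
  c(candidate_features(cand, sentence, hyper$k_cand),
    argument_features(arg, sentence, hyper$k_arg, kb, is_event = arg_is_event),
    joint_features(cand, arg, sentence, path))
}

# Feature vector for post-processing triples (trigger, argA, argB): union of
# the trigger's candidate features, both arguments' argument features, both
# trigger-argument joint sets and an argument-argument joint set.
triple_feature_vector <- function(trig, arg_a, arg_b, sentence, hyper,
                                  kb = NULL, a_is_event = FALSE,
                                  b_is_event = FALSE) {
  pa <- dependency_path(trig$head_tok, arg_a$head_tok, sentence,
                        hyper$prune, hyper$path_max)
  pb <- dependency_path(trig$head_tok, arg_b$head_tok, sentence,
                        hyper$prune, hyper$path_max)
  pab <- dependency_path(arg_a$head_tok, arg_b$head_tok, sentence,
                         hyper$prune, hyper$path_max)
  unique(c(candidate_features(trig, sentence, hyper$k_cand),
           argument_features(arg_a, sentence, hyper$k_arg, kb, a_is_event),
           argument_features(arg_b, sentence, hyper$k_arg, kb, b_is_event),
           joint_features(trig, arg_a, sentence, pa),
           joint_features(trig, arg_b, sentence, pb),
           joint_features(arg_a, arg_b, sentence, pab, ns = "aa")))
}

# Build (or apply) a feature vocabulary and the sparse indicator matrix.
features_to_matrix <- function(fvecs, vocab = NULL) {
  if (is.null(vocab)) vocab <- sort(unique(unlist(fvecs)))
  idx <- lapply(fvecs, function(fv) {
    m <- match(fv, vocab)
    sort(unique(m[!is.na(m)]))
  })
  lens <- lengths(idx)
  X <- Matrix::sparseMatrix(
    i = rep.int(seq_along(fvecs), lens),
    j = unlist(idx, use.names = FALSE),
    x = 1,
    dims = c(length(fvecs), length(vocab)))
  list(X = X, vocab = vocab)
}
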
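# Deterministic synthetic standoff corpora.  Sentences are built from a
# handful of syntactic templates whose dependency parses are emitted
# alongside the text, so the dependency-path features are informative by
# construction; gold events honour all type/argument constraints and form
# DAGs.  Generation is a pure function of the config.

#' Synthetic corpus configuration
#'
#' @param seed integer; same seed, same bytes.
#' @param n_documents,sentences_per_doc corpus shape.
#' @param proteins protein name vocabulary (includes classic Genia names so
#'   printed examples are exercised).
#' @param triggers named list: event type -> trigger lemma vector.  The
#'   default lemma sets are disjoint across types.
#' @param type_mix named probability vector over the nine event types.
#' @param p_binding_multitheme probability that a Binding has two themes.
#' @param p_reg_nested probability that a regulation theme is an event
#'   (applied again at each level up to `max_nesting_depth`).
#' @param max_nesting_depth maximum regulation nesting depth (>= 1).
#' @param p_reg_cause probability a regulation event carries a cause.
#' @param p_extra_protein probability of an extra, non-participating
#'   protein mention in a sentence.
#' @param noise probability that a sentence is a distractor: a trigger
#'   lemma used in a non-event context, with a protein present.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(seed = 1L, n_documents = 20L,
                          sentences_per_doc = 5L,
                          proteins = c("Tax", "CBP", "p300", "IL2",
                                       "STAT3", "Jak1", "Raf1", "Bcl2"),
                          triggers = default_trigger_lexicon(),
                          type_mix = default_type_mix(),
                          p_binding_multitheme = 0.4,
                          p_reg_nested = 0.4,
                          max_nesting_depth = 2L,
                          p_reg_cause = 0.3,
                          p_extra_protein = 0.3,
                          noise = 0) {
  cfg <- list(seed = as.integer(seed), n_documents = as.integer(n_documents),
              sentences_per_doc = as.integer(sentences_per_doc),
              proteins = proteins, triggers = triggers,
              type_mix = type_mix,
              p_binding_multitheme = p_binding_multitheme,
              p_reg_nested = p_reg_nested,
              max_nesting_depth = as.integer(max_nesting_depth),
              p_reg_cause = p_reg_cause,
              p_extra_protein = p_extra_protein, noise = noise)
  validate_config(cfg)
  structure(cfg, class = "corpus_config")
}

#' @rdname corpus_config
#' @export
default_trigger_lexicon <- function() {
  list(Gene_expression = c("expression", "production"),
       Transcription = c("transcription"),
       Protein_catabolism = c("degradation", "proteolysis"),
       Phosphorylation = c("phosphorylation"),
       Localization = c("localization", "secretion"),
       Binding = c("binding", "interaction"),
       Regulation = c("regulation", "modulation"),
       Positive_regulation = c("activation", "induction"),
       Negative_regulation = c("inhibition", "suppression"))
}

#' @rdname corpus_config
#' @export
default_type_mix <- function() {
  c(Gene_expression = 0.20, Transcription = 0.05, Protein_catabolism = 0.03,
    Phosphorylation = 0.05, Localization = 0.05, Binding = 0.15,
    Regulation = 0.12, Positive_regulation = 0.20,
    Negative_regulation = 0.15)
}

validate_config <- function(cfg) {
  probs <- c(cfg$p_binding_multitheme, cfg$p_reg_nested, cfg$p_reg_cause,
             cfg$p_extra_protein, cfg$noise, cfg$type_mix)
  if (any(probs < 0 | probs > 1))
    stop_config("probabilities must lie in [0, 1]")
  if (cfg$max_nesting_depth < 1L)
    stop_config("max_nesting_depth must be >= 1")
  if (!setequal(names(cfg$type_mix), EVENT_TYPES))
    stop_config("type_mix must cover exactly the nine event types")
  if (abs(sum(cfg$type_mix) - 1) > 1e-8)
    stop_config("type_mix must sum to 1")
  if (cfg$p_reg_nested > 0 &&
      !any(cfg$type_mix[REG_TYPES] > 0))
    stop_config("nesting requested but the type mix has no REG mass")
  missing <- setdiff(EVENT_TYPES[cfg$type_mix > 0], names(cfg$triggers))
  if (length(missing))
    stop_config("no trigger lemmas for type(s): ",
                paste(missing, collapse = ", "))
  invisible(cfg)
}

# --- sentence templates ----------------------------------------------------
# Each builder returns list(tokens = data.frame(surface, pos, head, deprel),
# events = list of specs over token indices, protein_toks = token indices).

tmpl_simple <- function(type, trig, theme_p, extra_p = NULL,
                        second_p = NULL, second_rel = NULL) {
  # "The <trig> of <P> [to/by <P2>] [in <P3> cells] was detected ."
  toks <- list(c("The", "DT"), c(trig, "NN"), c("of", "IN"), c(theme_p, "NN"))
  head <- c(2L, NA, 2L, 2L)
  rel <- c("DET", "NSUBJ", "PREP", "PREP_OF")
  if (!is.null(second_p)) {
    prepw <- if (second_rel == "PREP_TO") "to" else "by"
    toks <- c(toks, list(c(prepw, "IN"), c(second_p, "NN")))
    head <- c(head, 2L, 2L)
    rel <- c(rel, "PREP", second_rel)
  }
  if (!is.null(extra_p)) {
    toks <- c(toks, list(c("in", "IN"), c(extra_p, "NN"),
                         c("cells", "NNS")))
    n0 <- length(head)
    head <- c(head, 2L, n0 + 3L, 2L)
    rel <- c(rel, "PREP", "NN", "PREP_IN")
  }
  v <- length(toks) + 2L
  toks <- c(toks, list(c("was", "VBD"), c("detected", "VBN"), c(".", ".")))
  head <- c(head, v, 0L, v)
  rel <- c(rel, "AUX", "ROOT", "PUNCT")
  head[2] <- v
  finish_template(toks, head, rel)
}

tmpl_chain <- function(trigs, theme_p, cause_p = NULL) {
  # "The <t1> of the <t2> ... of <P> [by <Pc>] was detected ."
  toks <- list(c("The", "DT"), c(trigs[1], "NN"))
  head <- c(2L, NA)
  rel <- c("DET", "NSUBJ")
  prev <- 2L
  if (length(trigs) > 1L) for (t in trigs[-1]) {
    n0 <- length(head)
    toks <- c(toks, list(c("of", "IN"), c("the", "DT"), c(t, "NN")))
    head <- c(head, prev, n0 + 3L, prev)
    rel <- c(rel, "PREP", "DET", "PREP_OF")
    prev <- n0 + 3L
  }
  toks <- c(toks, list(c("of", "IN"), c(theme_p, "NN")))
  head <- c(head, prev, prev)
  rel <- c(rel, "PREP", "PREP_OF")
  if (!is.null(cause_p)) {
    toks <- c(toks, list(c("by", "IN"), c(cause_p, "NN")))
    head <- c(head, 2L, 2L)
    rel <- c(rel, "PREP", "PREP_BY")
  }
  v <- length(toks) + 2L
  toks <- c(toks, list(c("was", "VBD"), c("detected", "VBN"), c(".", ".")))
  head <- c(head, v, 0L, v)
  rel <- c(rel, "AUX", "ROOT", "PUNCT")
  head[2] <- v
  finish_template(toks, head, rel)
}

tmpl_distractor <- function(lemma, p) {
  # "A <lemma> assay was performed in <P> cells ." -- the lemma is not a
  # trigger here; its dependency context differs from event templates.
  toks <- list(c("A", "DT"), c(lemma, "NN"), c("assay", "NN"),
               c("was", "VBD"), c("performed", "VBN"), c("in", "IN"),
               c(p, "NN"), c("cells", "NNS"), c(".", "."))
  head <- c(3L, 3L, 5L, 5L, 0L, 5L, 8L, 5L, 5L)
  rel <- c("DET", "NN", "NSUBJ", "AUX", "ROOT", "PREP", "NN", "PREP_IN",
           "PUNCT")
  finish_template(toks, head, rel)
}

finish_template <- function(toks, head, rel) {
  df <- data.frame(surface = vapply(toks, `[`, "", 1L),
                   pos = vapply(toks, `[`, "", 2L),
                   head = head, deprel = rel, stringsAsFactors = FALSE)
  df
}

# --- sentence sampling -----------------------------------------------------

sample_sentence <- function(cfg) {
  if (cfg$noise > 0 && stats::runif(1) < cfg$noise) {
    lemma <- sample(unlist(cfg$triggers), 1L)
    p <- sample(cfg$proteins, 1L)
    return(list(tokens = tmpl_distractor(lemma, p),
                events = list(), prot_toks = 7L))
  }
  type <- sample(names(cfg$type_mix), 1L, prob = cfg$type_mix)
  trig <- sample(cfg$triggers[[type]], 1L)

  if (EVENT_CLASSES[[type]] == "REG") {
    # regulation chain: outer REG triggers, then an inner non-REG or
    # protein theme
    chain_types <- type
    while (length(chain_types) < cfg$max_nesting_depth &&
           stats::runif(1) < cfg$p_reg_nested) {
      nxt <- sample(names(cfg$type_mix), 1L, prob = cfg$type_mix)
      if (EVENT_CLASSES[[nxt]] == "REG") chain_types <- c(chain_types, nxt)
      else { chain_types <- c(chain_types, nxt); break }
    }
    trigs <- vapply(chain_types, function(tt)
      sample(cfg$triggers[[tt]], 1L), "")
    theme_p <- sample(cfg$proteins, 1L)
    cause_p <- NULL
    if (stats::runif(1) < cfg$p_reg_cause)
      cause_p <- sample(setdiff(cfg$proteins, theme_p), 1L)
    tokens <- tmpl_chain(trigs, theme_p, cause_p)
    trig_idx <- which(tokens$surface %in% trigs &
                        tokens$deprel %in% c("NSUBJ", "PREP_OF"))
    trig_idx <- trig_idx[seq_along(trigs)]
    theme_idx <- which(tokens$surface == theme_p &
                         tokens$deprel == "PREP_OF")
    theme_idx <- theme_idx[length(theme_idx)]
    prot_toks <- theme_idx
    events <- list()
    # innermost event first
    inner_ref <- list(kind = "protein", tok = theme_idx)
    for (k in rev(seq_along(chain_types))) {
      ev <- list(type = chain_types[k], trig_tok = trig_idx[k],
                 theme = inner_ref, theme2 = NULL, cause = NULL)
      events[[length(events) + 1L]] <- ev
      inner_ref <- list(kind = "event", idx = length(events))
    }
    if (!is.null(cause_p)) {
      cause_idx <- which(tokens$surface == cause_p &
                           tokens$deprel == "PREP_BY")[1]
      prot_toks <- c(prot_toks, cause_idx)
      events[[length(events)]]$cause <- list(kind = "protein",
                                             tok = cause_idx)
    }
    return(list(tokens = tokens, events = events,
                prot_toks = prot_toks))
  }

  if (type == "Binding" && stats::runif(1) < cfg$p_binding_multitheme) {
    ps <- sample(cfg$proteins, 2L)
    tokens <- tmpl_simple(type, trig, ps[1], second_p = ps[2],
                          second_rel = "PREP_TO")
    t1 <- which(tokens$surface == ps[1] & tokens$deprel == "PREP_OF")[1]
    t2 <- which(tokens$surface == ps[2] & tokens$deprel == "PREP_TO")[1]
    ev <- list(type = type, trig_tok = 2L,
               theme = list(kind = "protein", tok = t1),
               theme2 = list(kind = "protein", tok = t2), cause = NULL)
    return(list(tokens = tokens, events = list(ev), prot_toks = c(t1, t2)))
  }

  # single-theme event (SVT or singleton Binding)
  theme_p <- sample(cfg$proteins, 1L)
  extra <- NULL
  if (stats::runif(1) < cfg$p_extra_protein)
    extra <- sample(setdiff(cfg$proteins, theme_p), 1L)
  tokens <- tmpl_simple(type, trig, theme_p, extra_p = extra)
  t1 <- which(tokens$surface == theme_p & tokens$deprel == "PREP_OF")[1]
  prot_toks <- t1
  if (!is.null(extra))
    prot_toks <- c(prot_toks,
                   which(tokens$surface == extra &
                           tokens$deprel == "NN")[1])
  ev <- list(type = type, trig_tok = 2L,
             theme = list(kind = "protein", tok = t1),
             theme2 = NULL, cause = NULL)
  list(tokens = tokens, events = list(ev), prot_toks = prot_toks)
}

# --- corpus assembly -------------------------------------------------------

#' Generate a synthetic standoff corpus
#'
#' Writes, per document, `.txt`, `.a1`, `.a2` and `.tok.tsv` (token table
#' with POS, heads and dependency labels), plus a `config.yaml` snapshot.
#' Output is byte-identical for identical configs.
#'
#' @param config a [corpus_config()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
generate_corpus <- function(config, dir) {
  validate_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    for (d in seq_len(config$n_documents)) {
      sents <- lapply(seq_len(config$sentences_per_doc),
                      function(i) sample_sentence(config))
      write_synth_document(sprintf("doc%03d", d), sents, dir)
    }
  })
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Generate a linearly separable corpus
#'
#' Same generator, but verified to use disjoint trigger lemma sets across
#' event types and the template-distinct syntax, so that a linear separator
#' over the feature space exists (the trigger stem plus local path features
#' suffice).  Used for perfect-recovery testing.
#'
#' @inheritParams generate_corpus
#' @return `dir`, invisibly.
#' @export
make_separable_corpus <- function(config, dir) {
  lemmas <- unlist(config$triggers)
  stems <- porter_stem(lemmas)
  if (anyDuplicated(stems))
    stop_config("trigger lemma stems are not disjoint across types: ",
                paste(unique(stems[duplicated(stems)]), collapse = ", "))
  generate_corpus(config, dir)
}

write_synth_document <- function(doc_id, sents, dir) {
  text_parts <- character(0)
  tok_lines <- character(0)
  a1_lines <- character(0)
  trig_lines <- character(0)
  ev_lines <- character(0)
  offset <- 0L
  n_t <- 0L
  n_e <- 0L
  trig_tid <- list()  # "sent|tok" -> (Tid, type) for reuse within sentence

  for (si in seq_along(sents)) {
    s <- sents[[si]]
    tok <- s$tokens
    n <- nrow(tok)
    begins <- integer(n); ends <- integer(n)
    pos <- offset
    for (i in seq_len(n)) {
      begins[i] <- pos
      ends[i] <- pos + nchar(tok$surface[i])
      pos <- ends[i] + 1L  # single space between tokens
    }
    sent_text <- paste(tok$surface, collapse = " ")
    text_parts <- c(text_parts, sent_text)
    offset <- pos  # next sentence starts after the joining space

    tok_lines <- c(tok_lines, sprintf(
      "%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s", si, seq_len(n), tok$surface,
      begins, ends, tok$pos, tok$head, tok$deprel))

    for (pt in s$prot_toks %||% integer(0)) {
      n_t <- n_t + 1L
      a1_lines <- c(a1_lines, sprintf("T%d\tProtein %d %d\t%s", n_t,
                                      begins[pt], ends[pt],
                                      tok$surface[pt]))
      trig_tid[[paste0("P", si, "|", pt)]] <- sprintf("T%d", n_t)
    }
    # events: assign trigger T ids (shared per token) then E lines
    local_eids <- character(length(s$events))
    for (k in seq_along(s$events)) {
      ev <- s$events[[k]]
      key <- paste0(si, "|", ev$trig_tok)
      if (is.null(trig_tid[[key]])) {
        n_t <- n_t + 1L
        trig_tid[[key]] <- sprintf("T%d", n_t)
        trig_lines <- c(trig_lines, sprintf(
          "T%d\t%s %d %d\t%s", n_t, ev$type, begins[ev$trig_tok],
          ends[ev$trig_tok], tok$surface[ev$trig_tok]))
      }
      ref <- function(arg) {
        if (arg$kind == "protein")
          trig_tid[[paste0("P", si, "|", arg$tok)]]
        else local_eids[arg$idx]
      }
      n_e <- n_e + 1L
      local_eids[k] <- sprintf("E%d", n_e)
      line <- sprintf("E%d\t%s:%s Theme:%s", n_e, ev$type,
                      trig_tid[[key]], ref(ev$theme))
      if (!is.null(ev$theme2))
        line <- paste0(line, " Theme2:", ref(ev$theme2))
      if (!is.null(ev$cause))
        line <- paste0(line, " Cause:", ref(ev$cause))
      ev_lines <- c(ev_lines, line)
    }
  }

  base <- file.path(dir, doc_id)
  writeLines(paste(text_parts, collapse = " "), paste0(base, ".txt"),
             useBytes = TRUE)
  writeLines(a1_lines, paste0(base, ".a1"), useBytes = TRUE)
  writeLines(c(trig_lines, ev_lines), paste0(base, ".a2"), useBytes = TRUE)
  writeLines(tok_lines, paste0(base, ".tok.tsv"), useBytes = TRUE)
  invisible(base)
}
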
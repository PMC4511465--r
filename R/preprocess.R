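#' Sentence splitting
#'
#' Returns 0-based half-open character spans of sentences.  When spans are
#' provided (e.g. by a corpus that ships its own segmentation, or derived
#' from a token table) they are used verbatim; otherwise a simple rule-based
#' splitter breaks after `.`, `!` or `?` followed by whitespace and an
#' upper-case letter or digit.
#'
#' @param text document text.
#' @param spans optional list/matrix of `c(begin, end)` spans, used verbatim.
#' @return a two-column integer matrix `begin`, `end`.
#' @export
split_sentences <- function(text, spans = NULL) {
  if (!nzchar(text)) stop_data("cannot split empty text")
  if (!is.null(spans)) {
    m <- do.call(rbind, lapply(spans, as.integer))
    if (is.null(dim(m))) m <- matrix(m, ncol = 2L)
    if (any(m[, 1] >= m[, 2]) || any(m[, 2] > nchar(text)))
      stop_data("invalid provided sentence span")
    if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2]))
      stop_data("provided sentence spans overlap")
    colnames(m) <- c("begin", "end")
    return(m)
  }
  # boundary = terminal punctuation, whitespace, then capital/digit
  bpos <- gregexpr("[.!?](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- if (bpos[1] == -1L) integer(0) else as.integer(bpos)  # 1-based
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(text))
  spans <- matrix(NA_integer_, nrow = length(starts), ncol = 2L,
                  dimnames = list(NULL, c("begin", "end")))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    seg <- substr(text, starts[i], ends[i])
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    b <- starts[i] + lead; e <- ends[i] - trail
    keep[i] <- e >= b
    spans[i, ] <- c(b - 1L, e)  # to 0-based half-open
  }
  spans[keep, , drop = FALSE]
}

#' Coarse tokenization
#'
#' Whitespace tokenization with leading/trailing sentence punctuation
#' (`.,;:!?()[]"'`) peeled off as separate tokens; hyphens and slashes are
#' kept inside tokens so that compounds like `"LPS-activated"` survive as
#' one coarse token.
#'
#' @param text sentence (or document) text.
#' @param offset 0-based offset of `text` within the document.
#' @return data frame with `surface`, `begin`, `end` (0-based half-open).
#' @export
coarse_tokenize <- function(text, offset = 0L) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  out <- list()
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      b <- as.integer(m[i]); len <- attr(m, "match.length")[i]
      chunk <- substr(text, b, b + len - 1L)
      pieces <- peel_punct(chunk, offset + b - 1L)
      out[[length(out) + 1L]] <- pieces
    }
  }
  if (!length(out))
    return(data.frame(surface = character(0), begin = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

peel_punct <- function(chunk, begin0) {
  punct <- "[.,;:!?()\\[\\]\"']"
  lead <- regmatches(chunk, regexpr(paste0("^", punct, "+"), chunk))
  trail <- regmatches(chunk, regexpr(paste0(punct, "+$"), chunk))
  nl <- if (length(lead)) nchar(lead) else 0L
  nt <- if (length(trail)) nchar(trail) else 0L
  core <- substr(chunk, nl + 1L, nchar(chunk) - nt)
  if (!nzchar(core)) { core <- chunk; nl <- 0L; nt <- 0L }
  rows <- list()
  pos <- begin0
  if (nl > 0L) for (ch in strsplit(substr(chunk, 1L, nl), "")[[1]]) {
    rows[[length(rows) + 1L]] <- data.frame(surface = ch, begin = pos,
                                            end = pos + 1L)
    pos <- pos + 1L
  }
  rows[[length(rows) + 1L]] <- data.frame(surface = core, begin = pos,
                                          end = pos + nchar(core))
  pos <- pos + nchar(core)
  if (nt > 0L) for (ch in strsplit(substr(chunk, nchar(chunk) - nt + 1L,
                                          nchar(chunk)), "")[[1]]) {
    rows[[length(rows) + 1L]] <- data.frame(surface = ch, begin = pos,
                                            end = pos + 1L)
    pos <- pos + 1L
  }
  do.call(rbind, rows)
}

# Affixes at which hyphenated compounds may be split (plus protein surfaces
# and gazetteer triggers); splitting everywhere would over-fragment.
SPLIT_AFFIXES <- c("over", "up", "down", "co", "dependent", "independent",
                   "induced", "mediated")

#' Fine-grained tokenization of coarse tokens
#'
#' Splits compound coarse tokens at `-` and `/` when a resulting piece is a
#' known protein surface, a gazetteer trigger, or one of a small affix list
#' (`over, up, down, co, dependent, independent, induced, mediated`).
#' Pieces covered by an annotated protein span are always isolated.
#' Separators become their own tokens and the pieces tile the original
#' token's characters exactly.
#'
#' @param coarse data frame from [coarse_tokenize()].
#' @param protein_spans data frame or list with `begin`, `end`, `surface`
#'   of annotated proteins (may be empty).
#' @param known extra qualifying piece surfaces (e.g. gazetteer triggers).
#' @return data frame with `surface`, `begin`, `end`.
#' @export
tokenize_fine <- function(coarse, protein_spans = NULL, known = character(0)) {
  qual <- tolower(c(known, SPLIT_AFFIXES))
  psurf <- character(0); pb <- integer(0); pe <- integer(0)
  if (!is.null(protein_spans) && length(protein_spans$begin)) {
    psurf <- tolower(protein_spans$surface)
    pb <- protein_spans$begin; pe <- protein_spans$end
  }
  qual <- c(qual, psurf)
  rows <- list()
  emit <- function(s, b) rows[[length(rows) + 1L]] <<-
    data.frame(surface = s, begin = b, end = b + nchar(s))
  for (i in seq_len(nrow(coarse))) {
    surf <- coarse$surface[i]; b0 <- coarse$begin[i]; e0 <- coarse$end[i]
    # cut at protein boundaries inside the token
    cuts <- sort(unique(c(pb[pb > b0 & pb < e0], pe[pe > b0 & pe < e0])))
    bounds <- c(b0, cuts, e0)
    for (j in seq_len(length(bounds) - 1L)) {
      sb <- bounds[j]; se <- bounds[j + 1L]
      seg <- substr(surf, sb - b0 + 1L, se - b0)
      inside_prot <- any(pb <= sb & pe >= se)
      if (inside_prot || !grepl("[-/]", seg)) { emit(seg, sb); next }
      pieces <- strsplit(seg, "(?<=[-/])|(?=[-/])", perl = TRUE)[[1]]
      if (any(tolower(pieces[!pieces %in% c("-", "/")]) %in% qual)) {
        p <- sb
        for (pc in pieces) { emit(pc, p); p <- p + nchar(pc) }
      } else emit(seg, sb)
    }
  }
  if (!length(rows))
    return(data.frame(surface = character(0), begin = integer(0),
                      end = integer(0)))
  do.call(rbind, rows)
}

#' Protein-name masking
#'
#' Computes the feature surface of each token: tokens fully inside an
#' annotated protein span become `"PROT"`; tokens partially overlapping a
#' protein have the overlapping substring replaced by `"PROT"`
#' (`"LPS-activated"` becomes `"PROT-activated"`).  Original surfaces and
#' character spans are untouched; only the feature surface changes.
#'
#' @param tokens data frame with `surface`, `begin`, `end`.
#' @param proteins list of protein entities (with `begin`, `end`).
#' @return `tokens` with an added/updated `fsurf` column.
#' @export
substitute_proteins <- function(tokens, proteins) {
  fs <- tokens$surface
  if (length(proteins)) {
    pb <- vapply(proteins, `[[`, 0L, "begin")
    pe <- vapply(proteins, `[[`, 0L, "end")
    for (i in seq_len(nrow(tokens))) {
      tb <- tokens$begin[i]; te <- tokens$end[i]
      hit <- which(pb < te & pe > tb)
      if (!length(hit)) next
      if (any(pb[hit] <= tb & pe[hit] >= te)) { fs[i] <- "PROT"; next }
      s <- fs[i]
      # replace overlapped substrings right-to-left to keep positions valid
      segs <- cbind(pmax(pb[hit], tb), pmin(pe[hit], te))
      segs <- segs[order(-segs[, 1]), , drop = FALSE]
      for (r in seq_len(nrow(segs))) {
        a <- segs[r, 1] - tb + 1L; z <- segs[r, 2] - tb
        s <- paste0(substr(s, 1L, a - 1L), "PROT",
                    substr(s, z + 1L, nchar(s)))
      }
      fs[i] <- s
    }
  }
  tokens$fsurf <- fs
  tokens
}

# Feature stem of a masked surface: the placeholder is preserved verbatim,
# everything else is Porter-stemmed lowercase.
feature_stem <- function(fsurf) {
  ifelse(fsurf == "PROT", "PROT", porter_stem(fsurf))
}

# Assemble sentence structures from the token table: coarse layer, masking,
# stems, dependency graphs, and the entity -> token mapping.  Gold events
# whose trigger and arguments do not share one sentence are dropped with a
# message (their dependents likewise).
preprocess_document <- function(doc) {
  tok <- doc$tokens
  if (is.null(tok)) stop_data("document ", doc$doc_id, " has no token table")
  prot_ents <- doc$entities[doc$proteins]

  sent_ids <- sort(unique(tok$sent_idx))
  sentences <- vector("list", length(sent_ids))
  for (si in seq_along(sent_ids)) {
    rows <- tok[tok$sent_idx == sent_ids[si], , drop = FALSE]
    rows <- rows[order(rows$tok_idx), , drop = FALSE]
    b <- min(rows$begin); e <- max(rows$end)
    fine <- substitute_proteins(rows, prot_ents)
    fine$stem <- porter_stem(fine$surface)
    fine$fstem <- feature_stem(fine$fsurf)
    coarse <- coarse_tokenize(substr(doc$text, b + 1L, e), offset = b)
    coarse <- substitute_proteins(coarse, prot_ents)
    g <- igraph::make_empty_graph(n = nrow(fine), directed = TRUE)
    has_head <- fine$head > 0L
    if (any(has_head)) {
      el <- rbind(match(fine$head[has_head], fine$tok_idx),
                  which(has_head))
      g <- igraph::add_edges(g, as.vector(el),
                             attr = list(label = fine$deprel[has_head]))
    }
    sentences[[si]] <- list(index = sent_ids[si], begin = b, end = e,
                            fine = fine, coarse = coarse, graph = g,
                            proteins = character(0),
                            protein_entities = prot_ents)
  }
  sbegin <- vapply(sentences, `[[`, 0L, "begin")
  send <- vapply(sentences, `[[`, 0L, "end")
  if (length(sentences) > 1L && any(sbegin[-1] < send[-length(send)]))
    stop_data("overlapping sentence spans in ", doc$doc_id)

  # map entities (proteins + gold triggers) to sentences and token ranges
  for (id in names(doc$entities)) {
    ent <- doc$entities[[id]]
    si <- which(sbegin <= ent$begin & send >= ent$end)
    if (!length(si)) { doc$entities[[id]]$sent <- NA_integer_; next }
    si <- si[1]
    s <- sentences[[si]]
    hit <- which(s$fine$begin < ent$end & s$fine$end > ent$begin)
    if (!length(hit)) { doc$entities[[id]]$sent <- NA_integer_; next }
    ent$sent <- s$index
    ent$tok_from <- min(hit); ent$tok_to <- max(hit)
    ent$head_tok <- select_head_token(ent, s)
    doc$entities[[id]] <- ent
    if (ent$kind == "protein")
      sentences[[si]]$proteins <- c(sentences[[si]]$proteins, id)
  }

  # drop cross-sentence gold events
  if (length(doc$gold_events)) {
    keep <- rep(TRUE, length(doc$gold_events))
    repeat {
      changed <- FALSE
      kept_ids <- vapply(doc$gold_events[keep], `[[`, "", "id")
      for (i in seq_along(doc$gold_events)) {
        if (!keep[i]) next
        e <- doc$gold_events[[i]]
        sents <- doc$entities[[e$trigger_id]]$sent
        ok <- TRUE
        chk_ent <- function(id) {
          s2 <- doc$entities[[id]]$sent
          !is.na(s2) && !is.na(sents) && s2 == sents
        }
        if (isTRUE(e$theme_is_event)) {
          ok <- ok && e$theme_id %in% kept_ids
        } else ok <- ok && chk_ent(e$theme_id)
        if (!is.na(e$theme2_id)) ok <- ok && chk_ent(e$theme2_id)
        if (!is.na(e$cause_id)) {
          if (isTRUE(e$cause_is_event)) ok <- ok && e$cause_id %in% kept_ids
          else ok <- ok && chk_ent(e$cause_id)
        }
        if (is.na(sents)) ok <- FALSE
        if (!ok) { keep[i] <- FALSE; changed <- TRUE }
      }
      if (!changed) break
    }
    if (any(!keep))
      message("dropping ", sum(!keep), " cross-sentence/unmappable gold ",
              "event(s) in ", doc$doc_id)
    doc$gold_events <- doc$gold_events[keep]
  }

  # refresh per-sentence protein registries with the token-mapped entities
  prot_final <- doc$entities[doc$proteins]
  for (si in seq_along(sentences))
    sentences[[si]]$protein_entities <- prot_final

  doc$sentences <- sentences
  doc
}
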
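#' Sentences, mentions and candidate pairs
#'
#' Candidate generation turns a raw report sentence into the atomic labeling
#' units of the pipeline: all {spatial trigger, radiological entity} pairs.
#' Entities come from dictionary longest-match against the entity lexicon
#' (with the location-descriptor exception), a distance regex ("2 mm",
#' "1.5 cm") and a vertebral/segment regex ("C5-C7", "T12"); triggers come
#' from dictionary match against the trigger lexicon.
#'
#' Character offsets are 0-based half-open (`text[start:end]` in slice
#' notation equals the surface); token indices are 1-based.
#'
#' @name radspatial-candidates
NULL

TOKEN_PUNCT <- c(".", ",", ";", ":", "(", ")", "/")

slice0 <- function(text, start, end) substr(text, start + 1L, end)

#' Tokenize a sentence
#'
#' Splits on whitespace, then separates leading/trailing punctuation
#' (`. , ; : ( ) /`) into their own tokens. Hyphens and internal periods are
#' preserved, so "C5-C7" and "1.5" stay single tokens while "carina." splits
#' into "carina" and ".".
#'
#' @param text sentence text (may be empty).
#' @param doc_id,sent_id identifiers carried through the pipeline.
#' @return an `rs_sentence`: list with `doc_id`, `sent_id`, `text` and a
#'   `tokens` data.frame (surface, start, end) with 0-based half-open offsets.
#' @export
tokenize_sentence <- function(text, doc_id = "doc", sent_id = 0L) {
  stopifnot(length(text) == 1)
  starts <- integer(); ends <- integer()
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] != -1) {
    for (ci in seq_along(m)) {
      s <- m[ci] - 1L                      # 0-based
      e <- s + attr(m, "match.length")[ci]
      lead <- integer()
      while (e - s >= 2L && substr(text, s + 1L, s + 1L) %in% TOKEN_PUNCT) {
        lead <- c(lead, s); s <- s + 1L
      }
      trail <- integer()
      while (e - s >= 2L && substr(text, e, e) %in% TOKEN_PUNCT) {
        trail <- c(e - 1L, trail); e <- e - 1L
      }
      for (p in lead) { starts <- c(starts, p); ends <- c(ends, p + 1L) }
      starts <- c(starts, s); ends <- c(ends, e)
      for (p in trail) { starts <- c(starts, p); ends <- c(ends, p + 1L) }
    }
  }
  tokens <- data.frame(
    surface = vapply(seq_along(starts),
                     function(i) slice0(text, starts[i], ends[i]), character(1)),
    start = starts, end = ends, stringsAsFactors = FALSE)
  structure(list(doc_id = doc_id, sent_id = as.integer(sent_id),
                 text = text, tokens = tokens),
            class = "rs_sentence")
}

#' @export
print.rs_sentence <- function(x, ...) {
  cat("<rs_sentence> ", x$doc_id, "/", x$sent_id, ": ",
      x$text, " [", nrow(x$tokens), " tokens]\n", sep = "")
  invisible(x)
}

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), first_tok = integer(),
             last_tok = integer(), surface = character(),
             categories = character(), matcher = character(),
             stringsAsFactors = FALSE)
}

mention_row <- function(sent, first_tok, last_tok, categories, matcher) {
  start <- sent$tokens$start[first_tok]
  end <- sent$tokens$end[last_tok]
  data.frame(start = start, end = end, first_tok = first_tok,
             last_tok = last_tok, surface = slice0(sent$text, start, end),
             categories = paste(categories, collapse = "|"),
             matcher = matcher, stringsAsFactors = FALSE)
}

# all token-aligned dictionary matches (no overlap resolution)
match_all_spans <- function(sent, index) {
  n <- nrow(sent$tokens)
  out <- list()
  if (n == 0) return(empty_mentions())
  for (i in seq_len(n)) {
    for (j in i:min(n, i + index$max_tokens - 1L)) {
      key <- normalize_surface(
        slice0(sent$text, sent$tokens$start[i], sent$tokens$end[j]))
      cats <- index_lookup(index, key)
      if (length(cats) > 0)
        out[[length(out) + 1L]] <- mention_row(sent, i, j, cats, "dictionary")
    }
  }
  if (length(out) == 0) empty_mentions() else do.call(rbind, out)
}

# longest-match overlap resolution: longer char spans win, ties to the
# leftmost start; greedy over the sorted candidates
resolve_longest <- function(mentions) {
  if (nrow(mentions) == 0) return(mentions)
  ord <- order(-(mentions$end - mentions$start), mentions$start)
  mentions <- mentions[ord, , drop = FALSE]
  keep <- logical(nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    ok <- TRUE
    if (any(keep)) {
      k <- mentions[keep, , drop = FALSE]
      ok <- all(mentions$end[i] <= k$start | mentions$start[i] >= k$end)
    }
    keep[i] <- ok
  }
  out <- mentions[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag entity mentions by dictionary match
#'
#' Finds all token-aligned spans matching the entity lexicon
#' (case-insensitive) and keeps the longest among overlapping matches, ties
#' broken by leftmost start. Exception: when a selected multi-token anatomy
#' span begins with a location-descriptor term and the remainder is itself a
#' lexicon entry ("inferior cerebellar peduncle"), both the descriptor and
#' the remaining anatomy span are emitted as two separate mentions.
#'
#' @param sent an `rs_sentence`.
#' @param lex the entity `rs_lexicon`.
#' @return a mentions data.frame (start, end, first_tok, last_tok, surface,
#'   categories, matcher) sorted by start.
#' @export
tag_entities <- function(sent, lex) {
  if (nrow(lex$entries) == 0) stop("entity lexicon is empty")
  index <- lexicon_index(lex)
  kept <- resolve_longest(match_all_spans(sent, index))
  if (nrow(kept) == 0) return(kept)
  out <- list()
  for (i in seq_len(nrow(kept))) {
    m <- kept[i, ]
    split_done <- FALSE
    if (m$last_tok > m$first_tok &&
        "anatomy" %in% strsplit(m$categories, "|", fixed = TRUE)[[1]]) {
      head_key <- normalize_surface(sent$tokens$surface[m$first_tok])
      head_cats <- index_lookup(index, head_key)
      if ("location_descriptor" %in% head_cats) {
        rest_key <- normalize_surface(
          slice0(sent$text, sent$tokens$start[m$first_tok + 1L], m$end))
        rest_cats <- index_lookup(index, rest_key)
        if (length(rest_cats) > 0) {
          out[[length(out) + 1L]] <-
            mention_row(sent, m$first_tok, m$first_tok, head_cats, "dictionary")
          out[[length(out) + 1L]] <-
            mention_row(sent, m$first_tok + 1L, m$last_tok, rest_cats,
                        "dictionary")
          split_done <- TRUE
        }
      }
    }
    if (!split_done) out[[length(out) + 1L]] <- m
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match distance expressions
#'
#' Matches a number (integer, decimal or range "N-M") followed by a length
#' unit (mm, cm, millimeter(s), centimeter(s)); spans must align to token
#' boundaries. Matches carry the pseudo-category `distance` and matcher
#' `distance_regex`.
#'
#' @param sent an `rs_sentence`.
#' @return a mentions data.frame.
#' @export
match_distance <- function(sent) {
  pat <- "\\d+(\\.\\d+)?(\\s?-\\s?\\d+(\\.\\d+)?)?\\s?(mm|cm|millimeters?|centimeters?)"
  out <- empty_mentions()
  m <- gregexpr(pat, sent$text, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    s <- m[i] - 1L
    e <- s + attr(m, "match.length")[i]
    ft <- match(s, sent$tokens$start)
    lt <- match(e, sent$tokens$end)
    if (is.na(ft) || is.na(lt)) next
    row <- mention_row(sent, ft, lt, "distance", "distance_regex")
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Match vertebral/segment codes
#'
#' Matches single tokens of the form `[CTL]<1-2 digits>` optionally
#' hyphenated to a second code ("T12", "C5-C7"); tagged as `anatomy` with
#' matcher `segment_regex`.
#'
#' @param sent an `rs_sentence`.
#' @return a mentions data.frame.
#' @export
match_segment <- function(sent) {
  out <- empty_mentions()
  if (nrow(sent$tokens) == 0) return(out)
  hits <- grepl("^[CTL][0-9]{1,2}(-[CTL][0-9]{1,2})?$", sent$tokens$surface)
  for (i in which(hits))
    out <- rbind(out, mention_row(sent, i, i, "anatomy", "segment_regex"))
  rownames(out) <- NULL
  out
}

#' Tag spatial trigger mentions
#'
#' Longest-match dictionary tagging against the spatial-trigger lexicon.
#'
#' @param sent an `rs_sentence`.
#' @param triggers the trigger `rs_lexicon`.
#' @return a data.frame (start, end, first_tok, last_tok, surface) sorted by
#'   start.
#' @export
tag_triggers <- function(sent, triggers) {
  if (nrow(triggers$entries) == 0) stop("trigger lexicon is empty")
  index <- lexicon_index(triggers)
  out <- resolve_longest(match_all_spans(sent, index))
  out$categories <- NULL
  out$matcher <- NULL
  out
}

#' Generate candidate pairs
#'
#' Full cross product of triggers and entities from one sentence, minus pairs
#' whose spans overlap. `token_gap` counts tokens strictly between the two
#' spans; `side` is the entity's side relative to the trigger. Output ordered
#' by trigger start, then entity start.
#'
#' @param triggers trigger mentions data.frame.
#' @param entities entity mentions data.frame.
#' @return a data.frame (trigger_idx, entity_idx, token_gap, side).
#' @export
generate_pairs <- function(triggers, entities) {
  out <- data.frame(trigger_idx = integer(), entity_idx = integer(),
                    token_gap = integer(), side = character(),
                    stringsAsFactors = FALSE)
  if (nrow(triggers) == 0 || nrow(entities) == 0) return(out)
  to <- order(triggers$start)
  eo <- order(entities$start)
  for (ti in to) {
    for (ei in eo) {
      t <- triggers[ti, ]; e <- entities[ei, ]
      if (e$start < t$end && t$start < e$end) next  # overlap
      if (e$first_tok > t$last_tok) {
        gap <- e$first_tok - t$last_tok - 1L; side <- "right"
      } else {
        gap <- t$first_tok - e$last_tok - 1L; side <- "left"
      }
      out <- rbind(out, data.frame(trigger_idx = ti, entity_idx = ei,
                                   token_gap = gap, side = side,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Run full candidate generation on one sentence
#'
#' Dictionary entities plus distance/segment regex matches (regex matches
#' overlapping a dictionary mention are dropped), triggers, and all candidate
#' pairs.
#'
#' @param sent an `rs_sentence`.
#' @param entity_lex entity `rs_lexicon`.
#' @param trigger_lex trigger `rs_lexicon`.
#' @return an `rs_candidates`: list(sentence, entities, triggers, pairs).
#' @export
tag_sentence <- function(sent, entity_lex, trigger_lex) {
  ents <- tag_entities(sent, entity_lex)
  extra <- rbind(match_distance(sent), match_segment(sent))
  if (nrow(extra) > 0) {
    ok <- vapply(seq_len(nrow(extra)), function(i) {
      all(extra$end[i] <= ents$start | extra$start[i] >= ents$end)
    }, logical(1))
    extra <- resolve_longest(extra[ok, , drop = FALSE])
    ents <- rbind(ents, extra)
    ents <- ents[order(ents$start), , drop = FALSE]
    rownames(ents) <- NULL
  }
  trig <- tag_triggers(sent, trigger_lex)
  structure(list(sentence = sent, entities = ents, triggers = trig,
                 pairs = generate_pairs(trig, ents)),
            class = "rs_candidates")
}

#' @export
print.rs_candidates <- function(x, ...) {
  cat("<rs_candidates> ", x$sentence$doc_id, "/", x$sentence$sent_id, ": ",
      nrow(x$entities), " entities, ", nrow(x$triggers), " triggers, ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Read sentences from JSONL or plain text
#'
#' JSONL records carry `{doc_id, sent_id, text}`; plain text is one sentence
#' per line with `doc_id` taken from the file name.
#'
#' @param path input file.
#' @param format `"jsonl"` or `"text"`.
#' @return list of `rs_sentence`.
#' @export
read_sentences <- function(path, format = c("jsonl", "text")) {
  format <- match.arg(format)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "jsonl") {
    lapply(lines, function(l) {
      r <- jsonlite::fromJSON(l)
      tokenize_sentence(r$text, doc_id = r$doc_id, sent_id = r$sent_id)
    })
  } else {
    lapply(seq_along(lines), function(i)
      tokenize_sentence(lines[i], doc_id = basename(path), sent_id = i - 1L))
  }
}

#' Write candidate structures as standoff JSON
#'
#' @param cands an `rs_candidates` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_standoff_json <- function(cands, path) {
  if (inherits(cands, "rs_candidates")) cands <- list(cands)
  recs <- lapply(cands, function(cc) {
    list(doc_id = cc$sentence$doc_id, sent_id = cc$sentence$sent_id,
         text = cc$sentence$text,
         entities = cc$entities[, c("start", "end", "surface", "categories",
                                    "matcher")],
         triggers = cc$triggers[, c("start", "end", "surface")],
         pairs = cc$pairs)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
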
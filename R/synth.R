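#' Synthetic radiology-sentence generator
#'
#' Template-grammar sampling of radiology-like sentences with exact gold
#' spatial frames, standing in for restricted report corpora so every
#' pipeline stage is testable end to end. Seven reporting styles are
#' emulated: plain "finding in location", the "location: findings" colon
#' style, device position (with and without a relative-position term),
#' hedge+diagnosis, distance, reason, and associated-process sentences.
#' Generated text is pre-tokenized (single spaces, punctuation as its own
#' token); gold spans are recorded exactly and generation is reproducible by
#' seed.
#'
#' @name radspatial-synth
NULL

SYNTH_STYLES <- c("finding_in_location", "location_colon_finding",
                  "device_position", "hedge_diagnosis", "distance",
                  "reason", "process")

#' Synthetic-corpus configuration
#'
#' @param n_sentences number of sentences to generate.
#' @param seed RNG seed.
#' @param style_mix named proportions over the seven styles (must sum to 1).
#' @param misspell_rate per-token probability of a character-level edit on
#'   tokens outside gold spans, in [0, 0.3].
#' @param distractor_rate probability of a frame-free distractor sentence
#'   replacing a templated one.
#' @param vocab `rs_lexicon` supplying the term pools (defaults to the
#'   packaged entity mini-lexicon).
#' @return list of class `rs_synth_config`.
#' @export
synth_config <- function(n_sentences = 100L, seed = 7L,
                         style_mix = c(finding_in_location = 0.25,
                                       location_colon_finding = 0.10,
                                       device_position = 0.15,
                                       hedge_diagnosis = 0.20,
                                       distance = 0.10,
                                       reason = 0.10,
                                       process = 0.10),
                         misspell_rate = 0, distractor_rate = 0,
                         vocab = NULL) {
  stopifnot(abs(sum(style_mix) - 1) < 1e-8,
            all(names(style_mix) %in% SYNTH_STYLES))
  if (misspell_rate < 0 || misspell_rate > 0.3)
    stop("misspell_rate must lie in [0, 0.3]")
  if (distractor_rate < 0 || distractor_rate > 1)
    stop("distractor_rate must lie in [0, 1]")
  structure(list(n_sentences = as.integer(n_sentences),
                 seed = as.integer(seed), style_mix = style_mix,
                 misspell_rate = misspell_rate,
                 distractor_rate = distractor_rate, vocab = vocab),
            class = "rs_synth_config")
}

synth_pools <- function(vocab) {
  e <- vocab$entries[vocab$entries$source %in% c("base", "manual"), ,
                     drop = FALSE]
  of_cat <- function(cat) e$surface[e$category == cat]
  single <- function(x) x[!grepl(" ", x)]
  pools <- list(
    finding = intersect(single(of_cat("finding")),
                        c("opacity", "consolidation", "edema", "effusion",
                          "lesion", "cyst", "nodule", "mass", "hypodensity",
                          "infiltrate", "hemorrhage", "thickening")),
    diagnosis = intersect(of_cat("finding"),
                          c("pneumonia", "malignancy", "infection", "abscess",
                            "metastasis", "hyaline membrane disease",
                            "microvascular angiopathy")),
    reason_finding = intersect(of_cat("finding"),
                               c("infection", "inflammation", "aspiration",
                                 "scarring")),
    anatomy = setdiff(single(of_cat("anatomy")),
                      c("lobe", "cortex", "svc")),
    device = of_cat("device"),
    hedge = of_cat("hedge"),
    relpos = single(of_cat("relative_position")),
    posverb = intersect(of_cat("position_status"),
                        c("positioned", "advanced", "located")),
    process = single(of_cat("process")))
  empty <- names(pools)[lengths(pools) == 0]
  if (length(empty) > 0)
    stop("vocabulary lacks terms for required categories: ",
         paste(empty, collapse = ", "))
  pools
}

# sentence assembled as a word list plus named role ranges (token indices)
synth_record <- function(words, roles, style, doc_id, sent_id) {
  text <- paste(words, collapse = " ")
  sent <- tokenize_sentence(text, doc_id = doc_id, sent_id = sent_id)
  stopifnot(nrow(sent$tokens) == length(words))
  frames <- list()
  if (!is.null(roles)) {
    trig <- roles$trigger
    fe <- roles$fe
    fe_df <- if (length(fe) == 0)
      data.frame(label = character(), start = integer(), end = integer())
    else do.call(rbind, lapply(fe, function(r)
      data.frame(label = r$label,
                 start = sent$tokens$start[r$from],
                 end = sent$tokens$end[r$to], stringsAsFactors = FALSE)))
    frames <- list(list(trigger_start = sent$tokens$start[trig[1]],
                        trigger_end = sent$tokens$end[trig[2]],
                        fe_spans = fe_df))
  }
  list(sentence = sent, frames = frames, style = style, words = words,
       roles = roles)
}

pick <- function(pool, k = 1) pool[sample.int(length(pool), k)]

synth_one <- function(style, pools, doc_id, sent_id) {
  fe <- list()
  role <- function(label, from, to) list(label = label, from = from, to = to)
  nw <- function(x) length(strsplit(x, " ", fixed = TRUE)[[1]])
  if (style == "finding_in_location") {
    f <- pick(pools$finding); a <- pick(pools$anatomy)
    tg <- pick(c("in", "within", "of"))
    with_rp <- stats::runif(1) < 0.5
    if (with_rp) {
      rp <- pick(pools$relpos)
      words <- c("There", "is", f, tg, "the", rp, a, ".")
      fe <- list(role("FIGURE", 3, 3), role("RELATIVE_POSITION", 6, 6),
                 role("GROUND", 7, 7))
      trig <- c(4, 4)
    } else {
      words <- c("There", "is", f, tg, "the", a, ".")
      fe <- list(role("FIGURE", 3, 3), role("GROUND", 6, 6))
      trig <- c(4, 4)
    }
  } else if (style == "location_colon_finding") {
    f <- pick(pools$finding); a <- pick(pools$anatomy)
    words <- c(a, ":", "There", "are", f, ".")
    fe <- list(role("GROUND", 1, 1), role("FIGURE", 5, 5))
    trig <- c(4, 4)
  } else if (style == "device_position") {
    d <- pick(pools$device); a <- pick(pools$anatomy)
    dn <- nw(d)
    dw <- strsplit(d, " ", fixed = TRUE)[[1]]
    if (stats::runif(1) < 0.6) {
      pv <- pick(pools$posverb)
      words <- c("The", dw, "is", pv, "in", "the", a, ".")
      fe <- list(role("FIGURE", 2, 1 + dn),
                 role("POSITION_STATUS", 3 + dn, 3 + dn),
                 role("GROUND", 6 + dn, 6 + dn))
      trig <- c(4 + dn, 4 + dn)
    } else {
      rp <- pick(pools$relpos)
      words <- c("The", dw, "tip", "is", rp, "in", "the", a, ".")
      fe <- list(role("FIGURE", 2, 1 + dn),
                 role("POSITION_STATUS", 2 + dn, 2 + dn),
                 role("RELATIVE_POSITION", 4 + dn, 4 + dn),
                 role("GROUND", 7 + dn, 7 + dn))
      trig <- c(5 + dn, 5 + dn)
    }
  } else if (style == "hedge_diagnosis") {
    f <- pick(pools$finding); a <- pick(pools$anatomy)
    h <- pick(pools$hedge); dx <- pick(setdiff(pools$diagnosis, f))
    tg <- pick(c("in", "within"))
    hw <- strsplit(h, " ", fixed = TRUE)[[1]]
    dxw <- strsplit(dx, " ", fixed = TRUE)[[1]]
    hn <- length(hw); dxn <- length(dxw)
    words <- c("There", "is", f, tg, "the", a, hw, dxw, ".")
    fe <- list(role("FIGURE", 3, 3), role("GROUND", 6, 6),
               role("HEDGE", 7, 6 + hn),
               role("DIAGNOSIS", 7 + hn, 6 + hn + dxn))
    trig <- c(4, 4)
  } else if (style == "distance") {
    d <- pick(pools$device); a <- pick(pools$anatomy)
    dw <- strsplit(d, " ", fixed = TRUE)[[1]]
    dn <- length(dw)
    num <- pick(c("1", "2", "3", "4", "1.5", "2.5"))
    unit <- pick(c("cm", "mm"))
    tg <- pick(c("above", "below"))
    words <- c("The", dw, "is", num, unit, tg, "the", a, ".")
    fe <- list(role("FIGURE", 2, 1 + dn),
               role("DISTANCE", 3 + dn, 4 + dn),
               role("GROUND", 7 + dn, 7 + dn))
    trig <- c(5 + dn, 5 + dn)
  } else if (style == "reason") {
    f <- pick(pools$finding); a <- pick(pools$anatomy)
    rf <- pick(setdiff(pools$reason_finding, f))
    tg <- pick(c("in", "within"))
    words <- c("There", "is", f, tg, "the", a, "due", "to", rf, ".")
    fe <- list(role("FIGURE", 3, 3), role("GROUND", 6, 6),
               role("REASON", 9, 9))
    trig <- c(4, 4)
  } else if (style == "process") {
    p <- pick(pools$process); f <- pick(pools$finding)
    a <- pick(pools$anatomy)
    tg <- pick(c("in", "within"))
    words <- c("During", p, ",", "there", "is", f, tg, "the", a, ".")
    fe <- list(role("ASSOCIATED_PROCESS", 2, 2), role("FIGURE", 6, 6),
               role("GROUND", 9, 9))
    trig <- c(7, 7)
  } else stop("unknown style: ", style)
  synth_record(words, list(trigger = trig, fe = fe), style, doc_id, sent_id)
}

DISTRACTORS <- c("The heart size is normal .",
                 "No acute osseous abnormality is seen .",
                 "The study is otherwise unremarkable .")

#' Generate a synthetic corpus with gold frames
#'
#' @param config an `rs_synth_config`.
#' @return list of records, each `list(sentence, frames, style)` where
#'   `frames` is a list of gold frames
#'   (`trigger_start`, `trigger_end`, `fe_spans`); distractor records carry
#'   an empty frame list. Byte-identical for a fixed config.
#' @export
generate_corpus <- function(config = synth_config()) {
  vocab <- config$vocab
  if (is.null(vocab)) vocab <- radspatial_entities(expanded = FALSE)
  pools <- synth_pools(vocab)
  with_seed(config$seed, {
    styles <- sample(names(config$style_mix), config$n_sentences,
                     replace = TRUE, prob = config$style_mix)
    out <- vector("list", config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      doc_id <- sprintf("synth%04d", i)
      if (config$distractor_rate > 0 &&
          stats::runif(1) < config$distractor_rate) {
        txt <- pick(DISTRACTORS)
        words <- strsplit(txt, " ", fixed = TRUE)[[1]]
        out[[i]] <- synth_record(words, NULL, "distractor", doc_id, 0L)
      } else {
        out[[i]] <- synth_one(styles[i], pools, doc_id, 0L)
      }
    }
    if (config$misspell_rate > 0)
      out <- corrupt_corpus_impl(out, config$misspell_rate)
    out
  })
}

## ---- corruption -----------------------------------------------------------

edit_word <- function(w) {
  if (nchar(w) < 2) return(w)
  op <- sample(c("swap", "drop", "dup"), 1)
  i <- sample.int(nchar(w) - 1L, 1)
  ch <- strsplit(w, "")[[1]]
  if (op == "swap") {
    tmp <- ch[i]; ch[i] <- ch[i + 1]; ch[i + 1] <- tmp
  } else if (op == "drop") {
    ch <- ch[-i]
  } else {
    ch <- append(ch, ch[i], after = i)
  }
  paste(ch, collapse = "")
}

protected_tokens <- function(record) {
  prot <- integer()
  for (fr in record$frames) {
    toks <- record$sentence$tokens
    tsel <- which(toks$start < fr$trigger_end & toks$end > fr$trigger_start)
    prot <- c(prot, tsel)
    for (i in seq_len(nrow(fr$fe_spans)))
      prot <- c(prot, which(toks$start < fr$fe_spans$end[i] &
                              toks$end > fr$fe_spans$start[i]))
  }
  unique(prot)
}

corrupt_corpus_impl <- function(corpus, rate) {
  lapply(corpus, function(rec) {
    words <- rec$sentence$tokens$surface
    prot <- protected_tokens(rec)
    for (i in setdiff(seq_along(words), prot)) {
      if (grepl("^[[:alpha:]]+$", words[i]) && stats::runif(1) < rate)
        words[i] <- edit_word(words[i])
    }
    # rebuild: token count is preserved, so gold token ranges are stable and
    # char spans are recomputed from the new offsets
    toks <- rec$sentence$tokens
    old_ranges <- lapply(rec$frames, function(fr) {
      list(trig = range(which(toks$start < fr$trigger_end &
                                toks$end > fr$trigger_start)),
           fe = lapply(seq_len(nrow(fr$fe_spans)), function(i)
             range(which(toks$start < fr$fe_spans$end[i] &
                           toks$end > fr$fe_spans$start[i]))))
    })
    sent <- tokenize_sentence(paste(words, collapse = " "),
                              doc_id = rec$sentence$doc_id,
                              sent_id = rec$sentence$sent_id)
    frames <- lapply(seq_along(rec$frames), function(fi) {
      fr <- rec$frames[[fi]]; rg <- old_ranges[[fi]]
      fr$trigger_start <- sent$tokens$start[rg$trig[1]]
      fr$trigger_end <- sent$tokens$end[rg$trig[2]]
      for (i in seq_len(nrow(fr$fe_spans))) {
        fr$fe_spans$start[i] <- sent$tokens$start[rg$fe[[i]][1]]
        fr$fe_spans$end[i] <- sent$tokens$end[rg$fe[[i]][2]]
      }
      fr
    })
    rec$sentence <- sent
    rec$frames <- frames
    rec
  })
}

#' Corrupt a corpus with character-level noise
#'
#' Applies swap/drop/duplicate character edits to alphabetic tokens outside
#' gold spans (gold surfaces are untouched; their char offsets are remapped
#' to the corrupted text). Deterministic for a fixed seed; `rate = 0` is the
#' identity.
#'
#' @param corpus output of [generate_corpus()].
#' @param rate per-token edit probability in [0, 0.3].
#' @param seed RNG seed.
#' @return the corrupted corpus.
#' @export
corrupt_corpus <- function(corpus, rate, seed = 1L) {
  if (rate < 0 || rate > 0.3) stop("rate must lie in [0, 0.3]")
  if (rate == 0) return(corpus)
  with_seed(seed, corrupt_corpus_impl(corpus, rate))
}

#' Corrupt a single sentence
#'
#' Character-level edits on tokens outside `protect` spans. Offsets of later
#' tokens may shift; use [corrupt_corpus()] when gold spans must be
#' remapped.
#'
#' @param sentence an `rs_sentence`.
#' @param rate per-token edit probability in [0, 0.3].
#' @param seed RNG seed.
#' @param protect optional data.frame/list with `start`, `end` char spans to
#'   leave untouched.
#' @return a corrupted `rs_sentence`.
#' @export
corrupt_sentence <- function(sentence, rate, seed = 1L, protect = NULL) {
  if (rate < 0 || rate > 0.3) stop("rate must lie in [0, 0.3]")
  if (rate == 0) return(sentence)
  with_seed(seed, {
    toks <- sentence$tokens
    words <- toks$surface
    prot <- integer()
    if (!is.null(protect) && length(protect$start) > 0)
      for (i in seq_along(protect$start))
        prot <- c(prot, which(toks$start < protect$end[i] &
                                toks$end > protect$start[i]))
    for (i in setdiff(seq_along(words), unique(prot))) {
      if (grepl("^[[:alpha:]]+$", words[i]) && stats::runif(1) < rate)
        words[i] <- edit_word(words[i])
    }
    tokenize_sentence(paste(words, collapse = " "),
                      doc_id = sentence$doc_id, sent_id = sentence$sent_id)
  })
}

## ---- gold views and IO ----------------------------------------------------

#' Gold instances of a synthetic corpus
#'
#' @param corpus output of [generate_corpus()].
#' @return list of `rs_instance` with `provenance = "gold"`.
#' @export
synth_gold_instances <- function(corpus) {
  out <- list()
  for (rec in corpus)
    for (fr in rec$frames)
      out[[length(out) + 1L]] <- gold_instance(rec$sentence,
                                               fr$trigger_start,
                                               fr$trigger_end, fr$fe_spans)
  out
}

#' Write a synthetic corpus
#'
#' `write_corpus_jsonl` emits the sentence records
#' (`{doc_id, sent_id, text}`), `write_gold_standoff` the gold frames.
#'
#' @param corpus output of [generate_corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in corpus)
    writeLines(jsonlite::toJSON(list(doc_id = rec$sentence$doc_id,
                                     sent_id = rec$sentence$sent_id,
                                     text = rec$sentence$text),
                                auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
write_gold_standoff <- function(corpus, path) {
  recs <- lapply(corpus, function(rec) {
    list(doc_id = rec$sentence$doc_id, sent_id = rec$sentence$sent_id,
         text = rec$sentence$text,
         frames = lapply(rec$frames, function(fr)
           list(trigger_start = fr$trigger_start,
                trigger_end = fr$trigger_end, fe_spans = fr$fe_spans)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
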
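#' Baseline sequence tagger
#'
#' Trains a per-token classifier on BIO sequences with masked triggers and
#' decodes frame-element spans for new (sentence, trigger) inputs. The
#' dependency-light baseline backend is an averaged perceptron over window
#' features (token identity, shape, suffix, is-mask, lexicon categories,
#' +/-2 context, bucketed distance to the mask) with hard BIO-transition
#' constraints in greedy decoding. A `transformer` backend id is reserved as
#' an adapter contract: an external model honoring the same train/predict
#' signatures and CoNLL files (reference fine-tuning settings: maximum
#' sequence length 128, learning rate 2e-5, 4 epochs) can stand in for the
#' baseline; no such weights ship with the package.
#'
#' @name radspatial-tagger
NULL

tagset <- function() {
  c("O", paste0("B-", fe_labels()), paste0("I-", fe_labels()))
}

#' Tagger configuration
#'
#' @param backend `"baseline"` (implemented) or `"transformer"` (adapter
#'   contract only).
#' @param max_seq_len sequences longer than this are truncated with a
#'   warning.
#' @param epochs training passes over the data (baseline).
#' @param learning_rate recorded for the transformer contract; the
#'   perceptron uses unit updates.
#' @param seed RNG seed controlling the per-epoch shuffling.
#' @return list of class `rs_tagger_config`.
#' @export
tagger_config <- function(backend = c("baseline", "transformer"),
                          max_seq_len = 128L, epochs = 8L,
                          learning_rate = 2e-5, seed = 1L) {
  backend <- match.arg(backend)
  structure(list(backend = backend, max_seq_len = as.integer(max_seq_len),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "rs_tagger_config")
}

token_shape <- function(x) {
  x <- gsub("[A-Z]", "A", x)
  x <- gsub("[a-z]", "a", x)
  x <- gsub("[0-9]", "9", x)
  gsub("(.)\\1+", "\\1", x)
}

# per-token feature strings for a masked token sequence
featurize_tokens <- function(tokens, cat_map = NULL) {
  n <- length(tokens)
  low <- tolower(tokens)
  mask_pos <- which(tokens == SPTRG_MASK)
  ctx <- function(i) if (i < 1) "<s>" else if (i > n) "</s>" else low[i]
  lapply(seq_len(n), function(i) {
    d <- if (length(mask_pos) == 0) 99L
    else mask_pos[which.min(abs(mask_pos - i))] - i
    d <- max(-4L, min(4L, d))
    fs <- c(paste0("w=", low[i]),
            paste0("p1=", ctx(i - 1)), paste0("p2=", ctx(i - 2)),
            paste0("n1=", ctx(i + 1)), paste0("n2=", ctx(i + 2)),
            paste0("shape=", token_shape(tokens[i])),
            paste0("suf=", substr(low[i], max(1, nchar(low[i]) - 2),
                                  nchar(low[i]))),
            paste0("dist=", d),
            paste0("w|side=", low[i], "@", sign(d)))
    if (tokens[i] == SPTRG_MASK) fs <- c(fs, "ismask")
    if (!is.null(cat_map)) {
      cats <- cat_map[[low[i]]]
      if (!is.null(cats))
        fs <- c(fs, paste0("cat=", strsplit(cats, "|", fixed = TRUE)[[1]]))
    }
    fs
  })
}

score_tags <- function(env, feats, ntags) {
  s <- numeric(ntags)
  for (f in feats) {
    wv <- env[[f]]
    if (!is.null(wv)) s <- s + wv$w
  }
  s
}

allowed_tags <- function(prev_tag, tags) {
  ok <- !startsWith(tags, "I-")
  if (prev_tag != "O" && prev_tag != "<s>") {
    lab <- substring(prev_tag, 3)
    ok <- ok | tags == paste0("I-", lab)
  }
  ok
}

greedy_decode <- function(env, feat_seq, tags) {
  n <- length(feat_seq)
  pred <- character(n)
  prev <- "<s>"
  for (i in seq_len(n)) {
    s <- score_tags(env, feat_seq[[i]], length(tags))
    s[!allowed_tags(prev, tags)] <- -Inf
    pred[i] <- tags[which.max(s)]
    prev <- pred[i]
  }
  pred
}

perc_update <- function(env, feats, gold_i, pred_i, t) {
  for (f in feats) {
    wv <- env[[f]]
    if (is.null(wv)) {
      nt <- length(tagset())
      wv <- list(w = numeric(nt), u = numeric(nt), t = 0)
    }
    wv$u <- wv$u + wv$w * (t - wv$t)
    wv$w[gold_i] <- wv$w[gold_i] + 1
    wv$w[pred_i] <- wv$w[pred_i] - 1
    wv$t <- t
    env[[f]] <- wv
  }
}

#' Train the baseline tagger
#'
#' @param sequences list of `rs_bio` training sequences (valid BIO).
#' @param config an `rs_tagger_config`.
#' @param lexicon optional `rs_lexicon`; single-word entry categories become
#'   token features, which helps generalization to unseen-but-in-dictionary
#'   vocabulary.
#' @return an `rs_tagger`: averaged feature weights, tag inventory, config
#'   snapshot and truncation count. Training is reproducible bit-for-bit for
#'   a fixed seed and input order.
#' @export
train_tagger <- function(sequences, config = tagger_config(),
                         lexicon = NULL) {
  if (config$backend == "transformer")
    stop("the transformer backend is an adapter contract: supply an external ",
         "model honoring train/predict on the same CoNLL BIO files; only ",
         "the baseline backend ships with this package")
  if (length(sequences) == 0) stop("empty training set")
  for (i in seq_along(sequences)) {
    if (!validate_bio(sequences[[i]]$tags))
      stop("invalid BIO tags in training sequence ", i)
  }
  cat_map <- NULL
  if (!is.null(lexicon)) {
    single <- lexicon$entries[!grepl(" ", lexicon$entries$surface), ,
                              drop = FALSE]
    cat_map <- as.list(tapply(single$category, single$surface,
                              paste, collapse = "|"))
  }
  truncated <- 0L
  prep <- lapply(sequences, function(b) {
    toks <- b$tokens; tags <- b$tags
    if (length(toks) > config$max_seq_len) {
      truncated <<- truncated + 1L
      warning("sequence truncated at max_seq_len = ", config$max_seq_len,
              call. = FALSE)
      toks <- toks[seq_len(config$max_seq_len)]
      tags <- tags[seq_len(config$max_seq_len)]
      if (startsWith(tags[length(tags)], "I-") ||
          startsWith(tags[length(tags)], "B-"))
        tags[length(tags)] <- tags[length(tags)]  # kept; run end recorded
    }
    list(feats = featurize_tokens(toks, cat_map), tags = tags)
  })
  tags <- tagset()
  env <- new.env(parent = emptyenv())
  t <- 0
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(prep))
      for (si in ord) {
        sq <- prep[[si]]
        pred <- greedy_decode(env, sq$feats, tags)
        for (i in seq_along(pred)) {
          t <- t + 1
          if (pred[i] != sq$tags[i]) {
            gi <- match(sq$tags[i], tags)
            pi <- match(pred[i], tags)
            perc_update(env, sq$feats[[i]], gi, pi, t)
          }
        }
      }
    }
  })
  # finalize averaged weights
  avg <- new.env(parent = emptyenv())
  for (f in ls(env)) {
    wv <- env[[f]]
    a <- (wv$u + wv$w * (t - wv$t)) / max(t, 1)
    avg[[f]] <- list(w = a)
  }
  structure(list(weights = avg, tags = tags, config = config,
                 cat_map = cat_map, n_train = length(sequences),
                 truncated = truncated),
            class = "rs_tagger")
}

#' @export
print.rs_tagger <- function(x, ...) {
  cat("Baseline frame-element tagger (averaged perceptron)\n")
  cat("  trained on", x$n_train, "BIO sequences;",
      length(ls(x$weights)), "features;", x$config$epochs, "epochs\n")
  if (x$truncated > 0)
    cat("  truncated sequences during training:", x$truncated, "\n")
  invisible(x)
}

#' Predict tags for a prepared BIO token sequence
#'
#' Lower-level interface used by [predict.rs_tagger()] and the evaluation
#' pipeline: tags an already-masked token sequence.
#'
#' @param model an `rs_tagger`.
#' @param tokens character vector with `$sptrg$` at trigger positions.
#' @return character vector of BIO tags (always valid BIO by construction).
#' @export
tag_tokens <- function(model, tokens) {
  feats <- featurize_tokens(tokens, model$cat_map)
  greedy_decode(model$weights, feats, model$tags)
}

#' Predict frame-element spans for a sentence and trigger
#'
#' Masks the trigger tokens, tags the sequence and decodes maximal B/I runs
#' into character spans. Deterministic: identical inputs give identical
#' output.
#'
#' @param object an `rs_tagger`.
#' @param sentence an `rs_sentence`.
#' @param trigger numeric vector `c(start, end)` (0-based half-open char
#'   span of the trigger) or a list with `start`/`end`.
#' @param ... unused.
#' @return data.frame (label, start, end, first_tok, last_tok, surface).
#' @export
predict.rs_tagger <- function(object, sentence, trigger, ...) {
  if (is.list(trigger)) trigger <- c(trigger$start, trigger$end)
  toks <- sentence$tokens
  surf <- toks$surface
  masked <- toks$start < trigger[2] & toks$end > trigger[1]
  if (!any(masked)) stop("trigger span does not cover any token")
  surf[masked] <- SPTRG_MASK
  tags <- tag_tokens(object, surf)
  tags[masked] <- "O"
  spans <- bio_spans(list(tokens = surf, tags = tags,
                          token_start = toks$start, token_end = toks$end))
  if (nrow(spans) > 0)
    spans$surface <- vapply(seq_len(nrow(spans)), function(i)
      slice0(sentence$text, spans$start[i], spans$end[i]), character(1))
  else spans$surface <- character()
  spans
}
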
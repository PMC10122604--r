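test_that("generation is byte-identical for a fixed seed", {
  cfg <- synth_config(n_sentences = 30, seed = 19)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  c3 <- generate_corpus(synth_config(n_sentences = 30, seed = 20))
  expect_false(identical(lapply(c1, function(r) r$sentence$text),
                         lapply(c3, function(r) r$sentence$text)))
})

test_that("noise-free gold surfaces exist in the vocabulary or regexes", {
  vocab <- radspatial_entities(expanded = FALSE)
  corpus <- generate_corpus(synth_config(n_sentences = 80, seed = 3))
  ex <- expand_lexicon(vocab)
  for (rec in corpus) {
    for (fr in rec$frames) {
      s <- fr$fe_spans
      for (i in seq_len(nrow(s))) {
        surf <- substr(rec$sentence$text, s$start[i] + 1, s$end[i])
        known <- length(lexicon_lookup(ex, surf)) > 0 ||
          grepl("^[0-9.]+ (mm|cm)$", surf)
        expect_true(known, info = surf)
      }
    }
  }
})

test_that("gold spans are slice-exact and token-aligned", {
  corpus <- generate_corpus(synth_config(n_sentences = 50, seed = 13))
  for (rec in corpus) {
    toks <- rec$sentence$tokens
    for (fr in rec$frames) {
      expect_true(fr$trigger_start %in% toks$start)
      expect_true(fr$trigger_end %in% toks$end)
      s <- fr$fe_spans
      for (i in seq_len(nrow(s))) {
        expect_true(s$start[i] %in% toks$start)
        expect_true(s$end[i] %in% toks$end)
      }
    }
  }
})

test_that("every frame element appears in at least 1% of frames", {
  corpus <- generate_corpus(synth_config(n_sentences = 1000, seed = 2))
  frames <- unlist(lapply(corpus, function(r) r$frames), recursive = FALSE)
  n <- length(frames)
  for (lb in fe_labels()) {
    hits <- sum(vapply(frames, function(fr) lb %in% fr$fe_spans$label,
                       logical(1)))
    expect_gte(hits / n, 0.01)
  }
  # non-colon styles always satisfy the Figure+Ground constraint
  for (rec in corpus) {
    if (rec$style %in% c("location_colon_finding", "distractor")) next
    for (fr in rec$frames)
      expect_true(all(c("FIGURE", "GROUND") %in% fr$fe_spans$label))
  }
})

test_that("corruption is deterministic, bounded and leaves gold intact", {
  corpus <- generate_corpus(synth_config(n_sentences = 40, seed = 9))
  expect_identical(corrupt_corpus(corpus, 0, seed = 1), corpus)
  c1 <- corrupt_corpus(corpus, 0.3, seed = 4)
  c2 <- corrupt_corpus(corpus, 0.3, seed = 4)
  expect_identical(c1, c2)
  changed <- sum(vapply(seq_along(corpus), function(i)
    corpus[[i]]$sentence$text != c1[[i]]$sentence$text, logical(1)))
  expect_gt(changed, 0)
  # gold surfaces survive corruption verbatim
  for (i in seq_along(c1)) {
    for (fi in seq_along(c1[[i]]$frames)) {
      fr0 <- corpus[[i]]$frames[[fi]]; fr1 <- c1[[i]]$frames[[fi]]
      t0 <- substr(corpus[[i]]$sentence$text, fr0$trigger_start + 1,
                   fr0$trigger_end)
      t1 <- substr(c1[[i]]$sentence$text, fr1$trigger_start + 1,
                   fr1$trigger_end)
      expect_identical(t1, t0)
      for (k in seq_len(nrow(fr0$fe_spans))) {
        s0 <- substr(corpus[[i]]$sentence$text,
                     fr0$fe_spans$start[k] + 1, fr0$fe_spans$end[k])
        s1 <- substr(c1[[i]]$sentence$text,
                     fr1$fe_spans$start[k] + 1, fr1$fe_spans$end[k])
        expect_identical(s1, s0)
      }
    }
  }
  expect_error(corrupt_corpus(corpus, 0.5), "0.3")
})

test_that("gold-protected corruption keeps entity recall unchanged", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  corpus <- generate_corpus(synth_config(n_sentences = 40, seed = 17))
  noisy <- corrupt_corpus(corpus, 0.3, seed = 6)
  recall_of <- function(cp) {
    found <- 0; total <- 0
    for (rec in cp) {
      cc <- tag_sentence(rec$sentence, ent, tri)
      ek <- paste(cc$entities$start, cc$entities$end)
      for (fr in rec$frames) {
        s <- fr$fe_spans
        total <- total + nrow(s)
        found <- found + sum(paste(s$start, s$end) %in% ek)
      }
    }
    found / total
  }
  expect_equal(recall_of(noisy), recall_of(corpus))
})

test_that("distractors carry no frames and corpus files are written", {
  corpus <- generate_corpus(synth_config(n_sentences = 60, seed = 8,
                                         distractor_rate = 0.3))
  styles <- vapply(corpus, `[[`, character(1), "style")
  expect_gt(sum(styles == "distractor"), 0)
  for (rec in corpus[styles == "distractor"])
    expect_length(rec$frames, 0)
  tf1 <- withr::local_tempfile(fileext = ".jsonl")
  tf2 <- withr::local_tempfile(fileext = ".json")
  write_corpus_jsonl(corpus, tf1)
  write_gold_standoff(corpus, tf2)
  back <- read_sentences(tf1, "jsonl")
  expect_length(back, 60)
  gold <- jsonlite::read_json(tf2, simplifyVector = TRUE)
  expect_equal(length(gold$doc_id), 60)
})

test_that("missing vocabulary categories are a generation error", {
  small <- lexicon(c("opacity", "lung"), c("finding", "anatomy"))
  expect_error(generate_corpus(synth_config(n_sentences = 5, vocab = small)),
               "lacks terms")
})

test_that("the pipeline recovers at least 90% of gold on clean corpora", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  corpus <- generate_corpus(synth_config(n_sentences = 500, seed = 7))
  run <- weak_label_corpus(lapply(corpus, `[[`, "sentence"), ent, tri)
  kept <- filter_instances(run$instances,
                           filter_config(ground_only_mode = TRUE))
  gold <- synth_gold_instances(corpus)
  gold_trig <- do.call(rbind, lapply(gold, function(g)
    data.frame(doc_id = g$doc_id, sent_id = g$sent_id,
               start = g$trigger$start, end = g$trigger$end)))
  pred_trig <- do.call(rbind, lapply(kept, function(x)
    data.frame(doc_id = x$doc_id, sent_id = x$sent_id,
               start = x$trigger$start, end = x$trigger$end)))
  key <- function(d) paste(d$doc_id, d$start, d$end)
  trig_recall <- mean(key(gold_trig) %in% key(pred_trig))
  expect_gte(trig_recall, 0.9)
  # Ground span recovery across weak instances
  gold_ground <- 0; found_ground <- 0
  pred_by_key <- stats::setNames(kept, vapply(kept, function(x)
    paste(x$doc_id, x$trigger$start, x$trigger$end), character(1)))
  for (g in gold) {
    gs <- g$fe_spans[g$fe_spans$label == "GROUND", ]
    gold_ground <- gold_ground + nrow(gs)
    pk <- pred_by_key[[paste(g$doc_id, g$trigger$start, g$trigger$end)]]
    if (is.null(pk)) next
    ps <- pk$fe_spans[pk$fe_spans$label == "GROUND", ]
    found_ground <- found_ground +
      sum(paste(gs$start, gs$end) %in% paste(ps$start, ps$end))
  }
  expect_gte(found_ground / gold_ground, 0.9)
})
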
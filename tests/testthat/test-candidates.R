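test_that("tokenizer separates boundary punctuation and keeps internals", {
  s <- tokenize_sentence("")
  expect_equal(nrow(s$tokens), 0)

  s <- tokenize_sentence("ETT tube is 1 cm above the carina.")
  expect_equal(nrow(s$tokens), 9)
  expect_equal(s$tokens$surface[9], ".")

  s <- tokenize_sentence("Brain parenchyma: There are changes.")
  expect_equal(s$tokens$surface[2:3], c("parenchyma", ":"))

  # hyphens and internal periods survive
  s <- tokenize_sentence("Lesion at C5-C7 measures 1.5 cm (stable).")
  expect_true("C5-C7" %in% s$tokens$surface)
  expect_true("1.5" %in% s$tokens$surface)
  expect_true(all(c("(", ")", ".") %in% s$tokens$surface))
})

test_that("token offsets are 0-based half-open and slice-exact", {
  texts <- c("There is hazy opacity of the lung.",
             "A right PIC catheter terminates in the mid SVC.",
             "x", "  spaced   out  text . ")
  for (tx in texts) {
    s <- tokenize_sentence(tx)
    tk <- s$tokens
    if (nrow(tk) == 0) next
    for (i in seq_len(nrow(tk)))
      expect_identical(substr(tx, tk$start[i] + 1, tk$end[i]),
                       tk$surface[i])
    expect_true(all(diff(tk$start) > 0))
    expect_true(all(tk$end > tk$start))
    expect_true(all(tk$start[-1] >= tk$end[-nrow(tk)]))
  }
})

test_that("entity tagging keeps longest match with the descriptor exception", {
  ent <- fixture_entities()
  s <- tokenize_sentence("Signal change in the inferior cerebellar peduncle.")
  m <- tag_entities(s, ent)
  expect_true("inferior" %in% m$surface)
  expect_true("cerebellar peduncle" %in% m$surface)
  expect_false("inferior cerebellar peduncle" %in% m$surface)
  expect_true("location_descriptor" %in%
                strsplit(m$categories[m$surface == "inferior"], "|",
                         fixed = TRUE)[[1]])

  s2 <- tokenize_sentence("There is hazy opacity of the lung consistent with hyaline membrane disease.")
  m2 <- tag_entities(s2, ent)
  expect_setequal(m2$surface, c("opacity", "lung", "consistent with",
                                "hyaline membrane disease"))

  s3 <- tokenize_sentence("No matching vocabulary here whatsoever.")
  expect_equal(nrow(tag_entities(s3, ent)), 0)
})

test_that("dictionary mentions never overlap except via the descriptor split", {
  ent <- fixture_entities()
  for (tx in c("The right lower lobe and left lateral ventricle are clear.",
               "Opacity in the periventricular white matter and centrum semi-ovale.",
               "The inferior cerebellar peduncle is unremarkable.")) {
    m <- tag_entities(tokenize_sentence(tx), ent)
    if (nrow(m) < 2) next
    for (i in seq_len(nrow(m) - 1))
      expect_true(m$start[i + 1] >= m$end[i])
  }
})

test_that("distance regex matches numbers with units, not reversed order", {
  s <- tokenize_sentence("ETT tube is 1 cm above the carina.")
  m <- match_distance(s)
  expect_equal(m$surface, "1 cm")
  expect_equal(m$matcher, "distance_regex")
  expect_equal(m$categories, "distance")

  expect_equal(match_distance(tokenize_sentence("A nodule of 2 mm."))$surface,
               "2 mm")
  expect_equal(nrow(match_distance(tokenize_sentence("cm 1 is not a size"))),
               0)
  expect_equal(match_distance(tokenize_sentence("measuring 3-5 mm today"))$surface,
               "3-5 mm")
})

test_that("segment regex accepts vertebral codes and rejects others", {
  expect_equal(match_segment(tokenize_sentence("Fusion at C5-C7 noted."))$surface,
               "C5-C7")
  expect_equal(match_segment(tokenize_sentence("Fracture of T12."))$surface,
               "T12")
  expect_equal(nrow(match_segment(tokenize_sentence("X12 is not a segment"))),
               0)
  expect_equal(match_segment(tokenize_sentence("L4-L5 disc"))$categories, "anatomy")
})

test_that("trigger tagging is dictionary longest-match in sentence order", {
  tri <- fixture_triggers()
  s <- tokenize_sentence("There is hazy opacity of the lung near the hilum.")
  tg <- tag_triggers(s, tri)
  expect_equal(tg$surface, c("of", "near"))

  s2 <- tokenize_sentence("A right PIC catheter terminates in the mid SVC.")
  tg2 <- tag_triggers(s2, tri)
  expect_setequal(tg2$surface, c("terminates", "in"))

  # multi-word trigger wins over its single-word prefix-free parts
  s3 <- tokenize_sentence("Edema adjacent to the ventricle.")
  expect_equal(tag_triggers(s3, tri)$surface, "adjacent to")

  expect_equal(nrow(tag_triggers(tokenize_sentence("No spatial words here"),
                                 tri)), 0)
})

test_that("pair generation is the overlap-free cross product", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  cc <- tag_sentence(tokenize_sentence(worked_sentences()["p1"]), ent, tri)
  expect_equal(nrow(cc$pairs), 4)  # 1 trigger x 4 entities

  # sizes bound: |pairs| <= |triggers| x |entities|
  for (tx in worked_sentences()) {
    cc <- tag_sentence(tokenize_sentence(tx), ent, tri)
    expect_lte(nrow(cc$pairs), nrow(cc$triggers) * nrow(cc$entities))
    # pairs never overlap; token_gap consistent with sides
    for (i in seq_len(nrow(cc$pairs))) {
      t <- cc$triggers[cc$pairs$trigger_idx[i], ]
      e <- cc$entities[cc$pairs$entity_idx[i], ]
      expect_true(e$end <= t$start || e$start >= t$end)
      expect_gte(cc$pairs$token_gap[i], 0)
      if (cc$pairs$side[i] == "right") expect_gt(e$first_tok, t$last_tok)
      else expect_lt(e$last_tok, t$first_tok)
    }
  }
  expect_equal(nrow(generate_pairs(tag_triggers(
    tokenize_sentence("above"), tri), fixture_entities()$entries[0, ])), 0)
})

test_that("a surface in both dictionaries yields both mentions, no self-pair", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  cc <- tag_sentence(tokenize_sentence(
    "A right PIC catheter terminates in the mid SVC."), ent, tri)
  expect_true("terminates" %in% cc$entities$surface)
  expect_true("terminates" %in% cc$triggers$surface)
  tt <- cc$triggers[cc$triggers$surface == "terminates", ]
  self <- cc$pairs[cc$pairs$trigger_idx ==
                     which(cc$triggers$surface == "terminates"), ]
  ents <- cc$entities[self$entity_idx, ]
  expect_false(any(ents$start == tt$start & ents$end == tt$end))
})

test_that("sentence IO round-trips through JSONL", {
  tf <- withr::local_tempfile(fileext = ".jsonl")
  sents <- worked_sentence_objs()[1:3]
  con <- file(tf, "w")
  for (s in sents)
    writeLines(jsonlite::toJSON(list(doc_id = s$doc_id, sent_id = s$sent_id,
                                     text = s$text), auto_unbox = TRUE), con)
  close(con)
  back <- read_sentences(tf, "jsonl")
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$text, sents[[2]]$text)
  expect_equal(back[[2]]$tokens, sents[[2]]$tokens)
})
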
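test_that("default registry has 19 unique, label-pure LFs covering all FEs", {
  reg <- default_lf_registry()
  expect_length(reg, 19)
  nms <- vapply(reg, `[[`, character(1), "name")
  expect_equal(anyDuplicated(nms), 0)
  targets <- vapply(reg, `[[`, character(1), "target")
  expect_setequal(unique(targets), fe_labels())
})

test_that("every LF is deterministic and emits only its target label", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  corpus <- generate_corpus(synth_config(n_sentences = 40, seed = 11))
  cands <- lapply(corpus, function(r) tag_sentence(r$sentence, ent, tri))
  v1 <- apply_lfs(cands)
  v2 <- apply_lfs(cands)
  expect_identical(v1$votes, v2$votes)
  for (j in seq_len(ncol(v1$votes))) {
    col <- v1$votes[, j]
    expect_true(all(is.na(col) | col == v1$targets[j]))
  }
})

test_that("Ground heuristics match their published example sentences", {
  run <- run_worked_pipeline()
  v <- run$votes
  pick_row <- function(doc, trig, ent)
    which(v$pairs$doc_id == doc & v$pairs$trigger_surface == trig &
            v$pairs$entity_surface == ent)
  # copular trigger, left-adjacent entity
  expect_equal(unname(v$votes[pick_row("p7", "demonstrate", "lungs"),
                              "lf_ground_adjacency"]), "GROUND")
  # right-side anatomy within the gap
  expect_equal(unname(v$votes[pick_row("p1", "of", "lung"),
                              "lf_ground_adjacency"]), "GROUND")
  # closest-trigger rule with and without intervening tokens
  expect_equal(unname(v$votes[pick_row("p8", "in", "periventricular white matter"),
                              "lf_ground_closest"]), "GROUND")
  expect_equal(unname(v$votes[pick_row("p8", "in", "centrum semi-ovale"),
                              "lf_ground_closest"]), "GROUND")
  # category gate: finding on the right is not Ground
  expect_true(is.na(v$votes[pick_row("p1", "of", "hyaline membrane disease"),
                            "lf_ground_adjacency"]))
})

test_that("Diagnosis heuristics match their published example sentences", {
  run <- run_worked_pipeline()
  v <- run$votes
  pick_row <- function(doc, trig, ent)
    which(v$pairs$doc_id == doc & v$pairs$trigger_surface == trig &
            v$pairs$entity_surface == ent)
  # sentence-final finding after a prepositional hedge
  expect_equal(unname(v$votes[pick_row("p9", "within", "pneumonia"),
                              "lf_diagnosis_sentence_final"]), "DIAGNOSIS")
  expect_equal(unname(v$votes[pick_row("p1", "of", "hyaline membrane disease"),
                              "lf_diagnosis_sentence_final"]), "DIAGNOSIS")
  # right-window cue "versus"
  expect_equal(unname(v$votes[pick_row("p10", "in", "atelactases"),
                              "lf_diagnosis_hedge_window"]), "DIAGNOSIS")
  # left-window cue "consistent with"
  expect_equal(unname(v$votes[pick_row("p8", "in", "microvascular angiopathy"),
                              "lf_diagnosis_hedge_window"]), "DIAGNOSIS")
  # mid-sentence finding with no hedge: abstain (both "opacity" mentions)
  expect_true(all(is.na(v$votes[pick_row("p10", "in", "opacity"),
                                "lf_diagnosis_sentence_final"])))
})

test_that("the vote union covers the bolded FE of each exemplar sentence", {
  run <- run_worked_pipeline()
  v <- run$votes
  votes_for <- function(doc, ent) {
    rows <- which(v$pairs$doc_id == doc & v$pairs$entity_surface == ent)
    unique(stats::na.omit(as.vector(v$votes[rows, , drop = FALSE])))
  }
  expect_true("FIGURE" %in% votes_for("p1", "opacity"))
  expect_true("GROUND" %in% votes_for("p1", "lung"))
  expect_true("HEDGE" %in% votes_for("p1", "consistent with"))
  expect_true("DIAGNOSIS" %in% votes_for("p1", "hyaline membrane disease"))
  expect_true("POSITION_STATUS" %in% votes_for("p2", "terminates"))
  expect_true("RELATIVE_POSITION" %in% votes_for("p3", "high"))
  expect_true("DISTANCE" %in% votes_for("p4", "1 cm"))
  expect_true("REASON" %in% votes_for("p5", "lacune"))
  expect_true("ASSOCIATED_PROCESS" %in%
                votes_for("p6", "movement of the right foot"))
})

test_that("vote matrix shape, order and config overrides behave", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  # zero pairs -> 0 x m matrix
  v0 <- apply_lfs(tag_sentence(tokenize_sentence("Nothing at all"),
                               ent, tri))
  expect_equal(dim(v0$votes), c(0, 19))
  # column order equals registration order
  expect_equal(colnames(v0$votes),
               vapply(default_lf_registry(), `[[`, character(1), "name"))
  # emptying a cue list silences the dependent LF
  cc <- tag_sentence(tokenize_sentence(worked_sentences()["p5"]), ent, tri)
  cfg <- lf_config(reason_cues = "zzz-never-seen")
  v <- apply_lfs(cc, cfg = cfg)
  expect_true(all(is.na(v$votes[, "lf_reason_cue"])))
  expect_true(all(is.na(v$votes[, "lf_reason_final"])))
  # duplicate names are rejected
  reg <- default_lf_registry()
  reg[[2]]$name <- reg[[1]]$name
  expect_error(apply_lfs(cc, registry = reg), "duplicate")
})

test_that("vote TSV serialization round-trips with '-' abstains", {
  run <- run_worked_pipeline()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_votes_tsv(run$votes, tf)
  back <- read_votes_tsv(tf)
  expect_identical(unname(back), unname(run$votes$votes))
  expect_equal(colnames(back), colnames(run$votes$votes))
})
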
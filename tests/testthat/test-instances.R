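test_that("instances group labeled pairs by trigger with argmax labels", {
  run <- run_worked_pipeline()
  inst <- run$instances
  # the exemplar sentence yields one instance for "of" with all 4 FEs
  p1 <- inst[vapply(inst, function(x)
    x$doc_id == "p1" && x$trigger$surface == "of", logical(1))]
  expect_length(p1, 1)
  fe <- p1[[1]]$fe_spans
  expect_setequal(paste(fe$label, fe$surface),
                  c("FIGURE opacity", "GROUND lung",
                    "HEDGE consistent with",
                    "DIAGNOSIS hyaline membrane disease"))
  # no FE span overlaps its trigger; same-label spans are disjoint
  for (x in inst) {
    s <- x$fe_spans
    expect_true(all(s$end <= x$trigger$start | s$start >= x$trigger$end))
    for (lb in unique(s$label)) {
      sl <- s[s$label == lb, ]
      sl <- sl[order(sl$start), ]
      if (nrow(sl) > 1)
        expect_true(all(sl$start[-1] >= sl$end[-nrow(sl)]))
    }
  }
})

test_that("an entity shared by two triggers appears in both instances", {
  run <- run_worked_pipeline()
  # p2 has triggers "terminates" and "in"; "mid SVC" is Ground for both
  p2 <- run$instances[vapply(run$instances, function(x) x$doc_id == "p2",
                             logical(1))]
  expect_gte(length(p2), 2)
  carriers <- vapply(p2, function(x) "mid SVC" %in% x$fe_spans$surface,
                     logical(1))
  expect_gte(sum(carriers), 2)
})

test_that("all-abstain vote sets produce no instances", {
  ent <- fixture_entities(); tri <- fixture_triggers()
  cc <- tag_sentence(tokenize_sentence("The lung of."), ent, tri)
  v <- apply_lfs(cc)
  lab <- fit_majority(v)
  lab$abstained <- rep(TRUE, nrow(lab))
  expect_length(build_instances(cc, v, lab), 0)
})

test_that("figure-ground filter honors default and ground-only modes", {
  run <- run_worked_pipeline()
  with_fg <- run$instances[vapply(run$instances, function(x)
    all(c("FIGURE", "GROUND") %in% x$fe_spans$label), logical(1))]
  only_g <- run$instances[vapply(run$instances, function(x)
    "GROUND" %in% x$fe_spans$label &&
      !"FIGURE" %in% x$fe_spans$label, logical(1))]
  expect_gt(length(with_fg), 0)
  expect_gt(length(only_g), 0)
  dflt <- filter_config(); gonly <- filter_config(ground_only_mode = TRUE)
  expect_true(all(vapply(with_fg, filter_figure_ground, logical(1), dflt)))
  expect_false(any(vapply(only_g, filter_figure_ground, logical(1), dflt)))
  expect_true(all(vapply(only_g, filter_figure_ground, logical(1), gonly)))
  # empty instance fails both modes
  empty <- with_fg[[1]]
  empty$fe_spans <- empty$fe_spans[0, ]
  expect_false(filter_figure_ground(empty, dflt))
  expect_false(filter_figure_ground(empty, gonly))
})

test_that("frequent-phrase filter rejects configured contexts only", {
  s <- tokenize_sentence("There is a history of opacity in the lung.")
  span_of <- function(w) {
    i <- which(s$tokens$surface == w)[1]
    c(s$tokens$start[i], s$tokens$end[i])
  }
  no_spans <- data.frame(label = character(), start = integer(),
                         end = integer())
  of_inst <- gold_instance(s, span_of("of")[1], span_of("of")[2], no_spans)
  in_inst <- gold_instance(s, span_of("in")[1], span_of("in")[2], no_spans)
  cfg <- filter_config()
  expect_false(filter_frequent_phrases(of_inst, cfg))  # "history of"
  expect_true(filter_frequent_phrases(in_inst, cfg))
  # a trigger absent from the map always passes
  s2 <- tokenize_sentence("ETT tube is 1 cm above the carina.")
  i <- which(s2$tokens$surface == "above")
  above_inst <- gold_instance(s2, s2$tokens$start[i], s2$tokens$end[i],
                              no_spans)
  expect_true(filter_frequent_phrases(above_inst, cfg))
  # emptied phrase lists pass everything
  cfg0 <- filter_config(frequent_phrases = list(
    of = list(left = character(), right = character())))
  expect_true(filter_frequent_phrases(of_inst, cfg0))
})

test_that("filtering is monotone and idempotent", {
  run <- run_worked_pipeline()
  cfg <- filter_config()
  once <- filter_instances(run$instances, cfg)
  expect_lte(length(once), length(run$instances))
  twice <- filter_instances(once, cfg)
  expect_identical(twice, once)
})

test_that("BIO rendering masks the trigger and encodes the exemplar roles", {
  run <- run_worked_pipeline()
  p1 <- run$instances[vapply(run$instances, function(x)
    x$doc_id == "p1" && x$trigger$surface == "of", logical(1))][[1]]
  bio <- to_bio(p1)
  expect_equal(length(bio$tokens), length(bio$tags))
  tok <- function(w) which(p1$sentence$tokens$surface == w)[1]
  expect_equal(bio$tokens[tok("of")], "$sptrg$")
  expect_equal(bio$tags[tok("of")], "O")
  expect_equal(bio$tags[tok("opacity")], "B-FIGURE")
  expect_equal(bio$tags[tok("lung")], "B-GROUND")
  expect_equal(bio$tags[tok("consistent")], "B-HEDGE")
  expect_equal(bio$tags[tok("with")], "I-HEDGE")
  expect_equal(bio$tags[tok("hyaline")], "B-DIAGNOSIS")
  expect_equal(bio$tags[tok("membrane")], "I-DIAGNOSIS")
  expect_equal(bio$tags[tok("disease")], "I-DIAGNOSIS")
  # instance without FE spans: all O except mask positions
  empty <- p1; empty$fe_spans <- p1$fe_spans[0, ]
  b0 <- to_bio(empty)
  expect_true(all(b0$tags == "O"))
})

test_that("two triggers in one sentence differ only in mask and tags", {
  run <- run_worked_pipeline()
  p2 <- run$instances[vapply(run$instances, function(x) x$doc_id == "p2",
                             logical(1))]
  bios <- lapply(p2, to_bio)
  expect_gte(length(bios), 2)
  raw <- run$cands[[2]]$sentence$tokens$surface
  for (b in bios) {
    masked <- b$tokens == "$sptrg$"
    expect_identical(b$tokens[!masked], raw[!masked])
  }
  expect_false(identical(bios[[1]]$tokens, bios[[2]]$tokens))
})

test_that("every emitted sequence is valid BIO and round-trips its spans", {
  run <- run_worked_pipeline()
  for (inst in filter_instances(run$instances)) {
    bio <- to_bio(inst)
    expect_true(validate_bio(bio$tags))
    dec <- bio_spans(bio)
    # decode recovers exactly the surviving FE spans
    surv <- inst$fe_spans
    expect_setequal(paste(dec$label, dec$start, dec$end),
                    paste(surv$label, surv$start, surv$end))
  }
  expect_false(validate_bio(c("O", "I-GROUND")))
  expect_false(validate_bio(c("B-FIGURE", "I-GROUND")))
  expect_true(validate_bio(c("B-FIGURE", "I-FIGURE", "O")))
})

test_that("CoNLL files round-trip tokens, tags and instance metadata", {
  run <- run_worked_pipeline()
  bios <- lapply(filter_instances(run$instances), to_bio)
  tf <- withr::local_tempfile(fileext = ".conll")
  write_conll(bios, tf)
  back <- read_conll(tf)
  expect_length(back, length(bios))
  for (i in seq_along(bios)) {
    expect_identical(back[[i]]$tokens, bios[[i]]$tokens)
    expect_identical(back[[i]]$tags, bios[[i]]$tags)
    expect_identical(back[[i]]$meta$trigger_start,
                     bios[[i]]$meta$trigger_start)
  }
})
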
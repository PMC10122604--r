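# Shared fixtures: the worked example sentences, pipeline shortcuts, and
# independent oracles used across test files.

fixture_entities <- function() radspatial_entities()
fixture_triggers <- function() radspatial_triggers()

# the ten worked sentences: six frame-element exemplars plus four
# heuristic-illustration sentences
worked_sentences <- function() {
  c(p1 = "There is hazy opacity of the lung consistent with hyaline membrane disease.",
    p2 = "A right PIC catheter terminates in the mid SVC.",
    p3 = "The UV line tip is high in the right atrium.",
    p4 = "ETT tube is 1 cm above the carina.",
    p5 = "A subtle area of increased signal adjacent to the left lateral ventricle at the level of corona radiata could be due to a small lacune.",
    p6 = "During the movement of the right foot, there is a small area of cortical BOLD activation adjacent to the area of edema.",
    p7 = "The lungs demonstrate hazy bilateral opacity of hyaline membrane disease.",
    p8 = "There are scattered T2 high signal intensity foci in the periventricular white matter and centrum semi-ovale consistent with microvascular angiopathy.",
    p9 = "A patchy area of consolidation is seen within the right lower lobe concerning for pneumonia.",
    p10 = "There is stable opacity in the right lower lobe as well as a retrocardiac opacity, these are likely related to atelactases versus pneumonia.")
}

worked_sentence_objs <- function() {
  ws <- worked_sentences()
  lapply(seq_along(ws), function(i)
    tokenize_sentence(ws[[i]], doc_id = names(ws)[i], sent_id = 0L))
}

# run candidate generation + LFs + label model over the worked sentences
run_worked_pipeline <- function() {
  weak_label_corpus(worked_sentence_objs(), fixture_entities(),
                    fixture_triggers())
}

# the label-model argmax assigned to (doc, trigger surface, entity surface)
assigned_role <- function(run, doc, trigger, entity) {
  m <- run$votes$pairs
  i <- which(m$doc_id == doc & m$trigger_surface == trigger &
               m$entity_surface == entity)
  if (length(i) != 1) return(NA_character_)
  if (run$labels$abstained[i]) return(NA_character_)
  run$labels$label[i]
}

# independent brute-force FE scorer: exhaustive exact matching of
# (label, span) pairs per instance key, with explicit FP/FN trigger
# accounting; used as the oracle for score_fes
brute_force_fe_counts <- function(gold_instances, pred_instances, mode) {
  ikey <- function(x) paste(x$doc_id, x$sent_id, x$trigger$start,
                            x$trigger$end)
  gk <- vapply(gold_instances, ikey, character(1))
  pk <- vapply(pred_instances, ikey, character(1))
  tp <- fp <- fn <- 0
  for (k in union(gk, pk)) {
    gi <- gold_instances[gk == k]
    pi <- pred_instances[pk == k]
    gspans <- if (length(gi)) gi[[1]]$fe_spans else NULL
    pspans <- if (length(pi)) pi[[1]]$fe_spans else NULL
    if (length(gi) == 0 || length(pi) == 0) {
      if (mode == "predicted_triggers") {
        if (length(pi)) fp <- fp + nrow(pspans)
        if (length(gi)) fn <- fn + nrow(gspans)
      }
      next
    }
    used <- logical(if (is.null(pspans)) 0 else nrow(pspans))
    for (i in seq_len(if (is.null(gspans)) 0 else nrow(gspans))) {
      hit <- FALSE
      for (j in seq_along(used)) {
        if (!used[j] && gspans$label[i] == pspans$label[j] &&
            gspans$start[i] == pspans$start[j] &&
            gspans$end[i] == pspans$end[j]) {
          used[j] <- TRUE; hit <- TRUE; break
        }
      }
      if (hit) tp <- tp + 1 else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  list(tp = tp, fp = fp, fn = fn)
}

make_bio <- function(tokens, tags, doc_id = "d", sent_id = 0L,
                     trigger_start = 0L, trigger_end = 1L) {
  n <- nchar(tokens)
  end <- cumsum(n + 1L) - 1L
  start <- end - n
  structure(list(tokens = tokens, tags = tags, token_start = start,
                 token_end = end,
                 meta = list(doc_id = doc_id, sent_id = sent_id,
                             trigger_start = trigger_start,
                             trigger_end = trigger_end)),
            class = "rs_bio")
}
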
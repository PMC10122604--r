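#' Frame-element labels and labeling functions
#'
#' A labeling function (LF) is a deterministic heuristic that, given a
#' {trigger, entity} candidate pair in its sentence context, votes exactly
#' one frame-element label or abstains. Each LF declares a single target
#' label and may never emit any other (label purity). The default registry
#' holds 19 LFs spanning all nine frame elements: the two Ground and two
#' Diagnosis heuristics follow the published feature tables, and the
#' remaining heuristics are repo-defined stand-ins documented next to each
#' function.
#'
#' @name radspatial-lfs
NULL

#' The nine frame-element labels
#'
#' Declared enum order (used for deterministic tie-breaking everywhere):
#' FIGURE, GROUND, HEDGE, DIAGNOSIS, POSITION_STATUS, RELATIVE_POSITION,
#' DISTANCE, REASON, ASSOCIATED_PROCESS.
#'
#' @return character vector of length 9.
#' @export
fe_labels <- function() {
  c("FIGURE", "GROUND", "HEDGE", "DIAGNOSIS", "POSITION_STATUS",
    "RELATIVE_POSITION", "DISTANCE", "REASON", "ASSOCIATED_PROCESS")
}

#' Labeling-function configuration
#'
#' Window lengths and cue lists shared by the registry. `window_len` counts
#' tokens (an entity is "within the window" of a span when at most
#' `window_len - 1` tokens separate them); windows never cross sentence
#' boundaries. Cue lists match as lowercase substrings of the joined window
#' text, so the stem "indicat" hits "indicating" and "indicative".
#'
#' @param copula_triggers trigger surfaces treated as copular/report verbs.
#' @param hedge_left_window,hedge_right_window diagnosis cue lists.
#' @param window_len token window length (>= 1).
#' @param ground_gap_max maximum token gap for the right-side Ground rule.
#' @param reason_cues,process_cues cue lists for Reason / AssociatedProcess.
#' @param position_verbs surfaces of the position-status verb family.
#' @return a list of class `rs_lf_config`.
#' @export
lf_config <- function(copula_triggers = c("with", "without", "show", "shows",
                                          "demonstrate", "demonstrates",
                                          "is", "are", "reveal", "reveals"),
                      hedge_left_window = c("represent", "suggest", "indicat",
                                            "consistent with"),
                      hedge_right_window = c("ruled out", "excluded", "vs",
                                             "versus"),
                      window_len = 4L,
                      ground_gap_max = 2L,
                      reason_cues = c("due to", "secondary to", "from"),
                      process_cues = c("during", "while"),
                      position_verbs = c("terminates", "terminating", "tip",
                                         "positioned", "advanced",
                                         "located")) {
  stopifnot(window_len >= 1)
  structure(list(copula_triggers = tolower(copula_triggers),
                 hedge_left_window = tolower(hedge_left_window),
                 hedge_right_window = tolower(hedge_right_window),
                 window_len = as.integer(window_len),
                 ground_gap_max = as.integer(ground_gap_max),
                 reason_cues = tolower(reason_cues),
                 process_cues = tolower(process_cues),
                 position_verbs = tolower(position_verbs)),
            class = "rs_lf_config")
}

#' Define a labeling function
#'
#' @param name unique LF name.
#' @param target the only frame-element label the LF may emit.
#' @param fn function(pair, ctx, cfg) returning `target` or `NA_character_`;
#'   must be pure and deterministic.
#' @return an object of class `rs_lf`.
#' @export
labeling_function <- function(name, target, fn) {
  stopifnot(is.character(name), target %in% fe_labels(), is.function(fn))
  structure(list(name = name, target = target, fn = fn), class = "rs_lf")
}

## ---- context helpers ------------------------------------------------------

has_cat <- function(categories, cat) {
  cat %in% strsplit(categories, "|", fixed = TRUE)[[1]]
}

# LF evaluation context for one sentence: lowercased tokens, all mentions,
# and precomputed hedge spans (entity mentions with hedge/certainty category)
lf_context <- function(cands) {
  sent <- cands$sentence
  toks <- tolower(sent$tokens$surface)
  ents <- cands$entities
  hedge_rows <- which(vapply(ents$categories, function(cs)
    has_cat(cs, "hedge") || has_cat(cs, "certainty_descriptor"), logical(1)))
  list(sent = sent, toks = toks, ntok = length(toks),
       entities = ents, triggers = cands$triggers,
       hedges = ents[hedge_rows, , drop = FALSE])
}

join_window <- function(ctx, from, to) {
  from <- max(1L, from); to <- min(ctx$ntok, to)
  if (from > to) return("")
  paste(ctx$toks[from:to], collapse = " ")
}

contains_cue <- function(text, cues) {
  any(vapply(cues, function(cue) grepl(cue, text, fixed = TRUE), logical(1)))
}

# token index range strictly between two spans
between_range <- function(a, b) {
  lo <- min(a["last"], b["last"]) + 1L
  hi <- max(a["first"], b["first"]) - 1L
  c(lo, hi)
}

span_of <- function(row) c(first = row$first_tok, last = row$last_tok)

# is there another trigger mention strictly between the pair's trigger and
# entity spans?
trigger_between <- function(p, ctx) {
  rng <- between_range(span_of(p$t), span_of(p$e))
  if (rng[1] > rng[2]) return(FALSE)
  tr <- ctx$triggers
  any(tr$first_tok >= rng[1] & tr$last_tok <= rng[2] &
        !(tr$start == p$t$start & tr$end == p$t$end))
}

hedge_between <- function(p, ctx, prepositional = FALSE) {
  rng <- between_range(span_of(p$t), span_of(p$e))
  if (rng[1] > rng[2] || nrow(ctx$hedges) == 0) return(FALSE)
  h <- ctx$hedges[ctx$hedges$first_tok >= rng[1] &
                    ctx$hedges$last_tok <= rng[2], , drop = FALSE]
  if (nrow(h) == 0) return(FALSE)
  if (!prepositional) return(TRUE)
  any(vapply(tolower(h$surface), function(s) {
    any(c("of", "for", "with", "to") %in% strsplit(s, " ", fixed = TRUE)[[1]])
  }, logical(1)))
}

# a hedge span ending within k tokens left of the entity
hedge_left_of <- function(p, ctx, k) {
  if (nrow(ctx$hedges) == 0) return(FALSE)
  any(ctx$hedges$last_tok < p$e$first_tok &
        ctx$hedges$last_tok >= p$e$first_tok - k)
}

sentence_final <- function(p, ctx) {
  p$e$last_tok == ctx$ntok - 1L && ctx$toks[ctx$ntok] == "."
}

is_copula <- function(p, cfg) tolower(p$t$surface) %in% cfg$copula_triggers

within_window <- function(p, cfg) p$token_gap < cfg$window_len

## ---- the default registry -------------------------------------------------

# Ground rule 1 (published heuristic): copular trigger with the entity
# directly left-adjacent, or any other trigger with a right-side anatomy
# entity at most ground_gap_max tokens away.
lf_ground_adjacency_fn <- function(p, ctx, cfg) {
  if (is_copula(p, cfg)) {
    if (p$side == "left" && p$token_gap == 0L) return("GROUND")
  } else {
    if (p$side == "right" && p$token_gap <= cfg$ground_gap_max &&
        has_cat(p$e$categories, "anatomy")) return("GROUND")
  }
  NA_character_
}

# Ground rule 2 (published heuristic): right-side anatomy, adjacent or with
# no other trigger in between.
lf_ground_closest_fn <- function(p, ctx, cfg) {
  if (p$side == "right" && has_cat(p$e$categories, "anatomy") &&
      (p$token_gap == 0L || !trigger_between(p, ctx)))
    return("GROUND")
  NA_character_
}

# Ground rule 3 (repo-defined): the "location: findings" reporting style —
# anatomy entity immediately left of a ":" token with the trigger anywhere
# to the right of the colon.
lf_ground_colon_fn <- function(p, ctx, cfg) {
  i <- p$e$last_tok + 1L
  if (has_cat(p$e$categories, "anatomy") && i <= ctx$ntok &&
      ctx$toks[i] == ":" && p$t$first_tok > i)
    return("GROUND")
  NA_character_
}

# Diagnosis rule 1 (published heuristic): sentence-final finding introduced
# by a hedge — either a preposition-containing hedge between trigger and
# entity, or a hedge within the window left of the entity with no additional
# trigger between trigger and entity.
lf_diagnosis_sentence_final_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "finding") || !sentence_final(p, ctx))
    return(NA_character_)
  if (hedge_between(p, ctx, prepositional = TRUE)) return("DIAGNOSIS")
  if (hedge_left_of(p, ctx, cfg$window_len) && !trigger_between(p, ctx))
    return("DIAGNOSIS")
  NA_character_
}

# Diagnosis rule 2 (published heuristic): cue substrings in the token window
# around a finding entity ("consistent with" left / "versus" right).
lf_diagnosis_hedge_window_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "finding")) return(NA_character_)
  left <- join_window(ctx, p$e$first_tok - cfg$window_len, p$e$first_tok - 1L)
  right <- join_window(ctx, p$e$last_tok + 1L, p$e$last_tok + cfg$window_len)
  if (contains_cue(left, cfg$hedge_left_window) ||
      contains_cue(right, cfg$hedge_right_window)) return("DIAGNOSIS")
  NA_character_
}

# Figure rule 1 (repo-defined): finding/device entity left of the trigger
# within the window with no intervening trigger.
lf_figure_window_fn <- function(p, ctx, cfg) {
  if (p$side == "left" && within_window(p, cfg) &&
      (has_cat(p$e$categories, "finding") ||
         has_cat(p$e$categories, "device")) &&
      !trigger_between(p, ctx)) return("FIGURE")
  NA_character_
}

# Figure rule 2 (repo-defined): finding/device entity immediately right of a
# copular trigger ("There are <finding> ...", "<anatomy>: There are
# <finding>").
lf_figure_copula_fn <- function(p, ctx, cfg) {
  if (p$side == "right" && p$token_gap == 0L && is_copula(p, cfg) &&
      (has_cat(p$e$categories, "finding") ||
         has_cat(p$e$categories, "device"))) return("FIGURE")
  NA_character_
}

# Figure rule 3 (repo-defined, chained-frame): anatomy can itself be the
# Figure ("The tonsils are below the foramen magnum"): anatomy entity left of
# a NON-copular trigger within the window with a copular token in between.
lf_figure_chain_fn <- function(p, ctx, cfg) {
  if (p$side != "left" || !within_window(p, cfg) || is_copula(p, cfg) ||
      !has_cat(p$e$categories, "anatomy")) return(NA_character_)
  rng <- between_range(span_of(p$t), span_of(p$e))
  if (rng[1] <= rng[2] &&
      any(ctx$toks[rng[1]:rng[2]] %in% cfg$copula_triggers)) return("FIGURE")
  NA_character_
}

# Hedge rule 1 (repo-defined): hedge/certainty entity near the trigger or
# near a finding mention.
lf_hedge_window_fn <- function(p, ctx, cfg) {
  if (!(has_cat(p$e$categories, "hedge") ||
          has_cat(p$e$categories, "certainty_descriptor")))
    return(NA_character_)
  if (within_window(p, cfg)) return("HEDGE")
  ents <- ctx$entities
  for (i in seq_len(nrow(ents))) {
    if (!has_cat(ents$categories[i], "finding")) next
    gap <- if (ents$first_tok[i] > p$e$last_tok)
      ents$first_tok[i] - p$e$last_tok - 1L
    else p$e$first_tok - ents$last_tok[i] - 1L
    if (gap >= 0 && gap < cfg$window_len) return("HEDGE")
  }
  NA_character_
}

# Hedge rule 2 (repo-defined; added to honour the published LF count of 19):
# hedge/certainty entity immediately preceding a finding mention.
lf_hedge_prefinding_fn <- function(p, ctx, cfg) {
  if (!(has_cat(p$e$categories, "hedge") ||
          has_cat(p$e$categories, "certainty_descriptor")))
    return(NA_character_)
  ents <- ctx$entities
  hit <- any(ents$first_tok == p$e$last_tok + 1L &
               vapply(ents$categories, has_cat, logical(1), "finding"))
  if (hit) return("HEDGE")
  NA_character_
}

# Distance rule (repo-defined): regex-matched distance expression left of the
# trigger within the window ("1 cm above the carina").
lf_distance_left_fn <- function(p, ctx, cfg) {
  if (identical(p$e$matcher, "distance_regex") && p$side == "left" &&
      within_window(p, cfg)) return("DISTANCE")
  NA_character_
}

# RelativePosition rule 1 (repo-defined): relative-position/location-
# descriptor entity within the window of the trigger.
lf_relpos_window_fn <- function(p, ctx, cfg) {
  if ((has_cat(p$e$categories, "relative_position") ||
         has_cat(p$e$categories, "location_descriptor")) &&
      within_window(p, cfg)) return("RELATIVE_POSITION")
  NA_character_
}

# RelativePosition rule 2 (repo-defined): a location-descriptor span split
# off a longer anatomy match, directly adjacent to its anatomy span.
lf_relpos_descriptor_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "location_descriptor") ||
      !identical(p$e$matcher, "dictionary")) return(NA_character_)
  ents <- ctx$entities
  hit <- any(ents$first_tok == p$e$last_tok + 1L &
               vapply(ents$categories, has_cat, logical(1), "anatomy"))
  if (hit) return("RELATIVE_POSITION")
  NA_character_
}

# PositionStatus rule 1 (repo-defined): position-status entity left of the
# trigger within the window, with a device mentioned in the sentence.
lf_posstatus_device_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "position_status") || p$side != "left" ||
      !within_window(p, cfg)) return(NA_character_)
  if (any(vapply(ctx$entities$categories, has_cat, logical(1), "device")))
    return("POSITION_STATUS")
  NA_character_
}

# PositionStatus rule 2 (repo-defined): the position-verb family
# (terminates, tip, positioned, advanced, ...) near the trigger.
lf_posstatus_verb_fn <- function(p, ctx, cfg) {
  if (tolower(p$e$surface) %in% cfg$position_verbs && within_window(p, cfg))
    return("POSITION_STATUS")
  NA_character_
}

# Reason rule 1 (repo-defined): finding entity preceded within the window by
# a reason cue ("due to a small lacune").
lf_reason_cue_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "finding")) return(NA_character_)
  left <- join_window(ctx, p$e$first_tok - cfg$window_len, p$e$first_tok - 1L)
  if (contains_cue(left, cfg$reason_cues)) return("REASON")
  NA_character_
}

# Reason rule 2 (repo-defined): sentence-final finding after a reason cue
# with no hedge in the window.
lf_reason_final_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "finding") || !sentence_final(p, ctx))
    return(NA_character_)
  left <- join_window(ctx, p$e$first_tok - cfg$window_len, p$e$first_tok - 1L)
  if (contains_cue(left, cfg$reason_cues) &&
      !hedge_left_of(p, ctx, cfg$window_len)) return("REASON")
  NA_character_
}

# AssociatedProcess rule 1 (repo-defined): process entity inside a clause
# opened by a process cue (no clause boundary between cue and entity).
lf_process_clause_fn <- function(p, ctx, cfg) {
  if (!has_cat(p$e$categories, "process")) return(NA_character_)
  cue_pos <- which(ctx$toks %in% cfg$process_cues)
  cue_pos <- cue_pos[cue_pos < p$e$first_tok]
  for (cp in rev(cue_pos)) {
    segment <- if (cp + 1L > p$e$first_tok - 1L) character()
    else ctx$toks[(cp + 1L):(p$e$first_tok - 1L)]
    if (!any(segment %in% c(",", ".", ";", ":"))) return("ASSOCIATED_PROCESS")
  }
  NA_character_
}

# AssociatedProcess rule 2 (repo-defined): entity inside a "during"-prefixed
# phrase (the token "during" at most 2 tokens to its left).
lf_process_during_fn <- function(p, ctx, cfg) {
  from <- max(1L, p$e$first_tok - 2L)
  if (p$e$first_tok > 1L &&
      any(ctx$toks[from:(p$e$first_tok - 1L)] == "during"))
    return("ASSOCIATED_PROCESS")
  NA_character_
}

#' The default registry of 19 labeling functions
#'
#' @return list of `rs_lf` objects with unique names; exactly one target
#'   label each, jointly covering all nine frame elements.
#' @export
default_lf_registry <- function() {
  list(
    labeling_function("lf_ground_adjacency", "GROUND", lf_ground_adjacency_fn),
    labeling_function("lf_ground_closest", "GROUND", lf_ground_closest_fn),
    labeling_function("lf_ground_colon_style", "GROUND", lf_ground_colon_fn),
    labeling_function("lf_diagnosis_sentence_final", "DIAGNOSIS",
                      lf_diagnosis_sentence_final_fn),
    labeling_function("lf_diagnosis_hedge_window", "DIAGNOSIS",
                      lf_diagnosis_hedge_window_fn),
    labeling_function("lf_figure_window", "FIGURE", lf_figure_window_fn),
    labeling_function("lf_figure_copula", "FIGURE", lf_figure_copula_fn),
    labeling_function("lf_figure_chain", "FIGURE", lf_figure_chain_fn),
    labeling_function("lf_hedge_window", "HEDGE", lf_hedge_window_fn),
    labeling_function("lf_hedge_prefinding", "HEDGE", lf_hedge_prefinding_fn),
    labeling_function("lf_distance_left", "DISTANCE", lf_distance_left_fn),
    labeling_function("lf_relpos_window", "RELATIVE_POSITION",
                      lf_relpos_window_fn),
    labeling_function("lf_relpos_descriptor", "RELATIVE_POSITION",
                      lf_relpos_descriptor_fn),
    labeling_function("lf_posstatus_device", "POSITION_STATUS",
                      lf_posstatus_device_fn),
    labeling_function("lf_posstatus_verb", "POSITION_STATUS",
                      lf_posstatus_verb_fn),
    labeling_function("lf_reason_cue", "REASON", lf_reason_cue_fn),
    labeling_function("lf_reason_final", "REASON", lf_reason_final_fn),
    labeling_function("lf_process_clause", "ASSOCIATED_PROCESS",
                      lf_process_clause_fn),
    labeling_function("lf_process_during", "ASSOCIATED_PROCESS",
                      lf_process_during_fn)
  )
}

## ---- applying the registry ------------------------------------------------

pair_view <- function(cands, row) {
  list(t = as.list(cands$triggers[cands$pairs$trigger_idx[row], ]),
       e = as.list(cands$entities[cands$pairs$entity_idx[row], ]),
       token_gap = cands$pairs$token_gap[row],
       side = cands$pairs$side[row])
}

#' Apply a labeling-function registry to candidates
#'
#' Produces the vote matrix: one row per candidate pair, one column per LF,
#' each cell a frame-element label or `NA` (abstain). Label purity is
#' enforced: an LF emitting a label other than its declared target is an
#' error.
#'
#' @param cands an `rs_candidates` or a list of them (a corpus).
#' @param registry list of `rs_lf` (default [default_lf_registry()]).
#' @param cfg an `rs_lf_config`.
#' @return an `rs_votes` object: list with `votes` (character matrix, `NA`
#'   = abstain), `pairs` (metadata data.frame keyed by sentence and spans),
#'   `lf_names`, `targets`.
#' @export
apply_lfs <- function(cands, registry = default_lf_registry(),
                      cfg = lf_config()) {
  if (inherits(cands, "rs_candidates")) cands <- list(cands)
  lf_names <- vapply(registry, `[[`, character(1), "name")
  if (anyDuplicated(lf_names))
    stop("duplicate labeling-function names in registry")
  targets <- vapply(registry, `[[`, character(1), "target")
  rows <- list(); meta <- list()
  for (ci in seq_along(cands)) {
    cc <- cands[[ci]]
    if (nrow(cc$pairs) == 0) next
    ctx <- lf_context(cc)
    for (ri in seq_len(nrow(cc$pairs))) {
      p <- pair_view(cc, ri)
      votes <- vapply(seq_along(registry), function(j) {
        v <- registry[[j]]$fn(p, ctx, cfg)
        if (!is.na(v) && !identical(v, targets[j]))
          stop("labeling function ", lf_names[j],
               " emitted a label other than its target")
        v
      }, character(1))
      rows[[length(rows) + 1L]] <- votes
      meta[[length(meta) + 1L]] <- data.frame(
        cand_idx = ci, pair_row = ri,
        doc_id = cc$sentence$doc_id, sent_id = cc$sentence$sent_id,
        trigger_start = p$t$start, trigger_end = p$t$end,
        trigger_surface = p$t$surface,
        entity_start = p$e$start, entity_end = p$e$end,
        entity_surface = p$e$surface, entity_categories = p$e$categories,
        matcher = p$e$matcher, token_gap = p$token_gap, side = p$side,
        stringsAsFactors = FALSE)
    }
  }
  votes <- if (length(rows) == 0)
    matrix(NA_character_, nrow = 0, ncol = length(registry))
  else do.call(rbind, rows)
  colnames(votes) <- lf_names
  pairs <- if (length(meta) == 0) NULL else do.call(rbind, meta)
  structure(list(votes = votes, pairs = pairs, lf_names = lf_names,
                 targets = stats::setNames(targets, lf_names)),
            class = "rs_votes")
}

#' @export
print.rs_votes <- function(x, ...) {
  cat("<rs_votes>", nrow(x$votes), "pairs x", ncol(x$votes), "LFs;",
      sum(!is.na(x$votes)), "non-abstain votes\n")
  invisible(x)
}

#' Write / read a vote matrix as TSV
#'
#' Header = LF names; first column = pair id; cells are label names or `-`
#' for abstain.
#'
#' @param votes an `rs_votes` (or bare character matrix).
#' @param path output file.
#' @return `write_votes_tsv` returns `path` invisibly; `read_votes_tsv`
#'   returns a character matrix with `NA` for abstain.
#' @export
write_votes_tsv <- function(votes, path) {
  v <- if (inherits(votes, "rs_votes")) votes$votes else votes
  out <- v
  out[is.na(out)] <- "-"
  df <- data.frame(pair_id = seq_len(nrow(v)) - 1L, out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_votes_tsv
#' @export
read_votes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "-"] <- NA_character_
  rownames(m) <- NULL
  m
}
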
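#' Trigger-level instances, filtering, and BIO sequences
#'
#' After label aggregation, candidate pairs are regrouped per spatial
#' trigger: one `rs_instance` per trigger holds all entity spans that
#' received a (non-abstained) frame-element label, with their probabilities.
#' Two filters select the final weakly labeled training set: the
#' Figure+Ground constraint (a spatial frame needs both fundamental
#' elements; evaluation mode relaxes this to Ground-only to preserve trigger
#' recall) and a frequent-phrase check that suppresses false-positive
#' triggers such as "history of". Surviving instances are rendered as BIO
#' tag sequences with every trigger token replaced by the mask symbol
#' `$sptrg$`.
#'
#' @name radspatial-instances
NULL

SPTRG_MASK <- "$sptrg$"

#' Build trigger-level instances from labeled pairs
#'
#' Groups the non-abstained pairs of a vote set by trigger; each entity span
#' is recorded under its argmax label with its probability. Overlapping
#' same-label spans keep the higher probability, then the longer span; spans
#' overlapping the trigger are dropped.
#'
#' @param cands the `rs_candidates` list the votes were computed from.
#' @param votes the `rs_votes` produced by [apply_lfs()] on `cands`.
#' @param labels the probabilistic labels for `votes` (from
#'   [predict.felabel_model()] or [fit_majority()]).
#' @return list of `rs_instance` objects: each a list with `doc_id`,
#'   `sent_id`, `sentence`, `trigger` (start/end/first_tok/last_tok/surface)
#'   and `fe_spans` data.frame (label, start, end, first_tok, last_tok,
#'   surface, prob), `provenance = "weak"`.
#' @export
build_instances <- function(cands, votes, labels) {
  if (inherits(cands, "rs_candidates")) cands <- list(cands)
  meta <- votes$pairs
  if (is.null(meta) || nrow(meta) == 0) return(list())
  stopifnot(nrow(meta) == nrow(labels))
  keep <- !labels$abstained
  meta <- meta[keep, , drop = FALSE]
  lab <- labels[keep, , drop = FALSE]
  if (nrow(meta) == 0) return(list())
  key <- paste(meta$cand_idx, meta$trigger_start, meta$trigger_end)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    cc <- cands[[meta$cand_idx[idx[1]]]]
    ti <- which(cc$triggers$start == meta$trigger_start[idx[1]] &
                  cc$triggers$end == meta$trigger_end[idx[1]])[1]
    trig <- as.list(cc$triggers[ti, ])
    spans <- data.frame(label = lab$label[idx],
                        start = meta$entity_start[idx],
                        end = meta$entity_end[idx],
                        surface = meta$entity_surface[idx],
                        prob = lab$prob[idx], stringsAsFactors = FALSE)
    # map to token indices from the entity table
    ei <- match(paste(spans$start, spans$end),
                paste(cc$entities$start, cc$entities$end))
    spans$first_tok <- cc$entities$first_tok[ei]
    spans$last_tok <- cc$entities$last_tok[ei]
    # drop spans overlapping the trigger
    ok <- spans$end <= trig$start | spans$start >= trig$end
    spans <- spans[ok, , drop = FALSE]
    # within one label: keep higher probability, then longer span
    resolved <- list()
    for (lb in unique(spans$label)) {
      s <- spans[spans$label == lb, , drop = FALSE]
      s <- s[order(-s$prob, -(s$end - s$start), s$start), , drop = FALSE]
      kept <- s[0, ]
      for (i in seq_len(nrow(s))) {
        if (nrow(kept) == 0 ||
            all(s$end[i] <= kept$start | s$start[i] >= kept$end))
          kept <- rbind(kept, s[i, ])
      }
      resolved[[lb]] <- kept
    }
    spans <- do.call(rbind, resolved)
    spans <- spans[!duplicated(paste(spans$label, spans$start, spans$end)), ,
                   drop = FALSE]
    spans <- spans[order(spans$start), , drop = FALSE]
    rownames(spans) <- NULL
    out[[length(out) + 1L]] <- structure(
      list(doc_id = cc$sentence$doc_id, sent_id = cc$sentence$sent_id,
           sentence = cc$sentence, trigger = trig, fe_spans = spans,
           provenance = "weak"),
      class = "rs_instance")
  }
  out
}

#' Construct a gold instance
#'
#' Helper for assembling `rs_instance` objects from gold annotations (or the
#' synthetic generator): same shape as [build_instances()] output with
#' `provenance = "gold"` and probability 1.
#'
#' @param sentence an `rs_sentence`.
#' @param trigger_start,trigger_end 0-based half-open char span of the
#'   trigger.
#' @param fe_spans data.frame with columns label, start, end.
#' @return an `rs_instance`.
#' @export
gold_instance <- function(sentence, trigger_start, trigger_end, fe_spans) {
  toks <- sentence$tokens
  ft <- match(trigger_start, toks$start)
  lt <- match(trigger_end, toks$end)
  if (is.na(ft) || is.na(lt))
    stop("trigger span not token-aligned in ", sentence$doc_id)
  trig <- list(start = trigger_start, end = trigger_end,
               first_tok = ft, last_tok = lt,
               surface = slice0(sentence$text, trigger_start, trigger_end))
  if (is.null(fe_spans) || nrow(fe_spans) == 0) {
    fe_spans <- data.frame(label = character(), start = integer(),
                           end = integer(), surface = character(),
                           prob = numeric(), first_tok = integer(),
                           last_tok = integer(), stringsAsFactors = FALSE)
  } else {
    fe_spans$surface <- vapply(seq_len(nrow(fe_spans)), function(i)
      slice0(sentence$text, fe_spans$start[i], fe_spans$end[i]), character(1))
    fe_spans$prob <- 1
    fe_spans$first_tok <- match(fe_spans$start, toks$start)
    fe_spans$last_tok <- match(fe_spans$end, toks$end)
    if (anyNA(fe_spans$first_tok) || anyNA(fe_spans$last_tok))
      stop("gold FE span not token-aligned in ", sentence$doc_id)
  }
  structure(list(doc_id = sentence$doc_id, sent_id = sentence$sent_id,
                 sentence = sentence, trigger = trig, fe_spans = fe_spans,
                 provenance = "gold"),
            class = "rs_instance")
}

#' @export
print.rs_instance <- function(x, ...) {
  cat("<rs_instance> ", x$doc_id, "/", x$sent_id, " trigger '",
      x$trigger$surface, "' [", x$provenance, "]\n", sep = "")
  if (nrow(x$fe_spans) > 0)
    for (i in seq_len(nrow(x$fe_spans)))
      cat(sprintf("  %-18s %s (p=%.2f)\n", x$fe_spans$label[i],
                  x$fe_spans$surface[i], x$fe_spans$prob[i]))
  invisible(x)
}

#' Filtering configuration
#'
#' @param require_figure_ground keep only instances with at least one Figure
#'   and one Ground span (the training-set constraint).
#' @param ground_only_mode evaluation mode: keep instances with at least one
#'   Ground span, preserving trigger recall for downstream FE prediction.
#' @param frequent_phrases named list: trigger surface -> list(left =
#'   phrases, right = phrases). An instance is rejected when one of its
#'   trigger's left phrases ends at the token before the trigger or one of
#'   its right phrases starts at the token after. The shipped defaults are
#'   repo-chosen examples of non-spatial usages of "of", "with", "in".
#' @return list of class `rs_filter_config`.
#' @export
filter_config <- function(require_figure_ground = TRUE,
                          ground_only_mode = FALSE,
                          frequent_phrases = list(
                            of = list(left = c("history", "loss", "evidence",
                                               "status", "risk"),
                                      right = character()),
                            with = list(left = c("associated", "correlate"),
                                        right = character()),
                            `in` = list(left = c("resulting"),
                                        right = c("comparison")))) {
  frequent_phrases <- lapply(frequent_phrases, function(x)
    list(left = tolower(x$left), right = tolower(x$right)))
  structure(list(require_figure_ground = isTRUE(require_figure_ground),
                 ground_only_mode = isTRUE(ground_only_mode),
                 frequent_phrases = frequent_phrases),
            class = "rs_filter_config")
}

#' Figure+Ground filter
#'
#' Default mode: `TRUE` iff the instance holds at least one FIGURE and one
#' GROUND span. In `ground_only_mode` (evaluation) a single GROUND suffices.
#'
#' @param instance an `rs_instance`.
#' @param cfg an `rs_filter_config`.
#' @return logical.
#' @export
filter_figure_ground <- function(instance, cfg = filter_config()) {
  labs <- instance$fe_spans$label
  if (cfg$ground_only_mode) return("GROUND" %in% labs)
  ("FIGURE" %in% labs) && ("GROUND" %in% labs)
}

#' Frequent-phrase filter
#'
#' `TRUE` (keep) iff the trigger surface has no configured phrase list, or
#' none of its left phrases ends immediately before the trigger and none of
#' its right phrases starts immediately after (case-insensitive, token-wise).
#'
#' @param instance an `rs_instance`.
#' @param cfg an `rs_filter_config`.
#' @return logical.
#' @export
filter_frequent_phrases <- function(instance, cfg = filter_config()) {
  key <- tolower(instance$trigger$surface)
  fp <- cfg$frequent_phrases[[key]]
  if (is.null(fp)) return(TRUE)
  toks <- tolower(instance$sentence$tokens$surface)
  ft <- instance$trigger$first_tok; lt <- instance$trigger$last_tok
  for (phrase in fp$left) {
    pw <- strsplit(phrase, " ", fixed = TRUE)[[1]]
    from <- ft - length(pw)
    if (from >= 1 && identical(toks[from:(ft - 1L)], pw)) return(FALSE)
  }
  for (phrase in fp$right) {
    pw <- strsplit(phrase, " ", fixed = TRUE)[[1]]
    to <- lt + length(pw)
    if (to <= length(toks) && identical(toks[(lt + 1L):to], pw))
      return(FALSE)
  }
  TRUE
}

#' Apply both filters to an instance list
#'
#' @param instances list of `rs_instance`.
#' @param cfg an `rs_filter_config`.
#' @return the surviving sublist (filtering is monotone and idempotent).
#' @export
filter_instances <- function(instances, cfg = filter_config()) {
  keep <- vapply(instances, function(x)
    filter_figure_ground(x, cfg) && filter_frequent_phrases(x, cfg),
    logical(1))
  instances[keep]
}

#' Convert an instance to a BIO sequence
#'
#' Sentence tokens with every trigger token replaced by `$sptrg$` (one mask
#' token per original token, preserving alignment) and each FE span rendered
#' as `B-X` then `I-X`. Overlapping spans across labels resolve by higher
#' probability, then label enum order; masked positions stay `O`.
#'
#' @param instance an `rs_instance`.
#' @return an `rs_bio`: list with `tokens` (masked surfaces), `tags`,
#'   `token_start`, `token_end` (char offsets), and `meta` (doc_id, sent_id,
#'   trigger span).
#' @export
to_bio <- function(instance) {
  toks <- instance$sentence$tokens
  n <- nrow(toks)
  tags <- rep("O", n)
  surf <- toks$surface
  ft <- instance$trigger$first_tok; lt <- instance$trigger$last_tok
  surf[ft:lt] <- SPTRG_MASK
  spans <- instance$fe_spans
  if (nrow(spans) > 0) {
    if (anyNA(spans$first_tok) || anyNA(spans$last_tok))
      stop("FE span not token-aligned in instance ", instance$doc_id)
    ord <- order(-spans$prob, match(spans$label, fe_labels()))
    for (i in ord) {
      rng <- spans$first_tok[i]:spans$last_tok[i]
      if (any(tags[rng] != "O") || any(surf[rng] == SPTRG_MASK)) next
      tags[rng[1]] <- paste0("B-", spans$label[i])
      if (length(rng) > 1)
        tags[rng[-1]] <- paste0("I-", spans$label[i])
    }
  }
  structure(list(tokens = surf, tags = tags,
                 token_start = toks$start, token_end = toks$end,
                 meta = list(doc_id = instance$doc_id,
                             sent_id = instance$sent_id,
                             trigger_start = instance$trigger$start,
                             trigger_end = instance$trigger$end)),
            class = "rs_bio")
}

#' Decode a BIO sequence back to labeled spans
#'
#' Maximal `B-X (I-X)*` runs become spans; an `I-X` without a matching open
#' run is repaired by promotion to `B-X`.
#'
#' @param bio an `rs_bio` (or any list with `tokens`, `tags`, `token_start`,
#'   `token_end`).
#' @return data.frame (label, start, end, first_tok, last_tok).
#' @export
bio_spans <- function(bio) {
  tags <- bio$tags
  out <- data.frame(label = character(), start = integer(), end = integer(),
                    first_tok = integer(), last_tok = integer(),
                    stringsAsFactors = FALSE)
  open_label <- NULL; open_start <- NA_integer_
  close_run <- function(last) {
    if (!is.null(open_label))
      out <<- rbind(out, data.frame(
        label = open_label, start = bio$token_start[open_start],
        end = bio$token_end[last], first_tok = open_start, last_tok = last,
        stringsAsFactors = FALSE))
    open_label <<- NULL
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") { close_run(i - 1L); next }
    typ <- substr(tg, 1, 1)
    lab <- substring(tg, 3)
    if (typ == "B" || is.null(open_label) || lab != open_label) {
      close_run(i - 1L)
      open_label <- lab; open_start <- i
    }
  }
  close_run(length(tags))
  rownames(out) <- NULL
  out
}

#' Validate BIO tags
#'
#' @param tags character vector of `O`/`B-X`/`I-X` tags.
#' @return TRUE if no `I-X` lacks an immediately preceding `B-X`/`I-X` of the
#'   same label and every label is one of the nine frame elements.
#' @export
validate_bio <- function(tags) {
  valid <- c("O", paste0("B-", fe_labels()), paste0("I-", fe_labels()))
  if (!all(tags %in% valid)) return(FALSE)
  for (i in seq_along(tags)) {
    if (startsWith(tags[i], "I-")) {
      lab <- substring(tags[i], 3)
      if (i == 1 || !(tags[i - 1] %in% paste0(c("B-", "I-"), lab)))
        return(FALSE)
    }
  }
  TRUE
}

#' Write / read BIO sequences in CoNLL format
#'
#' One `token<TAB>tag` line per token, blank line between sequences, and an
#' instance metadata comment line `# doc sent trigger_start trigger_end`
#' before each sequence.
#'
#' @param bios list of `rs_bio`.
#' @param path output file.
#' @return `write_conll` returns `path` invisibly; `read_conll` a list of
#'   `rs_bio`-shaped lists (without char offsets, which CoNLL does not
#'   carry).
#' @export
write_conll <- function(bios, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (b in bios) {
    writeLines(paste("#", b$meta$doc_id, b$meta$sent_id,
                     b$meta$trigger_start, b$meta$trigger_end), con)
    writeLines(paste(b$tokens, b$tags, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list(); toks <- character(); tags <- character(); meta <- NULL
  flush_seq <- function() {
    if (length(toks) > 0)
      out[[length(out) + 1L]] <<- structure(
        list(tokens = toks, tags = tags, token_start = NULL,
             token_end = NULL, meta = meta), class = "rs_bio")
    toks <<- character(); tags <<- character(); meta <<- NULL
  }
  for (l in lines) {
    if (startsWith(l, "# ")) {
      p <- strsplit(sub("^# ", "", l), " ", fixed = TRUE)[[1]]
      meta <- list(doc_id = p[1], sent_id = as.integer(p[2]),
                   trigger_start = as.integer(p[3]),
                   trigger_end = as.integer(p[4]))
    } else if (!nzchar(l)) {
      flush_seq()
    } else {
      p <- strsplit(l, "\t", fixed = TRUE)[[1]]
      toks <- c(toks, p[1]); tags <- c(tags, p[2])
    }
  }
  flush_seq()
  out
}
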
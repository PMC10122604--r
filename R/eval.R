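#' Trigger-conditioned evaluation
#'
#' Strict (exact-boundary) scoring of spatial-trigger extraction and
#' frame-element span extraction. Because the pipeline predicts FEs per
#' trigger, end-to-end scoring must account for trigger errors: in
#' `predicted_triggers` mode every FE predicted under a false-positive
#' trigger counts as a false positive and every gold FE under a missed
#' trigger counts as a false negative; `gold_triggers` mode scores FEs only
#' within correctly identified triggers. Metrics are percentages; the
#' Overall row is micro-averaged (count-weighted) by default with a macro
#' option.
#'
#' @name radspatial-eval
NULL

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

span_key <- function(df, cols = c("doc_id", "sent_id", "start", "end")) {
  do.call(paste, c(df[cols], sep = "\r"))
}

#' Score spatial-trigger spans
#'
#' Exact char-span matching of predicted against gold trigger spans.
#'
#' @param gold,pred data.frames with columns doc_id, sent_id, start, end.
#' @return named numeric (precision, recall, f1) in percent.
#' @export
score_triggers <- function(gold, pred) {
  gk <- unique(span_key(gold)); pk <- unique(span_key(pred))
  tp <- length(intersect(gk, pk))
  prf(tp, length(pk) - tp, length(gk) - tp)
}

instance_key <- function(x) {
  paste(x$doc_id, x$sent_id, x$trigger$start, x$trigger$end, sep = "\r")
}

instance_triggers_df <- function(instances) {
  if (length(instances) == 0)
    return(data.frame(doc_id = character(), sent_id = integer(),
                      start = integer(), end = integer()))
  do.call(rbind, lapply(instances, function(x)
    data.frame(doc_id = x$doc_id, sent_id = x$sent_id,
               start = x$trigger$start, end = x$trigger$end,
               stringsAsFactors = FALSE)))
}

#' Score frame-element spans with trigger accounting
#'
#' Instances are keyed by (doc, sent, trigger span); FE spans match on exact
#' boundaries and label within matched triggers. In `predicted_triggers`
#' mode, FEs under unmatched predicted triggers add false positives and gold
#' FEs under missed triggers add false negatives; `gold_triggers` mode
#' ignores trigger errors.
#'
#' @param gold_instances,pred_instances lists of `rs_instance` (unique keys
#'   required).
#' @param mode `"predicted_triggers"` or `"gold_triggers"`.
#' @param macro use macro instead of micro averaging for the Overall row.
#' @return an `fe_eval_report`: list with `trigger` (P/R/F1 of the trigger
#'   spans), `per_fe` data.frame (label, precision, recall, f1, gold_count),
#'   `overall`, `mode`.
#' @export
score_fes <- function(gold_instances, pred_instances,
                      mode = c("predicted_triggers", "gold_triggers"),
                      macro = FALSE) {
  mode <- match.arg(mode)
  gkeys <- vapply(gold_instances, instance_key, character(1))
  pkeys <- vapply(pred_instances, instance_key, character(1))
  if (anyDuplicated(gkeys)) stop("duplicate gold instance keys")
  if (anyDuplicated(pkeys)) stop("duplicate predicted instance keys")
  labs <- fe_labels()
  tp <- fp <- fn <- stats::setNames(numeric(length(labs)), labs)
  gold_count <- stats::setNames(numeric(length(labs)), labs)
  for (g in gold_instances) {
    for (lb in g$fe_spans$label) gold_count[lb] <- gold_count[lb] + 1
  }
  both <- intersect(gkeys, pkeys)
  for (k in both) {
    g <- gold_instances[[match(k, gkeys)]]$fe_spans
    p <- pred_instances[[match(k, pkeys)]]$fe_spans
    gk <- paste(g$label, g$start, g$end)
    pk <- paste(p$label, p$start, p$end)
    for (lb in labs) {
      gl <- gk[g$label == lb]; pl <- pk[p$label == lb]
      m <- length(intersect(gl, pl))
      tp[lb] <- tp[lb] + m
      fp[lb] <- fp[lb] + length(pl) - m
      fn[lb] <- fn[lb] + length(gl) - m
    }
  }
  if (mode == "predicted_triggers") {
    for (k in setdiff(pkeys, gkeys)) {
      s <- pred_instances[[match(k, pkeys)]]$fe_spans
      for (lb in s$label) fp[lb] <- fp[lb] + 1
    }
    for (k in setdiff(gkeys, pkeys)) {
      s <- gold_instances[[match(k, gkeys)]]$fe_spans
      for (lb in s$label) fn[lb] <- fn[lb] + 1
    }
  }
  per_fe <- do.call(rbind, lapply(labs, function(lb) {
    m <- prf(tp[lb], fp[lb], fn[lb])
    data.frame(label = lb, precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], gold_count = gold_count[lb],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  overall <- if (macro) {
    scored <- per_fe[gold_count > 0 | tp + fp > 0, , drop = FALSE]
    c(precision = mean(scored$precision), recall = mean(scored$recall),
      f1 = mean(scored$f1))
  } else {
    prf(sum(tp), sum(fp), sum(fn))
  }
  trig <- score_triggers(instance_triggers_df(gold_instances),
                         instance_triggers_df(pred_instances))
  structure(list(trigger = trig, per_fe = per_fe, overall = overall,
                 mode = mode, macro = macro,
                 counts = list(tp = tp, fp = fp, fn = fn)),
            class = "fe_eval_report")
}

#' @export
print.fe_eval_report <- function(x, ...) {
  cat("Frame-element evaluation (", x$mode, ", ",
      if (x$macro) "macro" else "micro", " overall)\n", sep = "")
  cat(sprintf("Triggers: P %.2f  R %.2f  F1 %.2f\n",
              x$trigger["precision"], x$trigger["recall"], x$trigger["f1"]))
  cat(sprintf("%-20s %9s %9s %9s %7s\n", "Frame element", "Precision",
              "Recall", "F1", "Count"))
  for (i in seq_len(nrow(x$per_fe)))
    cat(sprintf("%-20s %9.2f %9.2f %9.2f %7d\n", x$per_fe$label[i],
                x$per_fe$precision[i], x$per_fe$recall[i], x$per_fe$f1[i],
                as.integer(x$per_fe$gold_count[i])))
  cat(sprintf("%-20s %9.2f %9.2f %9.2f %7d\n", "Overall",
              x$overall["precision"], x$overall["recall"], x$overall["f1"],
              as.integer(sum(x$per_fe$gold_count))))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Rows are frame elements with Overall last, mirroring the standard results
#' table layout.
#'
#' @param report an `fe_eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_tsv <- function(report, path) {
  df <- report$per_fe
  df <- rbind(df, data.frame(label = "Overall",
                             precision = report$overall["precision"],
                             recall = report$overall["recall"],
                             f1 = report$overall["f1"],
                             gold_count = sum(df$gold_count),
                             row.names = NULL, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
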
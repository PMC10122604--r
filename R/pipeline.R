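#' End-to-end weak-supervision pipeline
#'
#' Convenience drivers wiring the stages together: candidate generation ->
#' labeling functions -> generative label model -> trigger-level instances ->
#' filtering (training mode: Figure+Ground; evaluation mode: Ground-only to
#' preserve trigger recall) -> BIO sequences -> baseline tagger.
#'
#' @name radspatial-pipeline
NULL

#' Run the weak-labeling stages over a corpus
#'
#' @param sentences list of `rs_sentence`.
#' @param entity_lex entity `rs_lexicon`.
#' @param trigger_lex trigger `rs_lexicon`.
#' @param registry LF registry.
#' @param lf_cfg `rs_lf_config`.
#' @param lm_config `rs_lm_config`.
#' @param filter_cfg `rs_filter_config`.
#' @param aggregator `"em"` (generative label model) or `"majority"`.
#' @param label_model optional pre-fitted `felabel_model` to reuse (e.g. fit
#'   on training sentences, applied to held-out sentences).
#' @return list with `cands`, `votes`, `model`, `labels`, `instances` (all
#'   trigger-level instances) and `kept` (instances surviving the filters).
#' @export
weak_label_corpus <- function(sentences, entity_lex, trigger_lex,
                              registry = default_lf_registry(),
                              lf_cfg = lf_config(),
                              lm_config = label_model_config(),
                              filter_cfg = filter_config(),
                              aggregator = c("em", "majority"),
                              label_model = NULL) {
  aggregator <- match.arg(aggregator)
  cands <- lapply(sentences, tag_sentence, entity_lex = entity_lex,
                  trigger_lex = trigger_lex)
  votes <- apply_lfs(cands, registry, lf_cfg)
  model <- label_model
  if (nrow(votes$votes) == 0) {
    labels <- data.frame(label = character(), prob = numeric(),
                         abstained = logical())
  } else if (aggregator == "majority") {
    labels <- fit_majority(votes)
  } else {
    if (is.null(model)) model <- fit_label_model(votes, lm_config)
    labels <- predict(model, votes)
  }
  instances <- build_instances(cands, votes, labels)
  kept <- filter_instances(instances, filter_cfg)
  list(cands = cands, votes = votes, model = model, labels = labels,
       instances = instances, kept = kept)
}

#' Predict frame-element instances on new sentences
#'
#' The end-to-end inference protocol: the label-model stage proposes
#' triggers (instances passing the evaluation-mode filters), then the
#' trained tagger predicts the FE spans for each proposed trigger.
#'
#' @param tagger a trained `rs_tagger`.
#' @param sentences list of `rs_sentence`.
#' @param entity_lex,trigger_lex lexicons for candidate generation.
#' @param label_model fitted `felabel_model` used to propose triggers.
#' @param registry,lf_cfg LF registry and configuration.
#' @param filter_cfg filter configuration; defaults to evaluation mode
#'   (`ground_only_mode = TRUE`).
#' @return list of predicted `rs_instance` (FE spans from the tagger).
#' @export
predict_instances <- function(tagger, sentences, entity_lex, trigger_lex,
                              label_model,
                              registry = default_lf_registry(),
                              lf_cfg = lf_config(),
                              filter_cfg = filter_config(
                                ground_only_mode = TRUE)) {
  run <- weak_label_corpus(sentences, entity_lex, trigger_lex, registry,
                           lf_cfg, filter_cfg = filter_cfg,
                           label_model = label_model)
  lapply(run$kept, function(inst) {
    spans <- predict(tagger, inst$sentence,
                     c(inst$trigger$start, inst$trigger$end))
    spans$prob <- rep(1, nrow(spans))
    inst$fe_spans <- spans
    inst
  })
}
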
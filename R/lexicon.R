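#' Category-typed radiology lexicons
#'
#' A lexicon is the dictionary backbone of the pipeline: a set of lowercase
#' surface forms, each tagged with one of nine entity categories (finding,
#' anatomy, device, process, location_descriptor, certainty_descriptor, hedge,
#' position_status, relative_position) and a provenance tag recording whether
#' the entry was loaded from a base term list, added manually, or produced by
#' one of the expansion rules. Two lexicons drive candidate generation: a
#' radiological-entity dictionary and a spatial-trigger dictionary.
#'
#' @name radspatial-lexicon
NULL

LEX_CATEGORIES <- c("finding", "anatomy", "device", "process",
                    "location_descriptor", "certainty_descriptor", "hedge",
                    "position_status", "relative_position")

LEX_SOURCES <- c("base", "manual", "prepend_expansion",
                 "descriptor_expansion", "plural_expansion")

#' Normalize a surface form
#'
#' Trims, lowercases and collapses internal whitespace. Every surface stored
#' in a lexicon passes through this normalizer, as does every span of sentence
#' text before dictionary lookup, so matching is case-insensitive and
#' whitespace-insensitive.
#'
#' @param x character vector of raw surfaces.
#' @return normalized character vector.
#' @export
normalize_surface <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Construct a lexicon
#'
#' @param surface character vector of term surfaces (normalized internally).
#' @param category character vector (recycled) of entity categories; each must
#'   be one of the nine recognized categories.
#' @param source provenance tag, one of `base`, `manual`, `prepend_expansion`,
#'   `descriptor_expansion`, `plural_expansion` (recycled).
#' @param name identifier for the lexicon.
#' @return an object of class `rs_lexicon`: a list with an `entries`
#'   data.frame (surface, category, source) deduplicated on
#'   (surface, category), and a `name`.
#' @export
lexicon <- function(surface = character(), category = character(),
                    source = "base", name = "lexicon") {
  surface <- normalize_surface(as.character(surface))
  category <- as.character(category)
  source <- as.character(source)
  n <- length(surface)
  if (n > 0) {
    category <- rep_len(category, n)
    source <- rep_len(source, n)
  } else {
    category <- character()
    source <- character()
  }
  bad <- setdiff(unique(category), LEX_CATEGORIES)
  if (length(bad) > 0)
    stop("unknown lexicon category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(source), LEX_SOURCES)
  if (length(bad) > 0)
    stop("unknown lexicon source: ", paste(bad, collapse = ", "))
  keep <- nzchar(surface)
  entries <- data.frame(surface = surface[keep], category = category[keep],
                        source = source[keep], stringsAsFactors = FALSE)
  entries <- entries[!duplicated(entries[c("surface", "category")]), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, name = name), class = "rs_lexicon")
}

#' @export
print.rs_lexicon <- function(x, ...) {
  cat("<rs_lexicon>", x$name, "-", nrow(x$entries), "entries\n")
  tab <- table(x$entries$category)
  for (cat_name in names(tab))
    cat("  ", cat_name, ": ", tab[[cat_name]], "\n", sep = "")
  invisible(x)
}

#' @export
length.rs_lexicon <- function(x) nrow(x$entries)

#' Read a term list from TSV
#'
#' Column 1 is the surface; an optional column 2 overrides the default
#' category per row. Lines starting with `#` are comments. Surfaces are
#' case-folded and whitespace-collapsed, and duplicate (surface, category)
#' rows are merged.
#'
#' @param path TSV file path.
#' @param category default category for rows without an override.
#' @param source provenance tag for all loaded entries.
#' @param name lexicon identifier (defaults to the file name).
#' @return an `rs_lexicon`.
#' @export
read_term_list <- function(path, category = "finding", source = "base",
                           name = basename(path)) {
  if (!file.exists(path)) stop("term list not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty term list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  surfaces <- character(length(parts))
  cats <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 1 || !nzchar(trimws(p[1])))
      stop("malformed term list row at line ", i, " of ", path)
    surfaces[i] <- p[1]
    cats[i] <- if (length(p) >= 2 && nzchar(trimws(p[2]))) trimws(p[2]) else category
  }
  lexicon(surfaces, cats, source = source, name = name)
}

#' Merge lexicons
#'
#' @param ... `rs_lexicon` objects.
#' @param name identifier for the merged lexicon.
#' @return an `rs_lexicon` with the union of entries.
#' @export
merge_lexicons <- function(..., name = "merged") {
  ls <- list(...)
  entries <- do.call(rbind, lapply(ls, function(l) l$entries))
  out <- lexicon(entries$surface, entries$category, entries$source, name = name)
  out
}

#' Case-insensitive exact lookup
#'
#' @param lex an `rs_lexicon`.
#' @param surface a single string (normalized internally).
#' @return character vector of categories for the surface; empty when absent.
#' @export
lexicon_lookup <- function(lex, surface) {
  s <- normalize_surface(surface)
  if (!nzchar(s)) return(character())
  unique(lex$entries$category[lex$entries$surface == s])
}

# Fast hashed index surface -> categories ("|"-joined); built once per
# matching pass. Also records the maximum token count over entries so the
# n-gram matcher knows when to stop.
lexicon_index <- function(lex) {
  env <- new.env(parent = emptyenv(), size = max(64L, nrow(lex$entries) * 2L))
  sp <- split(lex$entries$category, lex$entries$surface)
  for (s in names(sp)) assign(s, unique(sp[[s]]), envir = env)
  ntok <- if (nrow(lex$entries) > 0)
    max(lengths(strsplit(lex$entries$surface, " ", fixed = TRUE))) else 1L
  list(env = env, max_tokens = as.integer(ntok))
}

index_lookup <- function(index, surface) {
  if (exists(surface, envir = index$env, inherits = FALSE))
    get(surface, envir = index$env, inherits = FALSE)
  else character()
}

# Irregular plurals consulted before the suffix rules. Small by design: the
# pipeline only needs the forms that actually occur in radiology vocabulary.
IRREGULAR_PLURALS <- c(
  focus = "foci", vertebra = "vertebrae", atrium = "atria",
  bronchus = "bronchi", diverticulum = "diverticula",
  ostium = "ostia", ramus = "rami"
)

#' Pluralize a term
#'
#' Rule-based pluralization applied to the final word of a (possibly
#' multi-word) term: irregulars first, then `-is` to `-es` (atelectasis to
#' atelectases), sibilant endings (`s`, `x`, `z`, `ch`, `sh`) take `-es`,
#' consonant + `y` becomes `-ies`, and everything else takes `-s`. Total
#' function; never returns its input.
#'
#' @param term non-empty string.
#' @return character vector of plural form(s) (currently always length 1).
#' @export
pluralize_term <- function(term) {
  term <- normalize_surface(term)
  if (!nzchar(term)) stop("cannot pluralize an empty term")
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  last <- words[length(words)]
  pl <- if (last %in% names(IRREGULAR_PLURALS)) {
    unname(IRREGULAR_PLURALS[last])
  } else if (grepl("is$", last) && nchar(last) > 3) {
    sub("is$", "es", last)
  } else if (grepl("(s|x|z|ch|sh)$", last)) {
    paste0(last, "es")
  } else if (grepl("[^aeiou]y$", last)) {
    sub("y$", "ies", last)
  } else {
    paste0(last, "s")
  }
  words[length(words)] <- pl
  out <- paste(words, collapse = " ")
  if (identical(out, term)) out <- paste0(term, "es")
  out
}

#' Expansion configuration
#'
#' Controls the three lexicon expansion rules: prepending region phrases to
#' finding terms ("area of" + "hypodensity" = "area of hypodensity"),
#' concatenating descriptor/target pairs ("petechial" + "hemorrhage"), and
#' adding plural forms of all terms.
#'
#' @param prepend_phrases phrases prepended to finding-category terms.
#' @param descriptor_pairs list of c(descriptor, target-term) pairs; every
#'   target must exist in the lexicon being expanded.
#' @param pluralize whether to add plural forms.
#' @return a list of class `rs_expansion_config`.
#' @export
expansion_config <- function(prepend_phrases = c("area of", "areas of",
                                                 "region of", "regions of",
                                                 "focus of", "foci of"),
                             descriptor_pairs = list(
                               c("petechial", "hemorrhage"),
                               c("intraparenchymal", "hemorrhage"),
                               c("frontoparietal", "lobe"),
                               c("frontoparietal", "cortex")),
                             pluralize = TRUE) {
  if (any(!nzchar(prepend_phrases)))
    stop("prepend phrases must be non-empty")
  structure(list(prepend_phrases = normalize_surface(prepend_phrases),
                 descriptor_pairs = lapply(descriptor_pairs, normalize_surface),
                 pluralize = isTRUE(pluralize)),
            class = "rs_expansion_config")
}

#' Expand a lexicon
#'
#' Applies the expansion rules of [expansion_config()] and returns a new,
#' strictly larger-or-equal lexicon; the input is not modified. Every added
#' entry carries its expansion rule as its source tag. Expansion is a fixed
#' point of itself: entries created by an expansion rule are not fed back into
#' the same rule, so a second pass with the same config adds nothing.
#'
#' @param lex an `rs_lexicon`.
#' @param config an `rs_expansion_config`.
#' @return the expanded `rs_lexicon`.
#' @export
expand_lexicon <- function(lex, config = expansion_config()) {
  if (nrow(lex$entries) == 0) stop("cannot expand an empty lexicon")
  e <- lex$entries
  add_s <- character(); add_c <- character(); add_src <- character()

  # prepend phrases x finding terms; only base/manual terms are eligible so
  # expansion is a fixed point of itself
  findings <- e[e$category == "finding" & e$source %in% c("base", "manual"), ,
                drop = FALSE]
  if (length(config$prepend_phrases) > 0 && nrow(findings) > 0) {
    starts_with_phrase <- Reduce(`|`, lapply(
      config$prepend_phrases,
      function(p) startsWith(findings$surface, paste0(p, " "))))
    base_f <- findings$surface[!starts_with_phrase]
    for (p in config$prepend_phrases) {
      add_s <- c(add_s, paste(p, base_f))
      add_c <- c(add_c, rep("finding", length(base_f)))
      add_src <- c(add_src, rep("prepend_expansion", length(base_f)))
    }
  }

  # descriptor-pair concatenations
  if (length(config$descriptor_pairs) > 0) {
    targets <- vapply(config$descriptor_pairs, `[`, character(1), 2)
    missing <- setdiff(unique(targets), e$surface)
    if (length(missing) > 0)
      stop("descriptor expansion targets absent from lexicon: ",
           paste(missing, collapse = ", "))
    for (dp in config$descriptor_pairs) {
      cats <- unique(e$category[e$surface == dp[2]])
      add_s <- c(add_s, rep(paste(dp[1], dp[2]), length(cats)))
      add_c <- c(add_c, cats)
      add_src <- c(add_src, rep("descriptor_expansion", length(cats)))
    }
  }

  out <- lexicon(c(e$surface, add_s), c(e$category, add_c),
                 c(e$source, add_src), name = lex$name)

  # plurals of everything that is not itself a plural-expansion entry
  if (config$pluralize) {
    eo <- out$entries
    bases <- eo[eo$source != "plural_expansion", , drop = FALSE]
    pls <- vapply(bases$surface, function(s) pluralize_term(s)[1], character(1))
    out <- lexicon(c(eo$surface, pls), c(eo$category, bases$category),
                   c(eo$source, rep("plural_expansion", length(pls))),
                   name = lex$name)
  }
  out
}

#' Write / read a lexicon as JSON
#'
#' JSON layout: `{name, entries: [{surface, category, source}, ...]}`.
#'
#' @param lex an `rs_lexicon`.
#' @param path output file.
#' @return `write_lexicon_json` returns `path` invisibly; `read_lexicon_json`
#'   returns an `rs_lexicon`.
#' @export
write_lexicon_json <- function(lex, path) {
  jsonlite::write_json(list(name = lex$name, entries = lex$entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lexicon_json
#' @export
read_lexicon_json <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lexicon(x$entries$surface, x$entries$category, x$entries$source,
          name = x$name)
}

#' Packaged mini-lexicons
#'
#' Small, self-contained stand-ins for the full RadLex/FMA/Radiopaedia
#' vocabularies: the radiological-entity dictionary covers the terms needed
#' for the worked examples plus the synthetic-corpus vocabulary, and the
#' spatial-trigger dictionary covers common prepositions and trigger verbs.
#' Users with access to real ontologies load their own term lists through
#' [read_term_list()] instead.
#'
#' @param expanded apply the default [expansion_config()] (adds plural forms
#'   and the documented prepend/descriptor products).
#' @return an `rs_lexicon`.
#' @export
radspatial_entities <- function(expanded = TRUE) {
  path <- system.file("extdata", "rad_entities.tsv", package = "radspatial")
  lex <- read_term_list(path, category = "finding", name = "rad_entities")
  if (expanded) lex <- expand_lexicon(lex) else lex
}

#' @rdname radspatial_entities
#' @export
radspatial_triggers <- function() {
  path <- system.file("extdata", "spatial_triggers.tsv", package = "radspatial")
  # trigger dictionary is untyped; category slot reused as 'finding' is never
  # consulted for triggers
  read_term_list(path, category = "finding", name = "spatial_triggers")
}
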
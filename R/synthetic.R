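default_symptom_templates <- function() {
  c("I've been having {} since chemo.",
    "Anyone else dealing with {} after treatment?",
    "The {} got worse again last night.",
    "My doctor says the {} should fade over time.",
    "Still struggling with {} most mornings.",
    "Does anyone have tips for coping with {}?")
}

default_noise_templates <- function() {
  c("Thanks everyone for the kind words.",
    "My appointment got moved to next week.",
    "The weather has been lovely here lately.",
    "I finally finished reading that book.",
    "Sending good thoughts to all of you.",
    "We drove out to see family on Sunday.")
}

#' Specification for a synthetic forum-sentence corpus
#'
#' Describes a stream of forum-style sentences in which known symptom
#' surface forms from a [lexicon()] are planted among noise sentences, with
#' exact ground truth. Emulates segmented patient-forum text at desk scale:
#' first-person template phrasing, a controllable symptom-bearing rate,
#' repeated plantings, and character-level paraphrases (1-2 edits) whose
#' recoverability under the fuzzy threshold is provable. It does not model
#' real clinical vocabulary spread, misspellings beyond 2 edits, or
#' synonym-level variation.
#'
#' @param lex a [lexicon()]; the planting vocabulary and ground truth.
#' @param n_sentences total number of sentences.
#' @param symptom_rate proportion of symptom-bearing sentences (planted
#'   count is `floor(symptom_rate * n_sentences)`).
#' @param dup_rate proportion of plantings that repeat an already-planted
#'   surface.
#' @param paraphrase_rate proportion of plantings written as a 1-2
#'   character edit of their source surface.
#' @param templates sentence templates with a `{}` slot.
#' @param noise_templates templates without a slot.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(lex, n_sentences = 200L, symptom_rate = 0.3,
                        dup_rate = 0.1, paraphrase_rate = 0,
                        templates = default_symptom_templates(),
                        noise_templates = default_noise_templates(),
                        seed = 1L) {
  stopifnot(inherits(lex, "lexicon"),
            symptom_rate >= 0, symptom_rate <= 1,
            dup_rate >= 0, dup_rate <= 1,
            paraphrase_rate >= 0, paraphrase_rate <= 1,
            length(templates) > 0L, length(noise_templates) > 0L)
  if (length(lex$entries) == 0L && symptom_rate > 0) {
    stop("symptom_rate > 0 requires a non-empty lexicon", call. = FALSE)
  }
  structure(list(lexicon = lex, n_sentences = as.integer(n_sentences),
                 symptom_rate = symptom_rate, dup_rate = dup_rate,
                 paraphrase_rate = paraphrase_rate, templates = templates,
                 noise_templates = noise_templates, seed = as.integer(seed)),
            class = "corpus_spec")
}

# one random character edit (substitute/insert/delete a letter), never
# touching the first character and never emptying the string
random_edit <- function(x) {
  letters_pool <- letters
  n <- nchar(x)
  op <- sample(c("sub", "ins", "del"), 1)
  if (op == "del" && n <= 2L) op <- "ins"
  pos <- sample(2:max(2L, n), 1)
  switch(op,
    sub = paste0(substr(x, 1, pos - 1), sample(letters_pool, 1),
                 substr(x, pos + 1, n)),
    ins = paste0(substr(x, 1, pos), sample(letters_pool, 1),
                 substr(x, pos + 1, n)),
    del = paste0(substr(x, 1, pos - 1), substr(x, pos + 1, n))
  )
}

paraphrase_surface <- function(x) {
  n_edits <- sample(1:2, 1)
  out <- x
  for (i in seq_len(n_edits)) out <- random_edit(out)
  if (normalize_surface(out) == normalize_surface(x)) out <- random_edit(out)
  out
}

plant_sentence <- function(template, filled) {
  sub("{}", filled, template, fixed = TRUE)
}

build_corpus <- function(plantings, n_noise, spec, shuffle = TRUE) {
  # plantings: data.frame surface/category/planted/paraphrased
  k <- nrow(plantings)
  sentences <- character(k + n_noise)
  ann_rows <- vector("list", k)
  if (k > 0L) {
    tpl <- spec$templates[sample.int(length(spec$templates), k,
                                     replace = TRUE)]
    for (i in seq_len(k)) {
      sentences[i] <- plant_sentence(tpl[i], plantings$planted[i])
    }
  }
  if (n_noise > 0L) {
    sentences[k + seq_len(n_noise)] <-
      spec$noise_templates[sample.int(length(spec$noise_templates), n_noise,
                                      replace = TRUE)]
  }
  ord <- if (shuffle) sample.int(k + n_noise) else seq_len(k + n_noise)
  ids <- sprintf("s%04d", seq_len(k + n_noise))
  items <- stream_frame(ids, sentences[ord], NA_character_)
  per_sentence <- vector("list", k + n_noise)
  for (i in seq_len(k)) {
    where <- match(i, ord)
    per_sentence[[where]] <- data.frame(
      id = ids[where], surface = plantings$surface[i],
      planted = plantings$planted[i], category = plantings$category[i],
      paraphrased = plantings$paraphrased[i], stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, per_sentence[!vapply(per_sentence, is.null,
                                             logical(1))])
  if (is.null(ann)) {
    ann <- data.frame(id = character(), surface = character(),
                      planted = character(), category = character(),
                      paraphrased = logical(), stringsAsFactors = FALSE)
  }
  ann <- ann[order(ann$id), , drop = FALSE]
  rownames(ann) <- NULL
  list(items = items,
       annotation = structure(list(plantings = ann), class =
                                "corpus_annotation"))
}

#' Generate a synthetic annotated forum corpus
#'
#' Deterministic under the spec's seed. Exactly
#' `floor(symptom_rate * n_sentences)` sentences carry one planted symptom
#' each; `floor(dup_rate * k)` of the plantings repeat an earlier surface
#' and `floor(paraphrase_rate * k)` are 1-2 character edits recorded with
#' their source surface. The annotation describes the emitted stream
#' exactly.
#'
#' @param spec a [corpus_spec()].
#' @return list with `items` (stream data.frame) and `annotation` (class
#'   `corpus_annotation`: data.frame `plantings` with columns `id`,
#'   `surface`, `planted`, `category`, `paraphrased`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_sentences
    k <- floor(spec$symptom_rate * n)
    surfaces <- names(spec$lexicon$entries)
    plantings <- NULL
    if (k > 0L) {
      n_dup <- floor(spec$dup_rate * k)
      base <- surfaces[sample.int(length(surfaces), k - n_dup,
                                  replace = k - n_dup > length(surfaces))]
      dups <- if (n_dup > 0L) {
        pool <- if (length(base) > 0L) base else surfaces
        pool[sample.int(length(pool), n_dup, replace = TRUE)]
      } else character()
      chosen <- c(base, dups)
      n_para <- floor(spec$paraphrase_rate * k)
      para_idx <- if (n_para > 0L) sample.int(k, n_para) else integer()
      planted <- chosen
      for (i in para_idx) planted[i] <- paraphrase_surface(chosen[i])
      plantings <- data.frame(
        surface = chosen, planted = planted,
        category = vapply(chosen, function(s)
          lexicon_category(spec$lexicon, s), character(1)),
        paraphrased = seq_len(k) %in% para_idx, stringsAsFactors = FALSE)
    } else {
      plantings <- data.frame(surface = character(), planted = character(),
                              category = character(), paraphrased = logical(),
                              stringsAsFactors = FALSE)
    }
    build_corpus(plantings, n - k, spec)
  })
}

#' Build a recovery corpus planting every masked symptom
#'
#' Drives the end-to-end recovery protocol: every surface hidden by
#' [mask_ontology()] is planted at least once (as a 1-2 character edit with
#' probability `paraphrase_rate` from `extra`), mixed with
#' `extra$n_sentences` noise sentences and shuffled under the spec's seed.
#'
#' @param record a `mask_record` from [mask_ontology()].
#' @param extra a [corpus_spec()] supplying templates, noise volume,
#'   `paraphrase_rate` and seed; its lexicon supplies the category ground
#'   truth for annotation.
#' @return list with `items` and `annotation`, as [generate_corpus()].
#' @export
corpus_for_recovery <- function(record, extra) {
  stopifnot(inherits(record, "mask_record"), inherits(extra, "corpus_spec"))
  if (length(record$masked) == 0L) {
    stop("mask record is empty; nothing to plant", call. = FALSE)
  }
  with_local_seed(extra$seed, {
    surfaces <- unlist(record$masked, use.names = FALSE)
    cats <- rep(names(record$masked),
                vapply(record$masked, length, integer(1)))
    k <- length(surfaces)
    planted <- surfaces
    para <- stats::runif(k) < extra$paraphrase_rate
    for (i in which(para)) planted[i] <- paraphrase_surface(surfaces[i])
    plantings <- data.frame(surface = surfaces, planted = planted,
                            category = cats, paraphrased = para,
                            stringsAsFactors = FALSE)
    build_corpus(plantings, extra$n_sentences, extra)
  })
}

#' Reconstruct a corpus annotation by brute-force lexicon scan
#'
#' Independent check of annotation soundness: scans every sentence for
#' word-bounded lexicon surface forms (and, when the annotation records
#' paraphrases, their planted variants). Used to confirm that the
#' annotation exactly describes the emitted stream.
#'
#' @param items stream data.frame.
#' @param lex a [lexicon()].
#' @param planted_variants optional data.frame with `planted`, `surface`,
#'   `category` for paraphrased forms to scan for as well.
#' @return data.frame with columns `id`, `surface`, `planted`, `category`.
#' @export
scan_corpus <- function(items, lex, planted_variants = NULL) {
  vocab <- data.frame(planted = names(lex$entries),
                      surface = names(lex$entries),
                      category = unname(lex$entries),
                      stringsAsFactors = FALSE)
  if (!is.null(planted_variants) && nrow(planted_variants) > 0L) {
    vocab <- rbind(vocab, planted_variants[, c("planted", "surface",
                                               "category")])
  }
  rows <- list()
  for (i in seq_len(nrow(items))) {
    s <- tolower(gsub("\\s+", " ", items$sentence[[i]]))
    for (j in seq_len(nrow(vocab))) {
      pat <- paste0("\\b", escape_regex(normalize_surface(vocab$planted[j])),
                    "\\b")
      if (grepl(pat, s, perl = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = items$id[[i]], surface = vocab$surface[j],
          planted = vocab$planted[j], category = vocab$category[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(), surface = character(),
                      planted = character(), category = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$surface), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a corpus to disk
#'
#' Stream as JSONL (`id`, `sentence`), annotation and lexicon as JSON.
#'
#' @param corpus list from [generate_corpus()] / [corpus_for_recovery()].
#' @param stream_path,annotation_path output paths.
#' @param lex optional [lexicon()]; written next to the annotation when
#'   `lexicon_path` given.
#' @param lexicon_path optional path.
#' @return `stream_path`, invisibly.
#' @export
write_corpus <- function(corpus, stream_path, annotation_path = NULL,
                         lex = NULL, lexicon_path = NULL) {
  lines <- vapply(seq_len(nrow(corpus$items)), function(i) {
    jsonlite::toJSON(list(id = corpus$items$id[[i]],
                          sentence = corpus$items$sentence[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, stream_path, useBytes = TRUE)
  if (!is.null(annotation_path)) {
    jsonlite::write_json(corpus$annotation$plantings, annotation_path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(lex) && !is.null(lexicon_path)) {
    jsonlite::write_json(as.list(lex$entries), lexicon_path,
                         auto_unbox = TRUE)
  }
  invisible(stream_path)
}
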
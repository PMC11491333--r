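#' Construct a symptom lexicon
#'
#' A lexicon maps normalized symptom surface forms to the category each
#' belongs to (e.g. `"hot flashes"` to `"Vasomotor symptoms"`). It is the
#' closed-world ground truth behind the deterministic oracle backend and the
#' synthetic corpus generator.
#'
#' @param entries named character vector or named list: names are surface
#'   forms, values are category names ending in the word "symptoms".
#' @return an object of class `lexicon`.
#' @export
lexicon <- function(entries) {
  entries <- unlist(entries)
  if (length(entries) == 0L) {
    return(structure(list(entries = character()), class = "lexicon"))
  }
  surfaces <- normalize_surface(names(entries))
  if (any(!nzchar(surfaces))) {
    stop("lexicon surface forms must be non-empty", call. = FALSE)
  }
  cats <- as.character(entries)
  bad <- !grepl(" symptoms$", cats, ignore.case = TRUE)
  if (any(bad)) {
    stop(sprintf("lexicon categories must follow the '<X> symptoms' pattern; offending: %s",
                 paste(unique(cats[bad]), collapse = ", ")), call. = FALSE)
  }
  structure(list(entries = stats::setNames(cats, surfaces)), class = "lexicon")
}

#' Build a lexicon from an ontology
#'
#' Every (symptom, group) membership edge becomes one lexicon entry; useful
#' for driving the oracle backend with the full pre-mask ontology as ground
#' truth.
#'
#' @param o an [ontology()] whose member symptoms sit in leaf-level groups
#'   named `<X> symptoms`.
#' @return a [lexicon()].
#' @export
lexicon_from_ontology <- function(o) {
  tab <- ontology_members(o)
  lexicon(stats::setNames(tab$group, tab$surface))
}

#' Load a lexicon from a JSON file
#' @param path JSON object mapping surface form to category name.
#' @return a [lexicon()].
#' @export
load_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lexicon(unlist(raw))
}

lexicon_category <- function(lex, surface) {
  key <- normalize_surface(surface)
  if (key %in% names(lex$entries)) unname(lex$entries[[key]]) else NA_character_
}

# ---- backend contract -------------------------------------------------------

AGENT_ROLES <- c("identify", "extract", "classify", "is_duplicate",
                 "generate_relation", "verify")

new_backend <- function(name, subclass, ...) {
  structure(
    list(name = name, log_env = local({
      e <- new.env(parent = emptyenv()); e$entries <- list(); e
    }), ...),
    class = c(subclass, "agent_backend")
  )
}

log_decision <- function(backend, role, input, raw, parsed) {
  e <- backend$log_env
  e$entries[[length(e$entries) + 1L]] <- list(
    role = role, input = input, raw = raw, parsed = parsed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  )
  invisible(NULL)
}

#' Decision log of a backend
#'
#' Every agent call appends exactly one record: role, input, raw backend
#' response and the parsed decision. The log can be written as JSONL and
#' replayed with [replay_backend()].
#'
#' @param backend an agent backend.
#' @return list of decision records, in call order.
#' @export
decision_log <- function(backend) backend$log_env$entries

#' Write a decision log as JSONL
#' @param backend an agent backend.
#' @param path output path; one JSON record per line.
#' @return `path`, invisibly.
#' @export
write_decision_log <- function(backend, path) {
  lines <- vapply(decision_log(backend), function(rec) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Reset a backend's decision log
#' @param backend an agent backend.
#' @return the backend, invisibly.
#' @export
reset_decision_log <- function(backend) {
  backend$log_env$entries <- list()
  invisible(backend)
}

#' @export
print.agent_backend <- function(x, ...) {
  cat(sprintf("<agent backend '%s'> %d logged decisions\n", x$name,
              length(decision_log(x))))
  invisible(x)
}

#' Agent role: does a sentence mention any symptom?
#'
#' First gate of the pipeline. The oracle backend answers yes exactly when
#' some lexicon surface form occurs in the sentence as a word-bounded,
#' case-insensitive match.
#'
#' @param backend an agent backend.
#' @param sentence non-empty sentence text.
#' @return `TRUE`/`FALSE`, or `NA` on an unrecoverable protocol error
#'   (the caller skips the sentence).
#' @export
agent_identify <- function(backend, sentence) UseMethod("agent_identify")

#' Agent role: extract symptom phrases from a sentence
#'
#' Called only for sentences that passed [agent_identify()]. Returns the
#' symptom surface forms found, deduplicated by normalized form, in order of
#' first occurrence. Treatments and bare body parts are not symptoms.
#'
#' @inheritParams agent_identify
#' @return character vector of surface forms (possibly empty), or `NULL` on
#'   protocol error.
#' @export
agent_extract <- function(backend, sentence) UseMethod("agent_extract")

#' Agent role: classify a symptom into an existing category
#'
#' Routes level by level for hierarchies deeper than one category level. A
#' name that does not exist in the ontology is coerced to absent and logged.
#'
#' @param backend an agent backend.
#' @param symptom_text symptom phrase.
#' @param o the current [ontology()].
#' @return an existing group name, or `NA_character_` when the symptom fits
#'   no existing category.
#' @export
agent_classify <- function(backend, symptom_text, o) UseMethod("agent_classify")

#' Agent role: is a symptom a duplicate of an existing member?
#'
#' The oracle backend declares a duplicate when the fuzzy score against any
#' member of the group exceeds the backend's duplication threshold
#' (default 90).
#'
#' @param backend an agent backend.
#' @param symptom_text symptom phrase.
#' @param group a `symptom_group` whose members are checked.
#' @return `TRUE`/`FALSE`; protocol errors degrade to `TRUE` (conservative:
#'   do not add).
#' @export
agent_is_duplicate <- function(backend, symptom_text, group) {
  UseMethod("agent_is_duplicate")
}

#' Agent role: propose a category for an unclassifiable symptom
#'
#' Called when [agent_classify()] returned absent. The answer is
#' canonicalized to the `<X> symptoms` pattern (first letter capitalized,
#' trailing word "symptoms" enforced).
#'
#' @inheritParams agent_classify
#' @return a category name, or `NA_character_` on protocol error (the
#'   caller parks the symptom).
#' @export
agent_generate_relation <- function(backend, symptom_text) {
  UseMethod("agent_generate_relation")
}

#' Agent role: verify a category-symptom assignment
#'
#' Final check before a symptom enters the ontology. The oracle backend
#' confirms membership exactly when the lexicon category of the symptom
#' equals the proposed category.
#'
#' @param backend an agent backend.
#' @param category proposed category name.
#' @param symptom_text symptom phrase.
#' @return `TRUE`/`FALSE`; protocol errors degrade to `FALSE` (reject).
#' @export
agent_verify <- function(backend, category, symptom_text) {
  UseMethod("agent_verify")
}

# ---- deterministic lexicon oracle backend -----------------------------------

#' Deterministic lexicon-oracle backend
#'
#' Answers all six agent roles as a pure function of a closed-world
#' [lexicon()]: identical inputs always yield identical decisions, so runs
#' are fully reproducible offline. Intended for testing, synthetic-corpus
#' experiments and as a reference behavior for the pipeline contracts.
#'
#' @param lex a [lexicon()].
#' @param dup_threshold fuzzy score (0-100) above which a symptom counts as
#'   a duplicate of an existing member; default 90.
#' @return an object of classes `oracle_backend`, `agent_backend`.
#' @export
oracle_backend <- function(lex, dup_threshold = 90) {
  stopifnot(inherits(lex, "lexicon"), dup_threshold >= 0, dup_threshold <= 100)
  new_backend("oracle", "oracle_backend", lexicon = lex,
              dup_threshold = dup_threshold)
}

# word-bounded, case-insensitive occurrence of each lexicon form; returns
# first-occurrence offsets (NA when absent)
lexicon_hits <- function(lex, sentence) {
  s <- tolower(gsub("\\s+", " ", sentence))
  forms <- names(lex$entries)
  if (length(forms) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  pos <- vapply(forms, function(f) {
    pat <- paste0("\\b", escape_regex(f), "\\b")
    m <- regexpr(pat, s, perl = TRUE)
    if (m[1] == -1L) NA_integer_ else as.integer(m[1])
  }, integer(1))
  pos[!is.na(pos)]
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' @export
agent_identify.oracle_backend <- function(backend, sentence) {
  stopifnot(nzchar(sentence))
  ans <- length(lexicon_hits(backend$lexicon, sentence)) > 0L
  log_decision(backend, "identify", sentence, if (ans) "yes" else "no", ans)
  ans
}

#' @export
agent_extract.oracle_backend <- function(backend, sentence) {
  hits <- lexicon_hits(backend$lexicon, sentence)
  forms <- names(hits)[order(unname(hits))]
  forms <- forms[!duplicated(normalize_surface(forms))]
  log_decision(backend, "extract", sentence,
               paste(forms, collapse = "; "), forms)
  forms
}

#' @export
agent_classify.oracle_backend <- function(backend, symptom_text, o) {
  cat_name <- lexicon_category(backend$lexicon, symptom_text)
  ans <- if (is.na(cat_name)) NA_character_ else match_group_name(o, cat_name)
  log_decision(backend, "classify", symptom_text,
               if (is.na(ans)) "No" else ans, ans)
  ans
}

#' @export
agent_is_duplicate.oracle_backend <- function(backend, symptom_text, group) {
  scores <- vapply(group$members,
                   function(m) fuzzy_score(symptom_text, m$surface),
                   numeric(1))
  ans <- length(scores) > 0L && any(scores > backend$dup_threshold)
  log_decision(backend, "is_duplicate",
               list(symptom = symptom_text, group = group$name),
               if (ans) "yes" else "no", ans)
  ans
}

#' @export
agent_generate_relation.oracle_backend <- function(backend, symptom_text) {
  cat_name <- lexicon_category(backend$lexicon, symptom_text)
  ans <- if (is.na(cat_name)) NA_character_ else canonicalize_category(cat_name)
  log_decision(backend, "generate_relation", symptom_text,
               if (is.na(ans)) "" else ans, ans)
  ans
}

#' @export
agent_verify.oracle_backend <- function(backend, category, symptom_text) {
  cat_name <- lexicon_category(backend$lexicon, symptom_text)
  ans <- !is.na(cat_name) &&
    normalize_surface(cat_name) == normalize_surface(category)
  log_decision(backend, "verify",
               list(category = category, symptom = symptom_text),
               if (ans) "yes" else "no", ans)
  ans
}

# ---- replay backend ---------------------------------------------------------

#' Replay backend: answer agent calls from a recorded decision log
#'
#' Given the decision log of a previous run, answers each role from the
#' first unconsumed record with a matching role and input. Running the
#' pipeline against a replay of its own log reproduces the identical final
#' ontology.
#'
#' @param log a list of decision records from [decision_log()].
#' @return an object of classes `replay_backend`, `agent_backend`.
#' @export
replay_backend <- function(log) {
  b <- new_backend("replay", "replay_backend")
  b$queue_env <- local({
    e <- new.env(parent = emptyenv()); e$records <- log; e$used <- rep(FALSE, length(log)); e
  })
  b
}

replay_answer <- function(backend, role, input) {
  e <- backend$queue_env
  key <- jsonlite::toJSON(input, auto_unbox = TRUE, null = "null")
  for (i in seq_along(e$records)) {
    rec <- e$records[[i]]
    if (!e$used[i] && identical(rec$role, role) &&
        identical(jsonlite::toJSON(rec$input, auto_unbox = TRUE,
                                   null = "null"), key)) {
      e$used[i] <- TRUE
      log_decision(backend, role, input, rec$raw, rec$parsed)
      return(rec$parsed)
    }
  }
  stop(sprintf("replay log has no unused record for role '%s'", role),
       call. = FALSE)
}

#' @export
agent_identify.replay_backend <- function(backend, sentence) {
  isTRUE(replay_answer(backend, "identify", sentence))
}
#' @export
agent_extract.replay_backend <- function(backend, sentence) {
  out <- replay_answer(backend, "extract", sentence)
  as.character(unlist(out))
}
#' @export
agent_classify.replay_backend <- function(backend, symptom_text, o) {
  out <- replay_answer(backend, "classify", symptom_text)
  if (is.null(out) || is.na(out)) NA_character_ else as.character(out)
}
#' @export
agent_is_duplicate.replay_backend <- function(backend, symptom_text, group) {
  isTRUE(replay_answer(backend, "is_duplicate",
                       list(symptom = symptom_text, group = group$name)))
}
#' @export
agent_generate_relation.replay_backend <- function(backend, symptom_text) {
  out <- replay_answer(backend, "generate_relation", symptom_text)
  if (is.null(out) || is.na(out)) NA_character_ else as.character(out)
}
#' @export
agent_verify.replay_backend <- function(backend, category, symptom_text) {
  isTRUE(replay_answer(backend, "verify",
                       list(category = category, symptom = symptom_text)))
}
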
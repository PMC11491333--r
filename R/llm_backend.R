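# Role-specific prompt blocks for the language-model backend. Each role
# sends a fixed system message plus the per-call human message; few-shot
# exemplar blocks are configurable and ship with two short defaults per role.

llm_prompts <- function(few_shot = default_few_shot()) {
  list(
    identify = list(
      system = paste(
        "Act as an experienced doctor. Given a sentence, if the sentence",
        "contains any symptoms, answer 'yes', otherwise answer 'no'."),
      human = function(sentence, ...) {
        paste("Does the following sentence contain any symptoms? Sentence:",
              sentence)
      }
    ),
    extract = list(
      system = paste(
        "This is a set of symptom recognition problems. The 'Sentence' is a",
        "sentence containing symptoms. The word 'symptom' and treatments,",
        "like chemo, are not counted as symptoms. Also notice that human",
        "body parts, like knees and back, are not counted as symptoms. The",
        "goal is to return a Python list containing all possible symptoms,",
        "without any explanations.",
        "Here are some examples of what I want:", few_shot$extract),
      human = function(sentence, ...) {
        paste("Which words in the following sentence contain symptoms?",
              "Sentence:", sentence)
      }
    ),
    classify = list(
      system_tpl = paste(
        "This is a set of symptom classification problems. The 'String' is a",
        "string describing symptoms. Use the following symptom_dictionary.json",
        "to answer the given questions. The structure of",
        "symptom_dictionary.json is: 'existing category 1': 'symptom 1',",
        "'symptom 2', 'symptom 3', 'existing category 2': 'symptom 4',",
        "'symptom 5', 'symptom 6'. The goal is to classify the string into",
        "one existing category. You only need to answer the name of the",
        "existing category should the string belongs. No explanation is",
        "needed. If the string does not belong to any existing category,",
        "simply answer 'No'.",
        "symptom_dictionary.json: %s",
        "Here are some examples of what I want:", few_shot$classify),
      human = function(symptom_text, ...) {
        paste("Which existing category should the following string belongs",
              "to? String:", symptom_text)
      }
    ),
    is_duplicate = list(
      system_tpl = paste(
        "This is a set of symptom classification problems. The 'String' is a",
        "string describing symptoms. Use the following list of exist_symptoms",
        "to answer the given questions. exist_symptoms is a list that",
        "contains several strings describing symptoms. The goal is to",
        "determine if the string is a repeated occurrence in the",
        "exist_symptoms. You only need to answer 'no' if the string is not a",
        "repeated occurrence in the exist_symptoms and answer 'yes'",
        "otherwise. No explanation is needed. exist_symptoms: %s",
        "Here are some examples of what I want:", few_shot$is_duplicate),
      human = function(symptom_text, ...) {
        paste("Does this string a repeated occurrence in the exist_symptoms?",
              "String:", symptom_text)
      }
    ),
    generate_relation = list(
      system = paste(
        "This is a set of symptom classification problems. Act as an",
        "experienced doctor. The 'Symptom' is a string representing",
        "symptoms. Given a symptom, the goal is to classify the symptom into",
        "a general type of medical symptom. List the symptoms in the format",
        "of 'XXX symptoms', such as Gastrointestinal symptoms, Gynecologic",
        "symptoms, and Musculoskeletal symptoms. No explanation is needed.",
        "Here are some examples of what I want:", few_shot$generate_relation),
      human = function(symptom_text, ...) {
        paste("Which broad category of symptoms does the given symptom",
              "belong to? Symptom:", symptom_text)
      }
    ),
    verify = list(
      system = paste(
        "Act as an experienced doctor. Given a string, if the string belongs",
        "to the given category, answer 'yes', otherwise answer 'no'."),
      human = function(category, symptom_text, ...) {
        paste("Does the string a symptom of the category? Category:",
              category, "String:", symptom_text)
      }
    )
  )
}

default_few_shot <- function() {
  list(
    extract = paste(
      "Sentence: I have nausea and joint pain. -> ['nausea', 'joint pain'];",
      "Sentence: The chemo made my back sore. -> ['sore back']"),
    classify = paste(
      "String: hot flashes -> Vasomotor symptoms;",
      "String: stock prices -> No"),
    is_duplicate = paste(
      "String: Hot flashes, exist_symptoms: ['hot flashes'] -> yes;",
      "String: nausea, exist_symptoms: ['joint pain'] -> no"),
    generate_relation = paste(
      "Symptom: nausea -> Gastrointestinal symptoms;",
      "Symptom: joint pain -> Musculoskeletal symptoms")
  )
}

# Default model-tier routing: identification, extraction, duplication
# checking and verification run on the cheaper tier; classification and
# relation generation on the stronger tier. Pure configuration passed to the
# transport; no behavioral difference inside this package.
default_model_routing <- function() {
  c(identify = "cheap", extract = "cheap", classify = "strong",
    is_duplicate = "cheap", generate_relation = "strong", verify = "cheap")
}

#' Language-model agent backend
#'
#' Serves the six agent roles by sending role-specific prompts through a
#' user-supplied transport function, so any chat-completion API (or a stub
#' in tests) can stand behind it. Responses are parsed defensively: a parser
#' never raises on arbitrary text; a malformed answer is retried up to
#' `retries` times and then degrades to the role's safe fallback (skip the
#' sentence, treat as duplicate, reject the assignment, or park the
#' symptom).
#'
#' @param transport `function(role, model, system, user)` returning the raw
#'   response text for one call.
#' @param retries number of re-asks after a malformed response (default 2).
#' @param model_routing named character vector mapping each role to a model
#'   tier label passed to the transport.
#' @param few_shot named list of exemplar text blocks per role.
#' @return an object of classes `llm_backend`, `agent_backend`.
#' @export
llm_backend <- function(transport, retries = 2,
                        model_routing = default_model_routing(),
                        few_shot = default_few_shot()) {
  stopifnot(is.function(transport), retries >= 0)
  new_backend("llm", "llm_backend", transport = transport,
              retries = retries, model_routing = model_routing,
              prompts = llm_prompts(few_shot))
}

# ask the transport, parse, retry on NA-parse; returns list(raw, parsed) with
# parsed = NULL on protocol exhaustion
llm_ask <- function(backend, role, system, user, parser) {
  raw <- NA_character_
  for (attempt in seq_len(backend$retries + 1L)) {
    raw <- tryCatch(
      as.character(backend$transport(role, backend$model_routing[[role]],
                                     system, user))[1],
      error = function(e) NA_character_
    )
    if (!is.na(raw)) {
      parsed <- parser(raw)
      if (!is.null(parsed)) return(list(raw = raw, parsed = parsed))
    }
  }
  list(raw = raw, parsed = NULL)
}

#' Parse a yes/no answer
#'
#' Case-insensitive; tolerates surrounding quotes, punctuation and short
#' prefixes such as "Answer: yes.". Returns `TRUE`, `FALSE`, or `NULL` when
#' the text contains neither a clear yes nor a clear no.
#'
#' @param raw raw response text.
#' @return logical scalar or `NULL`.
#' @export
parse_yes_no <- function(raw) {
  x <- tolower(trimws(raw))
  x <- gsub("^[[:punct:][:space:]]*(answer\\s*:)?[[:punct:][:space:]]*", "", x)
  if (grepl("^yes\\b", x)) return(TRUE)
  if (grepl("^no\\b", x)) return(FALSE)
  NULL
}

#' Parse a bracketed Python-style list of strings
#'
#' Accepts single or double quotes and surrounding prose; `[]` parses to an
#' empty character vector. Returns `NULL` when no well-formed bracketed list
#' is found.
#'
#' @param raw raw response text.
#' @return character vector or `NULL`.
#' @export
parse_bracketed_list <- function(raw) {
  x <- as.character(raw)[1]
  open <- regexpr("\\[", x)[1]
  close <- max(gregexpr("\\]", x)[[1]])
  if (open == -1L || close == -1L || close < open) return(NULL)
  body <- substr(x, open + 1L, close - 1L)
  if (!nzchar(trimws(body))) return(character())
  items <- regmatches(body,
                      gregexpr("'([^']*)'|\"([^\"]*)\"", body))[[1]]
  if (length(items) == 0L) return(NULL)
  out <- substr(items, 2L, nchar(items) - 1L)
  out <- out[nzchar(trimws(out))]
  as.character(out)
}

#' Canonicalize a category name to the `<X> symptoms` pattern
#'
#' Trims quotes and terminal punctuation, collapses whitespace, enforces the
#' trailing word "symptoms" (singular answers are pluralized, a missing tail
#' is appended) and capitalizes the first letter.
#'
#' @param raw a proposed category name.
#' @return canonical category name, or `NULL` for empty/unusable input.
#' @export
canonicalize_category <- function(raw) {
  x <- trimws(as.character(raw)[1])
  x <- gsub('^["‘’“”\']+|["‘’“”\'.]+$',
            "", x)
  x <- trimws(gsub("\\s+", " ", x))
  if (!grepl("[[:alpha:]]", x)) return(NULL)
  if (grepl("symptoms$", x, ignore.case = TRUE)) {
    x <- sub("symptoms$", "symptoms", x, ignore.case = TRUE)
  } else if (grepl("symptom$", x, ignore.case = TRUE)) {
    x <- sub("symptom$", "symptoms", x, ignore.case = TRUE)
  } else {
    x <- paste(x, "symptoms")
  }
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  x
}

#' @export
agent_identify.llm_backend <- function(backend, sentence) {
  stopifnot(nzchar(sentence))
  p <- backend$prompts$identify
  ans <- llm_ask(backend, "identify", p$system, p$human(sentence),
                 parse_yes_no)
  parsed <- if (is.null(ans$parsed)) NA else ans$parsed
  log_decision(backend, "identify", sentence, ans$raw, parsed)
  parsed
}

#' @export
agent_extract.llm_backend <- function(backend, sentence) {
  p <- backend$prompts$extract
  ans <- llm_ask(backend, "extract", p$system, p$human(sentence),
                 parse_bracketed_list)
  parsed <- ans$parsed
  if (!is.null(parsed)) {
    parsed <- parsed[!duplicated(normalize_surface(parsed))]
  }
  log_decision(backend, "extract", sentence, ans$raw, parsed)
  parsed
}

# flat dictionary of one hierarchy level: the level's categories with their
# direct members (keeps the prompt inside a context window; the whole tree
# is never embedded)
level_dictionary_json <- function(groups) {
  obj <- stats::setNames(
    lapply(groups, function(g) {
      vapply(g$members, function(m) m$surface, character(1))
    }),
    vapply(groups, function(g) g$name, character(1))
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = FALSE))
}

#' @export
agent_classify.llm_backend <- function(backend, symptom_text, o) {
  p <- backend$prompts$classify
  # route level by level: ask against the current level's categories, then
  # descend into the chosen category's subcategories while any exist
  groups <- o$root$children
  chosen <- NA_character_
  repeat {
    if (length(groups) == 0L) break
    system <- sprintf(p$system_tpl, level_dictionary_json(groups))
    ans <- llm_ask(backend, "classify", system, p$human(symptom_text),
                   function(raw) {
                     x <- trimws(gsub('^["\']+|["\'.]+$', "", trimws(raw)))
                     if (!nzchar(x)) NULL else x
                   })
    if (is.null(ans$parsed)) {
      log_decision(backend, "classify", symptom_text, ans$raw, NA_character_)
      return(NA_character_)
    }
    if (tolower(ans$parsed) == "no") {
      log_decision(backend, "classify", symptom_text, ans$raw, chosen)
      return(chosen)
    }
    nms <- vapply(groups, function(g) g$name, character(1))
    hit <- nms[normalize_surface(nms) == normalize_surface(ans$parsed)]
    if (length(hit) == 0L) {
      # hallucinated name: coerce to absent (or keep the last valid level)
      log_decision(backend, "classify", symptom_text, ans$raw, chosen)
      return(chosen)
    }
    chosen <- hit[[1]]
    g <- groups[[match(chosen, nms)]]
    if (length(g$children) == 0L) break
    groups <- g$children
  }
  log_decision(backend, "classify", symptom_text,
               if (is.na(chosen)) "No" else chosen, chosen)
  chosen
}

#' @export
agent_is_duplicate.llm_backend <- function(backend, symptom_text, group) {
  p <- backend$prompts$is_duplicate
  members <- vapply(group$members, function(m) m$surface, character(1))
  listing <- paste0("['", paste(members, collapse = "', '"), "']")
  system <- sprintf(p$system_tpl, listing)
  ans <- llm_ask(backend, "is_duplicate", system, p$human(symptom_text),
                 parse_yes_no)
  parsed <- if (is.null(ans$parsed)) TRUE else ans$parsed  # conservative
  log_decision(backend, "is_duplicate",
               list(symptom = symptom_text, group = group$name),
               ans$raw, parsed)
  parsed
}

#' @export
agent_generate_relation.llm_backend <- function(backend, symptom_text) {
  p <- backend$prompts$generate_relation
  ans <- llm_ask(backend, "generate_relation", p$system,
                 p$human(symptom_text), canonicalize_category)
  parsed <- if (is.null(ans$parsed)) NA_character_ else ans$parsed
  log_decision(backend, "generate_relation", symptom_text, ans$raw, parsed)
  parsed
}

#' @export
agent_verify.llm_backend <- function(backend, category, symptom_text) {
  p <- backend$prompts$verify
  ans <- llm_ask(backend, "verify", p$system, p$human(category, symptom_text),
                 parse_yes_no)
  parsed <- if (is.null(ans$parsed)) FALSE else ans$parsed  # reject
  log_decision(backend, "verify",
               list(category = category, symptom = symptom_text),
               ans$raw, parsed)
  parsed
}
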
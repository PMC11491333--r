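# Abbreviations protected from the sentence splitter (terminal-punctuation
# rule would otherwise cut after them).
SPLIT_ABBREVIATIONS <- c("Dr", "Mr", "Mrs", "Ms", "Prof", "St", "vs", "etc",
                         "e.g", "i.e", "approx", "No", "Jan", "Feb", "Mar",
                         "Apr", "Jun", "Jul", "Aug", "Sep", "Oct", "Nov",
                         "Dec")

#' Split free text into sentences
#'
#' Rule-based splitter: cuts after terminal punctuation (`.`, `!`, `?`)
#' followed by whitespace, with a guard list of common abbreviations
#' ("Dr.", "e.g.", ...) that never end a sentence. Empty segments are
#' dropped.
#'
#' @param text character vector; elements are split independently.
#' @return character vector of sentences in document order.
#' @export
split_sentences <- function(text) {
  out <- character()
  for (chunk in text) {
    x <- gsub("\\s+", " ", chunk)
    # protect abbreviation periods with a placeholder
    for (ab in SPLIT_ABBREVIATIONS) {
      x <- gsub(paste0("\\b", escape_regex(ab), "\\.(?=\\s+[a-z0-9A-Z])"),
                paste0(ab, "\x01"), x, perl = TRUE)
    }
    parts <- strsplit(x, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    parts <- gsub("\x01", ".", parts, fixed = TRUE)
    parts <- trimws(parts)
    out <- c(out, parts[nzchar(gsub("[[:punct:][:space:]]", "", parts))])
  }
  out
}

stream_frame <- function(id, sentence, source) {
  data.frame(id = id, sentence = sentence, source = source,
             stringsAsFactors = FALSE)
}

#' Segment raw input into a sentence stream
#'
#' Accepts three shapes and returns one uniform stream of items:
#' \describe{
#'   \item{txt}{plain text; every line is split into sentences.}
#'   \item{jsonl}{one JSON object per line with a `sentence` (or `text`)
#'     key and optional `id`/`source`.}
#'   \item{forum}{forum records (JSON array or JSONL) with keys
#'     `datePublished`, `dateModified`, `author` and `posts`; the post text
#'     is split into sentences and each sentence carries
#'     author/date provenance.}
#' }
#'
#' @param path input file, or a character vector of raw text when
#'   `format = "txt"`.
#' @param format `"auto"` (sniffed from content), `"txt"`, `"jsonl"` or
#'   `"forum"`.
#' @return data.frame with columns `id`, `sentence`, `source` — one row per
#'   sentence, in document order.
#' @export
segment_posts <- function(path, format = c("auto", "txt", "jsonl", "forum")) {
  format <- match.arg(format)
  if (length(path) == 1L && file.exists(path)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  } else if (format %in% c("auto", "txt")) {
    lines <- as.character(path)
    format <- "txt"
  } else {
    stop(sprintf("cannot read stream input: %s", path[1]), call. = FALSE)
  }
  if (format == "auto") format <- sniff_stream_format(lines)
  switch(format,
    txt = {
      sentences <- split_sentences(lines)
      stream_frame(sprintf("s%04d", seq_along(sentences)), sentences,
                   rep(NA_character_, length(sentences)))
    },
    jsonl = segment_jsonl(lines),
    forum = segment_forum(lines)
  )
}

sniff_stream_format <- function(lines) {
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0L) return("txt")
  first <- trimws(nonempty[[1]])
  if (!startsWith(first, "{") && !startsWith(first, "[")) return("txt")
  obj <- tryCatch(jsonlite::fromJSON(paste(lines, collapse = "\n"),
                                     simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(obj)) {
    obj <- tryCatch(jsonlite::fromJSON(first, simplifyVector = FALSE),
                    error = function(e) NULL)
  }
  probe <- if (!is.null(names(obj))) obj else if (length(obj)) obj[[1]] else NULL
  if (!is.null(probe) && "posts" %in% names(probe)) return("forum")
  "jsonl"
}

segment_jsonl <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      stop(sprintf("malformed JSONL at line %d: %s", i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    sent <- rec$sentence %||% rec$text
    if (is.null(sent)) {
      stop(sprintf("JSONL record at line %d lacks a 'sentence' key", i),
           call. = FALSE)
    }
    stream_frame(as.character(rec$id %||% sprintf("s%04d", i)),
                 as.character(sent),
                 as.character(rec$source %||% NA_character_))
  })
  do.call(rbind, rows)
}

segment_forum <- function(lines) {
  text <- paste(lines, collapse = "\n")
  recs <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                   error = function(e) NULL)
  if (is.null(recs)) {  # JSONL of records
    recs <- lapply(lines[nzchar(trimws(lines))], jsonlite::fromJSON,
                   simplifyVector = FALSE)
  }
  if (!is.null(names(recs)) && "posts" %in% names(recs)) recs <- list(recs)
  rows <- list()
  n <- 0L
  for (j in seq_along(recs)) {
    rec <- recs[[j]]
    if (!"posts" %in% names(rec)) {
      stop(sprintf("forum record %d lacks required key 'posts' (has: %s)",
                   j, paste(names(rec), collapse = ", ")), call. = FALSE)
    }
    src <- paste(c(rec$author %||% NA, rec$datePublished %||% NA),
                 collapse = "|")
    posts <- unlist(rec$posts)
    for (sent in split_sentences(posts)) {
      n <- n + 1L
      rows[[n]] <- stream_frame(sprintf("s%04d", n), sent, src)
    }
  }
  if (length(rows) == 0L) {
    return(stream_frame(character(), character(), character()))
  }
  do.call(rbind, rows)
}

#' Run configuration for the clustering loop
#'
#' @param backend an agent backend ([oracle_backend()], [llm_backend()] or
#'   [replay_backend()]).
#' @param enable_f4 run the duplication-check role before adding (default
#'   `TRUE`); disabling it is the duplication-check ablation.
#' @param enable_f6 run the relation-verification role before adding
#'   (default `TRUE`); disabling it is the verification ablation.
#' @param dup_threshold fuzzy score above which the oracle backend calls a
#'   duplicate (0-100, default 90).
#' @param retries re-asks allowed per malformed backend answer.
#' @param seed integer seed recorded with the run.
#' @param checkpoint_every write a recovery checkpoint of the ontology every
#'   N stream items (`checkpoint_path` must be set); default 500.
#' @param checkpoint_path optional path for checkpoints.
#' @return an object of class `run_config`.
#' @export
run_config <- function(backend, enable_f4 = TRUE, enable_f6 = TRUE,
                       dup_threshold = 90, retries = 2, seed = 1L,
                       checkpoint_every = 500L, checkpoint_path = NULL) {
  stopifnot(inherits(backend, "agent_backend"),
            dup_threshold >= 0, dup_threshold <= 100, retries >= 0)
  structure(list(backend = backend, enable_f4 = isTRUE(enable_f4),
                 enable_f6 = isTRUE(enable_f6),
                 dup_threshold = dup_threshold, retries = retries,
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_path = checkpoint_path),
            class = "run_config")
}

#' Integrate one extracted symptom into the ontology
#'
#' One step of the online clustering loop. Exactly one of four outcomes:
#' \enumerate{
#'   \item classification finds an existing group -> the symptom is added
#'     there after passing the enabled duplication check (f4) and
#'     verification (f6);
#'   \item f4 or f6 rejects -> the ontology is unchanged;
#'   \item classification is absent -> relation generation proposes a
#'     category; an existing group with that name (case/format-insensitive)
#'     is reused, otherwise a new generated group is created at the top
#'     level, and the symptom is added after the enabled f6 check;
#'   \item the backend exhausts its protocol retries -> the symptom is
#'     parked and the ontology unchanged.
#' }
#'
#' @param o the current [ontology()].
#' @param symptom_text extracted symptom phrase.
#' @param cfg a [run_config()].
#' @param source_ref optional stream item id recorded on the added symptom.
#' @return the updated ontology, with attribute `decision` describing the
#'   path taken (`added`, `duplicate`, `rejected`, `parked`).
#' @export
process_symptom <- function(o, symptom_text, cfg, source_ref = NULL) {
  b <- cfg$backend
  finish <- function(o, decision) {
    attr(o, "decision") <- decision
    o
  }
  group_name <- agent_classify(b, symptom_text, o)
  if (is.na(group_name)) {
    proposed <- agent_generate_relation(b, symptom_text)
    if (is.na(proposed)) return(finish(o, "parked"))
    existing <- match_group_name(o, proposed)
    if (!is.na(existing)) {
      group_name <- existing
    } else {
      if (cfg$enable_f6 && !agent_verify(b, proposed, symptom_text)) {
        return(finish(o, "rejected"))
      }
      o2 <- create_group(o, NULL, proposed)
      o2 <- add_symptom(o2, proposed,
                        symptom(symptom_text, provenance = "extracted",
                                source_ref = source_ref))
      return(finish(o2, "added"))
    }
  }
  grp <- get_group(o, group_name)
  if (cfg$enable_f4 && agent_is_duplicate(b, symptom_text, grp)) {
    return(finish(o, "duplicate"))
  }
  if (cfg$enable_f6 && !agent_verify(b, group_name, symptom_text)) {
    return(finish(o, "rejected"))
  }
  finish(add_symptom(o, group_name,
                     symptom(symptom_text, provenance = "extracted",
                             source_ref = source_ref)),
         "added")
}

#' Run the online clustering loop over a sentence stream
#'
#' Single-pass: each stream item is consumed exactly once, in order, with no
#' lookahead. For each item the identification role is asked once; when it
#' answers yes, every extracted symptom is integrated via
#' [process_symptom()]. The result always contains the input ontology
#' (extension never deletes or renames seed content).
#'
#' @param o the starting [ontology()].
#' @param items stream data.frame from [segment_posts()] (columns `id`,
#'   `sentence`; `source` optional).
#' @param cfg a [run_config()].
#' @return the extended ontology. Attribute `parked` lists symptoms that
#'   exhausted the agent protocol and were set aside.
#' @export
run_stream <- function(o, items, cfg) {
  stopifnot(inherits(o, "ontology"), inherits(cfg, "run_config"))
  if (is.character(items)) {
    items <- stream_frame(sprintf("s%04d", seq_along(items)), items,
                          NA_character_)
  }
  parked <- character()
  n_since_checkpoint <- 0L
  for (i in seq_len(nrow(items))) {
    sentence <- items$sentence[[i]]
    hit <- tryCatch(agent_identify(cfg$backend, sentence),
                    error = function(e) NA)
    if (isTRUE(hit)) {
      found <- agent_extract(cfg$backend, sentence)
      for (s in found %||% character()) {
        o <- process_symptom(o, s, cfg, source_ref = items$id[[i]])
        if (identical(attr(o, "decision"), "parked")) {
          parked <- c(parked, s)
        }
        attr(o, "decision") <- NULL
      }
    }
    n_since_checkpoint <- n_since_checkpoint + 1L
    if (!is.null(cfg$checkpoint_path) &&
        n_since_checkpoint >= cfg$checkpoint_every) {
      save_ontology(o, cfg$checkpoint_path)
      n_since_checkpoint <- 0L
    }
  }
  attr(o, "parked") <- parked
  o
}
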
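# run code under a local RNG state without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Fuzzy similarity score between two phrases
#'
#' Normalized Levenshtein similarity on a 0-100 scale:
#' `round(100 * (1 - D(a', b') / max(nchar(a'), nchar(b'))))` where `a'`,
#' `b'` are the normalized forms ([normalize_surface()]) and `D` the edit
#' distance. Two empty strings score 100; the score is symmetric, bounded in
#' \[0, 100\] and equals 100 exactly when the normalized forms are equal.
#' A masked symptom counts as recovered when the score against some
#' extracted phrase exceeds the recovery threshold (40 by default).
#'
#' @param a,b character scalars (empty allowed).
#' @return integer-valued numeric score in \[0, 100\].
#' @export
#' @examples
#' fuzzy_score("hot flashes", "Hot flashes")  # 100
#' fuzzy_score("nausea", "nauseas")           # 86
fuzzy_score <- function(a, b) {
  an <- normalize_surface(a)
  bn <- normalize_surface(b)
  L <- max(nchar(an), nchar(bn))
  if (L == 0L) return(100)
  d <- utils::adist(an, bn)[1, 1]
  round(100 * (1 - d / L))
}

# all-pairs score matrix (rows = a, cols = b) on normalized forms
fuzzy_score_matrix <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    return(matrix(numeric(0), nrow = length(a), ncol = length(b)))
  }
  an <- normalize_surface(a)
  bn <- normalize_surface(b)
  d <- utils::adist(an, bn)
  L <- outer(nchar(an), nchar(bn), pmax)
  sc <- round(100 * (1 - d / L))
  sc[L == 0] <- 100
  sc
}

#' Mask a fraction of each category's symptoms
#'
#' Per category, `ceiling(fraction * n)` members are removed uniformly at
#' random (capped so at least one member survives), producing the reduced
#' ontology plus an exact record of what was hidden. Deterministic for a
#' given seed. The recovery protocol then asks whether a run over text
#' re-discovers the hidden symptoms.
#'
#' @param o an [ontology()]; every category (group with members) must be
#'   non-empty.
#' @param fraction proportion of members to hide, in (0, 1); default 0.6.
#' @param seed integer seed.
#' @return list with elements `ontology` (masked) and `record` (class
#'   `mask_record`: `masked` = named list category -> removed surfaces,
#'   `fraction`, `seed`).
#' @export
mask_ontology <- function(o, fraction = 0.6, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  empty <- character()
  walk_groups(o$root, function(g, path) {
    if (length(g$members) == 0L && length(g$children) == 0L) {
      empty[[length(empty) + 1L]] <<- g$name
    }
  })
  if (length(empty) > 0L) {
    stop(sprintf("cannot mask: empty categories %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  masked <- list()
  with_local_seed(seed, {
    prune <- function(g) {
      n <- length(g$members)
      if (n > 0L) {
        k <- min(ceiling(fraction * n), n - 1L)
        if (k > 0L) {
          drop_idx <- sort(sample.int(n, k))
          masked[[g$name]] <<- vapply(g$members[drop_idx],
                                      function(m) m$surface, character(1))
          g$members <- g$members[-drop_idx]
        }
      }
      g$children <- lapply(g$children, prune)
      g
    }
    o$root <- prune(o$root)
  })
  list(
    ontology = validate_ontology(o),
    record = structure(list(masked = masked, fraction = fraction,
                            seed = as.integer(seed)),
                       class = "mask_record")
  )
}

#' Write / read a mask record as JSON
#'
#' @param record a `mask_record`.
#' @param path JSON path.
#' @return `path` (write) or the `mask_record` (read).
#' @export
write_mask_record <- function(record, path) {
  stopifnot(inherits(record, "mask_record"))
  jsonlite::write_json(
    list(masked = record$masked, fraction = record$fraction,
         seed = record$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_record
#' @export
read_mask_record <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(masked = lapply(raw$masked, as.character),
                 fraction = raw$fraction, seed = as.integer(raw$seed)),
            class = "mask_record")
}

#' Harmonic-mean F1 from precision and recall percentages
#'
#' @param pr,re percentages in \[0, 100\] (vectorized).
#' @return `2 * pr * re / (pr + re)` rounded to one decimal; 0 where
#'   `pr + re` is 0.
#' @export
#' @examples
#' f1_harmonic(62.5, 100)  # 76.9
f1_harmonic <- function(pr, re) {
  if (any(pr < 0 | pr > 100 | re < 0 | re > 100, na.rm = TRUE)) {
    stop("precision and recall must lie in [0, 100]", call. = FALSE)
  }
  out <- ifelse(pr + re == 0, 0, 2 * pr * re / (pr + re))
  round(out, 1)
}

#' Score masked-symptom recovery
#'
#' Per masked category C, let A be the extracted-provenance entities of C in
#' the extended ontology (deduplicated by normalized form) and M the
#' surfaces hidden by [mask_ontology()]. Then
#' \itemize{
#'   \item recall = 100 x |masked symptoms recovered by some extracted
#'     entity with fuzzy score > threshold| / |M|;
#'   \item precision = 100 x |extracted entities matching some masked
#'     symptom| / |A| (0 when A is empty);
#'   \item F1 = harmonic mean of the two.
#' }
#' Matching is many-to-many and scoped to the category by default; with
#' `scope = "global"` extracted entities from any category may recover a
#' masked symptom.
#'
#' @param extended the pipeline's output [ontology()].
#' @param record a `mask_record` from [mask_ontology()].
#' @param threshold recovery fuzzy-score threshold (strictly exceeded);
#'   default 40.
#' @param scope `"category"` (default) or `"global"`.
#' @return object of class `eval_report`: `per_category` data.frame with
#'   columns `category`, `n_masked`, `n_extracted`, `precision`, `recall`,
#'   `f1`; `matches` (best-scoring recovered pair per masked symptom);
#'   `threshold`; `scope`.
#' @export
recovery_metrics <- function(extended, record, threshold = 40,
                             scope = c("category", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(record, "mask_record"))
  tab <- ontology_members(extended)
  tab <- tab[tab$provenance == "extracted", , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$group, tab$normalized, sep = "\x1f")), ,
             drop = FALSE]
  cats <- names(record$masked)
  rows <- vector("list", length(cats))
  matches <- list()
  for (i in seq_along(cats)) {
    cat_name <- cats[[i]]
    M <- record$masked[[cat_name]]
    A <- if (scope == "category") {
      tab$surface[tab$group == cat_name]
    } else {
      tab$surface
    }
    A <- A[!duplicated(normalize_surface(A))]
    if (length(A) == 0L) {
      pr <- 0; re <- 0
    } else {
      sc <- fuzzy_score_matrix(M, A)
      recovered <- apply(sc, 1, function(r) any(r > threshold))
      relevant <- apply(sc, 2, function(cc) any(cc > threshold))
      re <- 100 * sum(recovered) / length(M)
      pr <- 100 * sum(relevant) / length(A)
      for (j in which(recovered)) {
        best <- which.max(sc[j, ])
        matches[[length(matches) + 1L]] <- data.frame(
          category = cat_name, masked = M[[j]], recovered = A[[best]],
          score = sc[j, best], stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- data.frame(
      category = cat_name, n_masked = length(M), n_extracted = length(A),
      precision = round(pr, 1), recall = round(re, 1),
      f1 = f1_harmonic(round(pr, 1), round(re, 1)),
      stringsAsFactors = FALSE)
  }
  structure(
    list(per_category = do.call(rbind, rows),
         matches = if (length(matches)) do.call(rbind, matches) else
           data.frame(category = character(), masked = character(),
                      recovered = character(), score = numeric()),
         threshold = threshold, scope = scope),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<recovery report> threshold %s, %s matching\n",
              x$threshold, x$scope))
  print(x$per_category, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report an `eval_report`.
#' @param csv_path optional CSV path (one row per category: PR, RE, F1).
#' @param json_path optional JSON path including match details.
#' @return the report, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_category, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(threshold = report$threshold, scope = report$scope,
           per_category = report$per_category, matches = report$matches),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}

#' Run the recovery protocol with named agents disabled
#'
#' Re-runs the stream with the duplication-check and/or verification roles
#' switched off and scores recovery against the same mask record, labeling
#' the report with the ablation. Dropping the duplication check can only
#' grow the extracted set, which inflates recall at the cost of precision.
#'
#' @param o the masked [ontology()] the run starts from.
#' @param items sentence stream (see [run_stream()]).
#' @param cfg a [run_config()]; its enable flags are overridden by `drop`.
#' @param drop subset of `c("f4", "f6")` naming the agents to disable.
#' @param record the `mask_record` to score against.
#' @param threshold recovery threshold (default 40).
#' @return an `eval_report` with an `ablation` field; the extended ontology
#'   is attached as attribute `ontology`.
#' @export
run_ablation <- function(o, items, cfg, drop = character(), record,
                         threshold = 40) {
  stopifnot(all(drop %in% c("f4", "f6")))
  cfg$enable_f4 <- !("f4" %in% drop)
  cfg$enable_f6 <- !("f6" %in% drop)
  extended <- run_stream(o, items, cfg)
  report <- recovery_metrics(extended, record, threshold = threshold)
  report$ablation <- drop
  attr(report, "ontology") <- extended
  report
}

#' Baseline ontology-extension strategies
#'
#' Two simpler strategies the multi-agent loop is compared against:
#' \describe{
#'   \item{separated}{entity extraction first over the whole stream
#'     (identification + extraction roles), then a single
#'     ontology-extension pass over the extracted batch — classification
#'     only, with no duplication check or verification.}
#'   \item{single_agent}{the stream is chunked to a context budget; each
#'     chunk together with the current flat-dialect ontology is submitted
#'     to the backend in one shot, and the returned dictionary becomes the
#'     current ontology. With the oracle backend the one-shot call is
#'     stood in by a lexicon scan of the chunk.}
#' }
#'
#' @param kind `"separated"` or `"single_agent"`.
#' @param o the starting [ontology()].
#' @param items sentence stream.
#' @param cfg a [run_config()].
#' @param context_budget character budget per chunk for `single_agent`
#'   (default 4000).
#' @return the extended ontology. For `separated`, attribute `extracted`
#'   carries the extracted entity multiset; for `single_agent`, attribute
#'   `n_chunks` the number of iterations.
#' @export
run_baseline <- function(kind = c("separated", "single_agent"), o, items,
                         cfg, context_budget = 4000L) {
  kind <- match.arg(kind)
  if (is.character(items)) {
    items <- stream_frame(sprintf("s%04d", seq_along(items)), items,
                          NA_character_)
  }
  b <- cfg$backend
  if (kind == "separated") {
    extracted <- character()
    for (i in seq_len(nrow(items))) {
      if (isTRUE(agent_identify(b, items$sentence[[i]]))) {
        extracted <- c(extracted, agent_extract(b, items$sentence[[i]]))
      }
    }
    for (s in extracted) {
      target <- agent_classify(b, s, o)
      if (is.na(target)) {
        proposed <- agent_generate_relation(b, s)
        if (is.na(proposed)) next
        target <- match_group_name(o, proposed)
        if (is.na(target)) {
          o <- create_group(o, NULL, proposed)
          target <- proposed
        }
      }
      o <- add_symptom(o, target, symptom(s, provenance = "extracted"))
    }
    attr(o, "extracted") <- extracted
    return(o)
  }
  # single_agent: chunk sentences to the context budget
  chunks <- list()
  current <- character()
  used <- 0L
  for (i in seq_len(nrow(items))) {
    len <- nchar(items$sentence[[i]]) + 1L
    if (length(current) > 0L && used + len > context_budget) {
      chunks[[length(chunks) + 1L]] <- current
      current <- character(); used <- 0L
    }
    current <- c(current, items$sentence[[i]])
    used <- used + len
  }
  if (length(current) > 0L) chunks[[length(chunks) + 1L]] <- current
  for (chunk in chunks) {
    o <- single_agent_step(b, o, chunk)
  }
  attr(o, "n_chunks") <- length(chunks)
  o
}

single_agent_step <- function(b, o, chunk) {
  if (inherits(b, "oracle_backend")) {
    # oracle stand-in for the one-shot call: scan the chunk for lexicon
    # forms and fold them into the dictionary under their lexicon category
    for (sentence in chunk) {
      for (s in names(lexicon_hits(b$lexicon, sentence))) {
        target <- lexicon_category(b$lexicon, s)
        if (is.na(match_group_name(o, target))) {
          o <- create_group(o, NULL, target)
        }
        o <- add_symptom(o, match_group_name(o, target),
                         symptom(s, provenance = "extracted"))
      }
    }
    return(o)
  }
  system <- paste(
    "You maintain a symptom dictionary. Given forum text and the current",
    "symptom_dictionary.json, return the extended dictionary as JSON in the",
    "same shape, keeping all existing entries. No explanation.")
  user <- paste("Text:", paste(chunk, collapse = " "),
                "symptom_dictionary.json:",
                level_dictionary_json(o$root$children))
  raw <- tryCatch(as.character(b$transport("single_agent", "strong",
                                           system, user))[1],
                  error = function(e) NA_character_)
  parsed <- tryCatch({
    open <- regexpr("\\{", raw)[1]
    close <- max(gregexpr("\\}", raw)[[1]])
    parse_ontology_json(jsonlite::fromJSON(substr(raw, open, close),
                                           simplifyVector = FALSE))
  }, error = function(e) NULL)
  if (is.null(parsed)) return(o)  # unparseable chunk: skipped
  merge_flat(o, parsed)
}

# fold the categories/members of `incoming` into `o`, marking novel content
# as extracted/generated
merge_flat <- function(o, incoming) {
  before <- ontology_members(o)
  key <- paste(before$group, before$normalized, sep = "\x1f")
  for (g in incoming$root$children) {
    target <- match_group_name(o, g$name)
    if (is.na(target)) {
      o <- create_group(o, NULL, g$name)
      target <- g$name
    }
    for (m in g$members) {
      if (!(paste(target, m$normalized, sep = "\x1f") %in% key)) {
        o <- add_symptom(o, target,
                         symptom(m$surface, provenance = "extracted"))
      }
    }
  }
  o
}
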
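#' Load an ontology from JSON
#'
#' Two dialects are accepted and auto-detected:
#' \describe{
#'   \item{flat}{a JSON object mapping category names to arrays of symptom
#'     strings (the `symptom_dictionary.json` shape used in agent prompts);
#'     expresses one level of categories.}
#'   \item{full}{a recursive object `{name, provenance, members, children}`
#'     for hierarchies of any depth; members carry `surface`, `provenance`
#'     and optionally `source_ref`.}
#' }
#' Input ordering of categories and members is preserved. A duplicate
#' normalized member within a category is a validation error.
#'
#' @param path path to a UTF-8 JSON file.
#' @return an [ontology()].
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("ontology file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("malformed ontology JSON in %s: %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  parse_ontology_json(raw)
}

parse_ontology_json <- function(raw) {
  if (!is.list(raw)) {
    stop("ontology JSON must be an object at the top level", call. = FALSE)
  }
  if (length(raw) == 0L) return(ontology())
  if (is_full_dialect(raw)) {
    return(ontology(list_of_groups(raw$children %||% list())))
  }
  # flat dialect: category name -> array of strings
  if (is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("flat ontology JSON must map category names to symptom lists",
         call. = FALSE)
  }
  groups <- lapply(names(raw), function(nm) {
    val <- raw[[nm]]
    if (!is.list(val) && !is.character(val)) {
      stop(sprintf("category '%s' must map to a list of symptom strings", nm),
           call. = FALSE)
    }
    surfaces <- vapply(val, function(s) {
      if (!is.character(s) || length(s) != 1L) {
        stop(sprintf("non-string symptom entry under category '%s'", nm),
             call. = FALSE)
      }
      s
    }, character(1))
    members <- lapply(surfaces, symptom, provenance = "seed")
    norms <- vapply(members, function(m) m$normalized, character(1))
    if (anyDuplicated(norms)) {
      stop(sprintf("duplicate symptom '%s' within category '%s'",
                   norms[duplicated(norms)][1], nm), call. = FALSE)
    }
    symptom_group(nm, members = members)
  })
  ontology(groups)
}

is_full_dialect <- function(raw) {
  !is.null(names(raw)) && all(c("name", "children") %in% names(raw))
}

list_of_groups <- function(lst) {
  lapply(lst, function(node) {
    if (!is.list(node) || is.null(node$name)) {
      stop("full-dialect group node must carry a 'name'", call. = FALSE)
    }
    members <- lapply(node$members %||% list(), function(m) {
      symptom(m$surface,
              provenance = m$provenance %||% "seed",
              source_ref = m$source_ref)
    })
    symptom_group(
      node$name,
      members = members,
      children = list_of_groups(node$children %||% list()),
      provenance = node$provenance %||% "seed"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save an ontology to JSON
#'
#' @param o an [ontology()].
#' @param path output path.
#' @param dialect `"flat"` writes the category-to-symptom-list dictionary
#'   (only for ontologies of depth <= 1; provenance is dropped), `"full"`
#'   writes the recursive dialect preserving provenance and source
#'   references, `"auto"` (default) picks flat when the depth permits.
#' @return `path`, invisibly. Loading the written file reproduces the
#'   ontology: exactly under the full dialect, up to provenance under flat.
#' @export
save_ontology <- function(o, path, dialect = c("auto", "flat", "full")) {
  dialect <- match.arg(dialect)
  validate_ontology(o)
  if (dialect == "auto") {
    dialect <- if (ontology_depth(o) <= 1L) "flat" else "full"
  }
  if (dialect == "flat" && ontology_depth(o) > 1L) {
    stop("flat dialect cannot represent an ontology of depth > 1",
         call. = FALSE)
  }
  json <- if (dialect == "flat") flat_json(o) else full_json(o)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

flat_json <- function(o) {
  groups <- o$root$children
  if (length(groups) == 0L) return("{}")
  obj <- stats::setNames(
    lapply(groups, function(g) {
      vapply(g$members, function(m) m$surface, character(1))
    }),
    vapply(groups, function(g) g$name, character(1))
  )
  jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE)
}

full_json <- function(o) {
  as_node <- function(g) {
    node <- list(
      name = jsonlite::unbox(g$name),
      provenance = jsonlite::unbox(g$provenance),
      members = lapply(g$members, function(m) {
        rec <- list(surface = jsonlite::unbox(m$surface),
                    provenance = jsonlite::unbox(m$provenance))
        if (!is.null(m$source_ref)) {
          rec$source_ref <- jsonlite::unbox(m$source_ref)
        }
        rec
      }),
      children = lapply(g$children, as_node)
    )
    node
  }
  jsonlite::toJSON(
    list(name = jsonlite::unbox(ROOT_NAME),
         provenance = jsonlite::unbox("seed"),
         members = list(),
         children = lapply(o$root$children, as_node)),
    pretty = TRUE
  )
}
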
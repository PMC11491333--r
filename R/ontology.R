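#' Normalize a symptom surface form
#'
#' Canonical form used for all comparisons: lower case, internal whitespace
#' collapsed to single spaces, leading/trailing whitespace and punctuation
#' stripped. Normalization is a pure function of the surface string.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized forms.
#' @export
#' @examples
#' normalize_surface("  Hot   Flashes! ")
normalize_surface <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  trimws(x)
}

#' Construct a symptom entity
#'
#' A symptom is a single phrase (e.g. "Hot flashes") that belongs to exactly
#' one symptom group. The normalized form is derived from the surface and is
#' what membership and duplication comparisons operate on.
#'
#' @param surface verbatim symptom phrase; must be non-empty after trimming.
#' @param provenance `"seed"` for symptoms present in the initial ontology,
#'   `"extracted"` for symptoms added from the stream.
#' @param source_ref optional id of the stream item that produced it.
#' @return an object of class `symptom`.
#' @export
symptom <- function(surface, provenance = c("seed", "extracted"),
                    source_ref = NULL) {
  provenance <- match.arg(provenance)
  surface <- as.character(surface)
  if (length(surface) != 1L || is.na(surface) || !nzchar(trimws(surface))) {
    stop("symptom surface must be a single non-empty string", call. = FALSE)
  }
  structure(
    list(
      surface = surface,
      normalized = normalize_surface(surface),
      provenance = provenance,
      source_ref = source_ref
    ),
    class = "symptom"
  )
}

#' Construct a symptom group (cluster)
#'
#' A group is a category node such as "Vasomotor symptoms": an ordered set of
#' member symptoms plus, for hierarchies deeper than one level, an ordered
#' set of child groups. Member normalized forms must be unique within the
#' group and child names unique among siblings.
#'
#' @param name category label.
#' @param members list of [symptom()] objects.
#' @param children list of `symptom_group` objects.
#' @param provenance `"seed"` or `"generated"` (created by the pipeline).
#' @return an object of class `symptom_group`.
#' @export
symptom_group <- function(name, members = list(), children = list(),
                          provenance = c("seed", "generated")) {
  provenance <- match.arg(provenance)
  name <- as.character(name)
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    stop("group name must be a single non-empty string", call. = FALSE)
  }
  g <- structure(
    list(name = name, members = members, children = children,
         provenance = provenance),
    class = "symptom_group"
  )
  validate_group(g)
  g
}

validate_group <- function(g) {
  norms <- vapply(g$members, function(m) m$normalized, character(1))
  if (anyDuplicated(norms)) {
    stop(sprintf("duplicate member '%s' in group '%s'",
                 norms[duplicated(norms)][1], g$name), call. = FALSE)
  }
  kid_names <- vapply(g$children, function(k) k$name, character(1))
  if (anyDuplicated(kid_names)) {
    stop(sprintf("duplicate child group name '%s' under '%s'",
                 kid_names[duplicated(kid_names)][1], g$name), call. = FALSE)
  }
  invisible(g)
}

ROOT_NAME <- ".root"

#' Construct an ontology
#'
#' The ontology is a rooted tree of symptom groups holding symptom entities.
#' A synthetic root (never serialized) holds the top-level categories; the
#' depth is the length of the longest root-to-leaf path counted in group
#' levels, so a flat category-to-symptoms dictionary has depth 1 and an empty
#' ontology depth 0.
#'
#' @param groups list of top-level [symptom_group()] objects.
#' @return an object of class `ontology`.
#' @export
ontology <- function(groups = list()) {
  root <- symptom_group(ROOT_NAME, members = list(), children = groups)
  o <- structure(list(root = root), class = "ontology")
  validate_ontology(o)
  o
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> depth %d, %d groups, %d symptoms\n",
              ontology_depth(x), length(group_names(x)),
              nrow(ontology_members(x))))
  for (g in x$root$children) {
    cat(sprintf("  %s (%d members%s)\n", g$name, length(g$members),
                if (length(g$children)) sprintf(", %d subgroups",
                                                length(g$children)) else ""))
  }
  invisible(x)
}

walk_groups <- function(g, fn, path = character()) {
  # preorder traversal over groups, excluding the synthetic root
  for (k in g$children) {
    fn(k, c(path, k$name))
    walk_groups(k, fn, c(path, k$name))
  }
  invisible(NULL)
}

#' Depth of an ontology
#'
#' @param o an [ontology()].
#' @return integer: longest root-to-leaf path in group levels (0 when empty).
#' @export
ontology_depth <- function(o) {
  depth_of <- function(g) {
    if (length(g$children) == 0L) return(0L)
    1L + max(vapply(g$children, depth_of, integer(1)))
  }
  depth_of(o$root)
}

#' All group names of an ontology (preorder)
#' @param o an [ontology()].
#' @return character vector of group names.
#' @export
group_names <- function(o) {
  out <- character()
  walk_groups(o$root, function(g, path) out[[length(out) + 1L]] <<- g$name)
  out
}

#' Flat table of ontology membership
#'
#' One row per (group, symptom) membership edge.
#'
#' @param o an [ontology()].
#' @return data.frame with columns `group`, `surface`, `normalized`,
#'   `provenance`.
#' @export
ontology_members <- function(o) {
  rows <- list()
  walk_groups(o$root, function(g, path) {
    for (m in g$members) {
      rows[[length(rows) + 1L]] <<- data.frame(
        group = g$name, surface = m$surface, normalized = m$normalized,
        provenance = m$provenance, stringsAsFactors = FALSE
      )
    }
  })
  if (length(rows) == 0L) {
    return(data.frame(group = character(), surface = character(),
                      normalized = character(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

validate_ontology <- function(o) {
  stopifnot(inherits(o, "ontology"))
  seen <- new.env(parent = emptyenv())
  check <- function(g, path) {
    validate_group(g)
    key <- paste(path, collapse = "\x1f")
    if (!is.null(seen[[key]])) {
      stop("cycle or repeated path in ontology tree", call. = FALSE)
    }
    seen[[key]] <- TRUE
    if (length(path) > 10000L) stop("ontology tree too deep", call. = FALSE)
  }
  walk_groups(o$root, check)
  invisible(o)
}

# Path (vector of child indices from root) to the first group named `name`
# in preorder, or NULL. Group names are only required to be unique among
# siblings; lookup by bare name resolves to the first preorder match.
find_group_path <- function(o, name) {
  found <- NULL
  search <- function(g, idx_path) {
    for (i in seq_along(g$children)) {
      if (!is.null(found)) return(invisible(NULL))
      k <- g$children[[i]]
      if (identical(k$name, name)) {
        found <<- c(idx_path, i)
        return(invisible(NULL))
      }
      search(k, c(idx_path, i))
    }
  }
  search(o$root, integer())
  found
}

get_group_at <- function(o, idx_path) {
  g <- o$root
  for (i in idx_path) g <- g$children[[i]]
  g
}

#' Fetch a group by name
#' @param o an [ontology()].
#' @param name group name (first preorder match).
#' @return the `symptom_group`, or an error if absent.
#' @export
get_group <- function(o, name) {
  p <- find_group_path(o, name)
  if (is.null(p)) {
    stop(sprintf("no group named '%s'; known groups: %s", name,
                 paste(group_names(o), collapse = ", ")), call. = FALSE)
  }
  get_group_at(o, p)
}

modify_group_at <- function(o, idx_path, fn) {
  rebuild <- function(g, path) {
    if (length(path) == 0L) return(fn(g))
    i <- path[[1]]
    g$children[[i]] <- rebuild(g$children[[i]], path[-1])
    g
  }
  o$root <- rebuild(o$root, idx_path)
  o
}

#' Add a symptom to a named group
#'
#' Appends the symptom to the group's members unless a member with the same
#' normalized form is already present, in which case the ontology is returned
#' unchanged. No other part of the tree is touched, so repeated application
#' is idempotent and the operation is monotone (content is never removed).
#'
#' @param o an [ontology()].
#' @param group_name name of an existing group.
#' @param s a [symptom()].
#' @return the updated ontology.
#' @export
add_symptom <- function(o, group_name, s) {
  stopifnot(inherits(s, "symptom"))
  p <- find_group_path(o, group_name)
  if (is.null(p)) {
    stop(sprintf("no group named '%s'; known groups: %s", group_name,
                 paste(group_names(o), collapse = ", ")), call. = FALSE)
  }
  modify_group_at(o, p, function(g) {
    norms <- vapply(g$members, function(m) m$normalized, character(1))
    if (s$normalized %in% norms) return(g)
    g$members[[length(g$members) + 1L]] <- s
    g
  })
}

#' Create a new (empty) group under a parent
#'
#' The new group carries provenance `"generated"`. Creating a group whose
#' name already exists among the parent's children is a validation error.
#'
#' @param o an [ontology()].
#' @param parent_name name of the parent group, or `NULL` for the top level.
#' @param new_name name of the group to create.
#' @return the updated ontology.
#' @export
create_group <- function(o, parent_name, new_name) {
  if (is.null(parent_name) || identical(parent_name, ROOT_NAME)) {
    p <- integer()
  } else {
    p <- find_group_path(o, parent_name)
    if (is.null(p)) {
      stop(sprintf("no group named '%s'; known groups: %s", parent_name,
                   paste(group_names(o), collapse = ", ")), call. = FALSE)
    }
  }
  modify_group_at(o, p, function(g) {
    kid_names <- vapply(g$children, function(k) k$name, character(1))
    if (new_name %in% kid_names) {
      stop(sprintf("a group named '%s' already exists under '%s'",
                   new_name,
                   if (identical(g$name, ROOT_NAME)) "the root" else g$name),
           call. = FALSE)
    }
    g$children[[length(g$children) + 1L]] <-
      symptom_group(new_name, provenance = "generated")
    g
  })
}

#' Look up a group name case- and format-insensitively
#'
#' Matches on the normalized form of the name; used when an agent proposes a
#' category whose spelling differs only in case or punctuation from an
#' existing group.
#'
#' @param o an [ontology()].
#' @param name proposed name.
#' @return the canonical existing group name, or `NA_character_`.
#' @export
match_group_name <- function(o, name) {
  target <- normalize_surface(name)
  nms <- group_names(o)
  hit <- nms[normalize_surface(nms) == target]
  if (length(hit) == 0L) NA_character_ else hit[[1]]
}
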
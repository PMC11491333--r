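# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (plain dynamic programming, brute-force scans) so they
# never share a code path with the implementation they check.

# textbook DP Levenshtein distance
dp_levenshtein <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in 1:na) {
    cur <- c(i, integer(nb))
    for (j in 1:nb) {
      cost <- if (av[i] == bv[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1L]
}

# fuzzy score recomputed from the DP distance and the stated formula
oracle_fuzzy <- function(a, b) {
  an <- normalize_surface(a)
  bn <- normalize_surface(b)
  L <- max(nchar(an), nchar(bn))
  if (L == 0L) return(100)
  round(100 * (1 - dp_levenshtein(an, bn) / L))
}

random_phrase <- function(min_len = 1, max_len = 14) {
  n <- sample(min_len:max_len, 1)
  paste(sample(c(letters, " ", " "), n, replace = TRUE), collapse = "")
}

# random valid ontology built straight from the constructors
random_ontology <- function(max_depth = 3) {
  counter <- new.env(parent = emptyenv())
  counter$g <- 0L; counter$s <- 0L
  mk_member <- function() {
    counter$s <- counter$s + 1L
    symptom(sprintf("symptom %03d", counter$s),
            provenance = sample(c("seed", "extracted"), 1),
            source_ref = if (stats::runif(1) < 0.3)
              sprintf("s%04d", counter$s) else NULL)
  }
  mk_group <- function(depth) {
    counter$g <- counter$g + 1L
    members <- lapply(seq_len(sample(0:3, 1)), function(i) mk_member())
    kids <- if (depth < max_depth && stats::runif(1) < 0.4) {
      lapply(seq_len(sample(1:2, 1)), function(i) mk_group(depth + 1L))
    } else list()
    symptom_group(sprintf("Group %03d symptoms", counter$g),
                  members = members, children = kids,
                  provenance = sample(c("seed", "generated"), 1))
  }
  ontology(lapply(seq_len(sample(1:4, 1)), function(i) mk_group(1L)))
}

# canonical byte representation for exact ontology comparison
ont_bytes <- function(o) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_ontology(o, tf, dialect = "full")
  paste(readLines(tf, warn = FALSE), collapse = "\n")
}

# brute-force word-bounded scan of a sentence stream for a set of phrases;
# returns one row per (sentence, phrase) hit
brute_scan <- function(items, phrases) {
  esc <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
  hits <- list()
  for (i in seq_len(nrow(items))) {
    s <- tolower(gsub("[[:space:]]+", " ", items$sentence[[i]]))
    for (p in phrases) {
      if (grepl(paste0("\\b", esc(tolower(p)), "\\b"), s, perl = TRUE)) {
        hits[[length(hits) + 1L]] <- data.frame(
          id = items$id[[i]], phrase = tolower(p), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(id = character(), phrase = character()))
  }
  do.call(rbind, hits)
}

# normalized (group, member) pair set for order-insensitive comparisons
pair_set <- function(o) {
  tab <- ontology_members(o)
  sort(paste(tab$group, tab$normalized, sep = " :: "))
}

fixture_depth3 <- function() {
  # two-level hierarchy for routing tests
  ontology(list(
    symptom_group("Somatic symptoms", children = list(
      symptom_group("Vasomotor symptoms",
                    members = list(symptom("Hot flashes"),
                                   symptom("Sweating"))),
      symptom_group("Musculoskeletal symptoms",
                    members = list(symptom("Joint pain")))
    )),
    symptom_group("Psychologic symptoms", children = list(
      symptom_group("Distress symptoms",
                    members = list(symptom("Nervousness")))
    ))
  ))
}
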
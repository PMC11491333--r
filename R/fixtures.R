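#' Packaged breast-cancer-survivor symptom ontology
#'
#' Nine top-level categories of symptoms reported by breast cancer
#' survivors (gastrointestinal, gynecologic, neuropsychologic, vasomotor,
#' musculoskeletal, integumentary, cardiorespiratory, distress and despair
#' symptoms), each seeded with two representative symptoms — 18 entities in
#' a depth-1 hierarchy. Ships with the package as
#' `extdata/symptom_ontology.json` in the flat dictionary dialect.
#'
#' @return an [ontology()] with 9 groups and 18 symptoms.
#' @export
#' @examples
#' o <- example_ontology()
#' group_names(o)
example_ontology <- function() {
  load_ontology(system.file("extdata", "symptom_ontology.json",
                            package = "ontoStream", mustWork = TRUE))
}

#' Lexicon derived from the packaged symptom ontology
#'
#' Maps each of the 18 seed symptoms to its category; the default ground
#' truth for the oracle backend and the synthetic corpus generator.
#'
#' @return a [lexicon()].
#' @export
example_lexicon <- function() {
  lexicon_from_ontology(example_ontology())
}
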
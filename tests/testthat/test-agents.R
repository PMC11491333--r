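fixture_backend <- function(dup_threshold = 90) {
  oracle_backend(example_lexicon(), dup_threshold = dup_threshold)
}

test_that("oracle identification requires a word-bounded lexicon hit", {
  b <- fixture_backend()
  expect_true(agent_identify(b, "I get hot flashes at night"))
  expect_false(agent_identify(b, "The weather is nice"))
  # word boundary: concatenated form does not count
  expect_false(agent_identify(b, "hotflashes ruined my day"))
  # ... and the brute-force scan agrees on all three
  items <- data.frame(id = c("a", "b", "c"),
                      sentence = c("I get hot flashes at night",
                                   "The weather is nice",
                                   "hotflashes ruined my day"),
                      stringsAsFactors = FALSE)
  hits <- brute_scan(items, names(example_lexicon()$entries))
  expect_identical(hits$id, "a")
})

test_that("oracle extraction returns lexicon forms in first-occurrence order, deduplicated", {
  b <- fixture_backend()
  out <- agent_extract(b, "sweating and hot flashes and sweating all week")
  expect_identical(out, c("sweating", "hot flashes"))
  out2 <- agent_extract(b, "nausea nausea nausea")
  expect_identical(out2, "nausea")
})

test_that("oracle classification maps through the lexicon into existing groups only", {
  b <- fixture_backend()
  o <- example_ontology()
  expect_identical(agent_classify(b, "hot flashes", o), "Vasomotor symptoms")
  expect_identical(agent_classify(b, "Nausea", o),
                   "Gastrointestinal symptoms")
  # lexicon category missing from the ontology -> absent
  small <- ontology(list(symptom_group("Distress symptoms",
                                       members = list(symptom("Nervousness")))))
  expect_identical(agent_classify(b, "hot flashes", small), NA_character_)
  # unknown symptom -> absent (closed world)
  expect_identical(agent_classify(b, "quantum gravity", o), NA_character_)
})

test_that("classification resolves to leaf groups in deeper hierarchies", {
  b <- fixture_backend()
  deep <- fixture_depth3()
  # lexicon says Vasomotor; the leaf group sits one level down
  expect_identical(agent_classify(b, "sweating", deep), "Vasomotor symptoms")
  expect_identical(agent_classify(b, "joint pain", deep),
                   "Musculoskeletal symptoms")
})

test_that("duplication check follows the fuzzy threshold, frozen against the DP oracle", {
  grp <- symptom_group("Vasomotor symptoms",
                       members = list(symptom("hot flashes")))
  b <- fixture_backend()
  expect_true(agent_is_duplicate(b, "Hot flashes", grp))     # score 100
  expect_false(agent_is_duplicate(b, "nausea",
                                  symptom_group("G symptoms",
                                                members = list(symptom("joint pain")))))
  # 'hot flash' vs 'hot flashes': distance 2 over max length 11 -> score 82
  expect_identical(oracle_fuzzy("hot flash", "hot flashes"), 82)
  expect_identical(fuzzy_score("hot flash", "hot flashes"), 82)
  expect_false(agent_is_duplicate(fixture_backend(90), "hot flash", grp))
  expect_true(agent_is_duplicate(fixture_backend(80), "hot flash", grp))
})

test_that("relation generation and verification answer from the lexicon", {
  b <- fixture_backend()
  expect_identical(agent_generate_relation(b, "nausea"),
                   "Gastrointestinal symptoms")
  lex2 <- lexicon(c("urinary urgency" = "Urinary symptoms"))
  b2 <- oracle_backend(lex2)
  expect_identical(agent_generate_relation(b2, "urinary urgency"),
                   "Urinary symptoms")
  expect_true(agent_verify(b, "Vasomotor symptoms", "sweating"))
  expect_false(agent_verify(b, "Vasomotor symptoms", "nausea"))
  expect_false(agent_verify(b, "Vasomotor symptoms", "unknown thing"))
})

test_that("the oracle backend is deterministic and logs one record per call", {
  set.seed(403)
  b1 <- fixture_backend()
  b2 <- fixture_backend()
  o <- example_ontology()
  sentences <- replicate(30, random_phrase(5, 40))
  for (s in sentences) {
    expect_identical(agent_identify(b1, s), agent_identify(b2, s))
    expect_identical(agent_extract(b1, s), agent_extract(b2, s))
    expect_identical(agent_classify(b1, s, o), agent_classify(b2, s, o))
  }
  expect_length(decision_log(b1), 90)
  expect_identical(
    vapply(decision_log(b1), `[[`, character(1), "role")[1:3],
    c("identify", "extract", "classify"))
})

test_that("yes/no parsing tolerates decoration and rejects ambiguity", {
  expect_true(parse_yes_no("Yes"))
  expect_true(parse_yes_no("  'yes.'"))
  expect_true(parse_yes_no("Answer: YES, definitely"))
  expect_false(parse_yes_no("no"))
  expect_false(parse_yes_no("No."))
  expect_null(parse_yes_no("maybe"))
  expect_null(parse_yes_no(""))
})

test_that("bracketed-list parsing covers the usual response shapes", {
  expect_identical(parse_bracketed_list("['nausea', 'joint pain']"),
                   c("nausea", "joint pain"))
  expect_identical(parse_bracketed_list('["hot flashes"]'), "hot flashes")
  expect_identical(parse_bracketed_list("Sure: ['rash'] hope that helps"),
                   "rash")
  expect_identical(parse_bracketed_list("[]"), character())
  expect_null(parse_bracketed_list("no list here"))
  expect_null(parse_bracketed_list("[nausea]"))  # unquoted items
})

test_that("category canonicalization enforces the '<X> symptoms' pattern", {
  cases <- list(
    c("gastrointestinal symptom", "Gastrointestinal symptoms"),
    c("Gastrointestinal symptoms.", "Gastrointestinal symptoms"),
    c("'Vasomotor Symptoms'", "Vasomotor symptoms"),
    c("urinary", "Urinary symptoms"),
    c("  despair   symptoms ", "Despair symptoms")
  )
  for (cs in cases) expect_identical(canonicalize_category(cs[1]), cs[2])
  expect_null(canonicalize_category("  "))
})

test_that("parsers never raise on arbitrary text", {
  set.seed(404)
  for (i in 1:200) {
    junk <- random_phrase(0, 30)
    expect_no_error(parse_yes_no(junk))
    expect_no_error(parse_bracketed_list(junk))
    expect_no_error(canonicalize_category(junk))
  }
})

test_that("the llm backend parses stubbed transports and retries malformed answers", {
  canned <- function(responses) {
    i <- 0L
    function(role, model, system, user) {
      i <<- i + 1L
      responses[[min(i, length(responses))]]
    }
  }
  b <- llm_backend(canned(list("Yes.")))
  expect_true(agent_identify(b, "I get hot flashes"))
  b2 <- llm_backend(canned(list("hmm", "garbage", "no")))
  expect_false(agent_identify(b2, "anything"))    # recovered on 3rd attempt
  expect_length(decision_log(b2), 1)
  b3 <- llm_backend(canned(list("['nausea', 'joint pain']")))
  expect_identical(agent_extract(b3, "x"), c("nausea", "joint pain"))
})

test_that("llm protocol exhaustion degrades to the role-specific fallback", {
  always_junk <- function(role, model, system, user) "???"
  b <- llm_backend(always_junk, retries = 1)
  o <- example_ontology()
  expect_true(is.na(agent_identify(b, "sentence")))          # skip
  expect_null(agent_extract(b, "sentence"))                  # skip
  expect_identical(agent_classify(b, "nausea", o), NA_character_)
  grp <- get_group(o, "Vasomotor symptoms")
  expect_true(agent_is_duplicate(b, "nausea", grp))          # conservative
  expect_identical(agent_generate_relation(b, "nausea"), NA_character_)
  expect_false(agent_verify(b, "Vasomotor symptoms", "nausea"))  # reject
})

test_that("llm classification routes level by level and coerces hallucinated names", {
  seen_systems <- list()
  transport <- function(role, model, system, user) {
    seen_systems[[length(seen_systems) + 1L]] <<- system
    if (grepl("Somatic symptoms", system, fixed = TRUE)) "Somatic symptoms"
    else "Vasomotor symptoms"
  }
  b <- llm_backend(transport)
  expect_identical(agent_classify(b, "sweating", fixture_depth3()),
                   "Vasomotor symptoms")
  expect_length(seen_systems, 2)  # one ask per level, whole tree never sent
  expect_false(grepl("Joint pain", seen_systems[[1]], fixed = TRUE))

  b2 <- llm_backend(function(...) "Imaginary symptoms")
  expect_identical(agent_classify(b2, "sweating", example_ontology()),
                   NA_character_)
  b3 <- llm_backend(function(...) "No")
  expect_identical(agent_classify(b3, "stock prices", example_ontology()),
                   NA_character_)
})

test_that("model routing defaults send heavy roles to the strong tier", {
  seen <- character()
  b <- llm_backend(function(role, model, system, user) {
    seen[[length(seen) + 1L]] <<- model
    if (role %in% c("classify", "generate_relation")) "No" else "yes"
  })
  agent_identify(b, "s")
  agent_generate_relation(b, "some symptom")
  expect_identical(seen[1:2], c("cheap", "strong"))
})
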
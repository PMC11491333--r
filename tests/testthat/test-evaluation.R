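test_that("fuzzy score matches hand-derived cases", {
  expect_identical(fuzzy_score("hot flashes", "Hot flashes"), 100)
  expect_identical(fuzzy_score("", "x"), 0)
  expect_identical(fuzzy_score("", ""), 100)
  # distance 1 over max length 7 -> 100 * 6/7 rounds to 86
  expect_identical(fuzzy_score("nausea", "nauseas"), 86)
})

test_that("fuzzy score is symmetric, bounded and 100 iff normalized forms match", {
  set.seed(406)
  for (i in 1:200) {
    a <- random_phrase(0, 12)
    b <- random_phrase(0, 12)
    s <- fuzzy_score(a, b)
    expect_identical(s, fuzzy_score(b, a))
    expect_gte(s, 0); expect_lte(s, 100)
    expect_identical(s == 100,
                     normalize_surface(a) == normalize_surface(b))
  }
})

test_that("fuzzy score agrees with the independent DP oracle", {
  set.seed(407)
  for (i in 1:300) {
    a <- random_phrase(0, 14)
    b <- random_phrase(0, 14)
    expect_identical(fuzzy_score(a, b), oracle_fuzzy(a, b))
  }
})

test_that("masking removes the ceiling per category, capped to leave a survivor", {
  o <- example_ontology()  # 2 members per category
  m <- mask_ontology(o, 0.6, seed = 21)
  for (g in names(m$record$masked)) {
    expect_length(m$record$masked[[g]], 1)        # ceiling(1.2)=2 capped to 1
    expect_length(get_group(m$ontology, g)$members, 1)
  }
  # ceiling arithmetic without the cap: 10 members, fraction 0.6 -> 6 removed
  big <- ontology(list(symptom_group("Big symptoms",
    members = lapply(sprintf("sym %02d", 1:10), symptom))))
  mb <- mask_ontology(big, 0.6, seed = 21)
  expect_length(mb$record$masked[["Big symptoms"]], 6)
  expect_length(get_group(mb$ontology, "Big symptoms")$members, 4)
  # every masked surface existed pre-mask under that category
  expect_true(all(mb$record$masked[["Big symptoms"]] %in%
                    sprintf("sym %02d", 1:10)))
})

test_that("masking is deterministic in the seed and rejects empty categories", {
  o <- example_ontology()
  m1 <- mask_ontology(o, 0.6, seed = 22)
  m2 <- mask_ontology(o, 0.6, seed = 22)
  expect_identical(m1$record, m2$record)
  expect_identical(ont_bytes(m1$ontology), ont_bytes(m2$ontology))
  m3 <- mask_ontology(o, 0.6, seed = 23)
  expect_false(identical(m1$record, m3$record))
  withempty <- create_group(o, NULL, "Hollow symptoms")
  expect_error(mask_ontology(withempty, 0.6, seed = 1), "Hollow symptoms")
})

test_that("mask records survive a JSON round trip", {
  m <- mask_ontology(example_ontology(), 0.6, seed = 24)
  tf <- tempfile(fileext = ".json")
  write_mask_record(m$record, tf)
  back <- read_mask_record(tf)
  expect_identical(back$masked, m$record$masked)
  expect_identical(back$fraction, m$record$fraction)
  expect_identical(back$seed, m$record$seed)
})

test_that("recovery metrics score single-pair cases as the DP oracle predicts", {
  rec <- structure(list(masked = list("Gastrointestinal symptoms" = "nausea"),
                        fraction = 0.6, seed = 1L), class = "mask_record")
  ext_with <- add_symptom(example_ontology(), "Gastrointestinal symptoms",
                          symptom("nauseas", provenance = "extracted"))
  r1 <- recovery_metrics(ext_with, rec)
  expect_identical(oracle_fuzzy("nausea", "nauseas"), 86)  # 86 > 40
  expect_identical(r1$per_category$recall, 100)
  expect_identical(r1$per_category$precision, 100)
  expect_identical(r1$matches$recovered, "nauseas")

  ext_miss <- add_symptom(example_ontology(), "Gastrointestinal symptoms",
                          symptom("joint pain", provenance = "extracted"))
  expect_lte(oracle_fuzzy("nausea", "joint pain"), 40)
  r2 <- recovery_metrics(ext_miss, rec)
  expect_identical(r2$per_category$recall, 0)
  expect_identical(r2$per_category$precision, 0)
  expect_identical(r2$per_category$f1, 0)

  # no extracted entities at all
  r3 <- recovery_metrics(example_ontology(), rec)
  expect_identical(unlist(r3$per_category[, c("precision", "recall", "f1")],
                          use.names = FALSE), c(0, 0, 0))
})

test_that("recovery metrics ignore duplicate extracted entries and unknown categories", {
  rec <- structure(list(masked = list("Vasomotor symptoms" = "Sweating",
                                      "Ghost symptoms" = "phantom"),
                        fraction = 0.6, seed = 1L), class = "mask_record")
  # same normalized entity extracted into two groups: global matching must
  # collapse it to one before computing the precision denominator
  ext <- ontology(list(
    symptom_group("Vasomotor symptoms",
                  members = list(symptom("Hot flashes"))),
    symptom_group("Distress symptoms",
                  members = list(symptom("Nervousness")))))
  ext <- add_symptom(ext, "Vasomotor symptoms",
                     symptom("sweating", provenance = "extracted"))
  ext <- add_symptom(ext, "Distress symptoms",
                     symptom("SWEATING !", provenance = "extracted"))
  r <- recovery_metrics(ext, rec, scope = "global")
  vaso <- r$per_category[r$per_category$category == "Vasomotor symptoms", ]
  expect_identical(vaso$n_extracted, 1L)  # deduplicated after normalization
  expect_identical(vaso$precision, 100)
  expect_identical(vaso$recall, 100)
  ghost <- recovery_metrics(ext, rec)$per_category
  ghost <- ghost[ghost$category == "Ghost symptoms", ]
  expect_identical(ghost$recall, 0)       # scored with an empty extracted set
})

test_that("global-scope matching can recover across categories", {
  rec <- structure(list(masked = list("Vasomotor symptoms" = "Sweating"),
                        fraction = 0.6, seed = 1L), class = "mask_record")
  ext <- add_symptom(example_ontology(), "Distress symptoms",
                     symptom("sweating", provenance = "extracted"))
  scoped <- recovery_metrics(ext, rec, scope = "category")
  global <- recovery_metrics(ext, rec, scope = "global")
  expect_identical(scoped$per_category$recall, 0)
  expect_identical(global$per_category$recall, 100)
})

test_that("harmonic F1 reproduces self-consistent published cells and validates input", {
  expect_identical(f1_harmonic(62.5, 100), 76.9)
  expect_identical(f1_harmonic(50.0, 75.0), 60.0)
  expect_identical(f1_harmonic(0, 0), 0)
  expect_identical(f1_harmonic(35.7, 100), 52.6)
  expect_error(f1_harmonic(120, 50), "0, 100")
  expect_error(f1_harmonic(-1, 50), "0, 100")
})

test_that("ablation with nothing dropped equals the standard run and labels toggles", {
  lex <- example_lexicon()
  m <- mask_ontology(example_ontology(), 0.6, seed = 25)
  corp <- corpus_for_recovery(m$record,
                              corpus_spec(lex, n_sentences = 6, seed = 25))
  std <- run_stream(m$ontology, corp$items, run_config(oracle_backend(lex)))
  std_rep <- recovery_metrics(std, m$record)
  abl <- run_ablation(m$ontology, corp$items,
                      run_config(oracle_backend(lex)), drop = character(),
                      record = m$record)
  expect_identical(abl$per_category, std_rep$per_category)

  b <- oracle_backend(lex)
  both <- run_ablation(m$ontology, corp$items, run_config(b),
                       drop = c("f4", "f6"), record = m$record)
  expect_identical(both$ablation, c("f4", "f6"))
  roles <- vapply(decision_log(b), `[[`, character(1), "role")
  expect_false(any(roles %in% c("is_duplicate", "verify")))
})

test_that("separated baseline extracts exactly the planted occurrences", {
  lex <- example_lexicon()
  m <- mask_ontology(example_ontology(), 0.6, seed = 26)
  corp <- corpus_for_recovery(m$record,
                              corpus_spec(lex, n_sentences = 7,
                                          paraphrase_rate = 0, seed = 26))
  out <- run_baseline("separated", m$ontology, corp$items,
                      run_config(oracle_backend(lex)))
  got <- sort(normalize_surface(attr(out, "extracted")))
  want <- sort(normalize_surface(brute_scan(corp$items,
                                            names(lex$entries))$phrase))
  expect_identical(got, want)
})

test_that("single-agent baseline chunking obeys the context budget", {
  lex <- example_lexicon()
  m <- mask_ontology(example_ontology(), 0.6, seed = 27)
  corp <- corpus_for_recovery(m$record,
                              corpus_spec(lex, n_sentences = 4, seed = 27))
  big <- run_baseline("single_agent", m$ontology, corp$items,
                      run_config(oracle_backend(lex)),
                      context_budget = 10000L)
  expect_identical(attr(big, "n_chunks"), 1L)
  small <- run_baseline("single_agent", m$ontology, corp$items,
                        run_config(oracle_backend(lex)),
                        context_budget = 80L)
  expect_gt(attr(small, "n_chunks"), 1L)
  expect_identical(pair_set(big), pair_set(small))
})

test_that("baselines leave an empty stream untouched and skip unparseable chunks", {
  o <- example_ontology()
  empty <- data.frame(id = character(), sentence = character(),
                      source = character())
  cfg <- run_config(oracle_backend(example_lexicon()))
  for (kind in c("separated", "single_agent")) {
    out <- run_baseline(kind, o, empty, cfg)
    expect_identical(pair_set(out), pair_set(o))
  }
  # llm single-agent with junk output: chunk skipped, ontology carried over
  junk <- llm_backend(function(...) "not json at all")
  out2 <- run_baseline("single_agent", o,
                       segment_posts("I have nausea."), run_config(junk))
  expect_identical(pair_set(out2), pair_set(o))
})

test_that("llm single-agent baseline folds a returned dictionary forward", {
  o <- example_ontology()
  reply <- paste0('{"Vasomotor symptoms": ["Sweating", "Hot flashes", ',
                  '"night sweats"], "Urinary symptoms": ["urgency"]}')
  b <- llm_backend(function(...) reply)
  out <- run_baseline("single_agent", o, segment_posts("night sweats again."),
                      run_config(b))
  tab <- ontology_members(out)
  expect_true("night sweats" %in% tab$normalized)
  expect_identical(tab$provenance[tab$normalized == "night sweats"],
                   "extracted")
  expect_identical(get_group(out, "Urinary symptoms")$provenance, "generated")
  # pre-existing seeds keep their provenance
  expect_identical(tab$provenance[tab$normalized == "sweating"], "seed")
})

test_that("evaluation reports write CSV and JSON", {
  m <- mask_ontology(example_ontology(), 0.6, seed = 28)
  ext <- add_symptom(m$ontology, "Vasomotor symptoms",
                     symptom(m$record$masked[["Vasomotor symptoms"]][1],
                             provenance = "extracted"))
  rep <- recovery_metrics(ext, m$record)
  csvf <- tempfile(fileext = ".csv"); jsonf <- tempfile(fileext = ".json")
  write_eval_report(rep, csv_path = csvf, json_path = jsonf)
  back <- utils::read.csv(csvf)
  expect_identical(nrow(back), nrow(rep$per_category))
  expect_true(all(c("precision", "recall", "f1") %in% names(back)))
  j <- jsonlite::fromJSON(jsonf)
  expect_equal(j$threshold, 40)
})
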
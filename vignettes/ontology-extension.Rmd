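---
title: "Growing a symptom ontology from streaming forum text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing a symptom ontology from streaming forum text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoStream)
```

## The problem and the model

An ontology here is a rooted tree: symptom groups (clusters such as
"Vasomotor symptoms") contain member symptoms ("Hot flashes", "Sweating")
and, in deeper hierarchies, child groups. Extension means integrating new
entities from a text stream so that the output ontology contains the input
ontology unchanged — no deletions, no renames — plus new members and, when
nothing fits, new generated groups.

Processing is **online**: each sentence is consumed exactly once, in
order, with no lookahead, so the method applies to unbounded streams. For
each sentence the loop asks six questions in sequence:

1. *identification* (f1): does the sentence mention a symptom at all? If
   not, the sentence is dropped — this cheap gate keeps the expensive
   roles off noise, which dominates forum text.
2. *extraction* (f2): which phrases are the symptoms? Treatments (e.g.
   "chemo") and bare body parts are excluded by the role's contract.
3. *classification* (f3): which existing group should hold the phrase?
   For hierarchies deeper than one category level the classifier routes
   level by level — broad category first, then subcategories of the chosen
   branch — so a prompt only ever carries one level's categories and their
   members, not the whole tree.
4. *duplication check* (f4): is the phrase semantically already present in
   the chosen group? We scope this check to the assigned group, not the
   whole ontology: cross-group similarity is legitimate (e.g. pain-like
   symptoms in several systems), and the group is where redundancy harms.
5. *relation generation* (f5): if no group fits, propose a category in the
   canonical `<X> symptoms` form.
6. *verification* (f6): confirm the final (category, symptom) assignment
   before it enters the ontology.

Two backends serve these roles behind one contract. The
**language-model backend** renders role-specific prompts through a
user-supplied transport function; its parsers are total (they map any
text to a decision or a protocol error, never an exception), malformed
answers are re-asked up to the retry budget, and exhaustion degrades to a
role-specific safe fallback: skip the sentence (f1/f2), treat the symptom
as absent (f3) or as a duplicate (f4, conservative — do not add), park the
symptom (f5), or reject the assignment (f6). The **lexicon oracle** is a
pure function of a closed-world surface-form-to-category map: it
identifies a sentence exactly when some lexicon form occurs word-bounded
and case-insensitively, extracts those forms in first-occurrence order,
and answers classification, generation and verification from the map.
Because the oracle is deterministic, every pipeline contract — order
insensitivity, idempotence, monotonicity, replay — is testable exactly.

Every agent call appends one record (role, input, raw response, parsed
decision) to a decision log; a replay backend answers from such a log, so
a recorded run can be reproduced byte-for-byte without the original
backend.

## Assumptions

- **Single membership.** A symptom belongs to exactly one group (the
  membership relation is drawn as a single edge). Multi-parent membership
  would be scientifically defensible (fatigue is both somatic and
  psychologic) but is out of scope; the duplicate check and the
  per-category evaluation both rely on unique placement.
- **Closed world for the oracle.** The oracle answers "not a symptom" for
  anything outside its lexicon. This is what makes ground truth provable;
  it also means oracle runs say nothing about open-vocabulary recall.
- **Category names follow `<X> symptoms`.** Generated category names are
  canonicalized to this pattern (first letter capitalized, trailing word
  "symptoms" enforced, singular answers pluralized), and a proposal that
  differs from an existing group only in case/spacing/punctuation is
  routed into that group rather than creating a sibling duplicate.

## Tunable parameters

| parameter | default | units | role |
|-----------|---------|-------|------|
| `dup_threshold` | 90 | fuzzy score, 0–100 | f4 (oracle): scores strictly above it are duplicates. High by design: only near-identical surface forms are suppressed, so legitimate variants ("hot flash" vs "hot flashes", score 82) are kept and left to semantic judgment when an LLM serves f4. |
| recovery `threshold` | 40 | fuzzy score, 0–100 | evaluation: a masked symptom counts as recovered when some extracted entity scores strictly above it. Read as a strict inequality from its definition ("above 40"). |
| `retries` | 2 | re-asks | LLM protocol: attempts = retries + 1, then the role fallback. |
| `enable_f4`, `enable_f6` | `TRUE` | — | ablation toggles; disabling f4 can only grow the membership (it removes a rejection path and changes nothing else), which inflates recall and depresses precision. |
| mask `fraction` | 0.6 | proportion | per category, `ceiling(fraction * n)` members are hidden, capped so one member always survives (a category must remain recognizable to the classifier). |
| `checkpoint_every` | 500 | stream items | recovery checkpoint cadence for aborted runs. |
| `context_budget` | 4000 | characters | single-agent baseline chunk size. |

## The fuzzy score and its numerical choices

`fuzzy_score(a, b) = round(100 * (1 - D(a', b') / max(|a'|, |b'|)))`, with
`D` the Levenshtein distance (computed by `utils::adist`) and `a'`, `b'`
the normalized forms: lower case, internal whitespace collapsed, edge
punctuation stripped. Two empty strings score 100 (they are equal);
one empty string scores 0. The score is symmetric, bounded in [0, 100],
and equals 100 exactly when the normalized forms coincide. The test suite
pins it exactly to an independently written dynamic-programming oracle on
random pairs, so the library call can never drift from the stated formula
unnoticed.

Rounding uses R's `round` (half-to-even); threshold comparisons are
strict (`>`), so a tie at the threshold does not count as a duplicate or a
recovery.

Degenerate inputs: empty streams return the input ontology unchanged; an
ontology `{}` loads as an empty tree of depth 0; masking refuses empty
categories (there is nothing to survive); classification against an empty
ontology is absent by construction.

## Evaluation protocol

`mask_ontology` hides a per-category uniform random subset under a local
RNG (the caller's RNG state is untouched), records exactly what was
hidden, and is deterministic in its seed. Per-category masking — rather
than pooled global masking — guarantees every category row of the report
is well defined. `recovery_metrics` then compares the extracted-provenance
entities `A` of each category against the hidden set `M`:

- recall = 100 × |{m ∈ M : ∃a ∈ A, score(m, a) > threshold}| / |M|
- precision = 100 × |{a ∈ A : ∃m ∈ M, score(a, m) > threshold}| / |A|,
  0 when A is empty
- F1 = harmonic mean, 0 when both are 0, rounded to one decimal.

Matching is many-to-many (one extracted phrase may recover several masked
variants) and category-scoped by default, since the report is
per-category; a global mode is available for cross-category credit.
Precision here is a reconstruction: the protocol's published description
defines recall operationally but describes precision only loosely
(extracted entities that are "not incorrect"), so we define it as the
fraction of extracted entities that match some masked symptom — the
natural dual of recall under the same threshold.

The published per-category F1 values can be rechecked against their
printed precision/recall by `f1_harmonic`; the test suite asserts exact
agreement on the rows where the printed triple is arithmetically
self-consistent at one decimal, and leaves alone rows that were evidently
rounded from unrounded precision/recall (plus one row whose printed F1 is
inconsistent with any rounding of its printed inputs).

## The synthetic corpus: what it does and does not show

The generator emulates segmented patient-forum text at desk scale:
first-person template sentences with one planted symptom slot, a
controllable symptom-bearing rate (`floor(rate * n)` exactly), repeated
plantings, and paraphrases implemented as 1–2 **character-level edits**.
Character edits, not synonyms, are deliberate: an edit of distance ≤ 2 on
these surface forms provably stays above the recovery threshold of 40, so
ground-truth recoverability is a theorem, not an assumption, and the
annotation can be verified by a brute-force scan of the emitted stream.

Consequently, a passing end-to-end run demonstrates the *machinery* —
segmentation, gating, extraction, classification, deduplication,
verification, scoring — under conditions where the intended answer is
known. It does not demonstrate robustness to real forum language:
misspellings beyond two edits, synonymy ("night sweats" for "sweating"),
negation, or symptoms phrased across sentence boundaries. Those depend on
the language-model backend's competence, which this package treats as an
exchangeable component and does not certify. For the same reason the
absolute recovery numbers published for GPT-class backends on the
original (undeposited) forum corpora are not reproduction targets here.

Problem sizes in the shipped tests and acceptance script — 1,000 random
string pairs, the 9-category/18-symptom packaged ontology, streams of tens
of sentences, 100 random trees — were chosen as the smallest sizes at
which every property is non-trivially exercised; all checks on them are
exact, so larger sizes would add cost without adding discrimination.

## Design choices where the design was open

- **f4 before f6**: the duplication check runs before verification —
  rejection by string similarity is cheaper than a verification query, and
  the two rejections commute (both leave the ontology unchanged).
- **New groups attach at the top level** for depth-1 ontologies (the only
  depth the flat dictionary dialect can express); for deeper trees the
  attachment level is a documented extension point rather than a guess.
- **Symptoms rejected by f6 are discarded** (logged), not re-classified:
  re-routing loops have no termination guarantee and no specified policy.
- **Two serialization dialects**: the flat category-to-list dictionary
  (byte-compatible with the classification prompt's `symptom_dictionary.json`
  shape, provenance dropped) for depth-1 interchange, and a recursive
  `{name, provenance, members, children}` dialect that round-trips
  everything exactly for any depth. The synthetic root is never
  serialized.
- **Extension is in-place growth**: the extended ontology is not a
  distinct type, because it is defined as the input plus new entities, and
  monotonicity is enforced by construction (`add_symptom` and
  `create_group` only append).
- **Duplication of normalized forms within a group is structurally
  impossible** (`add_symptom` is a checked no-op), so disabling f4 changes
  near-duplicate behavior, not exact-duplicate behavior.

## Known limitations

- Single-parent membership only; no OWL/OBO export; no cross-ontology
  alignment.
- The oracle's word-boundary matcher cannot find paraphrased or inflected
  surface forms; oracle-backend recall on paraphrased corpora is
  structurally zero for those plantings (by design — the oracle is a
  contract fixture, not an NLP system).
- The sentence splitter is rule-based with a fixed abbreviation guard
  list; exotic punctuation will mis-segment.
- The LLM backend ships prompts and parsers but no HTTP client; users
  supply a transport function, which is also where rate limiting and
  authentication belong.
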
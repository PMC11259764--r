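---
title: "Collaborative CKD screening over fragmented EHRs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative CKD screening over fragmented EHRs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedkg)
```

## The problem

Patients accumulate care across hospitals, and each hospital's EHR therefore
holds only a fragment of the longitudinal record. Chronic kidney disease (CKD)
is a worst case for this fragmentation: its operational definition is
*temporal* — kidney-function abnormality sustained over at least three months —
so two abnormal laboratory results that jointly establish chronicity may sit in
two different institutions, where neither record alone justifies a diagnosis
and non-nephrology clinicians have no reason to chase the missing half.
Centralizing raw EHR data to close the gap is usually barred by privacy and
governance constraints.

`fedkg` implements a collaborative reasoning architecture for exactly this
setting. Every hospital ("node") keeps its raw data and reasons locally; the
only artifact that crosses a hospital boundary is an **online subgraph**: a
hashed patient identity, virtual visit nodes carrying *dates only*, and
virtual finding nodes carrying a *hypernym concept* plus a positive/negative
label. A configurable **sponsoring node** aligns patients across sites by
digest equality, merges the virtual fragments into one pathway per patient,
and applies the chronicity criteria to the merged timeline. Everything
exchanged passes through a hash-chained ledger, so a run is ordered,
tamper-evident and replayable.

## Data model

Per-hospital data follow a deliberately narrow OMOP-style layout ("OMOP-lite"):
`person` (with a raw citizen-identity string, held strictly locally),
`visit_occurrence` (day-granular visit date plus department), and four event
tables unified into a single event collection with kinds *diagnosis*,
*measurement*, *drug*, *procedure*. Only the columns the reasoning touches are
modeled; admission spans collapse to their start date, and all intervals in
the package are closed on both ends. For semantic interoperability a store
projects into patient–visit–treatment RDF-style triples
(`<hospital>/person/p1 ehr:hasVisit <hospital>/visit/v1 .` …) with a canonical
sorted N-Triples-like serialization, used in tests as a determinism witness.

Albumin-to-creatinine ratios are accepted in either mg/g or mg/mmol; the
loader converts mg/mmol to mg/g (× 8.84) so thresholds see one unit. This
mirrors a real-world annoyance: cohort criteria for ACR are typically quoted
in mg/g while laboratory summaries often report mg/mmol.

## Vocabulary and hypernym abstraction

The concept vocabulary is a DAG. Leaves are the specific things records
mention (an eGFR result, a hyperkalemia diagnosis, a potassium-binder
prescription); selected internal concepts carry an `is_hypernym` flag marking
them as approved, deliberately coarse expressions ("abnormal blood
potassium"). The flag is vocabulary *data*, standing in for the expert
curation step of a deployed system: which generalizations are safe to share
is a clinical governance decision, not something the package computes.

`build_hypernym_map()` assigns every leaf the **most specific** hypernym
ancestor whose *leaf cohesion* — the mean pairwise cosine similarity of the
hypernym's descendant-leaf embeddings, 1.0 for a single leaf — reaches a
threshold (default 0.7; the scale of typical within-cluster similarities for
normalized embeddings). Ties at equal depth break to the lexicographically
smallest id, for determinism. When *no* ancestor reaches the threshold the
leaf falls back to its most **general** hypernym ancestor and is flagged
low-cohesion. We chose the general end deliberately: a subtree whose leaves
do not cohere is one whose hypernym would blur distinct meanings, and the
conservative response is to generalize further, not less. This choice also
gives the map a clean monotonicity property — raising the threshold can only
make a leaf's expression more general, never more specific — which the test
suite checks on randomized hierarchies. Leaves with no hypernym ancestor stay
unmapped and their findings are **dropped with a warning** at abstraction
time: transmitting a raw leaf would break the privacy contract, so privacy
dominates completeness.

Embeddings in the shipped CKD vocabulary are synthetic fixed vectors (one
dominant coordinate per hypernym cluster, small per-leaf offsets), emulating
an embedding space in which curated subtrees cohere. No embedding training is
performed or claimed.

## Local reasoning and the chronicity rule

Rule-based reasoning runs per visit, with no cross-visit state: measurement
rules fire on strict threshold comparison (eGFR **< 60** mL/min, ACR
**> 30** mg/g, plus common reference limits for creatinine, potassium,
glucose, BUN and uric acid), and diagnosis/drug rules map recorded concepts
to finding leaves. Strictness at the boundary follows the usual cohort
phrasing "lower than" / "higher than": an eGFR of exactly 60 is not abnormal.

A normal eGFR result (≥ 60) additionally emits a **negative** kidney-function
finding. These negative rows are the *recovery markers*: transient dysfunction
(post-surgical, drug-related) produces abnormal results that later normalize,
and treating any two abnormals ≥ 90 days apart as chronic would flag those
patients falsely. Only eGFR carries this role — a creatinine or ACR in normal
range does not certify normal kidney function, while eGFR is the principal
function measure. The chronicity criterion is then:

> **met** iff two abnormal kidney-function findings lie ≥ 90 days apart
> (inclusive) with no normal kidney-function observation dated strictly
> between them; `first_met_date` is the earliest qualifying second element.

Ninety days operationalizes "3 months" with a deterministic boundary; the
inclusive comparison is checked explicitly at 89/90 days. The implementation
is a linear scan over sorted unique dates (for each abnormal date, the
earliest abnormal at or after the last preceding normal); an O(n²)
brute-force oracle written directly from the rule statement is kept in the
test suite, and the two must agree on hundreds of random timelines. One open
modeling point: whether both qualifying abnormalities must come from the same
analyte. We accept any abnormal kidney-function finding concept, which is the
more sensitive reading; the rule set makes the concept list configurable.

## Eligibility, exclusion, and what crosses the boundary

The initiation protocol screens each patient locally: eligible iff the node
holds ≥ 1 kidney-function test for them, no nephrology-department visit, and
no kidney-disease diagnosis. The two "hard" clauses are exclusion criteria in
the clinical sense (the patient is already under nephrology care), so a
patient reported hard-excluded by *any* node is excluded consortium-wide;
only the digest and reason codes are announced, never the findings. The
`NO_KIDNEY_TEST` clause is different: under fragmentation it is *expected*
that some nodes hold no kidney tests for a shared patient. Such nodes still
contribute a visit-date-only subgraph (zero findings), because the sponsor
needs the visit pathway — in particular to recognize a transfer: a patient
whose criteria were satisfiable at hospital A and who then appears at
hospital B. Hard-excluded patients send nothing at all.

The subgraph constructor and deserializer both enforce the privacy contract
mechanically: findings may carry only (date, hypernym concept, label); a
`value`, `unit`, `identity`, `department` or provenance field anywhere in a
payload is a hard error, and any concept outside the hypernym whitelist is
rejected. The acceptance suite additionally byte-scans the union of all
ledger payloads from a full run for every raw identity string, every source
measurement value, and every non-hypernym concept id.

## Alignment, ledger, and the protocol

Identities are normalized (trim, uppercase, strip internal whitespace and
hyphens) and hashed as `SHA-256(salt ‖ identity)` with a consortium-shared
salt distributed out of band. The salt blocks dictionary attacks on
low-entropy identifiers while preserving the cross-site digest equality that
alignment relies on. Distinct local identities colliding on one digest are
flagged and withheld from matching rather than silently merged — a silent
merge would corrupt two patients' timelines. Alignment is exact-match only;
probabilistic linkage over non-unique identifiers is explicitly out of scope.

The synchronization layer is simulated as a single-sequencer hash chain:
`block_hash = SHA-256(index ‖ prev_hash ‖ payload_hash)`, genesis chained
from 64 zero hex digits, with synchronous broadcast and per-node receipts.
Consensus machinery (proof of stake, peer-to-peer networking) is deployment
infrastructure orthogonal to the reasoning contribution; what the protocol
actually relies on — ordered, tamper-evident, traceable delivery — is
preserved and tested (any single-byte mutation is detected and attributed to
the first invalid block). Access control is a per-message recipient
allow-list stand-in at delivery time rather than ciphertext-policy
attribute-based encryption. Where a decision needs a comparison of two raw
values held at different nodes, `secure_compare()` defines the interface —
references in, one of `<` `=` `>` out — with a plaintext trusted-evaluator
reference implementation behind it; a cryptographic two-party comparison
backend could be substituted without touching callers.

The five protocol steps: (1) initiation everywhere, announcements and initial
kidney-finding subgraphs to the ledger; (2) digest alignment at the sponsor;
(3) **ROI designation** — for each patient whose merged kidney timeline meets
the criteria, the region of interest spans from the first to the last
abnormal merged finding (the natural envelope of the qualifying chain; no
formula for the ROI bounds is canonical, and this one reproduces the
timeline-example behavior of ROI = [first abnormal, last abnormal]); (4)
ROI-restricted reasoning at every node — events outside every ROI are never
processed for export; (5) summarization: the verdict is recomputed on the
merged timeline, and detected patients are partitioned into
`transferred` (some single hospital's findings alone satisfy the criteria,
and the patient visited a different hospital after that date — the transfer
date being the first such visit), `multicenter_data` (no single hospital
suffices but the union does), or `single_center`. Every result carries its
supporting pair, ROI, risk list with origin tags, and the full merged
evidence trail, exportable as a JSON timeline with local/remote origin
classes for visualization.

## The synthetic consortium

The study conditions the package targets involve real multi-hospital EHR
data that cannot be shipped, so the test bed is a seeded generator whose
defaults encode those conditions: 3 hospitals, a ~5-year study window,
phenotype mix of 15% multicenter CKD, 15% transferred CKD, 10% recovery
confounders and 60% controls, plus 5% exclusion decoys on top; every patient
visits ≥ 2 hospitals under one identity (18-character citizen-ID-like
tokens) with different local person ids, and no hospital holds all of a
patient's visits. Background analyte values use population-plausible
means/SDs (potassium 4.27 ± 0.46 mmol/L, glucose 5.97 ± 1.92 mmol/L, …),
truncated inside normal ranges so controls cannot fire abnormal rules by
chance; comorbidity diagnoses (diabetes 13.5%, hypertension 23.7%,
cardiovascular disease 9%, hyperlipidemia 2.5%) match the variable list of
the emulated cohort. All measurement values are rounded to one decimal with
a forced nonzero decimal, which makes the privacy byte-scan exact: no other
payload content contains a decimal-pointed number.

Phenotype construction is by explicit placement, not by rejection sampling:

* **multicenter** — abnormal eGFR at hospital A at day *t₀* and at hospital B
  at *t₀ + gap*, gap ∈ [90, 220]; an optional extra abnormal at A within
  < 90 days of *t₀* keeps every single hospital unsatisfiable.
* **transferred** — two abnormals ≥ 90 days apart at A, then a first visit to
  B (no kidney tests there) 30–150 days after A's satisfiability date.
* **recovery confounder** — abnormal, normal (+60 d), abnormal (+150 d)
  across two hospitals: the normal sits strictly between every ≥ 90-day
  abnormal pair, so the union never durably satisfies the criteria.
* **control** — normal kidney values only. **Decoys** carry a CKD-like
  abnormal pattern *plus* a nephrology visit or kidney-disease diagnosis, so
  failing to exclude them would surface as false positives.

Planted positives receive 2–4 risk events (AKI or proteinuria diagnoses,
elevated BUN/uric acid/potassium/glucose, comorbidities) inside the planted
window, and their ground-truth diagnosis date is onset + U(90, 700) days —
enough spread to exercise the lead-time machinery without claiming to
reproduce any particular cohort's values. Before returning, the generator
re-verifies every patient against the brute-force chronicity oracle (union
and per-hospital), so the emitted labels are guaranteed, and the whole
consortium is a pure function of its config.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: realistic disease progression and measurement
autocorrelation, demographic structure beyond the variable list, coding
variation across sites (every node shares one vocabulary), identity-recording
errors (alignment here is exact by construction), and clinician behavior
(the synthetic diagnosis date stands in for chart review). Results on the
synthetic consortium validate the *machinery* — detection, grouping, privacy,
determinism — not clinical performance.

## Evaluation metrics

*Discovery lead time*: for multicenter patients, `t_diagnosis − t_CDS` (date
the merged criteria were met); for transferred patients,
`t_diagnosis − t_transfer` (first post-transfer visit). *Risk coverage*: the
percent ratio of the risk-hypernym set surfaced collaboratively within the
3-month window anchored at the **ROI end** (the most recent evidence a
clinician would review; the anchor is a declared choice) against the set a
single-hospital review of the sponsor's latest 3 months would surface;
per-patient ratios are averaged, with a pooled-count mode left to the caller
by aggregating the returned sets. *Duplicate-examination reduction*: remote
kidney tests inside the ROI not mirrored by a sponsor-side kidney test within
± 14 days (a configurable mirroring window; no canonical value exists).
Detection quality (sensitivity, specificity, PPV, group accuracy) is
computed against the generator's ground truth, with recovery confounders
tabulated separately as the designed false-positive pressure.

## Numerical and scale choices

Problem sizes in the shipped tests: the end-to-end suite runs one
1200-patient, 3-hospital consortium (the generator's default study mix) in
well under two minutes single-threaded, plus a 150-patient double run for
byte-level determinism and ten 20-patient consortia for alignment
exactness; the chronicity oracle comparison uses 500 random timelines.
Determinism is engineered, not hoped for: one RNG stream seeded once per
generation, canonical JSON with sorted keys and sorted node lists for every
payload, lexicographic tie-breaks everywhere an ordering is needed, and
sorted iteration over digests in the protocol. Degenerate inputs (empty
vocabularies, zero-event stores, empty subgraph sets, zero-finding patients)
are all defined and tested rather than rejected.

## Limitations

The ledger is a simulation of a synchronization layer, not a consensus
implementation; the secure-comparison backend is a plaintext reference;
alignment requires unique identifiers; the rule pack ships for CKD only
(the engine itself is disease-agnostic); and the clinical confirmation step
of a deployed system — nephrologist review of flagged patients — has no
synthetic counterpart here.
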
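---
title: "Cost-reduced record de-duplication: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-reduced record de-duplication: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dedupr)
```

## The problem

De-duplication asks which records in a dataset refer to the same real-world
entity — the same patient, customer or citation — when no shared unique
identifier exists. Comparing every record with every other costs
$\binom{n}{2}$ detailed comparisons, which is prohibitive even at moderate
$n$ (half a million comparisons for $n = 1000$). The practical remedy is an
*indexing* step that generates a much smaller set of candidate pairs, a
*comparison* step that scores each candidate field by field, and a
*classification* step that thresholds the aggregate score. This is the
standard pipeline of biomedical record-linkage systems, and everything in
`dedupr` is organised around it.

## Indexing: blocking and windowing

Each record is assigned a key value by encoding one or more of its fields:

* **soundex** — the American phonetic code (initial letter plus three
  digits; vowels separate adjacent consonants of equal code, `h`/`w` do
  not), so `smith` and `smyth` share `S530`;
* **substring-$k$** — the first $k$ characters of the normalised value,
  the least restrictive choice: two values share a key whenever their first
  $k$ characters agree.

An inverted index maps each key value to the records carrying it.
**Blocking** compares only within-bucket pairs. **Windowing** (the sorted
neighbourhood method) sorts the buckets by key value and slides a window of
$w$ consecutive buckets one bucket at a time, pairing all records that share
a window; $w = 1$ reduces to blocking. Whole buckets enter a window, so no
within-bucket tie-break is needed. Variants:

* **Composite-key blocking (CKB)** — the key concatenates two encoded
  fields (here `given_name + surname`), giving small buckets and the fewest
  comparisons;
* **Multipass blocking / windowing (MPB / MPW)** — the indexing step runs
  once per key (here one pass on each name field) and the candidate sets
  are unioned, giving dirty records several chances to meet.

Expected comparison counts under the uniform-bucket assumption
($b$ buckets of $n/b$ records) are available in closed form:

* blocking: $b \cdot \frac{(n/b)(n/b - 1)}{2}$;
* single-key blocking with $i$ distinct key values: the same with $b = i$;
* composite-key blocking with $i \ge j \ge 2$ distinct values per key:
  $\frac{ij}{2}$ average blocks of size $\frac{2n}{ij}$, which never
  exceeds the single-key count;
* two-pass multipass blocking: the sum of the two single-key counts;
* windowing:
  $\frac{\frac{wn}{b}(\frac{wn}{b}-1)}{2} + (b-w)\left[\frac{\frac{n}{b}(\frac{n}{b}-1)}{2} + (w-1)\frac{n^2}{b^2}\right]$.

The "average number of blocks $= ij/2$" step in the composite-key count is
a modelling assumption, not a derivation; we implement it verbatim and test
all five formulas against literal pair enumeration on uniform-bucket
indexes, where they are exact. The estimators return reals (expectations)
and never round.

```{r estimators}
est_block_comparisons(1000, 1)      # full index
est_ckb_comparisons(1000, 10, 4)
est_window_comparisons(100, 10, 2)
```

## Comparison and classification

Candidate pairs are scored on a five-field linking key chosen for its low
missing-value rate: `postcode` and `soc_sec_id` by normalised edit distance
($1 - \mathrm{lev}(a,b)/\max(|a|,|b|)$), `address_1` by bigram overlap
(common q-grams over the average q-gram count, no padding), and the two
name fields by exact agreement of their encoded form, where the encoding
follows the run's indexing choice. The per-field similarities form the
weight vector; the aggregate $F$ is their weighted arithmetic mean with
unit weights by default, which keeps $F \in [0,1]$ so thresholds are
scale-free. A pair is a **Match** when $F \ge T_U$, a **Non-Match** when
$F < T_L$, and a **Possible Match** (clerical review) in between, with the
boundaries exactly as written.

Design choices that were genuinely open:

* **Missing values.** If either field value is empty the field scores 0
  (disagreement). The linking fields are chosen to have few missing values,
  so this is rarely binding; `missing_ignore = TRUE` instead drops the
  field from the mean, which is preferable when a field is missing at
  random in one source.
* **q-gram formula.** The literature cites "q-gram distance" without
  fixing a normalisation; we use common-count over average count with
  $q = 2$ and no padding, the convention of the Febrl system this package
  inter-operates with.
* **Thresholds.** Defaults are $T_L = 0.5$, $T_U = 0.75$, chosen so that a
  single completely disagreeing field among five ($F = 0.8$) still
  matches while two disagreeing fields ($F = 0.6$) go to review. The
  benchmark study this design follows does not publish its thresholds, so
  absolute match counts on its datasets are reproducible only
  approximately; all quality claims we test are therefore either
  closed-form (from published counts) or computed on generated data with
  these defaults. `thresholds(1, 1)` recovers the deterministic rule
  (exact agreement on all linkage fields).

## The three-phase framework

Blocking alone misses duplicates whose key fields are corrupted; windowing
alone needs a large window (and hence many comparisons) when the data are
very dirty, and the right window size cannot be known in advance.
`run_framework()` therefore runs, in succession:

1. **CKB** on `given_name + surname` — cheapest, resolves the easy bulk;
2. **MPB** — one single-key pass per name field, union of candidates;
3. **MPW** — one sorted-neighbourhood pass per name field with a *small*
   window (default 3), to catch residual duplicates whose keys landed in
   nearby buckets.

Two accounting mechanisms connect the phases, both on by default and both
exposed as flags so either can be studied in isolation:

* **cross-phase cache** — a global compared-pair set; a pair generated
  again in a later phase is never re-scored, so the sum of
  `new_pairs_compared` over phases equals the total distinct pairs scored;
* **record removal before windowing** — every record that is a
  non-representative member of an already-resolved duplicate cluster
  (transitive closure of the match pairs; the representative is the
  lexicographically smallest `rec_id`, which is deterministic and
  order-independent) is dropped before the windowing indexes are built.
  This models the intended use: by phase 3 the dataset is already
  reasonably de-duplicated, so windows stay cheap.

Per-phase reports give pairs generated, new pairs compared and matches
newly found; "matches found" counts pairs newly classified as Match in that
phase, and the final match set is the union over phases. Whether the
windowing phase re-sorts the full or the reduced dataset was an open
choice; we sort the reduced one, consistent with the removal rationale.

## The synthetic dirty-data generator

Real benchmark files cannot ship with the package, so the generator
produces structurally equivalent data with a known gold standard: original
records drawn from built-in value pools (115 given names, ~130 surnames,
~60 street names, 80 suburbs, numeric generators for dates, ages, phone
and social-security numbers — sized so that a 500-original dataset shows
realistic name collisions), plus duplicates derived by single-character
edits (`insert`, `delete`, `substitute`, `transpose`) or a field clear,
applied at uniformly chosen positions to uniformly chosen non-empty
attributes. Record ids follow `rec-<k>-org` / `rec-<k>-dup-<j>`, from
which `derive_gold_standard()` recovers the true partition.

Two profiles mirror the benchmark conditions: **A** (*dirty*: 500
originals + 500 duplicates, one duplicate per original, exactly one
modification, at most one per attribute — 500 true pairs) and **C**
(*massively dirty*: 600 + 400, up to nine duplicates per original, up to
ten modifications per duplicate, at most three per attribute). Where the
benchmark's corruption distribution is unspecified we draw uniformly: the
number of modifications uniform on its allowed range, duplicates per
original uniform on `1..max` truncated to hit the duplicate total. Given a
seed, output is byte-identical across runs.

What the generator does *not* emulate: frequency-weighted value
distributions (real name frequencies are Zipf-like, so real blocks are more
skewed than ours), phonetic/OCR-style correlated errors, household
structure, and the exact corruption mix of the published benchmark files.
Consequently, tests on generated data validate *mechanisms* (candidate
generation, accounting, monotonicity, completeness on lightly corrupted
data) rather than exact published counts — with a uniform modification
count of 1–10, profile-C duplicates are on average dirtier than the
published massively-dirty set, so absolute completeness there is lower
than the published figures while every comparative claim (framework beats
wide-window multipass windowing at a fraction of the comparisons) still
holds and is asserted.

```{r framework, eval = FALSE}
out <- generate_dataset(dataset_profile("A", seed = 1))
res <- run_framework(out$dataset,
                     framework_config(encoder = "substring", prefix_len = 4,
                                      window_size = 3),
                     out$gold)
res$phase_reports
res$evaluation$metrics
```

## Evaluation

With a gold standard, a run is summarised by the confusion matrix over all
$\binom{n}{2}$ pairs and by four indexing metrics: pairs quality
$PQ = \frac{\text{matches found}}{\text{candidates generated}}$, pairs
completeness $PC = \frac{\text{matches found}}{\text{true matching
pairs}}$, reduction ratio $RR = 1 - \frac{\text{candidates}}{\binom{n}{2}}$
and the F-score. We compute the F-score as the plain harmonic mean
$\frac{2 \cdot PC \cdot RR}{PC + RR}$: the defining formula is sometimes
typeset with a spurious leading "1 −", but every published value we
reconstruct is consistent with the plain harmonic mean, which is also the
only reading that stays in $[0,1]$ and rewards good runs. "Matches found"
follows the reporting convention of the benchmark tables: the count of
pairs the classifier labels Match (the confusion matrix separates the
true/false split). When no gold standard exists, the expected true-pair
count for a dataset of $n$ records with duplicate ratio $DR$ and $d$
duplicates per original is $DR \cdot \frac{n}{d}\left[d +
\frac{d(d-1)}{2}\right]$.

For planning problem sizes: the bundled tests and the reproduction script
run the full pipeline at $n = 1000$ (the benchmark scale) and
property-style checks at $n \le 200$, which keeps a complete run in the
tens of seconds on one core while exercising every code path at the scale
the published counts refer to.

## Numerical and degenerate-input conventions

* Values are normalised at load: lower case, outer whitespace stripped,
  internal runs collapsed. Phonetic codes strip non-letters first;
  substring prefixes keep digits (postcodes).
* Records whose key fields are all missing are excluded from that pass's
  index rather than pooled (pooling is available via `empty_key_bucket`);
  with low missing rates a pooled junk bucket would dominate the counts.
* Bucket order for windowing is ascending byte-wise (radix) order of the
  encoded key, locale-independent.
* Zero denominators in metrics report 0 with a warning; the F-score is 0
  whenever $PC + RR = 0$.
* Pair sets are canonical (lexicographically ordered ids, sorted, unique),
  so set equality is object identity.

## Known limitations

* No Fellegi–Sunter probabilistic weight estimation; classification is
  threshold-based on an unweighted (by default) mean.
* No record merging/survivorship, clerical-review tooling, adaptive window
  sizing, size-capped blocking or fuzzy (threshold) bucketing.
* The generator's value pools are Anglophone and the phonetic encoder is
  English soundex; multilingual encodings are out of scope.
* Complexity estimators assume uniform bucket sizes; on Zipf-distributed
  keys they underestimate blocking costs.
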
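# dedupr

Record de-duplication — finding the records in a dataset that refer to the
same person — is quadratic if done naively: a 1 000-record file already
needs 499 500 detailed comparisons. `dedupr` implements a cost-reduction
pipeline for this problem, aimed at health-data integration and similar
person-record linkage tasks where no shared unique identifier exists:

* **Indexing** — inverted indexes on encoded keys (American soundex or
  substring-*k* prefixes), with *blocking* (compare within buckets),
  *sorted-neighbourhood windowing* (compare within a window of *w* adjacent
  buckets), composite keys and multipass unions; plus closed-form
  estimators of the expected comparison count for each variant under
  uniform bucket sizes.
* **Comparison** — per-field similarities (normalised Levenshtein, q-gram
  overlap, encoded exact agreement) combined into a weight vector and an
  aggregate score *F* ∈ [0, 1].
* **Classification** — two thresholds (T_L, T_U) split candidates into
  Match (*F* ≥ T_U), Possible Match and Non-Match (*F* < T_L).
* **The three-phase framework** — composite-key blocking, then two-pass
  multipass blocking, then two-pass multipass windowing with a *small*
  window (default 3), sharing a compared-pair cache and optionally removing
  already-resolved duplicates before the windowing phase. The point: the
  succession removes the need to guess a window size, and reaches
  wide-window recall at a fraction of the comparisons.
* **Evaluation** — confusion matrix against a gold standard; pairs quality
  PQ = matches/candidates, pairs completeness PC = matches/true pairs,
  reduction ratio RR = 1 − candidates/C(n,2), and the F-score
  2·PC·RR/(PC+RR).
* **Synthetic dirty data** — a generator of person records with corrupted
  duplicates and a known gold standard (`rec-<k>-org` / `rec-<k>-dup-<j>`
  naming), including a *dirty* profile A (500 + 500, one light modification
  per duplicate) and a *massively dirty* profile C (600 + 400, up to ten
  modifications per duplicate).

Input data are CSV files with a header containing `rec_id` plus twelve
person fields (`given_name`, `surname`, `street_number`, `address_1`,
`address_2`, `suburb`, `postcode`, `state`, `date_of_birth`, `age`,
`phone_number`, `soc_sec_id`), the layout used by Febrl-style benchmark
datasets.

## Worked example

```r
library(dedupr)

out <- generate_dataset(dataset_profile("A", seed = 1))   # 1000 records, 500 true pairs
cfg <- framework_config(encoder = "substring", prefix_len = 4, window_size = 3)
res <- run_framework(out$dataset, cfg, out$gold)
print(res)
```

```
framework_result
 phase pairs_generated new_pairs_compared matches_found
   CKB             494                494           445
   MPB            9216               8722            55
   MPW            8974               6919             0
 Total           18684              16135           500
final: 500 matches, 2 possible matches
metrics: PQ=0.030989 PC=1.000 RR=0.968 F=0.984 (16135 candidates, 500 matches, 500 true pairs, n=1000)
```

Reading this: composite-key blocking alone resolved 445 of the 500
duplicate pairs in 494 comparisons; the two multipass-blocking passes added
the remaining 55; the small-window pass confirmed nothing was left. The
whole run scored 16 135 candidate pairs instead of 499 500 — a reduction
ratio of 0.968 — and recovered every true pair (PC = 1.0).

The same pipeline is available from a shell via the bundled script:

```sh
Rscript inst/exec/dedup generate --profile A --out data.csv --gold gold.csv --seed 1
Rscript inst/exec/dedup run --input data.csv --gold auto --out report/
Rscript inst/exec/dedup estimate --n 1000 --b 100 --w 3 --i 10 --j 4
```

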
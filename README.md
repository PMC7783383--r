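# surgcomm

Discovering **natural surgical communities** from patient-flow data.

Hospitals that pool elective waiting lists need a defensible answer to the
question *which hospitals and which populations belong together?*
Administrative planning regions are one answer; patients' actual travel
patterns are another, and the two often disagree. `surgcomm` takes
admission-level hospital activity (patient origin area, treatment site,
dated procedure codes, diagnoses) and derives groups of small census areas
(LSOAs) whose residents present to the same surgical providers — surgical
communities — at several spatial scales, then measures how self-contained
each community is.

The package is aimed at health-services researchers and analysts working
with Hospital-Episode-Statistics-like tables. Because such data are
confidential, `surgcomm` includes a first-class synthetic generator with a
planted two-level geography, so the entire pipeline is demonstrable and
testable without any data access.

## The method in brief

1. **Events.** For each admission, keep every countable procedure on the
   *first operative day* (the first day with a countable code once
   U/Y/Z/X families are removed, concurrent C71+C75 lens pairs are merged
   and lower-GI endoscopies are grouped). Merge hospital sites within
   1 km. Select **high-volume procedures** (HVPs): the top codes jointly
   exceeding 50% of events; per HVP, keep the **regular providers**
   covering 99% of its volume.
2. **Risk.** Charlson comorbidity score from a 183-day lookback over the
   patient's admissions; risk class from the age x score grid
   (<60 / 60–74 / 75+ by 0 / 1–2 / 3+).
3. **Network.** Per LSOA, the vector of presentation proportions to each
   regular provider; pairwise cosine similarity

   `sim(A,B) = sum_i A_i B_i / sqrt(sum_i A_i^2 * sum_i B_i^2)`;

   sparsified by a relaxed minimum spanning tree (keep the MST, plus any
   edge shorter than its MST-path bottleneck plus a local nearest-
   neighbour scale).
4. **Communities.** Maximise **Markov stability**
   `r(t,H) = trace[H' (Pi exp(-t(I-M)) - pi pi') H]` with a generalised
   Louvain optimiser across a log-spaced grid of Markov times `t`;
   partitions that stay constant and reproducible (low variation of
   information across restarts) over a stretch of `t` are the robust
   scales, reported fine to coarse.
5. **Balance.** Per community: demand (events by residence), supply
   (events by site), percentage mismatch; per administrative region: the
   **equivalent market size** `EMS = 1 / sum_j s_j^2`, the effective
   number of communities it straddles.

## Worked example

The defaults reproduce the package's reference conditions: 2 regions x 3
subregions x 25 LSOAs, 50,000 synthetic patients, gravity-model site
choice with 5% cross-region leakage.

```r
library(surgcomm)

run <- file.path(tempdir(), "demo")
run_pipeline(pipeline_config(), run, seed = 1)

jsonlite::read_json(file.path(run, "selection.json"))$robust
str(jsonlite::read_json(file.path(run, "summary.json")))
```

The run takes under a minute on one CPU and prints two robust scales:

```
[[1]]  t = 11.3    n_communities = 6    stability = 0.789
[[2]]  t = 464     n_communities = 2    stability = 0.396

partition_1:  k = 6   median |mismatch| = 5.91 %   median EMS = 1.90
partition_2:  k = 2   median |mismatch| = 0.65 %   median EMS = 1.00
```

Reading: the scan found a fine scale of 6 communities (the six planted
subregions; adjusted Rand index 1.0 against the truth labels written to
`truth_labels.csv`) and a coarse scale of 2 (the two planted regions,
ARI 1.0). Median absolute supply–demand mismatch falls from 5.9% at the
fine scale to 0.65% at the coarse scale — coarser communities are more
self-contained — and the median administrative region straddles 1.9
communities at the fine scale but exactly 1 at the coarse scale. Of the
44 procedure codes in play, 2 are HVPs covering 53.4% of the 67,182
events; patients travel 11.3 km on average for them.

Each stage can also be run separately on the same directory
(`stage_simulate()`, `stage_preprocess()`, `stage_risk()`,
`stage_network()`, `stage_detect()`, `stage_report()`), or from a shell
via the thin CLI:

```sh
Rscript inst/cli/surgcomm.R run --config my.yaml --outdir out --seed 1
```

All outputs are plain CSV/JSON/GeoJSON; a fixed `(config, seed)` pair
reproduces every file byte for byte (`manifest.json` records the MD5 of
each output).

## Layout

```
R/                  implementation (one file per pipeline stage)
src/louvain.cpp     generalised Louvain optimiser (Rcpp)
inst/extdata/       Charlson condition-weight maps (CSV)
inst/cli/           command-line front end
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette: models, assumptions, design choices
scripts/            acceptance script (see above)
```
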
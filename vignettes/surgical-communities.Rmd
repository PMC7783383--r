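---
title: "Detecting natural surgical communities from patient-flow data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting natural surgical communities from patient-flow data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Elective surgical care in England is delivered by hundreds of hospital
sites to patients drawn from tens of thousands of small census areas
(LSOAs, around 1,700 residents each). Patients do not respect
administrative planning boundaries: the set of providers that the
residents of one LSOA actually attend is shaped by distance, capacity and
referral habit. When planners want hospitals to share pooled waiting
lists, the natural unit of collaboration is not an administrative region
but a *surgical community*: a group of LSOAs whose residents present to
the same providers, together with those providers.

`surgcomm` implements a pipeline that discovers such communities from
admission-level data and quantifies how self-contained they are:

1. **Preprocessing** reduces raw admissions to countable procedure events
   on the first operative day, merges near-duplicate hospital sites, and
   identifies high-volume procedures (HVPs) and their regular providers.
2. **Risk stratification** computes a Charlson comorbidity score over a
   six-month lookback and classifies each event as low, medium or high
   operative risk from age and score.
3. **Network construction** turns presentation proportions into a cosine
   similarity network over LSOAs and sparsifies it with a relaxed minimum
   spanning tree (RMST).
4. **Multiscale community detection** partitions the network by
   maximising Markov stability across a grid of Markov times and keeps
   the partitions that are robust.
5. **Service analysis** reports per-community caseloads, supply-demand
   mismatch, and the equivalent market size (EMS) of administrative
   regions.

Because admission-level hospital data are confidential, the package
ships a synthetic generator that emulates the relevant structure of such
data; every stage is exercised and tested against it.

## Models and procedures

### From admissions to events

An admission may record several procedure codes on several days. The
*first operative day* is the earliest day offset carrying at least one
countable code after code rules are applied; every countable code on
that day is counted, later days are dropped (procedures after the first
operative day are more likely to reflect complications than planned
activity). The code rules are:

* codes beginning `U`, `Y`, `Z`, `X` (imaging/testing, method, site,
  miscellaneous) are removed and can therefore never anchor the
  operative day;
* a same-day pair of lens extraction (`C71`) and prosthetic lens
  insertion (`C75`) is one procedure (merged code `LENSX`); a lone
  member of the pair passes through unchanged;
* lower-GI endoscopy codes are grouped under one code (`LGIEN`), since
  they frequently co-occur for what is clinically one endoscopy;
  diagnostic upper-GI endoscopy is deliberately *not* grouped;
* after grouping, duplicate identical codes within one day collapse to a
  single event (configurable off). Without this, the grouped endoscopy
  family would double-count single procedures.

Sites within 1 km of each other are treated as one site. We use
single-linkage components of the "closer than 1 km" relation (the
pairwise phrasing is silent on chains; single linkage is the only
transitive closure consistent with treating each close pair as
identical), represented by the highest-volume member, ties broken by
code order.

HVPs are the minimal descending-volume prefix of procedure codes whose
cumulative share *strictly* exceeds 50% of events; the regular providers
of each HVP are the minimal descending-volume prefix of sites reaching
99% (first point at or past the threshold, computed with a 1e-9
tolerance against floating-point rounding).

### Risk classification

The Charlson score sums the weights of the *distinct* comorbid
conditions flagged on the index admission or any admission of the same
patient in the 183 days up to and including the index date ("six
months", operationalised as an inclusive 183-day window). Two condition
maps ship with the package: the classic weighted 17-condition index
(weights 1/2/3/6) and a unit-weight 14-condition variant; which
modification a given study used should be chosen explicitly via
`load_charlson_map()`. Risk is then a 3-by-3 lookup: age bands
{<60, 60-74, 75+} by score bands {0, 1-2, 3+}, from Low (young,
no comorbidity) to High (old or highly comorbid).

### The LSOA similarity network

For each LSOA, the flow vector holds the proportion of its HVP events
presenting to each regular provider site, pooled over all HVPs (a
per-HVP variant that averages per-procedure similarities is available
behind `network$per_hvp`; pooling is the default because community
detection operates on a single network). The similarity of two LSOAs A
and B over the \(n\) provider sites is the cosine

\[
\mathrm{sim}_{AB} \;=\;
\frac{\sum_{i=1}^{n} A_i B_i}
     {\sqrt{\sum_{i=1}^{n} A_i^2}\;\sqrt{\sum_{i=1}^{n} B_i^2}} ,
\]

which is scale-invariant, so no further normalisation is applied.
LSOAs with no eligible events are excluded from the network and later
attached to the community of the nearest included centroid for complete
reporting.

The dense similarity matrix is sparsified with the RMST: distances
\(d = 1 - s\) (bounded, order-reversing, zero at perfect similarity);
the minimum spanning tree is always kept; a direct edge \((i,j)\)
survives whenever

\[
d_{ij} \;<\; \mathrm{maxlink}_{ij} + \min\!\big(d_i^{(k)}, d_j^{(k)}\big),
\]

where \(\mathrm{maxlink}_{ij}\) is the largest single step on the MST
path between \(i\) and \(j\) and \(d_i^{(k)}\) is \(i\)'s distance to
its \(k\)-th nearest neighbour (`k_local`, default 1). This keeps local
neighbourhoods intact without losing global connectivity.

### Markov stability

Communities are found by maximising Markov stability. For a weighted
graph with adjacency \(A\), strengths \(d\), total weight \(2m\),
stationary distribution \(\pi = d/2m\) and transition matrix
\(M = D^{-1}A\), the stability of a partition with indicator matrix
\(H\) at Markov time \(t\) is

\[
r(t, H) \;=\;
\mathrm{trace}\!\left[ H^{\top}\!\left(\Pi\, e^{-t(I-M)} - \pi\pi^{\top}\right) H \right] :
\]

the probability that a stationary continuous-time random walk stays in
the same community over a horizon \(t\), minus the same probability
under independence. Small \(t\) favours many small communities, large
\(t\) few large ones; sweeping \(t\) explores all scales with one
objective. A linearised variant
\(\mathrm{trace}[H^\top((1-t)\Pi + t\,\Pi M - \pi\pi^\top)H]\) (the
first-order expansion, equal to modularity at \(t=1\)) is provided for
graphs too large to exponentiate; the exact propagator is used up to a
few thousand nodes via one spectral decomposition of the symmetrised
Laplacian, after which every \(t\) costs only a rescaling.

The optimiser is a generalised Louvain: greedy node moves on the dense
stability matrix with strict-improvement acceptance (gains below 1e-12
are ties), ties resolved to the lowest community index, followed by
community aggregation, iterated to a fixed point. Each restart shuffles
the level-0 node order from a seed derived from the run index, so the
whole procedure is deterministic given `(graph, t, n_runs, seed)`.

### Scale selection

At each grid time the scan records the best of `n_runs` restarts, the
mean pairwise variation of information (VI) between restarts
(intra-time robustness) and the VI between consecutive best partitions.
A *robust scale* is a run of at least `min_plateau` consecutive grid
points with a constant number of communities and intra-time VI at most
`vi_max`; its representative is the best-scoring partition on the
plateau. Two trivial partitions are excluded: the single block (always
optimal at large enough \(t\)) and all-singletons (optimal as
\(t \to 0\), and returned again when \(e^{-t(I-M)}\) has numerically
converged to stationarity at very large \(t\), where all gains fall
below the tie tolerance). Robust partitions are reported fine to
coarse.

### Service analysis

Each site takes the community of its nearest LSOA centroid (communities
are LSOA sets; the package has no polygons, so nearest-centroid
assignment proxies geographic containment; ties go to the smaller LSOA
code). Demand of a community is the number of HVP events for its
residents; supply is the number performed at its sites; the mismatch is
\(100\,(\text{supply} - \text{demand})/\text{demand}\) (the denominator
is configurable to the supply-demand mean, since "percentage
difference" is ambiguous; demand is the default because capacity
planning asks how well residents' needs are met). Summing over
communities, supply and demand are both exactly the total event count
-- a conservation law the tests assert exactly.

For an administrative region \(i\) with a share \(s_{ij}\) of its LSOAs
in community \(j\), the equivalent market size is
\(\mathrm{EMS}_i = 1/\sum_j s_{ij}^2\), the reciprocal
Herfindahl-Hirschman index: the effective number of communities active
in the region, 1 when boundaries agree, up to \(N\) when maximally
fragmented. Shares are unweighted LSOA counts by default
(population-weighted behind a flag).

## The synthetic generator

`generate_world()` lays out a planar grid: square subregion blocks
(default 0.25 degrees, roughly 28 km) stacked within coarse regions,
regions side by side; LSOA centroids uniform within blocks; two hospital
sites near each block centre. This gives controllable contiguity and a
known two-level truth labelling without shapefiles. Structural quirks of
real admissions data are planted deliberately so the preprocessing rules
have something to do: a configurable fraction of sites gets a twin under
1 km away (site merging), admissions carry excluded-family codes on day
0 and countable codes on day 1 (operative-day logic), lens pairs co-occur
(C71/C75 merging), and lower-GI codes are drawn at high Zipf ranks
(grouping and de-duplication). Procedure volumes follow a Zipf law
(s = 1.2 over 46 countable codes) so a handful of top codes cover about
half of the volume, as in real elective case mix.

Patient choice follows a gravity model: the probability of presenting to
a site is proportional to \(e^{-d/\lambda}\), boosted by a factor
(default 5) for sites homed in the patient's own subregion, with a fixed
total mass (default 0.05) leaking to sites outside the patient's coarse
region. Ages are truncated normal (mean 61.4, SD 16.7, minimum 18);
comorbidity flags are independent Bernoulli per condition, optionally
age-correlated on the logit scale so the age-by-Charlson risk interaction
can be exercised both ways. Administrative region labels re-tile the map
offset by half a block in both axes, so they misalign with the planted
truth by construction and EMS is non-trivial.

Two generator defaults deserve explanation:

* **Decay length** `decay_lambda_km = 20`. The hierarchy is only real if
  a patient's choice mass on *neighbouring same-region subregions*
  exceeds the cross-region leakage. With blocks about 28 km apart, a
  20 km decay puts roughly 10% of choice mass on adjacent same-region
  subregions, above the 5% leakage; a short decay (say 5 km) would drop
  that coupling to a fraction of a percent, below leakage, and the
  "hierarchy" would invert -- cross-region similarity would exceed
  within-region similarity and no coarse scale matching the regions
  would exist to recover.
* **Leakage as a fixed mass.** Leakage rescales total cross-region
  probability to an exact value, which is what makes it a controlled
  experimental knob; set it to `NULL` for pure gravity choice (that is
  also the setting under which flat-gravity choice is provably uniform
  across sites, which the tests use).

What the generator does *not* emulate: real OPCS-4 semantics (codes are
opaque tokens with family tags), road or travel-time distances, seasonal
or day-of-week admission patterns, capacity constraints at sites,
correlated comorbidity profiles, or England's actual geography. Passing
tests on this generator therefore demonstrate that the pipeline's logic
and inference are correct under a known flow model with planted
structure -- not that any particular real health system partitions into
a particular number of communities.

## Numerical choices

* Haversine distances on a sphere of radius 6371.0 km; coordinates are
  validated to their ranges.
* Population-weighted centroids are degree-space weighted means, a
  planar approximation documented as such (synthetic worlds never
  straddle the antimeridian).
* The provider threshold comparison uses a 1e-9 slack; similarities are
  clamped to [0, 1] and the diagonal forced to 1.
* The matrix exponential is computed spectrally from the symmetrised
  Laplacian (exact for the sizes used here); the linearised objective is
  the documented fallback for larger graphs.
* Louvain accepts only strict gains above 1e-12 and breaks ties to the
  lowest community index; restart orders derive from
  `derive_seed(seed, tag)`, so no stage perturbs another's stream and
  pipeline output files are byte-identical across reruns.
* The default Markov-time grid is 40 points, log-spaced from 1e-2 to
  1e5. The upper end is deliberately far above the fine structural
  scale: under the reference generator the coarse (regional) scale only
  becomes optimal at Markov times of order 1e3 to 1e4, and a scan must
  extend past the coarsest structural scale to exhibit its plateau.
  Plateau criteria default to `min_plateau = 4` points and
  `vi_max = 0.05` nats.

## Reference problem sizes

The package's reference conditions (the defaults of `world_config()` and
`pipeline_config()`) are 2 regions x 3 subregions x 25 LSOAs (150
LSOAs), 2 sites per subregion plus twins, 50,000 patients, leakage 0.05
and boost 5, scanned over 40 Markov times with 50 restarts each. The
test suite additionally uses a battery of ten smaller replicate worlds
(12 LSOAs per subregion, 15,000 patients, 32 grid points, 30 restarts)
to check that the median absolute supply-demand mismatch falls from the
finest to the coarsest robust partition, and keeps its exhaustive
optimiser comparisons to graphs of at most 8 nodes, where all set
partitions can be enumerated. These sizes were chosen so that the full
suite runs comfortably on a single CPU while every stage still has
non-trivial structure to find.

## Known limitations

* Mismatch percentages depend on the chosen denominator; comparisons
  across studies that do not state theirs are approximate.
* Site-community assignment by nearest LSOA centroid can misassign a
  site that sits close to a community boundary.
* The Charlson map actually used by any given study may differ from both
  shipped variants; supply a CSV to match a specific modification.
* EMS over unweighted LSOA counts treats small and large LSOAs alike;
  the population-weighted flag changes the reading of "share of a
  region inside a community".
* The RMST relaxation term uses the k-nearest-neighbour local scale with
  `k_local = 1`; other published variants of the technique differ in
  this term, and edge sets are not identical across variants.
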
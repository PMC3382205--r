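---
title: "Reconstructing volatile compounds from aligned GC-MS fragments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing volatile compounds from aligned GC-MS fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocnet)
```

## The problem

Non-targeted headspace GC-MS of fruit volatiles yields, after baseline
correction and alignment, a wide table of *molecular fragments*: each row is
an ion (unit-resolution m/z in the 35–220 scan range) observed at a
retention time, with one intensity per chromatogram. Electron-impact
ionization shatters every compound into several such fragments, so the
table over-counts chemistry by roughly a factor of five. `vocnet`
reconstructs the compound level from the fragment level and then asks two
biological questions: which volatiles are co-regulated (the
metabolite–metabolite correlation network), and which track fruit quality
(trait correlations).

## Multivariate mass spectra reconstruction

The core assumption is that the fragments of one compound are redundant
measurements of the same underlying abundance: across a sufficiently
variable sample set their intensities are proportional, hence almost
perfectly correlated, and they elute together. Two published criteria
formalize this — pairwise Pearson correlation above `r_min = 0.8`, and
co-elution within `rt_window_s = 3` seconds, the maximum chromatographic
peak width at half height on the 60-m column this kind of experiment uses.

`cluster_fragments()` automates what is often finished by manual dendrogram
inspection:

* complete-linkage agglomeration on distance `1 - r`, cut at height
  `1 - r_min`. With complete linkage the merge height of a cluster equals
  its *worst* intra-cluster distance, so the cut guarantees every
  intra-cluster pair satisfies `r >= r_min` — the published rule becomes a
  property of the output rather than a heuristic;
* retention-time enforcement as a separate second pass: clusters whose RT
  span exceeds the window are split at their largest RT gaps until every
  span fits. Keeping the two criteria in separate passes means
  `verify_clusters()` can audit each independently.

Numerical policy: correlations use pairwise-complete observations over
biological *and* reference samples; pairs sharing fewer than
`min_overlap = 10` samples are undefined and treated as distance 2, so they
can never merge (the cut height is at most 1). Fragments are sorted
lexicographically by id before clustering, which fixes merge-tie order and
makes the partition invariant to input order. One-fragment clusters are
kept and flagged as singletons: discarding them would silently hide real
compounds that yield a single usable ion.

Two caveats are worth stating. The window is enforced as a bound on total
cluster *span*, the stricter reading of "eluted within a 3-s window".
And after RT splitting, the output is provably maximal against merging any
two of its own clusters (the test suite checks this by exhaustively
enumerating coarsenings), but maximality against arbitrary regroupings of
fragments is not a theorem of the algorithm.

## Pseudo-spectra, identification, quantification ions

Each cluster's spectrum is assembled from the median of each fragment's
detected intensities, jointly rescaled to base peak 999. The median is
robust to single-chromatogram saturation and replaces any manual choice of
a "most suitable" chromatogram.

Library matching uses cosine similarity on square-root-scaled intensities,
reported on the conventional 0–1000 scale. The *forward* match runs over
the union of m/z bins. The *reverse* match restricts to the query's bins:
a pseudo-spectrum reconstructed from a handful of fragments should not be
penalized for library peaks it never had a chance to contain, so a clean
subset of a library spectrum scores a reverse match of 1000. (A proprietary
library-search formula would not be reproducible; the sqrt-cosine is fully
specified and rank-agrees with dot-product matching.) A candidate is
identified only if the best forward match exceeds `match_min = 800` *and*
every cluster fragment's m/z occurs in the library entry — the containment
rule rejects chimeric clusters that happen to resemble a library spectrum.
Best-hit ties break by higher reverse match, then name, so identification
is library-order independent. Unidentified candidates are named `Ni_01`,
`Ni_02`, … in retention-time order.

The quantification ion is the strongest ion not present in any candidate
eluting within `co_elution_window_s = 9` s (three clustering windows);
if every ion is shared, the base peak is used and a warning raised.

## Reference-normalized quantification

Abundances are `log2(max(signal, floor) / max(ref, floor))`, where `ref` is
the mean quantification-ion signal of the pooled reference injections run
on the *same analysis day* (one pooled mix is injected daily precisely to
track fiber aging and detector drift; same-day normalization is what makes
that correction work, and days with no reference are a hard error naming
the day). Because sample and reference share the day's multiplicative drift
factor, the ratio is exactly drift-invariant — the suite checks that
scaling a whole day by an arbitrary factor leaves that day's values
unchanged. The floor is the 1st percentile of all positive intensities in
the table: it scales with the data's intensity units, keeps missing values
(below the detection floor) finite after the log, and is inert for any
signal comfortably above it.

## Network and trait analysis

Metabolite correlations are Pearson on the log2-normalized values over
biological samples only, with p-values from the t transform on
`n_obs - 2` degrees of freedom. The network keeps edges at `r >= 0.6` or
`r <= -0.6`, labelling `|r| >= 0.7` "strong" — the same conventions used
for published volatile networks — and exports GraphML/SIF for Cytoscape.
Metabolite HCA is complete linkage on `1 - r`; flat groups are cut at
height 0.4 (i.e. r = 0.6) so that group membership and network
connectivity agree. That cut height is a free parameter: published cluster
counts of this kind come from visual inspection, so no single height is
canonical.

Trait tables report, per trait, the `k = 9` strongest significant positive
and negative correlations sorted by `|r|`. Selection uses raw p-values at
`alpha = 0.05` — matching how such tables are conventionally reported — and
a Benjamini–Hochberg column is added for reference only. With 85 samples
the null probability of `|r| >= 0.6` is vanishing (the suite verifies
~0 hits over 1,000 simulated noise traits), so the raw-p convention is not
the liability it would be in smaller designs.

## What the synthetic generator emulates

`generate_truth()` draws compound abundances from a latent-factor model on
the log2 scale:

```
log2 A_cs = base_c + lambda_c * rho_s + gamma_c * g_{G(c),s}
            + genotype effect + N(0, sigma_log)
```

* `rho_s` is a latent ripening score that increases with maturity stage
  (centred at stage 2.5, unit step per stage) and with the shelf-life
  treatment (+0.7), with 0.15 sd of biological scatter;
* every chemical group (lactones, linear esters, lipid-derived volatiles,
  terpenoids, carboxylic acids, long-chain aldehydes, other) has its own
  iid standard-normal factor `g`, and `gamma_c` in 0.8–1.1 ties group
  members together. A planted group is a genuinely co-regulated unit: one
  group-level ripening loading is drawn per group and compounds scatter
  only ±0.15 around it. (A consequence: in the noise-free limit,
  within-group correlations approach but do not reach exactly 1, because
  small loading differences are structure, not noise — fragments of one
  *compound* are exactly rank-1.)
* lactones load positively on ripening (1.2–1.8 log2 units per unit score)
  and lipid-derived "green note" volatiles negatively (−1.8 to −1.2),
  which plants the lactone ↔ lipid anticorrelation that must surface as
  negative network edges;
* traits are driven by the same `rho`: colour index `1 + 4.5*rho` (green
  fruit negative, ripening positive), firmness `4.2 - 1.5*rho` kgf, weight
  and soluble solids weakly coupled (15 g and 0.8 °Brix per unit), each
  with realistic measurement scatter.

The default design mirrors a multi-genotype stone-fruit study: four
genotypes, two followed over four maturity stages, one grown in two
locations, everything measured at harvest and after shelf life — 22
condition cells of 3–4 fruits totalling exactly 85 biological samples,
plus 12 daily pooled references across 12 analysis days and 5 blanks.
Per-cell fruit counts are this package's fixed allocation within the
published 3–6 range. Rendering multiplies abundance by the fragment
pattern (3–8 fragments per compound, base 999), a per-day drift factor
(default 0.97^(day−1)), and log-normal noise, adds baseline noise, and
censors values below `peak_threshold_factor × baseline_sd = 10 × 40` — the
detection-floor reading of an alignment tool's peak-threshold setting.
`sigma_log = 0.15` is used both for sample-level abundance scatter and for
per-fragment rendering noise; one knob controls both layers. Contaminants
are planted at siloxane m/z values inside the scan range (73, 147, 207,
208) in every injection including blanks; references carry the
all-biological-sample mean profile, i.e. a pooled mix.

What the generator does **not** emulate: chromatographic co-elution with
shared m/z bins between overlapping spectra, mass error, retention-time
misalignment (fragments are emitted pre-aligned; the upstream alignment
step is out of scope), saturation, or genotype-by-environment structure
beyond a per-genotype offset. Passing recovery tests therefore shows the
reconstruction logic is correct under the stated model, not that the
pipeline deconvolves heavily overlapping real chromatograms — true
co-elution recovery depends on upstream deconvolution quality.

Compound retention times are spread ~35 s apart with ±10 s jitter, and
fragment RT jitter is 0.5 s sd, so true compounds stay well inside the 3-s
window and distinct compounds far outside it; effect sizes for genotype
and location are free parameters of the generator, not estimates.

## Contaminant filtering

Blank evidence is required throughout, per fragment. `flag_blank_present()`
flags a fragment detected in ≥ 50% of blanks whose mean blank intensity is
at least 10% of its biological median — the second condition protects
analytes that bleed marginally into blanks by carry-over.
`flag_polysiloxane()` additionally requires the m/z to lie on the siloxane
series {73, 147, 207, 208, 221, 281}; m/z alone is never sufficient since
genuine analytes also produce ions at these masses. Both thresholds are
configurable; whole-branch exclusion (flagging entire dendrogram limbs) is
deliberately not implemented — per-fragment flagging is auditable.

## Problem sizes and determinism

The test suite runs the full default-scale design (85 + 12 + 5 samples,
~60 compounds, ~336 fragments) once, plus many reduced designs (16 + 4 + 2
samples, 14 compounds) chosen so the whole suite completes in a few
seconds; the exhaustive partition oracle uses 10 fragments in 3 clusters,
where all coarsenings can be enumerated. All generator randomness flows
from the design seed (truth uses `seed`, rendering `seed + 1`), so equal
seeds give byte-identical tables and the pipeline itself is
deterministic — rerunning on the same inputs reproduces every stage output
file byte for byte.

## Known limitations

* Exact-set compound recovery (precision/recall in
  `score_against_truth()`) is strict: one stray fragment fails the match
  even when the quantification ion is still clean.
* The reverse match is informative only when the query is fragment-poor
  relative to the library entry; it is not a NIST reverse-search clone.
* The percentile floor couples all samples weakly through the global
  intensity distribution; per-batch floors are not implemented.
* Retention-index calibration, isotope patterns and model-peak
  deconvolution are out of scope; identifications are "putative" in the
  usual library-match sense.
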
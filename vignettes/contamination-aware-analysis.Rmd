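---
title: "Contamination-aware community analysis of low-biomass subsurface amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contamination-aware community analysis of low-biomass subsurface amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tephra)
```

## The problem

Amplicon surveys of the rocky subsurface work with nanograms of DNA per
tens of grams of rock. At that biomass, three contamination vectors can
contribute as many reads as the community of interest:

* **drilling fluid** — coring requires a circulating fluid; when that fluid
  is seawater (even filtered and UV-treated), marine taxa and taxa that
  bloom in the stored fluid are smeared across every core;
* **natural seawater inflow** — in a young, porous marine volcanic deposit,
  cool seawater infiltrates the deeper submarine section, so some marine
  taxa are *true* residents at depth and must not be discarded;
* **reagents** — DNA extraction kits and PCR reagents carry their own
  well-documented flora, visible in extraction negative controls.

`tephra` implements a decontamination cascade that attacks each vector
with its own evidence source, followed by the standard community-ecology
battery (rarefaction, alpha diversity with ANOVA/Tukey, Bray-Curtis, NMDS,
PERMANOVA, environmental vector fitting) and a simple negative-binomial
differential-abundance test. A synthetic-community generator with ground
truth closes the loop: every stage can be validated end to end against
planted contaminants.

## The decontamination cascade

### Stage 1 — prevalence test against negative controls

For each feature detected in at least one negative control, build the 2x2
table `[present, absent] x [true samples, negative controls]` (presence =
count `>= min_count`, default any read). The two-sided p-value is a
Pearson chi-square without continuity correction; whenever any expected
cell is below 5 (the standard small-sample rule) the test falls back to
Fisher's exact test. A feature is removed when `p < threshold` **and** its
prevalence fraction is higher in controls than in true samples. The
default threshold is 0.5 — deliberately aggressive: at this stage a coin
flip's worth of evidence that a feature tracks the controls is enough,
because reagent taxa missed here are carried into every downstream
statistic. The directional condition prevents the opposite mistake: a
genuine resident that happens to appear in a control is never flagged,
however small its p-value. Features absent from all controls are retained
untested.

### Stage 2 — taxonomy screen

Five deterministic lineage rules: order `Chloroplast`, family
`Mitochondria`, kingdom `Eukaryota`, unassigned kingdom, and genus on a
user-editable blocklist (case-insensitive exact match). All missing-name
spellings (`NA`, empty, `unclassified`, `Unknown`) are canonicalized to a
single `UNASSIGNED` sentinel at read time precisely so these rules are
deterministic. `default_blocklist()` ships a small illustrative set of
classic kit contaminants; real studies should substitute their own curated
list — published compilations run to dozens of genera.

### Stage 3 — overlap classification

The geologically informed stage. Samples are grouped into subaerial drill
cores (`SUB_A`), submarine drill cores (`SUB_M`), drilling fluid (`DF`)
and seawater (`SW`); each feature's presence pattern across the four
groups drives three rules, evaluated in priority order:

1. **R1 (remove)** `SUB_A & (DF | SW)` — the subaerial deposit sits above
   coastal sea level, fed by meteoric water, with a hot tidal-flux zone
   beneath it acting as a thermal barrier; no marine taxon should occur
   there. Presence in subaerial cores *and* a marine source is therefore
   diagnostic of fluid carryover.
2. **R3 (retain)** `SUB_M & DF & SW` (and not `SUB_A`) — marine taxa found
   in submarine cores, the fluid *and* the sea are consistent with the
   natural seawater inflow into the deep submarine section and are kept.
3. **R2 (remove)** `SUB_M & DF` — shared only between submarine cores and
   the fluid: carryover of taxa that bloomed in the recirculated fluid.

Everything else is an endemic candidate. R1 outranks R3 so that a feature
present in all four groups is removed: subaerial presence trumps the
inflow excuse. Because only the presence pattern matters, the verdicts are
invariant to how counts are distributed within a group and to feature
order — both properties are tested.

The default subaerial/submarine boundary is 58 m below surface (the zone
of tidal flux); `default_overlap_groups()` exposes it, and
`presence_pattern()` accepts any explicit group map for designs where the
boundary is contested.

Removal deletes the feature's whole row rather than zeroing it per sample:
a contaminant identified anywhere is untrustworthy everywhere, and row
deletion keeps per-group feature tallies interpretable. Cleaned datasets
drop the drilling-fluid and negative-control samples, which have served
their purpose once the calls are made.

## Community statistics

* **Rarefaction** subsamples each library without replacement to an even
  depth (default: the minimum library size), seeded and reproducible.
  Samples below the depth are dropped with a warning.
* **Alpha diversity**: observed richness and Shannon `H = -sum p log p` in
  natural log (the phyloseq convention). Group differences use classical
  one-way ANOVA and Tukey HSD on the studentized range.
* **Bray-Curtis** dissimilarity feeds the beta-diversity stack.
* **NMDS** minimizes Kruskal stress-1 with pool-adjacent-violators
  isotonic regression (primary tie handling: tied dissimilarities are
  ordered by the current configuration distances) and Guttman-transform
  majorization. An update is accepted only if stress does not increase, so
  the stress trace is non-increasing by construction; iteration stops when
  the improvement falls below `tol` (1e-7 on the [0,1] stress scale) or no
  improving step exists. Restart 1 starts from classical metric scaling,
  the remaining 19 from random Gaussian configurations; the best of 20
  wins, and the stored stress is recomputed from the returned coordinates
  (they match to 1e-10 by contract). Note that sharply clustered data —
  including the default synthetic communities — can reach near-zero
  stress through the well-known cluster-collapse quasi-degeneracy of
  NMDS; a stress that low on real data is a red flag, not a triumph.
* **PERMANOVA** partitions squared dissimilarities
  (`SS_total = (1/N) sum_{j<k} d^2`, within-group terms weighted `1/n_g`)
  into a pseudo-F, with `p = (1 + #[F_perm >= F_obs]) / (1 + m)` under
  free label permutation. `exhaustive = TRUE` enumerates all label
  permutations, which makes the permutation p exactly equal to the
  enumeration over distinct group assignments — used at small n where
  sampled permutations cannot be exact. Pairwise comparisons run on each
  pair's sub-matrix with Benjamini-Hochberg adjustment (the conventional
  choice where only "adjusted p" is specified).
* **envfit** regresses each centered environmental variable on the
  ordination axes; `r^2 = 1 - SS_res/SS_tot`, direction is the unit
  coefficient vector, significance by permuting the variable. Samples
  with a missing value are dropped from that variable's fit with a logged
  warning — the reader keeps such samples, and each downstream operation
  declares its own exclusion rule.

## Differential abundance

`nb_wald_two_group()` is a deliberately simple count-based test and says
so: median-of-ratios size factors (geometric means over positive counts),
a method-of-moments dispersion `alpha = max(alpha_min, (V - mu)/mu^2)`
floored at `alpha_min = 1e-8`, a pseudo-count of 0.5 stabilizing
`lfc = log2((mu_B + 0.5)/(mu_A + 0.5))` when a group mean is zero, a
delta-method standard error and a normal Wald p-value with BH adjustment
(significance convention: adjusted p below 0.01). There is no dispersion
shrinkage, no GLM iteration and no LFC shrinkage, so feature lists will
not match shrinkage-based tools on real data; what the package promises —
and tests — is the statistical contract: type-I error near nominal under a
null negative-binomial simulation and unbiased recovery of a planted fold
change. One consequence of normalization worth remembering: a fold change
shared by *every* feature is absorbed into the size factors and is
unidentifiable; validation simulations therefore plant effects on a
subset of features over a null background.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` draws five feature pools (defaults: 60 subaerial
endemics, 120 submarine endemics, 70 seawater taxa, 35 fluid-specific
taxa, 15 reagent taxa; 300 features) with fixed log-normal base
abundances (`meanlog 0, sdlog 1`) — the habitat signal lives in the
mixing, not in per-sample abundance noise. Endemic features carry a
Gaussian thermal niche (optima uniform on 10-125 °C, width 25 °C, chosen
once so that communities along a 20-124 °C borehole profile overlap but
remain distinguishable). The sampling design mirrors a real drilling
campaign: 17 drill cores at fixed depths/temperatures in four depth
categories (2 + 3 + 7 + 5), 18 borehole fluids, 2 fumaroles, 4 seawater
profiles, 8 drilling-fluid aliquots, 2 negative controls; library sizes
are log-normal around 30,000 reads (sdlog 0.3) and counts multinomial.

Contamination enters three ways. Each core's expected composition is
`(1 - c_j) * true community + c_j * fluid-specific profile` with
`c_j ~ Beta(2, 6)` (mean 25%, long right tail — a modelling choice, since
only an order-of-magnitude carryover average is ever reported for real
operations). Deep (DC_4) cores receive 10% seawater-pool mass as natural
inflow, which is part of their *true* community, not of the carryover.
Negative controls contain the reagent pool; 5% of reagent features carry
blocklisted genera and 2% of all features carry order `Chloroplast`, so
the taxonomy screen has planted targets.

A design decision deserves emphasis: the carryover component into cores is
the *fluid-specific* pool, while drilling-fluid samples themselves contain
the seawater pool plus the fluid-specific pool. The alternative — carrying
the full fluid profile, seawater taxa included, into every core — puts
every seawater taxon into the subaerial cores, where rule R1 removes the
entire seawater pool and the retained-inflow class R3 can never occur.
That scenario describes a catastrophically contaminated study in which
contaminants and inflow are genuinely confounded; the generator instead
models the regime the classifier is designed for, where the three verdict
classes (R1/R2 removals, R3 retention) are all realized and recovery can
be scored per class.

The generator does **not** emulate: sequencing error, chimeras or PCR
bias (features are abstract, no read-level process); taxonomic or
phylogenetic correlation of abundances; batch or run effects; overdispersion
beyond multinomial sampling; cross-contamination between true samples; or
compositional artifacts of varying extraction efficiency. Passing the
recovery tests therefore shows that the cascade's logic is correct under
its own model — clean pools, presence-driven sharing — not that it will
reach the same F1 on real data, where contaminant and resident abundances
correlate and presence patterns are noisier.

## Numerical choices and degenerate inputs

* All randomized procedures (simulation, rarefaction, NMDS restarts,
  permutation tests) consume an explicit seed through an isolated RNG
  scope; nothing touches the caller's RNG state, and the pipeline derives
  per-stage seeds from one global integer by fixed offsets.
* Prevalence p-values exactly at the threshold are a knife edge: `p <
  0.5` on a table whose exact p is 0.5 is decided by floating-point
  summation order. The implementation makes no special case; the test
  suite treats such tables as ties.
* All-zero samples are errors (named) in Bray-Curtis, richness and
  Shannon rather than silent NaNs; an all-zero distance matrix yields
  pseudo-F 0 with p 1.
* Permutation p-values use the add-one convention and can never be 0;
  with m permutations the floor is `1/(m+1)`.
* `harmonize()` is idempotent, drops unannotated samples with a warning,
  and backfills missing taxonomy with `UNASSIGNED` rows, so every
  downstream operation can assume a fully annotated dataset.

## Validation scale

The shipped validation suite runs at desk scale: the default 300-feature,
51-sample simulation for recovery and end-to-end checks; exhaustive
permutation enumeration at n = 5-6; 500 null simulations (199 permutations
each) for PERMANOVA calibration; 2,000 null features for the
differential-abundance type-I check; 1,000 rarefaction draws against the
hypergeometric closed form. These sizes were chosen so the full suite
completes in about a minute while keeping Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

* The prevalence stage uses presence/absence only; a frequency-based
  (DNA-concentration) score and batch-aware designs are out of scope.
* The overlap classifier is sharp: a single stray read in a subaerial
  core flips a feature from R3 to R1. `min_count` is the only blunting
  knob.
* The differential-abundance stage is the declared simplification above;
  use it for ranking and calibration-checked screening, not as a drop-in
  replacement for shrinkage estimators.
* NMDS on strongly clustered data can collapse clusters and report
  near-zero stress; compare with the PERMANOVA R^2 rather than reading
  stress alone.
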
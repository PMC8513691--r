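# tephra

Contamination-aware 16S rRNA amplicon community analysis for low-biomass
subsurface samples.

Rock cores recovered by drilling carry three kinds of unwanted DNA on top
of the resident community: taxa smeared across every core by the
circulating drilling fluid (often seawater), marine taxa that *naturally*
infiltrate the deeper submarine deposits and must not be thrown away, and
the reagent flora visible in extraction negative controls. `tephra` is for
microbiologists analysing ASV tables from such campaigns: it removes the
first and third signal, keeps the second, and then runs the standard
community-ecology battery on the cleaned data.

## What it does

**Three-stage decontamination cascade**

1. *Prevalence test* — per feature, the 2x2 presence table
   `[present, absent] x [true samples, negative controls]` is tested with a
   chi-square (Fisher's exact when any expected cell < 5); a feature is
   removed when `p < 0.5` and it is proportionally more prevalent in the
   controls.
2. *Taxonomy screen* — order Chloroplast, family Mitochondria, kingdom
   Eukaryota, unassigned kingdom, and a user-editable genus blocklist.
3. *Overlap classifier* — features are scored by presence across four
   sample groups: subaerial cores (SUB_A), submarine cores (SUB_M),
   drilling fluid (DF), seawater (SW). In priority order:

   | rule | pattern | verdict |
   |------|---------|---------|
   | R1 | `SUB_A & (DF \| SW)` | remove — no marine taxon belongs in the subaerial deposit |
   | R3 | `SUB_M & DF & SW`, not `SUB_A` | retain — consistent with natural seawater inflow |
   | R2 | `SUB_M & DF` | remove — drilling-fluid carryover |
   | — | anything else | endemic candidate |

**Community statistics** — seeded rarefaction to even depth; observed and
Shannon diversity with one-way ANOVA and Tukey HSD; Bray-Curtis
dissimilarity; NMDS (Kruskal stress-1, isotonic regression, 20 restarts);
PERMANOVA (`pseudo-F`, free label permutation, exact enumeration at small
n) with pairwise BH-adjusted comparisons; envfit-style fitting of depth
and temperature vectors onto the ordination.

**Differential abundance** — a simple two-group negative-binomial Wald
test (median-of-ratios normalization, method-of-moments dispersion, BH
adjustment). Deliberately shrinkage-free; see the vignette for what that
does and does not buy you.

**Synthetic communities with ground truth** — `simulate_dataset()` draws a
full campaign (endemic pools on a thermal niche gradient, drilling-fluid
carryover `c_j ~ Beta(2,6)`, 10% seawater inflow into the deep cores,
reagent taxa in the controls) and labels every feature's origin, so the
whole cascade can be scored with precision/recall/F1 and compositional
error against the known target communities.

## Worked example

```r
library(tephra)

sim <- simulate_dataset(sim_config(), seed = 42)
sim$dataset
#> <tephra_dataset> 300 features x 51 samples
#> sample types: borehole_fluid (18), drill_core (17), drilling_fluid (8),
#>   fumarole (2), negative_control (2), seawater (4)

dec <- decontaminate(sim$dataset)
dec$summary
#> # A tibble: 4 x 3
#>   stage      rule                n_features
#> 1 overlap    R1_subaerial_marine         35
#> 2 prevalence prevalence_p                15
#> 3 taxonomy   chloroplast                  6
#> 4 taxonomy   genus_blocklist              1

evaluate_calls(dec$calls, sim$truth)
#> # A tibble: 1 x 8
#>      tp    fp    fn    tn precision recall    f1 precision_defined
#> 1    50     6     0   244     0.893      1 0.943 TRUE
```

All 35 fluid-specific and 15 reagent features are recovered (recall 1);
the six false positives are endemic features that the simulator planted
with a Chloroplast lineage, which the taxonomy screen removes by design.
Cleaning brings the mean Bray-Curtis distance of the drill cores to their
true communities from 0.198 down to 0.040:

```r
composition_error(sim$dataset$counts, sim$truth)   # 0.198
composition_error(dec$cleaned$counts, sim$truth)   # 0.040
```

Downstream statistics on the cleaned data:

```r
rare <- rarefy_even_depth(dec$cleaned$counts, seed = 1)
d    <- bray_curtis(rare)
ord  <- nmds(d, seed = 1)
grp  <- dec$cleaned$metadata$sample_type[match(labels(d),
          dec$cleaned$metadata$sample_id)]
permanova(d, grp, n_permutations = 999, seed = 1)
#> # A tibble: 1 x 7
#>   name      statistic df_between df_within n_permutations     p r_squared
#> 1 permanova      9.70          3        37            999 0.001     0.440
```

Habitat explains 44% of the community variance (pseudo-F = 9.70, the
permutation floor p = 0.001 at 999 permutations). On the drill-core
ordination, depth fits with r² = 0.59 (p = 0.003) and temperature with
r² = 0.29 (p = 0.089) — the simulated communities are structured along the
borehole gradient, as designed. `autoplot(ord, metadata)` draws the
ordination; `tidy()` / `glance()` expose coordinates and stress.

## Further reading

The methods vignette
(`vignettes/contamination-aware-analysis.Rmd`) documents the model behind
each stage, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the numerical
conventions (seeding, tie handling, degenerate inputs).
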
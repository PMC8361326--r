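# mklconn

Multi-kernel SVM classification of multi-weight structural brain
connectomes, for researchers who study group differences (e.g. patients
vs. controls) in diffusion-MRI white-matter networks.

A tractography connectome over the 90-region AAL parcellation can be
weighted three ways on the same topology: streamline count (FN), mean
fractional anisotropy of the connecting fibers (FA), and mean diffusivity
(MD). `mklconn` treats the `3 × 4,005 = 12,015` edge weights of each
subject as features and classifies subjects with a multiple-kernel
support vector machine whose kernel is a learned convex combination of
one kernel per network:

```
max_α  Σᵢ αᵢ − ½ Σᵢⱼ αᵢαⱼ yᵢyⱼ Σₘ βₘ k⁽ᵐ⁾(xᵢ⁽ᵐ⁾, xⱼ⁽ᵐ⁾)
s.t.   Σᵢ αᵢyᵢ = 0,  0 ≤ αᵢ ≤ C,   βₘ ≥ 0, Σₘ βₘ = 1
f(x) = sign( Σᵢ αᵢyᵢ Σₘ βₘ k⁽ᵐ⁾(xᵢ⁽ᵐ⁾, x⁽ᵐ⁾) + b )
```

The inner dual is solved by a compiled SMO solver; the kernel weights β
are learned by reduced-gradient descent on the probability simplex (the
simpleMKL scheme). Around the classifier the package provides:

* construction of FN/FA/MD networks from labeled streamline sets, with
  strict co-topology invariants, plus delimited-matrix / manifest I/O;
* F-score and lasso feature selection;
* leakage-safe leave-one-out cross-validation (fold-wise normalization
  and selection on training rows only), grid search over C and the
  selected-feature fraction, confusion metrics and rank-statistic
  ROC/AUC;
* a consensus discriminative-edge report (|hyperplane coefficient| ×
  network weight, averaged over folds, aggregated per edge and network);
* a synthetic cohort generator with controllable group effects, so the
  full pipeline is testable without MRI data.

## Worked example

Simulate a 90-node cohort of 20 controls and 20 patients in which 12
edges carry the expected degeneration pattern (FN −1 SD, FA −1 SD,
MD +1.5 SD), then cross-validate the multi-kernel classifier:

```r
library(mklconn)

cfg <- cohort_config(
  n_nodes = 90, density = 0.15, n_per_group = c(20, 20),
  effect = group_effect_spec(effect_fn = -1, effect_fa = -1,
                             effect_md = 1.5, n_affected = 12),
  seed = 42)
cohort <- generate_cohort(cfg)
tab <- vectorize_cohort(cohort)
tab
#> feature_table: 40 subjects x 12015 features (90 nodes, 3 networks), labels 20/20

report <- loocv(tab, C = 1, count_or_fraction = 0.0014)
report
#> evaluation_report (multi_kernel, fscore): acc 1.000, sens 1.000, spec 1.000, AUC 1.000 (n = 40)

dr <- discriminative_report(tab, report$folds)
dr
#> discriminative_report: 10 consensus features, 8 edges
#> network totals: FN 0.060, FA 0.112, MD 1.270
head(dr$edge_weights, 3)
#>    i  j          region_i          region_j    weight
#> 1 33 40    Cingulum_Mid_L ParaHippocampal_R 0.2849891
#> 7 43 51       Calcarine_L   Occipital_Mid_L 0.2696589
#> 4 13 16 Frontal_Inf_Tri_L Frontal_Inf_Orb_R 0.2216855
```

`count_or_fraction = 0.0014` selects `round(0.0014 × 12015) = 17`
top-F-score columns per fold. The injected 1.5-SD effect separates the
groups perfectly (accuracy and AUC 1.0 over 40 folds); the learned
kernel weights and the network totals both identify MD — the weighting
that carries the largest injected effect — as dominant, and the top
consensus edges are the injected ones. On real cohorts accuracies are
far from 1 and the grid search (`grid_search`, C 0.5–5, fraction
0.0014–0.0028) matters; see the vignette for the method's assumptions
and biases.

A thin command-line wrapper with `simulate`, `build-network`,
`run-loocv`, `grid-search` and `report-features` subcommands is installed
at `inst/cli/mklconn.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mklconn.R", package = "mklconn"))')" \
  simulate --out sim --seed 7
```

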
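# patchentropy

Patch-based spatio-temporal entropy decomposition and weighted multiway
correspondence analysis for categorical and compositional grid data.

## What it is for

Ecologists, geographers and epidemiologists often ask not just *how mixed*
a categorical map is, but *how its mixing is organised in space and time*:
do land-cover classes form a few large persistent patches or many small
ephemeral ones, and which categories drive the structure? Plain Shannon
entropy of the category distribution cannot answer this — it is invariant
to any spatial rearrangement. `patchentropy` makes the spatio-temporal
organisation itself the object of measurement. From a compositional grid
time series (per cell, time and category, a fraction of occupation) it:

1. builds **spatial patches** (connected cells with fraction above a
   threshold, per category and time) and **temporal patches** (maximal
   runs of consecutive above-threshold steps, per category and cell), and
   classifies their sizes (`Si`, `Ti`), shapes (`Sh`, via seeded clustering
   of geometric features) and ordinal motifs (`Th`, permutation patterns);
2. crosses the resulting labels into a **multiway distribution-like
   table** — occurrences, patch occurrences, order-*k* co-occurrences
   under a per-dimension distance rule, or distance-ratio weights;
3. quantifies the structuring by **entropy decomposition** and by
   **multiway correspondence analysis**.

The entropy machinery covers the decomposition chain
`H(S,T,C) = H(S) + H(T|S) + H(C|S,T)`, mutual information, the normalized
forms `Hu = H / log(cardinality)` with their log-cardinality combination
weights

```
Hu(S,C) = log|S|/(log|S|+log|C|) * Hu(S) + log|C|/(log|S|+log|C|) * Hu(C|S)
```

conditional-entropy ratios, and per-cell heterogeneity maps. The multiway
correspondence analysis decomposes the ratio-to-independence tensor into
rank-one components under the margin-weighted metric,

```
p_STC / (pS x pT x pC) = 1 + sum_r sigma_r (vS_r x vT_r x vC_r),
sum_r sigma_r^2 = 1 + chi^2/N,
```

with CTR (relative-contribution) tensors, CTR-entropy summaries, analytic
positive splitting of signed rank-one tensors, and signed per-cell score
maps. A seeded softmax-of-Gaussian-fields generator supplies realistic
synthetic compositions so every stage is testable without any download.

## Worked example

```r
library(patchentropy)

g   <- simulate_composition(simulation_spec(n_rows = 14, n_cols = 14,
                                            n_times = 24, n_categories = 11,
                                            seed = 11))
u   <- label_patch_units(g, threshold = 0.15)       # cells -> patches, Si, Ti
tab <- occurrence_table(u, modes = c("Si", "Ti", "category"))
tab
#> multiway_table (occurrence): Si(7) x Ti(8) x category(11), N = 3525.66

entropy_decompose(tab, chain = c("Si", "Ti", "category"))
#> entropy_report — chain: Si -> Ti -> category
#>   H(joint) = 2.160523 nats; MI = 1.115625
#>   H(Si) = 1.236302
#>   H(Ti|Si) = 0.514782
#>   H(category|Si,Ti) = 0.409439
#>   Hu(joint) = 0.3363599; weights: Si=0.3029481, Ti=0.3237368, category=0.3733151
#>   Hu(Si) = 0.6353336
#>   Hu(Ti|Si) = 0.2475578
#>   Hu(category|Si,Ti) = 0.1707492
#>   max identity residual: 5.55e-17

decompose_fca(tab, n_components = 4, seed = 11)
#> mwca_result: chi2/N = 12.618904, total SS = 13.618904, residual 1.64e+00
#>   r=0  sigma = 1.000000  share = 7.34%
#>   r=1  sigma = 2.723950  share = 54.48%
#>   r=2  sigma = 0.997520  share = 7.31%
#>   r=3  sigma = 0.932613  share = 6.39%
#>   r=4  sigma = 0.795355  share = 4.64%
```

Reading the output: the 7×8×11 table crosses spatial size classes
(`1, 2, >2, >7, >25, >50, >100`), temporal size classes
(`1, 2, >2, >4, >7, >20, >30, >60`) and the 11 categories, with each
above-threshold cell weighted by its fraction. A joint `Hu` of 0.34 says
the occurrence mass is far from uniform over label combinations; the small
`Hu(category|Si,Ti)` says size classes largely determine the category mix.
In the correspondence analysis, complete independence (component 0, always
`sigma = 1` with all-ones vectors) holds 7.3% of the variability while the
leading rank-one interaction pattern holds 54.5%; its signed CTR tables
(`ctr(fit, 1)`) name which size classes and categories associate. The same
pipeline runs from a shell via `exec/patchentropy` with a YAML config
(subcommands `simulate`, `patches`, `tabulate`, `entropy`, `fca`, `run`),
writing a checksummed artifact manifest.

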
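# prognet

Discovery and evaluation of prognostic gene-network modules for basal-like
breast cancer (BLBC), with a fully synthetic test world.

## The problem

BLBC patients split into clinically distinct groups — early relapse versus
long-term survival — that neither standard clinical variables nor
general-purpose genomic signatures (built around proliferation and ER
biology) can separate. `prognet` implements a network-based approach:

1. screen the most variably expressed probes with univariate Cox
   proportional-hazards regression (select `p < 0.05`, direction from the
   hazard ratio);
2. map the selected genes onto a functional interaction network and weight
   each edge with `|Pearson r|` of the two genes' expression;
3. cluster the weighted network with Markov clustering (MCL) and keep
   modules of ≥ 8 genes with mean pairwise Pearson correlation ≥ 0.25;
4. score each sample per module with the **module index**

   ![index](https://latex.codecogs.com/svg.image?I=\Big(\textstyle\prod_{i\in%20P}x_i\Big)^{1/n_P}-\Big(\textstyle\prod_{j\in%20N}x_j\Big)^{1/n_N})

   the difference of geometric means of log2 expression between
   poor-outcome genes `P` and good-outcome genes `N`, and with the
   **combination index** (mean of all module indices);
5. stratify at the median combination index and evaluate with Kaplan–Meier
   curves, the log-rank test, and per-unit-index Cox hazard ratios.

The Cox partial likelihood (Efron/Breslow ties), Kaplan–Meier estimator,
log-rank test and Cox score test are implemented from first principles and
cross-checked against independent oracles in the test suite. The package
also provides nearest-centroid molecular subtyping (Spearman correlation to
standardized centroids over an intrinsic gene list), hypergeometric pathway
over-representation with BH FDR, and a 3-marker immunohistochemistry
composite risk score (`Allred_JUN − Allred_CD8 − Allred_CD20`, range
[−16, 8], max over three cores per marker).

A synthetic-cohort generator plants co-expressed, network-coherent,
prognostic modules with known ground truth (rank-1 latent-factor expression
model, exponential proportional-hazards survival, calibrated censoring), so
every stage is testable without any external download.

## Worked example

```r
library(prognet)

cfg    <- synthetic_config(seed = 7)       # 500 genes, 300 samples,
cohort <- simulate_cohort(cfg)             # two planted 12-gene modules
disc   <- run_discovery(cohort)
for (m in disc$modules) print(m)

vcoh <- simulate_cohort(synthetic_config(seed = 1007))  # independent cohort
rep  <- run_validation(disc$modules, vcoh$expr, vcoh$surv)
print(rep$table, digits = 3)
```

prints

```
module 0 - 13 genes, mean pairwise r = 0.509
  poor: 1  good: 12
module 1 - 12 genes, mean pairwise r = 0.581
  poor: 12  good: 0

       module hazard_ratio  p_value hr_groups logrank_p surv_low surv_high
1    module_0         1.23 1.13e-05      1.54  1.42e-03    0.406     0.228
2    module_1         1.56 8.87e-15      2.06  7.03e-08    0.445     0.196
3 combination         2.10 3.73e-20      2.47  5.47e-11    0.471     0.170
```

Both planted modules are recovered (one good-outcome, one poor-outcome;
module 0 picked up one chance-selected extra gene — a known property of MCL,
which assigns pendant nodes to their only neighbour's cluster). On the
independent validation cohort, each module index predicts survival per unit
increase (`hazard_ratio`, Wald `p_value`), the median split separates risk
groups (`hr_groups` = high-vs-low Cox HR, `logrank_p`), and the high-risk
group has much worse 10-year (120-month) survival (`surv_high` vs
`surv_low`). The combination index beats either single module, as expected
when modules carry complementary signal.

## Command-line interface

`inst/cli/prognet.R` wraps the main stages:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","prognet.R",package="prognet"))')" \
    simulate --seed 7 --n-genes 200 --n-samples 150 --out cohort/
# ... modules / score / evaluate / ihc — see the script header
```

Exit codes: 0 ok, 2 input/format error, 3 numerical error.
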
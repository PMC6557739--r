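# scipso

Hybrid gene selection for labelled expression matrices: a three-level
filter cascade followed by an improved particle swarm optimizer, with an
extreme learning machine (ELM) as the in-the-loop classifier.

## Who this is for

Analysts with a samples × genes expression matrix (microarray or counts
already normalized to expression levels) and a class label per sample —
tumor subtype, responder status — who want a *small* gene subset (3–13
genes) that discriminates the classes, plus a stability report saying which
genes are selected repeatedly.

## The method

1. **IIC ranking (level 1).** Each gene is scored by the information index
   to classification,
   `d(g) = Σ_j Σ_{k≠j} [ ½·|μ_j−μ_k|/(σ_j+σ_k) + ½·ln((σ_j²+σ_k²)/(2σ_jσ_k)) ]`,
   computed per class on the training split; the top 200–400 genes form the
   first-level pool.
2. **Randomized screening (level 2).** Thousands of random subsets of the
   pool are scored by stratified 5-fold cross-validation accuracy of an
   ELM; subsets below a threshold `θ_ac` are deleted, survivors ranked
   1..l_se by accuracy.
3. **Gene scoring (level 3).** Each gene's score is the sum of reversed
   ranks `l_se − R_j + 1` over surviving subsets containing it, min–max
   normalized; the top 40 genes form the search pool.
4. **Improved PSO.** Particles are integer-coded gene subsets of fixed size
   D; velocity updates use a linearly decreasing inertia weight (0.9 → 0.4,
   `c1 = c2 = 1.49445`). The swarm's best position is updated by a
   Metropolis criterion (`accept near-ties with p = exp(−|Δf|/T)`) under a
   linearly annealed temperature, and half the swarm is reinitialized after
   `N_mu = 3` stagnant generations. Fitness is the same 5-fold CV ELM
   accuracy.

The ELM trains in one linear solve — output weights are the minimum-norm
least-squares solution `w_o = H⁺T` via the Moore–Penrose pseudoinverse —
which is what makes tens of thousands of subset evaluations per run
affordable. See `vignette("scipso-methods")` for assumptions, parameter
semantics, and design choices.

## Worked example

```r
library(scipso)

# microarray-shaped synthetic data with 5 planted informative genes
out <- generate_synthetic(synth_spec(n_per_class = c(12, 12), n_genes = 150,
                                     n_informative = 5, effect_size = 6,
                                     sigma = 0.5, seed = 55))
out$truth
#> [1]   1  51  85  99 123

cfg <- scipso_config(n_top = 40, n_subsets = 150, subset_size_range = c(3, 6),
                     theta_ac = 0.7, pool3_size = 12, n_select = 3,
                     swarm_size = 10, max_iter = 6, n_repeats = 5,
                     master_seed = 42)
report <- run_scipso(out$dataset, cfg)
report
#> Hybrid gene-selection report
#>   data: 24 samples x 150 genes, 2 classes (14 train / 10 test)
#>   repeats: 5; mean 5-fold CV accuracy 100.00%; mean test accuracy 98.00%
#>   top selected genes (serial:frequency): 51:4, 85:2, 99:2, 1:2, 123:1, 7:1, 50:1, 142:1, 129:1

head(report$frequency, 5)
#>   rank serial gene_id frequency     score
#> 1    1     51  g00051         4 0.8090480
#> 2    2     85  g00085         2 0.8647080
#> 3    3     99  g00099         2 0.7552013
#> 4    4      1  g00001         2 0.6707693
#> 5    5    123  g00123         1 0.7285256
```

Every repeat selects 3 genes; the selection-frequency table aggregates the
5 repeats, and its top entries (serials 51, 85, 99, 1, 123) are exactly the
planted informative genes. `mean 5-fold CV accuracy` is the fitness of each
repeat's best subset on the training split; `mean test accuracy` is the
held-out accuracy of an ELM retrained on the training split with that
subset. Serial numbers are 1-based column positions in the input matrix.

Stage functions (`build_first_level_pool()`, `screen_and_rank_subsets()`,
`score_genes()`, `build_third_level_pool()`, `run_ipso()`) are exported
individually, and `sweep_parameter()` scans `theta_ac` or the number of
selected genes.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "scipso", package = "scipso"))')
Rscript $CLI synth --genes 2000 --per-class 30,30 --informative 10 \
        --effect 2 --seed 1 --out expr.csv --truth-out truth.tsv
Rscript $CLI run --data expr.csv --labels label --repeats 20 --out results/
Rscript $CLI sweep --data expr.csv --param theta_ac --values 0.7,0.8,0.9 --out results/
```

`run` writes `report.json`, `frequency.tsv` (rank, 1-based serial, gene id,
score, frequency) and `config.json`; configs are flat YAML/JSON mirrors of
`scipso_config()` and unknown keys are rejected.

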
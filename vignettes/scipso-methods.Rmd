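---
title: "Hybrid gene selection: filter cascade, ELM fitness, and the improved PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid gene selection: filter cascade, ELM fitness, and the improved PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classifying tissue samples from expression profiles is an
n-much-smaller-than-G problem: tens of samples, thousands of genes. Most
genes are irrelevant to the class distinction, and classifiers built on the
full matrix overfit. Gene selection seeks a small subset — typically 3 to 13
genes — whose expression discriminates the classes, both for prediction and
because the selected genes are themselves of biological interest.

`scipso` implements a hybrid filter–wrapper strategy: a cheap three-level
filter cascade shrinks the gene universe from thousands to a pool of ~40
candidates, and a wrapper search (a particle swarm optimizer with a
classifier in the loop) then picks the final subset of a fixed size from
that pool.

## Stage 1 — IIC ranking

For each gene $g$, with per-class training means $\mu_j$ and standard
deviations $\sigma_j$, the information index to classification is

$$d(g) = \sum_{j=1}^{c}\sum_{k \ne j}\left[
  \frac{1}{2}\frac{|\mu_j - \mu_k|}{\sigma_j + \sigma_k}
  + \frac{1}{2}\ln\frac{\sigma_j^2 + \sigma_k^2}{2\sigma_j\sigma_k}
\right].$$

The first term rewards separated class means; the second is zero when the
class spreads agree and positive otherwise, so a gene can be informative
through unequal variances alone. The double sum runs over *ordered* pairs,
so each unordered class pair contributes twice; we implement the sum exactly
as written rather than a halved variant, so multi-class values match the
formula. Both terms are invariant under positive affine rescaling of the
gene, which the test suite asserts. The `n_top` (default 300, the
conventional 200–400 range) highest-$d(g)$ genes form the level-1 pool.

Numerical care: a gene constant within a class has $\sigma_j = 0$ and the
log term diverges. We floor each class standard deviation at
$\max(10^{-6}\,\hat\sigma_g,\,10^{-12})$, where $\hat\sigma_g$ is the gene's
global training standard deviation, and warn. Ties in $d(g)$ break to the
lower gene index.

## Stage 2 — randomized subset screening

From the level-1 pool we draw `n_subsets` random gene subsets (default
$20\times$ the pool size, i.e. 6{,}000 at the default pool of 300), each of
a size drawn uniformly from 5–15 — bracketing the subset sizes such methods
typically report. Each subset is scored by the stratified 5-fold
cross-validation accuracy of an ELM on the training split projected onto
the subset; subsets below the survival threshold `theta_ac` (default 0.80)
are deleted. Survivors are ranked $1..l_{se}$ by decreasing accuracy, ties
breaking to the smaller subset and then to draw order. Duplicate subsets
across draws are allowed: the scoring stage is unaffected by them, and
deduplication would bias the effective draw distribution.

If no subset survives, the run stops with an instruction to lower
`theta_ac` — proceeding silently with an empty pool would be worse than
failing.

## Stage 3 — rank-based gene scoring

Only the *ranks* of the surviving subsets are used, which makes the score
robust to the noisy accuracy values themselves. A gene's raw score is

$$s(i) = \sum_{j:\, i \in S_j} (l_{se} - R_j + 1),$$

i.e. membership weighted by reversed rank: belonging to the top-ranked
subset is worth $l_{se}$ points, to the bottom-ranked one 1 point. Raw
scores are min–max normalized to $[0,1]$ over the genes that appear in at
least one surviving subset; genes in no surviving subset score 0. When all
member genes tie, the degenerate normalization maps them to 1. The scoring
kernel is a pluggable function, so a reciprocal-rank variant
($\sum 1/R_j$) is a one-line swap. The `pool3_size` (default 40)
top-scoring genes form the level-3 pool, ties breaking by higher IIC and
then lower index.

## Stage 4 — the improved PSO

Particles are integer-coded gene subsets: a position is a vector of $D$
(`n_select`) real coordinates in $[0, |\text{pool}|-1]$, decoded by
rounding, clamping, and repairing collisions by advancing cyclically to the
nearest unused pool slot. This keeps the classical continuous updates

$$v_{id}(t+1) = w(t)\,v_{id}(t) + c_1 Y_1 (p_{ibd}-x_{id}) + c_2 Y_2 (p_{gd}-x_{id})$$

literal while guaranteeing every particle decodes to $D$ distinct genes.
The inertia weight decreases linearly from 0.9 to 0.4 over the run;
velocities clamp to $\pm v_{max}$ (default half the pool size) and positions
to the pool range. The fitness of a particle is the same stratified 5-fold
CV accuracy used in stage 2, with fold assignment and per-fold hidden
layers frozen once per run, so a subset's fitness is a stable, memoizable
number within a run — this makes stagnation detection well-defined.

Two modifications distinguish the improved optimizer from plain PSO:

1. **Metropolis-managed global best.** A candidate replaces the swarm best
   $p_g$ outright when its fitness gain is at least $\varepsilon$
   (default 0.01 on the accuracy scale); a near-tie
   ($|\Delta f| < \varepsilon$) is accepted with probability
   $e^{-|\Delta f|/T(t)}$ under a temperature that anneals linearly from
   $T_0 = 0.1$ to $T_{end} = 0.001$; a loss of at least $\varepsilon$ is
   rejected. Accepting near-ties lets $p_g$ drift across equal-quality
   positions instead of pinning the swarm to the first good one. The rule
   is applied per particle per generation. Because $p_g$ may move to a
   marginally worse position, the best subset ever observed is tracked
   separately and greedily; results always report the best-ever record,
   and its fitness is non-decreasing by construction.
2. **Half-swarm reinitialization.** If the best-ever fitness has not
   improved for `n_mu` (default 3) consecutive generations,
   $\lfloor n/2 \rfloor$ particles chosen uniformly are redrawn uniformly
   at random (positions, velocities, and personal bests reset); $p_g$ and
   the best-ever record are untouched. This restores diversity after the
   swarm collapses onto a local optimum.

In the cold limit $T \to 0^+$, $\varepsilon \to 0^+$ the Metropolis rule
degenerates to `accept iff` $\Delta f \ge 0$: an acceptance probability of
exactly 1 (an exact tie) is taken without consuming a random draw, so the
improved optimizer's trajectory is *bit-identical* to the greedy-update
variant (`gbest_update = "greedy"`) on shared seeds. For the same reason the
package's greedy rule accepts exact ties; this is deliberate, so that the
two update rules form a continuum and the limit equivalence is testable
exactly.

## The ELM fitness classifier

The extreme learning machine is a single-hidden-layer network whose input
weights and biases are drawn once — uniformly from $[-1,1]$, the standard
choice — and never trained. With hidden activations
$H_{ij} = g(w_j \cdot x_i + b_j)$ (sigmoid by default) and 0/1 one-hot
targets $T$, the output weights are the minimum-norm least-squares solution
$w_o = H^+T$ via the Moore–Penrose pseudoinverse, computed by SVD with
singular values below $10^{-10}$ of the largest truncated. Prediction
decodes the maximal output neuron, ties to the lowest class index. Training
is a single linear solve, which is what makes ~30{,}000 subset evaluations
per repeat affordable.

**Hidden width.** The number of hidden neurons is the one genuinely free
model parameter. With $N_H$ equal to the training count the network
interpolates its training fold exactly (zero training error, which the test
suite verifies on full-rank cases), but interpolating classifiers built on
a few dozen samples give high-variance held-out predictions — we observed a
trivially separable 20-sample problem failing to reach perfect 5-fold CV
accuracy purely because of interpolation-regime noise. The default is
therefore `min(ceiling(n_train / 2), 20)`: well below the interpolation
threshold, capped to keep cross-validation cheap. It is exposed as
`elm_n_hidden` in every relevant function and in the run config; on new
data it deserves the same scrutiny as any classifier hyperparameter.

**Standardization.** Expression values are z-scored per gene using
training-split statistics (frozen, then applied to the test split) before
any ELM sees them; raw microarray intensities in the hundreds saturate a
sigmoid hidden layer. This is toggleable (`standardize = FALSE`).

## Cross-validation and test-set hygiene

Folds are stratified by class — with 6-sample classes, unstratified folds
can lose a class entirely — and a `degraded` flag is raised when a class is
smaller than $k$. The stratified train/test split allocates
`round(train_fraction * n_class)` samples per class (at least one) to
training. Nothing in stages 1–4 reads the test rows: the test suite
asserts that scrambling the held-out rows changes no selected gene and no
CV fitness. Held-out accuracy is computed once per repeat, from an ELM
trained on the full training split projected onto the selected subset.

## Repeats, seeds, and determinism

A run consists of `n_repeats` (default 100, matching the repeated-trial
protocol such experiments conventionally use) independent repeats of stages
2–4 above a shared split and level-1 pool (stage 1 is deterministic given
the split). The master seed fans out via a fixed pseudo-random schedule to
per-stage, per-repeat seeds, so any single repeat is reproducible in
isolation and the full report is byte-identical across runs with the same
`(config, master_seed)`. Per-gene selection frequencies over repeats are the
primary stability report; frequencies sum to `n_repeats * n_select`.

## The synthetic generator

`generate_synthetic()` emulates the shape of the classic public microarray
benchmarks: tens of samples, thousands of genes, 2–5 classes.
Non-informative genes are i.i.d. $N(0, \sigma^2)$ regardless of class;
each of the $k$ planted genes has its class means spaced
$\delta\sigma$ apart. Gaussian noise is chosen because both IIC terms have
closed-form behavior under normality, which makes the filter's recovery
properties analyzable; a log-normal toggle provides strictly positive,
heavier-tailed intensities. Planted genes are shuffled into random column
positions so off-by-one bookkeeping errors surface in recovery tests.
`deceptive_landscape()` additionally plants decoy gene sets that carry the
class signal on only a fraction of samples (default 60%), creating genuine
local optima for subset search; it backs the comparison between the
improved and plain optimizers.

What the generator does *not* emulate: probe-level artifacts, batch
structure, correlated co-expression modules, heavy-tailed outliers. Passing
recovery tests on this generator demonstrates the machinery is sound, not
that the method's accuracy on real microarray data is reproduced.

## Problem sizes used in the automated experiments

The packaged experiments run the full pipeline on 60 samples × 2,000 genes
with 10 planted genes at $\delta = 2$ and 20 repeats, plus a
300-gene deceptive-landscape comparison over 50 paired optimizer runs —
sizes chosen to exercise every stage at microarray-like shape while a
complete run stays in the minutes range on one core.

## Known limitations

* **Fitness plateaus.** On small training splits the 5-fold CV accuracy has
  granularity $1/n_{train}$ and saturates at 1.0 for many subsets of a
  well-filtered pool. On such a plateau the optimizer cannot distinguish a
  fully informative subset from one carrying a couple of passenger genes,
  and the reported subset is effectively an arbitrary member of the
  plateau — the winner's curse of maximizing a noisy estimate. Selection
  *frequency* across repeats remains informative (planted genes dominate
  the top of the frequency table even when single repeats carry
  passengers), which is why the repeated-run report, not a single subset,
  is the primary output.
* The annealing constants $T_0$, $T_{end}$ and $\varepsilon$ are defaults
  on the accuracy scale, not tuned values; their influence grows as fitness
  differences shrink.
* `n_select` must be chosen by the user (the sweep driver helps); the
  method does not infer subset size.
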
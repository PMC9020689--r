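---
title: "Effective population sizes for cultural traits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective population sizes for cultural traits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultne)
```

## The model

`cultne` simulates the cultural analogue of a haploid Wright–Fisher
population. A population of census size $N$ holds one variant of a single
cultural trait per individual. Each discrete generation, every *learner* of
the new generation either

* innovates, with probability $\mu$, adopting a brand-new variant that has
  never been seen before (the infinite-alleles assumption), or
* copies a member of the role-model pool.

Under unbiased transmission the pool is the whole parental generation and a
learner adopts variant $i$ with probability $\frac{n_i}{N}(1-\mu)$, where
$n_i$ is the variant's count among the role models. The package records, for
every parent, its **cultural influence** $k$: the number of learners that
copied it. Innovating learners have no cultural parent and are credited to
nobody, so the mean influence is $\bar k \approx 1 - \mu$; since innovation
is an alternative to copying, at the default $\mu = 10^{-4}$ this is
indistinguishable from 1.

From the per-generation influence moments the package computes two
effective population sizes,

$$
N_e^i \;=\; \frac{N_{t-1}\,\bar k - 1}{\bar k - 1 + \sigma^2/\bar k},
\qquad
N_e^v \;=\; \frac{(N_{t-1}-1)\,\bar k}{\sigma^2 / \bar k},
$$

the inbreeding formulation (probability that two random offspring share a
cultural parent) and the variance formulation (magnitude of random
variant-frequency change). When $\bar k = 1$ both collapse to the simplified
$N_e = (N-1)/\sigma^2$, which is what the per-generation column `ne_simple`
reports. $\sigma^2$ is computed with the *population* convention (divisor =
role-model pool size): only with this convention does the simulated
one-to-many variance match its closed form $(N-1)/R$ exactly in expectation.
Generations where a formula is undefined ($\sigma^2 = 0$, or a non-positive
inbreeding denominator) yield `NA` and are excluded from replicate averages.

Diversity is tracked as the Simpson index $D = 1 - \sum_i (n_i/N)^2$
computed on the full census (no finite-sample correction) and the number of
unique variants $S$.

## Transmission modes

**One-to-many** (`step_one_to_many()`): each generation $R$ individuals,
redrawn uniformly without replacement, are the only eligible role models.
Influence counts still span all $N$ parents (ineligible ones score 0), which
pools the transmitting and non-transmitting sub-populations and gives
$\sigma^2_{\mathrm{OTM}} = (N-1)/R$ and $N_e = R$ — the closed forms exposed
as `otm_sigma2()` and `otm_ne()`.

**Frequency-dependent** (`step_frequency_dependent()`): a learner adopts
variant $i$ with probability $n_i^\theta / \sum_m n_m^\theta \,(1-\mu)$;
$\theta > 1$ is conformity, $\theta < 1$ anti-conformity, $\theta = 1$ is
exactly unbiased. The model specifies adoption at the variant level only; to
keep influence per-parent the package credits a uniformly random carrier of
the adopted variant — the unique attribution that is symmetric among
carriers. Equivalently, parents are drawn with per-parent weight
$n_{v}^{\theta-1}$, which is how the kernel implements it. A consequence
worth stating explicitly: for conformity the between-carrier variance of
expected influence is bounded (at $\theta = 1.5$ it never exceeds about 0.05
for any two-variant split), so under this attribution a conformist switch at
low innovation rates produces only a shallow, transient dip of mean $N_e$ a
few percent below $N$; deep troughs arise on the anti-conformist side, where
singletons carry weight $n^{-1/2}$, or at high $\mu$.

**Connectedness** (`step_migration()`, `step_exchange()`, `step_influx()`):
two demes share one innovation counter. Migration permanently swaps
$X \sim \mathrm{Binomial}(N, m)$ uniformly chosen individuals symmetrically
(disjoint sets, so censuses never change; `fixed_count = TRUE` uses
$\mathrm{round}(mN)$ instead). Cultural exchange temporarily appends
$X \sim \mathrm{Binomial}(N, e)$ members of the other deme to the role-model
pool: $N(1+e)$ parents transmit to $N$ learners, so $\bar k = 1/(1+e)$ and
the inbreeding size rises to $\approx (N-1)(1+e)$ while the variance size
stays at $\approx N$. The influx scenario adds a fixed number of immigrants
from a large source population each generation, so the focal census grows
linearly and effective sizes must be read from the unequal-size
formulations; the source keeps evolving unbiasedly at constant size, with
immigrants drawn uniformly without replacement each generation.

**Networks** (`step_network()`): individuals occupy the nodes of a fixed
undirected graph and copy uniformly among their direct neighbours, never
themselves. Node positions are heritable slots. Isolated nodes (possible in
sparse random graphs) have no role models: they retain their variant unless
they innovate, and are credited as their own parent so influence stays
conserved. Graph generation delegates to igraph where possible:
Erdős–Rényi via independent edge flips, Barabási–Albert via preferential
attachment with weight $k^\pi$ (two edges per arriving node from a two-node
seed, hence exactly $2(N-2)+1$ edges), and Watts–Strogatz as a ring lattice
with $K$ neighbours per side whose edges are rewired with probability $p_r$
by a hand-rolled one-pass scan that replaces the clockwise endpoint while
refusing self-loops and duplicates, preserving the $NK$ edge count exactly
(igraph's rewiring cannot guarantee that invariant).

## Experiment protocol

`run_experiment()` executes a configured experiment
(`experiment_config()`): per replicate it derives an independent seed from
the master seed, draws a fresh graph for network modes, equilibrates the
population, then records the configured number of generations (default 300)
with one row of statistics per generation. `run_sweep()` grids one
parameter. Summaries report across-replicate means with 90% prediction
intervals, computed as empirical 5th/95th percentiles with R's default
linear-interpolation quantiles (the interval definition is not prescribed by
the underlying theory; percentiles are the assumption made here). A
replicate's $N_e$ estimate is the mean of its per-generation estimates over
the recorded generations, undefined generations excluded. Because
$1/\sigma^2$ is convex this estimator carries a small upward Jensen bias of
relative order $\mathrm{cv}(\sigma^2)^2$ (about 0.3% at $N = 1000$), well
inside the prediction intervals at the replicate counts used.

**Initial state and burn-in.** Every run starts from maximal diversity (all
labels distinct) and burns in under unbiased dynamics for `burn_in`
generations, default $4N$: population turnover and coalescence operate on a
timescale of order $N$ generations, so $4N$ comfortably passes several time
constants (at $N=1000$, $\mu = 10^{-4}$ the decay constant of the
homozygosity recursion is $\approx (1/N + 2\mu)^{-1} \approx 830$
generations). Network modes burn in under the network dynamic itself, since
the graph is the population's permanent structure; two-deme experiments burn
each deme in isolation before coupling; a frequency-dependent run burns in
at $\theta = 1$ and generation 1 is the first to use the configured
$\theta$, so recorded trajectories show the post-switch transient.

One deliberate exception: the distribution of influence counts under
one-to-many and network-constrained copying does not depend on the variant
composition at all (who copies whom is decided before what is copied), so
experiments whose outputs are only influence moments and effective sizes are
equally valid with little or no burn-in. The bundled tests and the
acceptance script use short burn-ins for exactly those runs, and full
burn-ins wherever diversity is measured.

## Problem sizes and reproducibility

Published-scale runs use 1000 replicates; the package defaults its CLI
presets to 200 and the bundled test-suite and acceptance checks run 10–100
replicates per condition with 100–500 recorded generations, sizes chosen so
that each sampling distribution is tight enough for its assertion while a
full check runs on a laptop in minutes. The test suite asserts, among other
things:

* exact one-generation transition distributions for $N \le 6$ against
  brute-force enumeration (chi-square at $10^5$ draws) for all four step
  kernels;
* $\bar k = 1$ exactly and $\mathbb{E}[\sigma^2] = 1 - 1/N$ for ideal
  resampling;
* $\sigma^2 \to (N-1)/R$ and $N_e \to R$ under one-to-many transmission,
  with $N_e = 1$ holding exactly at $R = 1$, $\mu = 0$;
* the connectedness contrasts (migration neutral for both $N_e$ measures
  but diversity-increasing; exchange raising inbreeding $N_e$ to its closed
  form while variance $N_e$ stays at $N$);
* the network ordering small-world $>$ random $\approx N$ $>$ scale-free.

Identical configuration plus master seed reproduces bit-identical records;
run metadata (including timestamps) is written to `meta.json` rather than
into the CSV tables so that repeated runs produce byte-identical tables.

## What the generator does and does not emulate

The simulator is a neutral, discrete-generation model: no selection or
payoff bias, no overlapping generations, no continuous traits or copying
error, haploid "inheritance" of a single trait, at most two demes, and
static networks. Passing tests therefore demonstrate internal consistency
of drift, innovation and transmission structure — not that any real cultural
system satisfies these assumptions. In empirical data, transmission modes
are usually mixtures, networks rewire on the timescale of transmission, and
innovation is rarely a constant per-capita rate; all three violations move
effective sizes in ways the model can only bracket.

## Known numerical limitations

* Variant labels are doubles; a run would need $> 2^{53}$ innovations to
  risk label collision, far beyond any practical configuration.
* The worked bottleneck example quotes an expected unique-variant count for
  an ideal population at $\mu = 0.1$. Direct simulation of the model as
  stated (innovate with probability $\mu$, otherwise copy) equilibrates
  about 10% below a closed-form prediction that ignores the $(1-\mu)$
  thinning of copying mass; at realistic innovation rates
  ($\mu \le 10^{-2}$) the two agree. The package reports the simulated
  value.
* `simple_ne()` assumes a constant census; for exchange and influx records
  the `ne_simple` column uses the role-model pool size and is reported for
  completeness, but `nei`/`nev` are the meaningful estimators there.
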
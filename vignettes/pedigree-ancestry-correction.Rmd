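---
title: "Correcting local-ancestry calls with pedigree structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting local-ancestry calls with pedigree structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(famanc)
```

## The problem

Local ancestry — the ancestral population of origin of each chromosomal
segment in an admixed individual — is usually inferred per individual by
HMM-based callers that assume the study subjects are unrelated. Applied to
pedigree data (a three-generation family study, say), that assumption is
false, and the independent per-individual calls routinely contradict
Mendelian inheritance: a child is called homozygous African at a marker
where a parent is called homozygous European, or a track briefly flips
ancestry and back within a fraction of a centiMorgan.

This package takes the per-marker diploid dosage calls of such an upstream
tool (0, 1 or 2 copies of population-A ancestry per marker per individual,
population A being African in the African-American setting that motivates
the defaults), together with the known pedigree and a genetic map, and

1. **detects** probable inference errors,
2. **estimates** the allelic error rate of the upstream caller from the
   Mendelian inconsistencies it produced, and
3. **corrects** the flagged loci by maximum a-posteriori (MAP) selection
   over Mendelian-consistent configurations.

## Model

### Coding and notation

At locus $t$, individual $i$ carries two latent ancestry alleles
$A^{[1]}_{i,t}, A^{[2]}_{i,t} \in \{0,1\}$ (1 = population A); the true
dosage is $X_{i,t} = A^{[1]}_{i,t} + A^{[2]}_{i,t}$ and the upstream caller
reports $Y_{i,t}$. Marginally $X_{i,t} \sim \mathrm{Binom}(2, \lambda)$,
where $\lambda$ is the genome-wide population-A admixture proportion
(default 0.8). $\tau$ denotes the number of generations since admixture
(default 8, a standard figure for African-Americans).

### Allelic error model

Each inferred allele independently differs from the truth with probability
$\varepsilon$. The induced dosage-level inference probabilities
$P(Y_{i,t}\!=\!y \mid X_{i,t}\!=\!x)$ are the rows of
`inference_matrix(epsilon)`; e.g. $P(y\!=\!1 \mid x\!=\!1) =
(1-\varepsilon)^2 + \varepsilon^2$ (neither or both alleles flipped). The
expected dosage error rate $E|Y - X|$ follows by enumeration over the nine
$(x, y)$ cells:

$$\mathrm{err} = 2\varepsilon(1-\varepsilon)
  + 2\varepsilon^2[\lambda^2 + (1-\lambda)^2].$$

A widely quoted closed form for this quantity carries the quadratic term
without the factor 2. Both are available from `expected_dosage_error()`
(variants `"flip_model"` and `"literal"`); the difference is at most
$\varepsilon^2$ and irrelevant at realistic error rates (0.01–0.03), but
the exact flip-model variant is the reporting default because it agrees
with the error-injection simulation to Monte-Carlo precision.

### Transition model

Along the map, each haploid ancestry track is a two-state Markov chain:
over $d$ Morgans, with probability $e^{-d\tau}$ the state survives,
otherwise it is redrawn from the stationary distribution
$(1-\lambda, \lambda)$. The printed form of this kernel in the HMM
literature sometimes writes the redraw weight $\lambda$ in both rows, which
is not row-stochastic for the state-0 row; `haploid_transition()` uses the
standard conditional form with stationary weights, which reproduces the
usual expression for the population-A row exactly and restores
normalisation. The dosage-level kernel `diploid_transition()` composes two
independent haploid chains and projects ordered pairs onto dosages; it is
row-stochastic and preserves the $\mathrm{Binom}(2,\lambda)$ stationary
law (both properties are tested to 1e-12).

### Mendelian consistency

A dosage configuration $X_t$ over the pedigree is *consistent* when some
assignment of ordered allele pairs realises every dosage with each
non-founder receiving one allele from each recorded parent. For a
parent–offspring trio exactly 15 of the 27 configurations are consistent
(`enumerate_ped()`). Consistency is decided by genotype elimination — a
depth-first search over ordered pairs in parents-first order, implemented
in C++ because the corrector evaluates it for hundreds of candidate
configurations per flagged locus. Missing calls leave the member
unconstrained, so an ungenotyped connector still transmits constraints
between its relatives.

### Error detection

`flag_loci()` applies three detectors:

* **mendelian** — the locus configuration fails the consistency check;
* **double_crossover** — an individual's dosage track reverts to its
  flanking state within a window shorter than `window_cM` (default 2 cM).
  Under the Poisson crossover model the chance of two or more crossovers
  in 2 cM at $\tau = 8$ is `double_crossover_prob(0.02, 8)` $\approx$
  0.0115, so such reversions are treated as inference errors. One
  condition is added beyond the window rule: the reverted run must be no
  longer than either flanking run. Without it, when two isolated
  erroneous blips bracket a stretch of *true* calls closer together than
  the window, the true stretch itself matches the
  "short run with equal flanks" pattern; at realistic error rates this
  flags the majority of the chromosome and removes the trusted
  neighbours the corrector depends on. Requiring the reversion to be the
  transient state restores the intended asymmetry at no cost to genuine
  double crossovers;
* **low_quality** — the upstream caller's posterior confidence for a call
  is below `quality_threshold` (default 0.90).

### MAP correction

For a flagged locus $t$ with nearest trusted neighbours $X_{t-}$ (left,
already corrected or never flagged) and $X_{t+}$ (right, never flagged),
the corrected configuration is

$$\hat X_t = \arg\max_{X_t \in \mathrm{Ped}}
  P(Y_t \mid X_t)\, P(X_{t+} \mid X_t)\, P(X_t \mid X_{t-}),$$

each factor a product over individuals (inference probabilities and
diploid transitions at the flanking map distances). At chromosome ends the
absent factor is dropped. The search space is restricted to consistent
configurations within Hamming distance `max_diff = 2` of the observation —
with per-individual error probability around $2\varepsilon \approx 0.02$,
three or more simultaneous errors at one locus are rare even in a
20-member pedigree, and the binomial bound makes the truncation safe. If
no consistent candidate exists within the radius, the radius is escalated
once; a locus that still has no candidate is left unchanged and reported.
Scores are compared in log space with zero probabilities floored at
1e-300; ties within 1e-12 resolve to the fewest changes, then
lexicographically, so results are deterministic.

The sweep runs left to right; corrected loci become trusted left context,
while the right context is always an originally unflagged locus. In
`mode = "block"`, maximal runs of identical configurations are corrected
as units with the flanking blocks as neighbours — the natural granularity
when ancestry blocks span many markers — and double-crossover runs are
resolved by the same machinery rather than by a bespoke deletion rule.

### Estimating the allelic error rate

`estimate_epsilon()` inverts the expected relationship between
$\varepsilon$ and the number of Mendelian-inconsistent loci in nuclear
families. The pedigree is first partitioned into non-overlapping nuclear
families (`extract_nuclear_families()`, greedy: larger sibships first,
then earlier generation — sibship size carries more Mendelian information
per family, and the ordering makes the partition deterministic).
"Mendelian error" is operationalised as a 0/1 event per family-locus: the
family's dosage vector admits no allele assignment. For a family with two
parents and $m$ children the expected per-locus rate is a quadratic
polynomial in $\varepsilon$ derived under the assumption that at most one
member errs per locus; a companion polynomial covers one-parent families.
Exact enumeration of that error mechanism reproduces the two-parent
polynomial to machine precision; the one-parent polynomial deviates from
its mechanism by a term bounded by $\varepsilon^2$ (the package implements
the polynomials as published and the test suite measures and bounds the
discrepancy). Summing expected counts over families gives an aggregate
quadratic whose root in $[0, 0.5)$ is $\hat\varepsilon$; the smaller root
is taken when both qualify.

Because real data violate the one-error-per-locus assumption (two members
can err at once), $\hat\varepsilon$ is mildly conservative: on simulated
two-parent families (50 families, $m = 2$, 2000 loci, $\lambda = 0.8$)
recovery is within about −5% at $\varepsilon = 0.01$ and −10% at
$\varepsilon = 0.03$, well inside the ±20% band the recovery test
enforces. The polynomial machinery itself inverts its own forward
predictions to 1e-10.

## The simulator

`simulate_ancestry()` reproduces the data-generating design the method is
built for, at the level the method operates on — ancestry dosages, not
genotypes:

* **founders**: each haplotype is a two-state Markov chain along the map;
  first locus $\sim$ Bernoulli($\lambda$), and over each interval a
  recombination occurs with probability $1 - e^{-d\tau}$ (at most one per
  interval), after which the ancestry is redrawn from
  Bernoulli($\lambda$). Redraws landing on the current state are
  invisible; the marginal process is exactly the conditional transition
  model, which the switch-rate test verifies;
* **meioses**: a child haplotype copies one of the parent's two tracks,
  starting from a uniformly chosen one and switching source with
  probability $1 - e^{-d}$ per interval ($\tau = 1$ for a single
  generation);
* **errors**: every allele flips independently with probability
  $\varepsilon$; a constant 0.99 quality matrix is attached, with optional
  demoted cells to exercise the low-quality detector.

Default conditions are $\lambda = 0.8$, $\tau = 8$, $\varepsilon = 0.01$,
2000 markers at 0.03 cM (a 60 cM, chromosome-22-like map), applied to
three representative fixture pedigrees of 20, 10 and 4 members
(`example_pedigree()`).

What the simulator does *not* emulate matters for interpreting results:
real upstream callers make spatially correlated errors — entire mis-placed
block boundaries ("shifting recombination points"), reference-panel
mismatch, LD structure — whereas injected allelic flips are independent
across markers. Isolated flips are the easiest errors for this method to
find (most become single-marker reversions or Mendelian conflicts), so
simulated error reductions here are substantially larger than what
correlated real-data errors allow; handling shifted block boundaries is
out of scope, as no current method addresses them. The end-to-end tests
therefore assert the *direction* and Mendelian-clearing property of the
correction, not a specific reduction factor.

## Numerical and design choices

* Distances are carried in Morgans internally; maps are read in cM.
  Co-located markers ($d = 0$) are legal; $d = 0$ transitions are exact
  identity matrices.
* Missing dosage cells are excluded from inference and transition
  products; a wholly uncalled member constrains the configuration only
  through Mendelian inheritance.
* One flag-and-correct sweep by default (`sweeps` is available but the
  neighbour logic already handles runs of consecutive flagged loci).
* ε-estimation aggregates expected counts across heterogeneous families
  by summation and solves the quadratic in closed form, erroring with the
  observed rate and the model's maximum when no root lies in $[0, 0.5)$.
* The corrector assumes flanking calls are correct; when both flanks of a
  flagged locus are themselves wrong the correction can be wrong — the
  boundary-locus forms (single-flank) are the mild version of this and
  are measurably less reliable, as expected.
* Problem sizes in the test suite (500–3000 markers, pedigrees up to
  n = 20, $10^5$ Monte-Carlo replicates per grid cell) were chosen so the
  full suite exercises every study condition at desk scale.

## Known limitations

* Two-way admixture only; no locus-specific $\lambda$; no X chromosome.
* No inbreeding-aware likelihood peeling: consistency search handles
  loops correctly via backtracking, but runtimes are tuned for outbred
  pedigrees.
* $\hat\varepsilon$ has no uncertainty interval and is not re-estimated
  after correction.
* Errors spanning many consecutive markers (shifted block boundaries)
  are detected only insofar as they create Mendelian conflicts, and their
  correction inherits the flanks' reliability.
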
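---
title: "Extracting characteristic interaction sets from network-prediction ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting characteristic interaction sets from network-prediction ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnsets)
```

## The problem

Reverse-engineering a gene regulatory network from expression data rarely
has a unique answer. Non-deterministic inference — stochastic optimisation,
resampling, genetic algorithms over dynamical models — produces hundreds or
thousands of candidate networks that fit the data comparably well. Ensemble
voting summarises them by per-interaction frequency, which is robust when
the candidates are variations on one topology. When they are not — when the
data admit several genuinely different wirings — frequency averaging mixes
the alternatives into uninformative intermediate weights and the structure
of the disagreement is lost.

`grnsets` makes that disagreement explicit. The key observation is that
interactions realizing one functional alternative tend to *co-occur*: a
network either contains the whole alternative or none of it. Sets of
co-occurring intermediate-frequency interactions therefore mark the
boundaries between groups of topologically similar predictions, and voting
within groups preserves what voting across them destroys.

## The extraction model

Let $N$ be the number of predicted networks and $f(i)$ the fraction of
networks containing signed interaction $i$.

**Step 1 — tiers.** $i$ is a high-confidence interaction if $f(i) > c_{hc}$,
a high-confidence non-interaction if $f(i) < c_{nc}$, and low-confidence
otherwise. Only low-confidence interactions carry grouping information:
high-confidence interactions are common to all candidates and
non-interactions to none.

**Step 2 — pairwise dependencies.** For low-confidence $a, b$ with joint
frequency $f(a \wedge b)$, define association-rule confidences
$\mathrm{conf}(a \to b) = f(a \wedge b) / f(a)$. Then

$$\mathrm{AND}(a,b) = \min\{\mathrm{conf}(a \to b), \mathrm{conf}(b \to a)\},
\qquad
\mathrm{EX}(a,b) = \min\{\mathrm{conf}(a \to \neg b), \mathrm{conf}(b \to \neg a)\}.$$

The min conjunction is the standard conservative combiner from approximate
reasoning; `and_score()`/`ex_score()` isolate it so the product or bounded
product can be swapped in via the `conjunction` argument. A pair is
AND-related when $\mathrm{AND} > c_s$ *and* $f(a \wedge b) > c_j$;
EX-related when $\mathrm{EX} > c_s$ and both exclusive frequencies exceed
$c_j$. The frequency gate keeps relations whose entire evidence could be
noise out of the system. Because
$\mathrm{AND}(a,b) + \mathrm{EX}(a,b) \le 1$ (the two scores are
$f_{ab}/\max(f_a, f_b)$ and $1 - f_{ab}/\min(f_a, f_b)$), any
$c_s > 0.5$ guarantees at most one relation per pair; the constructor
`cutoff_config()` enforces this.

**Step 3 — sets, competition, grouping.** Characteristic sets are the
connected components (size ≥ 2) of the AND graph — the transitive closure of
pairwise co-occurrence. Sets joined by an EX relation are competing: a valid
network contains at most one of them. Networks are grouped by the exact
combination of sets they fully contain; networks containing no set carry no
grouping signal and are excluded from ensemble creation. Signed voting
(net vote $(n_+ - n_-)/N$ per gene pair, weight $|v|$ with the majority
sign) is applied per group.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `hc` | 0.8 | frequency above which an interaction is high-confidence |
| `nc` | 0.1 | frequency below which it is a confident non-interaction |
| `joint` | 0.1 | minimum evidence frequency for an AND/EX relation |
| `score` | 0.7 | minimum AND/EX relation score (must exceed 0.5) |

All four are relative frequencies (dimensionless, in $[0,1]$). The defaults
are a sensible operating point for collections of a few hundred networks;
with very few networks the frequency resolution ($1/N$) becomes coarse
relative to the gates. Cutoffs trade sensitivity against noise robustness
and are best assessed per data set: stringent first, then relaxed while the
extracted sets stay few, large and interpretable.

Boundary handling is strict everywhere ("above"/"exceed" mean $>$): a
frequency exactly at a cutoff is low-confidence, a score exactly at $c_s$
does not qualify. This keeps borderline interactions inside the dependency
analysis rather than silently promoting them.

## Design choices

* **Crisp containment.** A network contains a set iff it contains every
  member. Fuzzy membership would tolerate noise better but blurs the
  competition semantics; it is deliberately out of scope.
* **Conflicts are reported, never resolved.** An EX relation between two
  members of one AND component contradicts the component's own evidence.
  `build_characteristic_sets()` records such pairs as conflicts,
  `group_networks()` withholds the affected sets unless `force = TRUE`, and
  the extraction report carries a `manual_resolution_required` flag.
* **Networks exhibiting competing sets simultaneously** can arise from
  noise even though the competition semantics forbid them. They are flagged
  and excluded by default; `keep_violations = TRUE` keeps them under the
  signature of all contained sets.
* **Signed voting convention.** The net-vote form $(n_+ - n_-)/N$ is one of
  several published consensus schemes; it is isolated behind the `scheme`
  argument (with plain per-sign frequency voting as the alternative) and is
  never changed silently. When only one sign of an edge occurs, both schemes
  coincide.
* **Entropy.** Ensemble entropy is the sum of per-interaction binary
  entropies over the candidate universe, in bits. The logarithm base is an
  argument; entropy *ratios* (the group-vs-full comparison) are independent
  of it. Never-predicted candidates have frequency 0 and contribute nothing.
* **AUPRC.** Interactions are ranked by descending weight; equal weights
  share one threshold, so permuting tied entries cannot change the area.
  Integration is rectangular over the distinct thresholds with $R_0 = 0$ —
  no interpolation — making areas bit-reproducible. Sign matching is exact
  by default (a predicted activation where the reference has an inhibition
  is a false positive); `unsigned = TRUE` collapses signs. The candidate
  universe is all ordered gene pairs without self-loops, both signs;
  self-loops and double-sign edges are rejected on input unless explicitly
  enabled, since the targeted dynamical frameworks assign one regulatory
  role per gene pair and autoregulation is not modelled.
* **Determinism.** Set ids are assigned by lexicographically smallest
  member, pair tables and reports are sorted, and score ties in
  `select_top_fraction()` break by network id, so repeated runs are
  byte-identical.

## The synthetic benchmark

`generate_collection()` emulates the *output* of a non-deterministic
reverse-engineering run directly, rather than simulating expression data
and refitting dynamical models — which inference algorithm produced a
collection is immaterial to the extraction itself. The generative model:

* a random reference over `n_genes = 10` genes, each with 1–3 effectors
  (uniform in-degree, the range configurable) and equiprobable signs;
* two competing planted sets of `set_size = 3` interactions: one drawn from
  the reference (the true hypothesis), one rewiring the same targets to
  alternative effectors absent from the reference (the false competitor);
  each network realizes exactly one, per `group_proportions` (default
  50/50);
* the remaining reference edges form a high-confidence backbone, present
  with probability `backbone_presence = 0.95` per network;
* `n_variable_edges = 4` unspecific variable edges, each present
  independently with probability 0.4 — intermediate-frequency interactions
  with no co-occurrence structure;
* presence noise: every admissible signed edge flips with
  `noise_rate = 0.02` (additions that would put both signs on one pair are
  reverted). The default noise is kept below `nc`, so noise alone cannot
  fake low-confidence structure;
* per-network scores drawn uniformly from `[0.05, 0.15]`, standing in for a
  fit statistic such as RMSD solely to exercise score-based selection
  (`select_top_fraction()`, `group_score()`).

Defaults are `n_networks = 500` networks; the test suite runs the stochastic
properties over 50 generator seeds each, with smaller collections (120–300
networks) in the faster smoke tests.

What this generator does *not* emulate: correlated noise from a shared
optimisation trajectory, more than two alternatives per locus unless
configured, frequency gradients within a set, or any coupling between a
network's score and its topology. Passing tests therefore demonstrate that
the extraction machinery is correct and well-behaved under planted
structure — not that real reverse-engineering output will contain sets this
clean. On real collections the cutoff-assessment loop above matters.

## What the benchmarks show

Three properties, each checked across 50 generator seeds in the test suite:

1. **Recovery** — at the default conditions the extraction returns exactly
   the planted sets, their competition, and group assignments matching the
   planted ones for ≥ 95% of the grouped networks.
2. **Entropy reduction** — mean group-ensemble entropy is below the
   full-ensemble entropy: within a group, set members move from frequency
   ≈ 0.5 to ≈ 1 and the competitor's members to ≈ 0.
3. **Validation benefit** — simulating the experimental validation of one
   characteristic-set member (rejecting the networks the result
   contradicts) raises the ensemble AUPRC at least as often as not, and its
   mean gain exceeds that of validating an unspecific variable edge. This is
   the operational payoff: co-occurring interactions are the efficient
   targets for follow-up experiments, because one measurement rejects an
   entire competing hypothesis.

## Limitations

* Pair enumeration is quadratic in the number of low-confidence
  interactions; fine for the tens typical of converged collections, not for
  thousands.
* Competition is pairwise; a three-way exclusive structure appears as three
  pairwise competitions, which is correct but less compact.
* Scores do not weight votes (all retained networks count equally), and
  cutoffs are not auto-tuned; both are intentional simplifications at the
  module boundary.
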
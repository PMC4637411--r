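---
title: "Reconstructing interaction networks with the inverse Q-state Potts model"
author: "PottsNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing interaction networks with the inverse Q-state Potts model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PottsNet)
```

## The problem

Affiliation data record which members of an organization took part in which
activities — senators co-sponsoring bills, authors signing papers, users
joining events. The standard route from such a two-mode (member × activity)
table to a one-mode member–member network is to count and normalize
co-occurrences (Jaccard index, match counts, cross-products, covariance,
correlation). Those projections have no probabilistic content: they cannot
weigh noise, anti-correlations, or the highly ambiguous event of two members
being *jointly inactive*.

PottsNet instead treats each activity as one observation ("snapshot") of the
N members' discrete states and poses network reconstruction as an inverse
problem for a pairwise Markov random field: find the couplings of a Q-state
Potts model under which the observed state statistics are typical. Links are
then read off from the inferred coupling strengths rather than from raw
co-occurrence counts, which lets the method surface interactions that
co-occurrence counting misses (including "out-of-diagonal" correlations
between *different* states of two members).

## The model

Configurations $x \in \{0,\dots,Q-1\}^N$ carry probability

$$P(x) \;\propto\; \exp\!\Big[-\sum_{(i,j)\in E} H_{(i,j)}(x_i, x_j)\Big],$$

one pair potential per edge. Each potential is expanded in the discrete
orthonormal (Gram/Chebyshev) polynomial basis $\Phi_k$ on the integer grid
$\{0,\dots,Q-1\}$ under the counting measure,

$$H_{(i,j)}(x_i,x_j) = \frac{1}{Q}\sum_{k\ge 1}\big[J^{(k,0)}\Phi_k(x_i) +
J^{(0,k)}\Phi_k(x_j)\big] + \sum_{k,l} J^{(k,l)}\Phi_k(x_i)\Phi_l(x_j),$$

with the $(0,0)$ constant absorbed into the normalization. The expansion is
implemented verbatim, so the mixed $(k,0)$ terms contribute both through the
$1/Q$-weighted field sum and the double sum; round-trip tests pin this
convention. One sign convention holds everywhere: probability is
$\exp(-\text{energy})$ and the conventional minus sign of the ferromagnetic
energy lives inside the stored coupling values.

Two properties make the counting-measure orthonormal basis
($\sum_x \Phi_k(x)\Phi_l(x)=\delta_{kl}$, $\Phi_0 = 1/\sqrt{Q}$, positive
leading coefficients) the right normalization:

* marginal tables expand as
  $P_i(x) = 1/Q + \sum_{k\ge1} \langle\Phi_k(x_i)\rangle\,\Phi_k(x)$ and
  analogously for pairs, where $\langle\cdot\rangle$ are plain sample
  moments — with uniform weights the expansion of a histogram *is* the
  histogram, exactly;
* the closed-form Bethe inversion
  $$J^{(k,l)}_{(i,j)} = -\sum_{x_i}\sum_{x_j}\Phi_k(x_i)\Phi_l(x_j)
  \ln P_{(i,j)}(x_i,x_j)$$
  is an exact inverse of the pair-potential expansion on an isolated pair
  (the $\ln Z$ term projects to zero against any $k\ge1$ polynomial).

Both properties are asserted to $10^{-10}$ in the test suite. The basis is
built by a Stieltjes three-term recurrence with one re-orthogonalization
pass; naive Gram–Schmidt on the monomials (used as the independent oracle in
the tests at small Q) loses all accuracy beyond $Q \approx 13$ because the
Vandermonde matrix is severely ill-conditioned, while the recurrence stays
orthonormal to machine precision through the supported range ($Q \le 64$).

## From affiliation data to observations

`assignStates()` maps each activity to one observation: active members get
state 1; inactive members get state 0 at $Q=2$, and for $Q>2$ an
independent uniform draw from the $Q-1$ non-active states
$\{0,2,\dots,Q-1\}$. Randomizing inactive states dilutes the spurious
correlation created by the (overwhelmingly common) event of joint
inactivity. Uniformity is deliberate — any non-uniform prior would encode
an assumption about group structure that the method is supposed to infer —
and its known side effect (a bias toward communities of similar size) is
documented behavior.

`minQForInactive()` implements the calibration rule for how large Q must
be: the random probability of two members sharing an inactive state,
$p_{ina} = (N - N_A)/((Q+1)N)$, must not exceed the empirical probability
$p_{act} = N_A/N$ of sharing the active one. At the chamber-scale
parameters $N=338$, $N_A=8$, $p_{act}=0.024$, the rule gives $Q \ge 40$.
Note that the $p_{ina}$ formula is used verbatim as stated by its source;
it is not the collision probability $1/(Q-1)$ implied by the uniform
assignment above. The two disagree mildly for moderate Q; since nothing
downstream consumes $p_{ina}$ except this calibration, we implement the
stated rule and record the discrepancy here rather than resolving it.

## Observation strategies and the alpha schemes

Three strategies turn data into the sample averages the inversion needs:

* **pure observational** — averages taken directly from the assigned
  states, with the inactive state excluded from the inversion sums
  (`excludeInactive`), the stated necessity when information is limited to
  $Q = 2$;
* **semi-observational** — the observed samples are kept but reweighted by
  their probability under an alpha-parameterized generative Potts model
  $P(x)\propto\exp[\tfrac12\sum_{ij}\alpha_{ij}\delta(x_i,x_j)]$
  (`generativeWeights()`), nudging the averages toward a preliminary
  standard reconstruction;
* **generative** — observations are Gibbs-sampled from that alpha model
  outright (100,000 samples by default), useful when only aggregate data
  exist.

The $\alpha_{ij}$ come from weighted co-occurrence counts
(`alphaLiu()`: $\sum_\mu \delta(d^\mu_i,d^\mu_j,1)/n_\mu$), their
per-activity average (`alphaFrequentist()`), or the activity-adjusted
variant that divides by the pair's combined participation count
(`alphaActivityAdjusted()`). All use the generalized Kronecker delta
$\delta(i,j,k)=1 \iff i=j=k$ — only *active* co-occurrences count. In the
generative sampler itself, by contrast, $\delta(x_i,x_j)$ is the plain
equal-states delta (matching inactive states attract exactly as matching
active ones); damping inactive matches is the job of the alpha scheme
upstream, not of the sampler. For the pure observational strategy a
constant $\alpha = 0.01$ is recorded in the metadata as the conventional
numerical-stability fallback.

## Sampling

`gibbsSample()` uses single-site heat-bath updates in fixed node order
(one pass = one sweep); exact full conditionals cost Q terms per update and
mix quickly at the weak couplings in scope. Defaults: 1,000 burn-in sweeps,
thinning 5, 100,000 kept samples for the generative strategy. The sampler
runs on its own splitmix64-derived integer stream, so identical seeds give
identical samples on any platform and no call disturbs R's global RNG
state. Correctness is asserted against exhaustive enumeration (total
variation below 0.02 on three-node models at 50,000 samples) and against
two-node closed forms.

## From couplings to a network

Raw marginal tables estimated from finite samples contain zeros, and the
inversion needs strictly positive entries; `marginalTables()` therefore
clips entries below at a smoothing floor (default $10^{-6}$;
$1/(Q^2 M)$ is a natural sample-scaled alternative) and renormalizes. With
zero smoothing the tables are exactly the empirical histograms.

The floor has a consequence worth knowing about: a pair of members that is
*never* observed co-active has an empirical $(1,1)$ cell of zero, and the
inversion turns the clipped cell into a repulsive coupling of magnitude
$\sim|\ln(\text{smoothing})|$. Such pairs — the majority in sparse
affiliation data — therefore receive couplings whose scale is set by the
floor, not by the data, and they can dominate the upper range of the
intensity distribution. This is a property of the closed-form
log-projection itself (zero co-occurrence genuinely is evidence of
repulsion; only its magnitude is arbitrary), and it is the same mechanism
behind the known failure mode of the pure observational variant, which
floods the thresholded network with noise links. Raising the smoothing
toward $1/(Q^2 M)$ compresses the artifact; the threshold sweep and the
community analysis are the tools for judging what survives it.

The inversion yields a full Q × Q coupling block per pair;
`edgeIntensities()` scalarizes it as the Frobenius norm of the interaction
sub-block ($k,l \ge 1$) — the standard gauge-clean coupling score in
inverse-Potts contact inference; field and constant terms, which carry no
interaction information, are excluded. Scores are min-max normalized over
the off-diagonal pairs into $[0,1]$ (an all-equal score vector maps to 0),
and `thresholdNetwork()` keeps links strictly above $t_m$, so $t_m = 1$ is
the empty graph and ties at the threshold are unambiguous.

On an isolated pair with exact marginals the inversion recovers the
generating block to $10^{-10}$; on a 3-node chain the non-adjacent pair's
intensity is strictly below either direct edge (indirect correlations are
detected but weaker); and on a planted 15-node, 20-edge, Q = 3 benchmark
with couplings ±0.8, ranking pairs by raw intensity from 20,000 Gibbs
samples separates true edges from non-edges with AUC above 0.9 (AUC 1.0 at
the default seeds).

## Communities, forced merging, and misclassification

`cnmCommunities()` is greedy modularity agglomeration on the weighted
graph (strength-based null model): merge the community pair with the
largest modularity gain until no positive gain remains, breaking ties by
the lexicographically smallest pair of community ids so partitions are
exactly reproducible. After thresholding, surviving links keep their
weights — the graph is thresholded, not binarized. With `forceK` the
merging continues past the modularity maximum, taking the best (possibly
negative) gain until exactly `forceK` communities remain — the "force the
algorithm to merge further" analysis mode for comparing, say, a 5-party
partition against a 3-bloc alliance structure; both labelings are just
different truth files to `fdr()`.

A known limitation, kept deliberately: greedy agglomeration does not
always attain the global modularity maximum. On small dense random graphs
(n ≤ 8) it misses the brute-force optimum on a minority of instances, and
`igraph::cluster_fast_greedy` returns the identical suboptimal value on
each such instance — it is a property of the algorithm, not of this
implementation. The test suite asserts both facts: agreement with igraph's
modularity computation, and the (occasionally failing) comparison against
exhaustive partition enumeration.

`fdr()` scores a partition against ground truth as the fraction of members
outside the community matched to their true group, under the
overlap-maximizing one-to-one assignment between communities and groups.
The assignment is computed by an exact bitmask dynamic program (identical
optimum to exhaustive enumeration; bounded at 10 truth groups). One-to-one
matching, rather than per-community majority vote, prevents one large
community from absorbing several groups at zero cost.

## The synthetic benchmark generator

No deposited dataset exists for the study system, so `generateAffiliation()`
emulates its published statistics: 338 members, 3,100 activities, a mean of
8 participants per activity, five planted groups in two alliances plus a
mixed group. Free choices, fixed once:

* participant counts are $1 + \mathrm{Pois}(\bar n - 1)$ — the minimal
  distribution honoring the published mean and the fact that every
  activity has at least one sponsor;
* group sizes follow proportions (0.33, 0.15, 0.27, 0.13, 0.12): two large
  parties each flanked by a smaller ally, plus a mixed group, mirroring
  the described chamber composition; the alliance map is (1, 1, 2, 2, 3);
* each participant slot is filled from the proposing group with
  probability 0.8, else uniformly from the rest of the chamber; 0.8 makes
  the standard Jaccard baseline recover the five planted groups cleanly,
  so the benchmark actually exercises the comparison the method is built
  for.

What the generator does *not* emulate: temporal drift of memberships,
sponsor-versus-cosponsor roles, heavy-tailed participation rates across
members, or alliance-level correlation beyond group sizes. Passing tests
on this fixture therefore demonstrate the pipeline's mechanics and its
qualitative behavior (threshold sweeps, community plateaus, FDR), not
fidelity to any real chamber's politics.

## Problem sizes and numerical choices in the test suite

The suite runs exact-enumeration oracles at $Q^N \le 10^6$ (guarded),
50,000-sample chains on three-node models, the 15-node planted-edge
benchmark at 20,000 samples, and one full-scale synthetic run (338 × 3,100,
semi-observational Q = 5 plus the Jaccard baseline with a 21-point
threshold sweep). Degenerate inputs are defined, not special-cased:
zero-weight graphs yield singleton partitions with modularity 0; all-equal
intensities normalize to 0; empty activities are skipped with a warning;
pairs with no joint activity get $\alpha = 0$.

## Limitations

* The closed-form inversion uses pairwise marginals only — no iterative
  message passing to a fixed point, no susceptibility propagation or
  pseudo-likelihood refinement; it inherits the Bethe approximation's
  blindness to strong loop corrections.
* Min-max normalization makes intensities comparable only within one run;
  thresholds are not transferable across runs.
* The greedy community detector is not globally optimal (see above), and
  modularity itself has a resolution limit on small, dense graphs.
* $Q > 64$ is out of range; the dense Q × Q per-edge storage assumes the
  moderate Q this model targets.
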
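---
title: "Top-down keystone detection: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-down keystone detection: models, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keystone)
```

## The problem

A keystone taxon is a native member of a community whose presence or
absence disproportionately reshapes the abundance profile of everything
else. Direct identification requires addition/removal perturbation
experiments, which are rarely available for natural microbial communities;
what is abundant instead are cross-sectional surveys — hundreds of samples,
thousands of taxa, relative abundances only. This package implements a
top-down framework that (i) defines and measures presence-impact in
simulated perturbation experiments, (ii) estimates the same quantity from
cross-sectional data alone via three empirical presence-abundance
interrelation (EPI) measures, (iii) corroborates cross-sectional estimates
with a longitudinal within-subject variant, and (iv) examines how candidate
keystones organize into co-occurrence modules. None of the steps
reconstructs a pairwise interaction network, so the approach is agnostic to
the (generally unknown and non-linear) form of the underlying dynamics.

## Community simulator

The synthetic-data generator is a generalized Lotka-Volterra (GLV) model

$$\frac{dx_i}{dt} = x_i\Big(r_i + \sum_j a_{ij} x_j\Big), \qquad
a_{ii} = -1,$$

with growth rates $r_i \sim U(0,1)$ and non-zero interaction strengths
$a_{ij} \sim U(-\sigma_A, \sigma_A)$ on either an Erdős–Rényi (ER)
topology (each directed off-diagonal entry present with probability
$\langle d\rangle/(N-1)$) or a directed Barabási–Albert (BA) topology
(preferential attachment from a fully connected seed clique; each edge is
oriented out of its higher-degree endpoint with probability $d$, otherwise
uniformly). A *sample* is a steady state reached from a random initial
condition: every taxon initially present with probability 0.8 with
abundance $U(0,1)$, absent taxa at exactly zero. Steady-state profiles are
normalized to unit sum, so only relative abundances flow into the analysis
— mirroring sequencing surveys.

Artificial keystones come in two flavours. *Strength-based* keystones
multiply a taxon's out-going interactions $a_{ji}$ by a boost $K$
(`boost_species()`); self-regulation stays $-1$, so the boost changes the
taxon's influence, not its carrying capacity. We exclude the diagonal from
the boost deliberately: scaling $a_{ii}$ would conflate keystone strength
with carrying capacity. *Structure-based* keystones are the natural hubs of
the BA topology, whose orientation bias gives hubs a large out-degree.
Ensembles with a continuum of keystone strengths use per-taxon boosts
drawn log-normal(meanlog 0.5, sdlog 1) (`lognormal_boosts()`): most taxa
near neutral, a few strongly influential.

### Parameters that matter

* `sigma_a` — interaction scale. Default $0.5/\sqrt{\langle d\rangle}$,
  half the May-style stability bound $\sigma_A\sqrt{\langle d\rangle} = 1$.
  At this scale effectively all samples converge to a stable steady state,
  also under a $K = 10$ boost. Larger values strengthen every signal but
  risk divergence.
* `presence_prob` — initial presence probability, default 0.8. Together
  with competitive exclusion it sets each taxon's realized frequency, and
  hence the size of the "absent" group that every EPI contrast relies on.
* `inoculum` — the abundance at which an addition experiment introduces an
  absent taxon, default 0.5 (the midpoint of the initial-condition law).
  In multistable communities the post-perturbation state can depend on it,
  so it is an explicit, recorded parameter rather than a hidden constant.

### Numerical integration

Steady states are computed with `deSolve`'s `lsodar`, the GLV right-hand
side supplied as compiled C for speed. Integration proceeds in chunks of
250 time units; after each chunk the relative derivative norm
$\max_i |\dot x_i| / \max(\max_i |x_i|, 10^{-12})$ is tested against
`tol = 1e-8`, and abundances below `extinction_eps = 1e-8` are clipped to
exactly zero so that presence/absence of a steady state is binary. The
time horizon defaults to `t_max = 5000`: slow extinction transients
routinely need a few thousand time units to pass the $10^{-8}$ criterion
even though they are ecologically settled much earlier, and a shorter
horizon misclassifies them as non-converged. Two safeguards address
artifacts of integrating near the invariant manifold $x_i = 0$: a
compiled root function stops the solver the moment any $|x_i|$ reaches
`blowup_cap = 1e6` (true finite-time divergence of unstable GLV systems),
and an "alive mask" pins taxa that are exactly zero at a chunk boundary,
because rounding noise of order $10^{-15}$ would otherwise seed an absent
taxon whose positive growth rate then amplifies the artifact to order one.
Samples whose perturbed re-integration fails to converge are flagged and
excluded from impact averages, with counts reported.

## Presence-impact from perturbation experiments

For sample $k$ and focal taxon $i$, the presence state of $i$ is reversed
(removed if present, introduced at the inoculum if absent) and the system
re-integrated from the perturbed state — the same community is perturbed,
not a fresh random one. Both the pre- and post-perturbation profiles are
reduced by deleting taxon $i$ and renormalizing to unit sum; this removes
the purely compositional coupling between $i$ and the rest. The per-sample
impact $I_k^i$ is the dissimilarity (Bray–Curtis by default, root
Jensen–Shannon optionally) between the two reduced profiles, and the
taxon's presence-impact $I^i$ is the mean over samples. A taxon is called
a keystone when $I^i$ exceeds the mean impact of all taxa by more than two
standard deviations; one-tailed z-test p-values are reported with the
focal taxon excluded from the background.

## Cross-sectional EPI

Given any cohort, the samples split into $G^i$ (taxon $i$ present) and
$\bar G^i$ (absent), and all profiles are reduced and renormalized as
above. Three separation measures are computed:

* $D_1$ — the mean dissimilarity over all cross pairs
  $(k \in G^i, k' \in \bar G^i)$;
* $D_2$ — the dissimilarity between the two group mean profiles;
* $Q$ — the two-group modularity of a sample-similarity network: samples
  are nodes, edges join the `p_q` most similar pairs (threshold at the
  empirical quantile with ties admitted, so edge counts are deterministic),
  labels are presence/absence of taxon $i$, and

  $$Q = \frac{1}{2w}\sum_{\alpha\beta}\Big[b_{\alpha\beta} -
  \frac{d_\alpha d_\beta}{2w}\Big]\frac{s_\alpha s_\beta + 1}{2}.$$

  The double sum runs over *all* ordered node pairs including
  $\alpha = \beta$ (where only the null-model term contributes); this is
  the convention under which uniform labels give exactly $Q = 0$, two
  disconnected equal cliques with matching labels give $Q = 1/2$, and $Q$
  is confined to $[-0.5, 1]$. Isolated nodes stay in the network and
  contribute only null-model terms.

$D_1$ suits clustered, linearly separable groups; $D_2$ tolerates
non-separable ones; $Q$ uses only short-range similarity structure and is
therefore the most robust to the unreliability of long distances in
high-dimensional compositional spaces.

A taxon is *eligible* when it is present in some samples and absent in
others — a taxon present everywhere has no presence contrast, so its EPI
is undefined — and, optionally, when its frequency lies in a window
$[f_{lo}, f_{hi}]$. The window is inclusive at both ends (the narrative
"between 0.25 and 0.75" does not specify strictness; inclusivity retains
more taxa). For real surveys the recommended window is $[0.25, 0.75]$,
because taxa near the frequency extremes carry a strong upward bias in
$D_1$ and $D_2$: their minority group is tiny and its sampling noise
inflates the cross-group distance. Candidates are taxa whose EPI exceeds
the mean over eligible taxa by two standard deviations, with the focal
taxon included in the statistics.

## Longitudinal EPI

With two collections from the same subjects, the longitudinal EPI $L^i$
averages, over the subjects in which taxon $i$'s presence state reversed
between visits, the dissimilarity between the two visits' reduced
profiles. Because the contrast is within-subject, between-subject
confounders (host genetics, diet, lifestyle) largely cancel. Taxa whose
$L$ would rest on ten or fewer reversal subjects are filtered out
(implemented as $n \ge 11$). `compare_epi_longitudinal()` correlates $L$
with any cross-sectional EPI column and tests candidate-set overlap (top
5% of each ranking, stable tie-break by taxon order) with a one-sided
Fisher exact test — one-sided because the scientific question is
enrichment of shared candidates, not depletion.

The simulated paired generator redraws each subject's community
independently at the second visit (presence resampled at the same
probability). This emulates substantial between-visit reassembly; it does
not model temporal autocorrelation within subjects, so simulated $L$
values carry more reassembly noise than real longitudinal data, where
consecutive samples are correlated.

## Co-occurrence networks and keystone modules

The co-occurrence network connects taxon pairs whose presence/absence
vectors share the top quartile of normalized mutual information (NMI),
each edge signed by the Pearson correlation of the presence vectors. NMI
is normalized by the arithmetic mean of the marginal entropies (a
geometric-mean variant is selectable; the choice only rescales values,
and for the binary vectors used here the two are nearly
indistinguishable); constant vectors have zero entropy and are defined to
share zero information. `neighbor_epi_correlation()` tests whether
adjacent taxa share EPI values — the statistical signature of keystone
modules — against a null that reshuffles EPI values over nodes; the edge
statistic uses each undirected edge in both orientations so it is
symmetric in the endpoints. `keystone_modules()` (greedy modularity on
the NMI-weighted graph) is provided as an exploratory convenience:
module extraction, and in particular separating true keystones from
satellite taxa inside a module, is an open problem.

## Null model for presence structure

`shuffle_presence()` randomizes a presence matrix by checkerboard swaps,
exactly preserving each taxon's frequency (row sums) and each sample's
richness (column sums) — the standard fixed-margin binary null. The
default number of attempted swaps is ten times the number of ones. A
matrix with no checkerboard (e.g. all ones) is returned unchanged with a
warning flag. Degenerate corner: a $2\times 2$ checkerboard alternates
between its two states, so an even number of successful swaps returns the
input; randomization is only meaningful for matrices with many boards.

## Problem sizes and what the tests show

The packaged experiments run at desk scale: communities of 30–100 taxa,
cohorts of 20–100 samples, 5–20 replicate seeds. At these sizes the
perturbation side is strong — a $K = 10$ keystone in an ER community of
50 taxa with mean degree 10 attains the top impact in about 95% of
replicates. The cross-sectional EPI contrast grows with coupling density:
under dense, strongly coupled conditions (mean degree about half the
community, unit growth rates) all three EPI measures flag the designated
keystone, while in sparsely coupled communities (mean degree 10 at the
default interaction scale) the EPI separation is often within the noise
of the 2-SD rule, and the EPI–impact rank correlation is diluted by the
many taxa whose true impact is essentially zero and whose EPI is
dominated by frequency bias — the modularity measure $Q$ degrades most
gracefully. Passing tests therefore demonstrate the machinery and its
behaviour in the regimes above; they do not certify detection power on
real surveys, whose noise sources (sequencing depth, compositional zeros,
host covariates) the generator does not emulate.

## Known limitations

* GLV dynamics with pairwise interactions are the generator, not a claim
  about real microbiomes; the detection measures themselves are
  dynamics-agnostic.
* EPI is correlational: a taxon that is strongly *affected* by the
  community also scores high. Disentangling cause from effect requires
  perturbation experiments.
* The detection threshold treats any positive abundance as presence;
  real survey "absence" means below detection limit, and the threshold is
  configurable for that reason.
* Abundance-impact (response to changing a taxon's abundance rather than
  its presence) is out of scope.
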
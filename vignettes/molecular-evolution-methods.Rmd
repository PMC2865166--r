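---
title: "Models and methods in molevolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in molevolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

molevolkit is a toolkit for asking, of a family of protein-coding genes,
four related questions: *where* along the protein is amino-acid variability
concentrated (reverse conservation analysis), *which codons* are under
positive or purifying selection (a random-effects likelihood scan),
*which codon pairs* change together on the tree (substitution mapping plus
a Bayesian network over sites), and *whether the gene family itself* has
grown or shrunk faster than a neutral gain/loss process allows (a
birth–death test on a dated species tree). A codon-level simulator with
recorded ground truth backs every stage, so the whole pipeline can be
exercised and calibrated without any external data. This vignette explains
the models, the defaults, and the numerical choices; it states no result
that the package's tests and acceptance script do not themselves compute.

## Site rates and reverse conservation analysis

Per-column evolutionary rates on an amino-acid alignment are estimated by
empirical Bayes under a JTT substitution model with alignment-wide
empirical frequencies. Rates across sites follow a discretized gamma
distribution: `K = 16` equal-probability categories represented by their
category means (`phangorn::discrete.gamma`), with the shape `alpha`
estimated by maximizing the marginal log-likelihood
`sum_i log mean_k L_i(r_k)`; each column's likelihood `L_i(r)` is computed
by Felsenstein pruning with all branch lengths multiplied by `r`. The
posterior-mean rate per column is then standardized over columns to give
the S score (mean 0, sd 1; high = variable). Gaps and ambiguous residues
are summed over all states, so an all-gap column carries no information
and a rate near zero on an invariant column recovers the stationary
frequency of the shared residue. Columns with more than 50% gaps are
scored but flagged, and the flag travels into downstream tables.

The guide tree is user-supplied or, by default, neighbour joining on
Poisson-corrected distances — the same distance family the package's
phylogeny module exposes (`d = -ln(1 - p)`, with complete or pairwise
deletion of gapped columns; a JTT maximum-likelihood pairwise distance is
available as an alternative metric). NJ is delegated to `ape::nj`, with
negative branch-length estimates clamped to zero and the deficit pushed
onto the adjacent branches; ties in the agglomeration are resolved by
ape's deterministic ordering, so builds are reproducible. Bootstrap
support is the percentage of column-resampled replicates containing each
internal bipartition of the point-estimate tree.

Reverse conservation analysis standardizes the S scores (again to mean 0,
sd 1 — the operation is idempotent, and normalization deliberately
precedes windowing), smooths with a centred sliding window of `n = 7`
residues, and calls peaks as maximal runs with window mean `W >= 0.5`
(the threshold is inclusive: a window exactly at 0.5 standard deviations
counts). Edge windows shrink so every residue gets a value; a flag
switches to undefined edges instead. There is no minimum peak length, but
Roman-numeral labels are only assigned to peaks spanning at least three
residues, mirroring how multi-residue variable regions are labelled in
practice. Clade comparison takes two profiles on a shared coordinate
frame and reports maximal runs where exactly one clade's `W` exceeds the
threshold — a stated operationalization of "regions with different window
score distributions", not a claim that any particular published figure
used the same rule.

## The REL positive-selection scan

The selection scan uses an MG94-style codon model crossed with a
constrained reversible nucleotide model. Only single-nucleotide codon
moves have positive rate: `q(i -> j) = rho[exchange] * pi[j] * dS` for
synonymous and `... * dN` for non-synonymous moves, over the 61 sense
codons of the universal code, with `pi` from the F3x4 estimator by
default (empirical codon frequencies behind a flag). The constraint map
assigns each of the six unordered nucleotide exchanges to a named rate
parameter, with unnamed exchanges sharing the reference rate fixed at 1 —
so a model string like "C<->T gets its own rate" is
`nuc_model_spec(CT = "RCT")`, and a five-parameter map with shared
A<->C/A<->T and C<->G/G<->T rates is expressed the same way. Arbitrary
maps are supported, so alternative readings of a published model string
cost nothing.

Under the random-effects model, dN and dS each take one of three values
with free weights, giving nine (dN, dS) classes. Fitting is two-stage,
matching how the REL method was historically run: the nucleotide stage
estimates branch lengths and exchange rates by a GTR fit on the
nucleotide data (via `phangorn::optim.pml`), which are collapsed onto the
constraint map by averaging grouped exchanges; the codon stage then
maximizes the mixture log-likelihood over the six grid values, the four
free weights and a single tree-scale factor by Nelder-Mead with seeded
multi-start jitter. Identifiability is resolved by normalizing the grid
so the prior-mean synonymous rate is 1 (absorbing the scale confound
between rates and branch lengths) and sorting each marginal ascending.
Site pattern compression makes the per-evaluation cost proportional to
the number of distinct columns.

Per site, the posterior over the nine classes is the prior weight times
the site likelihood, normalized. `P+` is the posterior mass on classes
with dN > dS (classes with |dN - dS| < 1e-9 count toward neither side),
and the Bayes factor is posterior odds over prior odds. Sites classify as
strong positive (BF >= 50), weak positive (10 <= BF < 50), purifying
(symmetric BF for dN < dS >= 50), else neutral. A degenerate prior
(`P+` of 0 or 1) flags the result and uses the documented infinite/zero
Bayes-factor convention. Below ten sequences the fit warns: with so
little data the random-effects distributions are weakly identified.

## Co-evolving codon detection

The co-evolution scan maps non-synonymous substitutions onto branches and
asks which site pairs light up together. Ancestral codon states are
reconstructed marginally (posterior per node and site) under a
single-ratio MG94 fit, with ambiguous tip characters averaged over
compatible codons. For each branch and site the mapper computes the exact
joint posterior over (parent, child) codon states and from it the
probability that the branch changed the amino acid at that site; the
branches-by-sites matrix of these probabilities is binarized at 0.5
(the raw probabilities are exported alongside for audit). Sites with
fewer than three inferred non-synonymous branch changes are dropped —
below that the network has essentially no signal to work with.

Over the retained sites, a Bayesian network with in-degree at most two is
scored with Bernoulli–Dirichlet local marginal likelihoods (BDeu prior,
equivalent sample size 1) under a sparsity prior proportional to
`0.3 ^ n_edges`. The sparsity prior is the package's specificity control:
under a uniform structure prior the exact posterior calls about 7% of
independent-noise pairs at the 0.5 association threshold (measured on
Bernoulli(0.2) columns over 40 branches), which a screening tool cannot
afford; at the default prior the same null study yields about 2% while
strongly coupled pairs still reach posteriors near 1. Edge posteriors
are estimated by
Metropolis–Hastings over structures with a pairwise three-state proposal
(for a random ordered site pair, the edge between them is absent,
forward, or reverse; one of the other two states is proposed uniformly,
subject to the in-degree cap and acyclicity). This kernel mixes across
edge directions directly, and on five or fewer sites the sampler agrees
with exhaustive enumeration of all valid structures (`bgm_exact_posteriors`)
to well within 0.05 per edge — that enumeration oracle is the package's
correctness bar for the sampler, and the reason structure-space (rather
than node-order) sampling was chosen: order sampling targets a different,
order-modular prior and cannot be validated against the same enumeration.
Two independent chains run by default; if they disagree by more than 0.1
on any edge the function warns with diagnostics attached. Pair
association is direction-marginalized (an edge in either orientation),
and co-evolving groups are connected components of the association graph
at the 0.5 posterior threshold.

## Gene-family birth–death analysis

Family sizes evolve along a dated species tree by a linear birth–death
process with equal per-gene birth and death rate `lambda` per time unit
(units: whatever the tree's branch lengths are in — typically millions of
years). The transition probability from size `s` to `c` over time `t` has
the classical closed form in `alpha = lambda*t / (1 + lambda*t)`, valid
for `lambda*t < 1`; longer branches are automatically split into
segments combined by Chapman–Kolmogorov matrix products over a truncated
size range (the raw single-segment form is reachable with
`split = FALSE`, which errors outside its domain instead). Family
likelihoods marginalize ancestral sizes by pruning over 0..`max_size`
(default twice the largest observed count) with the root drawn from a
uniform prior on 1..`max_size` — the root prior is a documented choice;
nothing in the data identifies it. `lambda` is estimated by bounded 1-D
search on the summed family log-likelihood, excluding all-zero families
(standard ascertainment: a family extinct everywhere is never observed),
and collapsing to a flagged 0 for constant tables.

Family-level significance is Monte-Carlo: simulate families under the
null (root from the prior, global `lambda`), and report the fraction with
likelihood at most the observed one, add-one corrected. Branch
identification combines a Viterbi (max-product) joint assignment of
ancestral sizes with two per-branch scores: an exceedance p-value (the
total probability of child sizes no more probable than the Viterbi
transition, given the parent size) and a likelihood ratio refitting that
branch's rate freely against the global rate. The printed-style cutoffs
(p <= 0.05, ratio > 50) flag branches. The "likelihood ratio" here is a
stated operationalization — the branch-specific free-rate refit — since
more than one definition is compatible with common usage.

## Codon usage and identity composition

Codon counting uses the universal code over the 61 sense codons; a
terminal stop is tolerated and excluded, an internal stop is an error.
Correspondence analysis is the standard singular decomposition of the
chi-square standardized residuals of the relative-frequency matrix,
performed on within-gene relative codon frequencies by default (raw-count
and RSCU modes behind flags; Met and Trp codons are retained in the
default mode). Axis signs are canonicalized so each axis's
largest-magnitude coordinate is positive — CA axes are sign-arbitrary and
this keeps plots reproducible. Pairwise nucleotide identity excludes
positions gapped in either sequence and reports the mean and sample
standard deviation over unordered pairs.

## The simulator and what it does (not) emulate

The generator evolves each codon site independently (except engineered
pairs) by exact event-by-event simulation of the MG94 process: waiting
times are exponential in the current codon's total exit rate, moves are
single-nucleotide, non-synonymous rates scale with the site's omega and
optional per-site rate multiplier, and the root sequence is drawn from
the stationary codon distribution. Event-level simulation (rather than
transition-matrix sampling) is essential because the co-evolution signal
is defined on substitution events: for an engineered pair, once the
driver site sustains a non-synonymous substitution on a branch, the
partner site's non-synonymous rates are multiplied by the coupling factor
for the remainder of that branch (simulated piecewise-homogeneously
around the driver's event time). Every realized substitution is recorded
in the truth tables, including the branches-by-sites non-synonymous
indicator the co-evolution mapper tries to recover. All randomness flows
from one explicit seed; no global state is shared between generators.

What the simulator does **not** emulate: insertions and deletions,
introns, recombination, selection on codon usage, and lineage-specific
rate shifts. Passing recovery tests on simulated data therefore shows the
estimators are correct under their own model assumptions — it does not
show robustness to alignment error or model misspecification in real
data.

Family-size data are simulated by the same linear birth–death process the
analysis assumes (death equals birth; size zero absorbing), recording
sizes at every internal node.

## Study sizes used by the tests and acceptance script

The recovery studies use deliberately compact problem sizes chosen as
realistic for the data regime this package targets (gene families of a
few hundred codons over roughly 6–30 taxa):

- Site-rate recovery: 12 taxa, 400 codons, gamma shape 0.5.
- RCA end-to-end: 12 taxa, 120 codons with one 12-codon fast block,
  20 seeded replicates.
- REL: one 12-taxon, 400-codon fit with 10% of sites at omega = 5 over
  a purifying background (omega 0.1 and 0.8) for the enrichment check —
  backgrounds with bulk mass exactly at omega = 1 put the fitted neutral
  class on a knife edge around dN = dS and make "positive" prior mass,
  and hence Bayes factors, unstable (see the limitation noted above);
  three 12-taxon, 300-codon null replicates for
  the specificity guard, simulated as a purifying gene (omega in
  {0.2, 0.8}) — the regime of the actin/elongation-factor style control
  genes such a scan is calibrated against.
- Co-evolution: 20 replicates of a 36-taxon tree with long terminal
  branches, one engineered pair (driver omega 3, coupling 300 on a
  purifying partner). Long terminals matter: a substitution on a terminal
  branch is pinned by the observed tip state, whereas signal on very
  short internal branches is smeared across neighbours by reconstruction
  uncertainty, and an over-saturated partner site (too-high coupling)
  destroys the ancestral consensus the mapper relies on. These two
  failure modes bound the effect sizes a branch-level binary mapper can
  ever detect, and real-data users should expect the same: co-evolution
  detection is most sensitive for pairs of moderate variability on trees
  with informative terminal branches.
- Birth–death: calibration and recovery on three-taxon dated trees with
  200 families; Monte-Carlo p-values at 100–1000 resamplings.

## Known limitations

- The REL grid optimization is non-convex; multi-start Nelder-Mead with
  the documented normalization is robust in testing, but pathological
  data can still require more starts (`starts` argument).
- Bayes factors compare posterior odds under the *fitted* grid; they do
  not propagate uncertainty in the grid itself (an inherent property of
  the empirical-Bayes REL approach).
- When a large fraction of sites sits exactly at omega = 1, the
  maximum-likelihood grid tends to interlace dN levels above dS levels
  (both distributions absorb sampling dispersion), and strong-positive
  Bayes factors become anticonservative — neutral sites can be called at
  BF >= 50 in bulk. This is a property of the dual-variation
  random-effects model itself, not of the optimizer; interpret
  strong-positive calls cautiously for genes suspected to be largely
  neutral, and prefer the purifying-control comparison the test suite
  demonstrates.
- The substitution mapper reports amino-acid-changing branches, not
  counts of multiple hits within a branch.
- The birth–death model assumes one global rate with birth = death;
  asymmetric gain/loss and per-clade rates are out of scope.
- Exact numerical replication of any specific historical server or
  release of the corresponding tools is not claimed anywhere; defaults
  are documented and parameterized instead.
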
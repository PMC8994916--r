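---
title: "Decomposing contact graphs into chromatin-mark interaction probabilities"
author: "hicdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing contact graphs into chromatin-mark interaction probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdecomp)
```

## The model

Chromosome-conformation-capture assays (Hi-C and its nucleosome-resolution
variant Micro-C) report which pairs of genomic loci touch in 3D.  Chromatin
marks — histone modifications and transcription-factor binding sites — are
known to be enriched around contact structures such as TADs and A/B
compartments, but individual marks explain contacts poorly; pairs of marks
acting jointly do much better.  `hicdecomp` estimates exactly that joint
quantity: a symmetric matrix $X = \{x_{mn}\}$ where $x_{mn}$ is the
probability that a co-occurring pair of marks $(m, n)$ at two loci produces
a contact.

Each site $u$ carries a mark vector $C_u$ (binary per mark at restriction-site
resolution; counts after binning).  Every co-occurring mark pair is an
independent chance to create a contact, so

$$P(E_{uv} \mid X) \;=\; 1 - \prod_{m,n} (1 - x_{mn})^{c^u_m c^v_n}.$$

Sites sharing many active mark pairs get many chances, hence higher contact
probability.  The Bernoulli likelihood over observed edges *and* observed
non-edges is non-convex in $X$, but the change of variables
$x = 1 - e^{-z}$ (so $z \ge 0$) makes the negative log-likelihood convex in
$Z$, with the clean bilinear form $s_{uv} = C_u^T Z C_v$ and
$P(E_{uv}) = 1 - e^{-s_{uv}}$.  Two penalties encode prior structure:

$$\min_{Z \ge 0}\; -\log L(Z) + \lambda_1 \|Z\|_* + \lambda_2 \|Z\|_1 ,$$

the nuclear norm favouring block/community structure among marks (low rank)
and the L1 norm favouring a sparse set of active mark pairs.  The whole
problem is convex (the package's test suite checks the Jensen inequality on
random draws), so the solver's answer is the global optimum.

## The solver

The objective is non-differentiable, so it is split ADMM-style with two
auxiliary copies $Z_1, Z_2$ of $Z$ and scaled duals $U_1, U_2$:

* **Likelihood block** — minimize the smooth negative log-likelihood plus the
  two quadratic consensus terms over $Z \ge 0$, by projected gradient with
  Armijo backtracking (inner cap 200 iterations, relative-move tolerance
  $10^{-6}$, 50 step halvings before giving up with a warning).
* **Nuclear block** — closed form: soft-threshold the singular values of
  $Z + U_1$ at $\lambda_1/\rho$.
* **L1 block** — closed form: entrywise soft-threshold $Z + U_2$ at
  $\lambda_2/\rho$ (dead zone below the threshold, shrink above).
* **Dual updates** — $U \leftarrow U + (Z - Z_{\text{aux}})$.

Iterations stop when $\max(\text{primal}, \text{dual}) / \max(1, \|Z\|_F)$
drops below `tol` ($10^{-4}$ by default).  The primal consensus gap alone is
not a safe stop: when $\lambda/\rho$ is small the prox steps are
near-identities and the gap collapses to $\|U\| \approx 0$ after one
iteration while $Z$ is still moving, so the standard dual residual
$\rho\,\|Z_{\text{aux}} - Z_{\text{aux}}^{\text{old}}\|$ participates too.
For the same reason the default penalty parameter is
$\rho = \max(1, \lambda_1, \lambda_2)$: with $\rho$ far below the penalty
weights the consensus residuals decay over hundreds of iterations; keeping
$\rho$ on the penalty scale removes that stall without changing the optimum
(ADMM converges for any fixed $\rho > 0$).  Both defaults are overridable.

Symmetry is maintained by symmetrizing the gradient (equivalently, averaging
$Z$ with its transpose); the prox operators preserve symmetry of symmetric
inputs.  Only $Z$ is sign-constrained — $Z_1$ may go negative inside the
consensus loop, which is reconciled by the constraint $Z = Z_1$ at
convergence.

### Computational form of the likelihood

The non-edge sum $\sum_{(u,v) \notin E} s_{uv}$ is never looped: with
$t = \sum_u C_u$ per chromosome,
$\sum_{u<v} s_{uv} = \tfrac12 (t^T Z t - \sum_u C_u^T Z C_u)$, and edges and
held-out pairs are subtracted from it.  Two further reductions keep big
fits cheap: binary mark vectors mean edges collapse to *distinct pattern
pairs* with multiplicities (a 500-site fixture's 21k edges reduce to ~1.2k
patterns), and held-out pairs only enter linearly, so they reduce to the
single constant matrix $\sum C_u C_v^T$.  A brute-force double-loop oracle
in the test suite pins the aggregated form to $10^{-9}$ relative accuracy.

Edges whose endpoints carry no marks have $s_{uv} = 0$ and likelihood zero;
their linear predictor is clamped at `clamp_eps` ($10^{-10}$) with a warning
rather than returning $-\infty$, since such edges are simply outside the
model's explanatory scope.

### Held-out pairs

Cross-validation needs pairs that are neither edges nor background.  The
`exclude` argument removes held-out pairs from **both** the edge set and the
non-edge sum.  Removing them from only one side is incoherent — a held-out
positive would keep its $-\log(1-e^{-s})$ reward while losing its $-s$
penalty, making the likelihood unbounded along that direction.

## The binned variant

Binned data have integer contact counts and integer mark counts.  The count
between two bins is then a sum of independent non-identical Bernoulli slot
trials — a Poisson-binomial over $T = C_u^T \mathbf{1} C_v$ slots, the
mark-pair probability $x_{mn}$ repeated $c^u_m c^v_n$ times.
`poisson_binomial_pmf()` computes the exact pmf by dynamic-programming
convolution (the subset-enumeration definition is kept as a test oracle up
to $T = 12$).  Inside the likelihood the Le Cam Poisson approximation with
rate $\lambda_{uv} = C_u^T X C_v$ is used, whose total-variation error is
bounded by $\sum_i p_i^2$ — small exactly when marks are sparse per bin,
the regime binning at kb-scale produces.  The Poisson-approximated problem
is treated as nonconvex, so `fit_binned()` runs projected gradient with
Armijo backtracking from 5 random starts (box constraint
$0 \le x \le 1 - 10^{-6}$, penalties applied on the transformed scale) and
returns the best objective.

## Preprocessing conventions

* Coordinates 0-based; peaks half-open `[start, end)` (BED); bins half-open
  at a fixed resolution; positions map to bins by floor division.
* A mark belongs to a site when a peak of that mark is within `max_dist`
  (default 100 bp, inclusive) of the site position — distance zero inside
  the peak, else the gap to the nearest interval edge coordinate.  One peak
  may serve several nearby sites.
* Binning sums member-site indicators (assignments) and member-pair counts
  (contacts); intra-bin pairs leave the likelihood (it runs over distinct
  nodes) and are reported so totals reconcile.
* Signal-track binarization: average replicate RPKM per bin, then
  $\log(1+x)$ (natural log), then threshold at 0.5, inclusive.  Averaging
  precedes the transform.
* The non-edge background defaults to within-chromosome pairs
  (`pair_scope = "within"`), matching per-chromosome fitting; `"all"` is
  available.

## Evaluation toolkit

Link prediction is scored by ROC/AUC with rank-averaged ties (the Wilcoxon
statistic).  The null predictor is distance decay,
$P = \alpha\, d(u,v)^{-\beta}$ with $\beta \in \{1, 1.5, 2\}$ and $\alpha$
learned by 1-D Bernoulli maximum likelihood on the training pairs (AUC is
invariant to $\alpha$ below the probability clip).  A/B-compartment calls
take the sign pattern of the leading principal component of the input's
correlation matrix; partitions are compared by variation of information
normalized by $\log n$ (0 = identical, 1 = maximally different);
TAD-boundary sets are compared by greedy nearest-first one-to-one matching
within a bin tolerance (default 0, i.e. exact; the package accepts
externally produced domain partitions rather than re-implementing a domain
caller).  Replicate stability is Spearman correlation over upper-triangle
mark-pair entries.  `nested_cv()` implements fivefold-outer /
fourfold-inner selection of $(\lambda_1, \lambda_2)$, with outer folds
either random pair partitions (same-chromosome mode) or whole chromosomes
(leave-one-chromosome-out); ties go to the more regularized pair, and all
fold draws are seed-deterministic.  During the grid search the ADMM runs at
relaxed caps (the objective plateaus within a few outer iterations, and
ranking by AUC is insensitive to consensus polish); final fits use full
tolerances.

Perturbation experiments mirror two in-silico designs: `mask_marks()`
zeroes chosen mark columns inside a region (e.g. CTCF sites at a TAD
boundary; by the product form, masking can only lower predicted
probabilities — a property test checks 10,000 pairs), and
`delete_region()` excises a segment, rejoins the flanks with shifted
coordinates, and drops incident contacts, emulating a structural deletion.

## The synthetic world

`make_truth()` draws a ground-truth $X$ either with a prescribed sparse
support or with block structure (constant within-group probability, giving
a low-rank-plus-sparse target).  Per-mark occurrence densities are drawn
once from Uniform(0.05, 0.3) — peak tracks differ widely in genomic
coverage, and this heterogeneity is what makes recovery non-trivial.
Synthetic restriction sites sit 4 kb apart on one pseudo-chromosome
(a typical restriction-fragment scale; positions only matter for binning
and the distance baselines).  `sample_contacts()` simulates the generative
model forward: Bernoulli edges from the product form, or binned counts
either exactly (slot-level Poisson-binomial draws) or from the Le Cam
Poisson.  The fixture suite fixes three sizes: tiny (3 marks / 8 sites,
solvable by brute-force oracles), small (6 marks / 500 sites, two
3-mark blocks at within-probability 0.4 — the parameter-recovery fixture),
and medium (16 marks / 3000 sites, support sparsity 0.05 — a scaled-down
genome-wide catalog).

What the simulator deliberately does **not** emulate: distance-dependent
contact decay, TAD-shaped truth, coverage biases, or overdispersion — the
generative model has none of these.  A green recovery test therefore
establishes that the estimator inverts its own generative process at
realistic sparsity, not that real Hi-C obeys the model; conversely it is
exactly why distance-decay baselines *should* lose on this data, which the
baseline-ordering test asserts.

## Numerical choices

* `clamp_eps` $= 10^{-10}$ floors the edge linear predictor inside logs.
* Transform round-trips $z \to x \to z$ are exact to the representation
  limit: near $z = 20$, $x$ sits within machine epsilon of 1 and the
  recoverable precision of $z$ is $\sim \epsilon\, e^{z}$.
* Armijo sufficient-decrease constant $10^{-4}$; step doubles after each
  accepted iteration (cheap quasi-adaptivity).
* CV tie-breaks: larger $\lambda_1 + \lambda_2$, then larger $\lambda_1$.
* ROC requires both classes and errors otherwise, naming the missing class;
  compartment calls error on zero-variance (degenerate) inputs.
* Randomness is localized: every sampling function takes a seed, uses it in
  a local RNG scope, and restores the caller's RNG state.

## Limitations

The mark-pair matrix is assumed global (the same $X$ everywhere on the
genome); regional variation is outside the model.  The unbinned likelihood
treats contacts as presence/absence.  No contact-map normalization
(ICE/KR), read processing, peak calling, or TAD calling is included — the
package starts from called peaks and contact lists and ends at fitted
probabilities, predictions, and partition/boundary comparisons.

## A complete run

```{r example, eval = FALSE}
truth <- make_truth(n_marks = 6, seed = 1,
                    block_structure = list(groups = list(1:3, 4:6),
                                           within = 0.4, between = 0))
asg <- sample_assignment(truth)
ctc <- sample_contacts(truth, asg)
cv <- nested_cv(ctc, asg, list(c(0.1, 0.1), c(1, 1), c(5, 5)),
                seed = 11, max_iter = 30, max_inner = 40)
fit <- hicdecomp(ctc, asg, lambda1 = cv$lambda[1], lambda2 = cv$lambda[2])
summary(fit)
ut <- upper.tri(coef(fit), diag = TRUE)
cor(coef(fit)[ut], truth$X$X[ut])   # recovery of the generating matrix
```
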
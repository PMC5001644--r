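---
title: "sitemech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sitemech: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitemech)
```

This vignette is the package's own account of its science: the
probabilistic model, what each tunable parameter means and why its
default is what it is, what the synthetic generators do and do not
emulate, and the numerical and design decisions that were genuinely open.

## The probabilistic model

For a missense variant `x` on a structure and a residue function `f`
(zinc binding, catalysis, phosphorylation, ...), the package separates
two routes to functional alteration: the substitution disrupts protein
stability (`S`) and thereby function, or it leaves the fold intact
(`S-bar`) yet changes the residue's functional propensity. The loss
probability marginalizes the two strata:

    P(loss of f | x) = P(loss | S, x) P(S | x) + P(loss | S-bar, x) (1 - P(S | x))

with two approximations that make the model estimable from site
predictors alone:

* `P(loss | S, x) ~ P(f | x'_wt)` — a large stability change abolishes
  whatever function the residue had, so the loss probability collapses
  to the probability that the residue was functional in the first place;
* `P(gain | S, x) ~ 0` — an unfolded or grossly perturbed site
  essentially never creates new function.

In the intact stratum the same structure-based predictor is applied
twice — to the wild-type environment and to the environment with only
the root's amino acid label substituted — giving the product formulas

    P(loss | S-bar, x) = p_wt (1 - p_mt)
    P(gain | S-bar, x) = (1 - p_wt) p_mt.

This is deliberately a **two-stratum** model: stability is dichotomized
at |ddG| > 0.5 kcal/mol in training labels. A continuous treatment would
replace the sum with an integral over stability change; the package
implements exactly the two-stratum version and exposes `P(S|x)` (`p_S`)
as an explicit argument everywhere, so any external stability posterior
can be plugged in.

Over a set of functions the joint posteriors are not learnable from the
sparse site data, so two approximations from the marginals are offered:
the independence model `1 - prod(1 - v_f)` (an upper-leaning estimate,
since real functions co-occur) and the max model `max(v_f)`
(conservative; always a lower bound on the independence value). Both are
reported; disagreement between them brackets the truth.

## Microenvironments and graphlet kernels

Contact graphs use the **any-atom 4.5 Å** rule by default; the
**C-alpha 6.0 Å** rule is available as a configuration. Both definitions
are standard in the contact-map literature and the package treats the
any-atom rule as normative because it is the one under which the
predictors are described; the C-alpha variant exists because level-based
renderings of contact graphs conventionally use it. Neither is
privileged beyond the default argument.

A residue's microenvironment is the BFS ball of depth `level = 3`
(configurable). Depth 3 balances locality against context: depth 1-2
under-describes binding pockets assembled from several chain segments,
while depth 4+ balls in dense cores approach whole-domain size and
dilute the root's signal.

Environments are compared by counting **rooted vertex-labeled
graphlets** up to `N = 4` vertices by default (`N = 5` supported; the
model-selection grid searches both). Counting is exact: every connected
induced subgraph containing the root is enumerated once and
canonicalized by brute-force minimization over root-fixing permutations
(at most 4! orderings at N = 5) — correctness over speed at graphlet
scale. Edit-distance smoothing spreads each raw count over its
neighborhood `E(n_i, m)` with unit weights; the searched budget is
`m ∈ {0, 1}`, where `m = 0` is the standard graphlet kernel.

Three points about the edit operations were genuinely open and are
resolved as follows:

* **Vertex insertion** as a single operation would create a disconnected
  graph; here insertion attaches the new vertex to one existing vertex
  by one edge (any label in the alphabet), and deletion — its inverse —
  removes a non-root leaf. Every m = 1 neighbor is therefore itself a
  valid graphlet, and the edit relation stays symmetric, which the
  smoothing implementation exploits (accumulating each raw count into
  its own neighborhood) and the test suite asserts directly.
* **Inserted labels** may be any symbol in the alphabet, not only labels
  observed in the data: the neighborhood is a property of the kernel
  spec, not of a sample.
* **Edge-label substitutions** are vacuous (contact edges are
  unlabeled) and accepted as no-ops.

Cross-size neighbors (full mode) are representable because smoothed
vectors are indexed over all orders up to N. Profiles are sparse maps
keyed by canonical id: the dense vector over all labeled 5-graphlets on
a 40-symbol alphabet is astronomically long, while the formulas are
index-free under sparsity.

The conservation split (20 to 40 symbols) recodes residues below the
pivot to lowercase forms. The pivot is the median conservation over the
**entire training collection**, never per chain — per-chain pivots would
make identical environments compare differently across proteins. Ties
at the pivot go to the conserved class, making the split deterministic
when the median is an attained value. Conservation scores are an input
(any per-residue scalar, e.g. relative entropy from a user-supplied
alignment); the package does not compute alignments. A mutant root
**inherits the wild type's conservation class**, since conservation is a
property of the alignment column, not of the substituted residue; this
is a modeling convention, flagged here because no principled transfer
rule exists without re-aligning the mutant sequence.

## Positive-unlabeled training

All predictors are trained from positives plus unlabeled residues. The
non-traditional classifier (labeled vs unlabeled) is a C-SVM on the
precomputed normalized kernel with capacity `C = 1` — the standard
default heuristic `C = 1/mean(k(x, x))` reduces to 1 on a unit-diagonal
kernel. Decision values are calibrated with Platt's sigmoid (regularized
ML with the usual smoothed targets, Newton iteration with backtracking);
calibration on out-of-fold scores is preferred when available, since
calibrating on training scores is optimistic. The traditional posterior
follows from the class prior via

    P(y=+1|x) = alpha * (n/m) * p_l / (1 - p_l),

clipped to [0, 1]: the formula is exact only under assumptions
(labeled points exchangeable with unlabeled positives) and unbounded in
finite samples, while every downstream formula needs a probability.

Class-prior estimation is a pluggable interface. Mixture-proportion
algorithms of the AlphaMax family are out of scope; the built-in
baseline is the mean-posterior-ratio estimator (Elkan & Noto's e1),
`alpha = mean_unlabeled(p_l) / mean_labeled(p_l)`, which is accurate
exactly when the calibrated posterior nearly vanishes on the background
component. For one-dimensional score data `pu_prior_from_scores()`
therefore fits the logistic classifier on `log(s)` and `log(1-s)` — the
sufficient statistics of a Beta family — rather than on raw scores,
which keeps the background posterior near zero and the e1 bias around
+0.01 on the default generator (a raw-score sigmoid leaves ~+0.04).
User-supplied priors are accepted verbatim.

The stability predictor augments the kernel representation with 33
mutation features: a 20-slot wild-type/mutant indicator block and 13
physicochemical property differences. The identities of the 13
properties are known only by citation; the default table
(`aa_property_table()`) is a **reconstruction** from standard published
scales (Kyte-Doolittle hydropathy, residue volume, Grantham polarity,
charge, pI, flexibility, accessible surface area, mass, H-bond
donor/acceptor counts, aromaticity, branching, side-chain pKa) and is an
argument, not a constant.

## Evaluation and model selection

Cross-validation is per-chain, 10-fold, near-balanced in chain count and
deterministic per seed: residues of one chain never straddle the
train/test boundary, which would otherwise leak near-identical
environments. Specificity at the reporting threshold is computed over
unlabeled-as-negative — a documented optimistic bias inherent to PU
evaluation, since some "negatives" are latent positives. The threshold
is the smallest score achieving specificity >= 0.99 over the pooled
negatives; pooling (rather than per-fold thresholds) is our choice where
the convention is unstated, because per-fold thresholds on small folds
are order statistics of noisy samples. MCC at that threshold guards the
zero-denominator case by reporting 0. AUC uses the rank statistic with
tie-averaging and is checked against exhaustive pair counting.

The model-selection grid spans alphabet size {20, 40}, m in {0, 1}, N in
{4, 5} and the three edit modes, maximizing mean CV AUC; ties break
toward smaller (N, m, alphabet) for parsimony.

## Empirical null and enrichment

The decision threshold at false positive rate q is the
`ceiling((1-q) n)`-th order statistic of the neutral score sample, and
exceedance is **strictly greater** — "a greater probability than the
threshold" — so ties at the threshold do not exceed. On a tie-free null
with integral `n q` the null's own exceedance is then exactly q, a
self-calibration property the tests assert. Enrichment is a one-tailed
Fisher's exact test per (function, output) cell; single-function cells
form a Bonferroni family of 2 x 29 = 58 (loss and gain jointly, per
output), combined-model cells a separate family of 4. Single-variant
empirical p-values use the add-one rule `(1 + #{null >= s})/(1 + n)`,
avoiding zero p-values from finite nulls. The family sizes are
configurable because whether any rows were excluded from the published
correction is not stated beyond the printed cutoffs.

## Variant-to-structure mapping

A 51-residue window centered on the variant is matched **verbatim**
(100% identity, no gaps) against ATOM-record sequences of structures
passing the quality filters (X-ray-style resolution < 2.5 Å, chain
length > 50). Windows are clamped, not padded, at the termini — padding
has no exact-match semantics. Among multiple hits the best (lowest)
resolution wins; resolution ties break lexicographically by structure id
for reproducibility. Unmapped variants are flagged with a reason, never
dropped silently. Residue identity uses author numbering with insertion
codes concatenated into the index key.

## What the synthetic generators do and do not emulate

The generators exist so that every pipeline stage can be exercised with
known ground truth:

* `synth_structure()` plants verifiable geometry — a self-avoiding
  C-alpha walk with backbone and pseudo side-chain atoms, optionally a
  Zn ion with k coordinating S atoms at 2.0-2.9 Å while all other N/O/S
  atoms stay beyond 3.5 Å. Only interatomic distances matter to every
  downstream rule, so no attempt is made at physically valid
  conformations, rotamers or secondary structure.
* `synth_pu_scores()` draws calibrated-posterior-like scores from Beta
  components (background Beta(1, 9), positive Beta(9, 1)) — bounded to
  [0, 1] and well-separated, with the class prior as the mixture weight.
* `synth_motif_graphs()` plants a rooted labeled graphlet as an induced
  subgraph at the roots of positives (default: a Cys-rooted Cys-His-His
  triangle) and verifies its absence in negatives.
* `synth_cohorts()` raises disease tail mass so the expected exceedance
  at the neutral 1% threshold matches a requested effect.

Every generator is a pure function of its parameters and seed. Passing
tests on these fixtures demonstrates that the machinery — counting,
kernels, calibration, conversion, thresholds, tests — is correct; it
does **not** demonstrate accuracy on real proteins, where environments
are correlated within folds, positives are biased toward
well-crystallized families, conservation is estimated rather than
given, and the unlabeled pool is contaminated at an unknown rate.

## Numerical choices

* Probability products with a factor above 0.999 are evaluated in
  log1p space to avoid cancellation (`a * (1 - b)` as
  `exp(log a + log1p(-b))`).
* Kernel normalization defines 0/0 as 0 (all-zero profiles).
* PSD is enforced on input kernels with tolerance `-1e-8` relative to
  the spectral radius; violations suggest diagonal jitter rather than
  silently repairing.
* Alternate-location conformers resolve to the highest summed occupancy,
  ties to the first altLoc identifier alphabetically.
* Canonicalization minimizes the (label vector, edge bitmask) pair
  lexicographically; pair positions are nested — (1,2), (1,3), (2,3),
  (1,4), ... — so an n-graphlet's edge bits are a prefix of an
  (n+1)-graphlet's, which lets vertex insertion keep existing bits in
  place.
* Degenerate inputs error early and specifically: empty nulls, empty
  function sets, single-class calibration inputs, non-PSD kernels,
  residues missing C-alpha under the c_alpha rule, restriction-emptied
  unlabeled pools.

## Problem sizes in the test and acceptance suites

The suites are sized for exactness where exactness is claimed and for
stable statistics elsewhere: graphlet-count equivalence is exhaustive on
random graphs up to 12 vertices (N up to 5); Fisher agreement is
exhaustive over all 2x2 tables with total at most 20; prior recovery
uses 5 000 + 5 000 scores per prior; the planted-motif benchmark trains
on 320 environments of 10 vertices and evaluates on 80 held out; the
mechanism calculus properties are checked on 1 000 random draws. The
full suite completes in well under a minute on one core.

## Limitations

* The prior-conversion formula is exact only under exchangeability of
  labeled and unlabeled positives; violations (annotation bias toward
  certain folds or residue types) propagate directly into posterior
  scale.
* Specificity against unlabeled-as-negative overstates true
  specificity by the latent-positive rate.
* The two-stratum stability model ignores the magnitude of ddG beyond
  the 0.5 kcal/mol dichotomy.
* The mutant environment is the wild-type graph with one label changed:
  real substitutions can remodel side-chain packing and hence the
  contact topology itself.
* Exact-match mapping discards variants whose 51-mer window differs
  from every crystallized sequence — conservative, and biased toward
  well-characterized proteins.
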
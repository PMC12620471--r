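---
title: "Configurational satisfaction analysis: Fuzzy Delphi screening and rough-set rule mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configurational satisfaction analysis: Fuzzy Delphi screening and rough-set rule mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughdelphi)
```

## The problem

Satisfaction with assistive health technology — here, home treatment
devices used by older adults in a sub-health state — rarely traces back to
one dominant factor. Different users reach the same satisfaction level
through different *configurations* of conditions, and the conditions that
produce satisfaction are not simply the mirror image of those that produce
dissatisfaction (equifinality and causal asymmetry). This package
implements a two-stage pipeline for that setting: a Fuzzy Delphi screen
that distills a broad candidate list of evaluation criteria into the key
antecedent conditions, and a rough-set analysis that mines an ordinal
satisfaction survey for certain decision rules describing those
configurations. Both stages work on small samples of ordinal data and make
no distributional assumptions.

## Stage 1: Fuzzy Delphi screening

Each expert rates each candidate criterion with an interval on a 1–10
scale: a conservative score $C^i$ and an optimistic score $O^i$. Per
criterion and per series the pipeline:

1. **Trims outliers** beyond two sample standard deviations
   ($n-1$ denominator), in a single pass. A single pass (survivors are not
   re-tested) avoids cascade removal on panels of 15–20 experts, where a
   second pass on the post-trim statistics can eat into legitimate
   variation. With zero variance nothing is removed.
2. **Builds a triangular fuzzy number** (minimum, geometric mean, maximum).
   The geometric mean is the classical choice for aggregating multiplicative
   judgment scales and is the default; published consensus tables are
   sometimes computed with arithmetic means instead, so
   `build_tfn(central = "arithmetic")` is available. By AM–GM the mode
   never exceeds the arithmetic mean.
3. **Tests convergence** of the conservative TFN $(C_L, C_M, C_U)$ against
   the optimistic TFN $(O_L, O_M, O_U)$ via the gray zone
   $Z = C_U - O_L$ and the mode gap $M = O_M - C_M$:
   * $C_U < O_L$: the intervals do not overlap; opinions converge
     trivially and $G = (C_M + O_M)/2$.
   * $C_U \ge O_L$ and $Z \le M$: acceptable overlap;
     $$G = \frac{C_U\,O_M - O_L\,C_M}{(C_U - C_M) + (O_M - O_L)},$$
     the abscissa of the crossing point of the two triangular membership
     functions. When $C_U = O_L = k$ this reduces algebraically to $k$,
     which pins down the branch choice at the boundary: the crossing-point
     formula, not the mode midpoint, applies when the intervals touch
     (the two differ unless $C_M + O_M = 2k$).
   * $Z > M$: divergent. The criterion is flagged for a second survey
     round, never silently dropped. (The package flags; it does not
     simulate iterative re-survey rounds.)
4. **Screens** against a retention threshold, default 7 of 10, with a
   $\ge$ comparison and a $10^{-9}$ machine tolerance so consensus values
   that equal the threshold algebraically are retained regardless of
   floating-point representation.

The formula in step 3 has one degenerate input — $C_U = C_M$ and
$O_M = O_L$ simultaneously, where both triangles have a vertical edge in
the gray zone — which raises an explicit error rather than returning
0/0.

The package bundles a published reference table of twelve candidate
criteria with printed $(C_U, O_L, C_M, O_M)$ (`fdm_reference()`).
Recomputing $G$ row-wise reproduces every printed 4-decimal consensus
value within $10^{-3}$ (printed values are truncations of repeating
decimals) and the published 9-of-12 retention verdict; this is the
package's validation of its consensus arithmetic, and the acceptance
script recomputes it from scratch.

## Stage 2: rough-set analysis

A survey is a decision table $S = (U, C \cup \{D\}, V, f)$: respondents
$U$, nine ordinal condition attributes $C$ on $\{1..5\}$, one decision
attribute $D$ on $\{1,2,3\}$ (dissatisfied / neutral / satisfied).
Values are compared by equality only — classical indiscernibility.
Dominance-based variants that exploit the ordering of Likert codes are
deliberately out of scope, and tables with missing cells are rejected at
load rather than imputed.

From the indiscernibility partition the package computes lower and upper
approximations of each decision class, per-class accuracy
$|\underline{B}X| / |\overline{B}X|$, and the quality of classification
$\gamma_B(D)$. The empty target set is defined as vacuously exact
(accuracy 1); it never arises for observed decision classes.
$\gamma_C(D) = 1$ means the table is consistent: every condition profile
determines its decision.

**Reducts and core.** All minimal attribute subsets preserving
$\gamma_C(D)$ are found by exhaustive subset-lattice search in increasing
size with superset pruning, exact up to 20 condition attributes (the
study schema needs $2^9 = 512$ evaluations). Wider tables are refused
unless the clearly-labelled greedy backward-elimination heuristic is
requested. The core is the intersection of all reducts and may be empty.
An equivalent characterisation — $a$ is in the core iff dropping $a$
from $C$ lowers $\gamma$ — is used as a cross-check in the tests.

**Rule induction.** Certain rules are induced per decision class from its
lower approximation by LEM2-style minimal covering: literals are chosen
greedily by most uncovered goal objects matched, ties by fewer matches
overall, then attribute order, then value order; finished conjunctions are
pruned to condition-minimality and redundant rules removed. The covering
emits only enough rules to cover each lower approximation — by design it
does *not* enumerate every regularity in the data. For that there is
`induce_rules(method = "all")`, an Apriori-style enumeration of every
condition-minimal certain rule up to `max_length` literals (default 3,
matching the longest conjunction the analysis reports). The exhaustive
mode is the right surface for parameter-recovery checks against planted
rules; covering is the right surface for compact reporting and
classification.

**Support, coverage, filtering.** For a rule $\Phi \to \psi$, support is
$|\,\Phi \wedge \psi\,|$, coverage divides support by the *full-table
size of the decision class* $\mathrm{card}(\|\psi\|)$, and certainty
divides by the premise matches (1 for certain rules). The class-size
denominator is what makes printed rule coverages exact integer ratios
(e.g. 49/108 = 45.37 %). Configurational reporting keeps rules with
coverage $\ge$ 10 % in the two outer classes — the filter is applied
*after* induction, with the boundary kept.

**Classification and cross-validation.** There is no single canonical
strategy for classifying with a certain-rule set, so the package uses a
simple deterministic one, documented as plumbing: exactly-matching rules
vote with weight equal to support; with no exact match the best partial
match decides (largest fraction of satisfied literals, ties by support,
then rule order). Cross-validation stratifies folds by decision class with
a seeded shuffle; folds whose training portion would lose a class entirely
are merged with a warning. Reported accuracy is the mean over folds of the
held-out fraction correct, by default validating the full induced set
(validating the filtered set is a flag).

## The synthetic-data generator

No raw survey accompanies the published analysis, so the generator is a
first-class module, not a fixture dump. It emulates:

* **Expert panels** (`generate_panel()`): per expert × criterion,
  conservative/optimistic scores drawn around
  `importance ∓ interval_width/2` (normal, `score_sd`, rounded and clamped
  to 1–10, ordered). Defaults — 18 experts, interval width 2, score SD 1 —
  are typical of validated Delphi panels. Aberrant responses (probability
  `outlier_rate`) land near the end of the scale *opposite* the
  criterion's importance; on a 1–10 scale with high-importance criteria
  this is the only direction in which a response can sit beyond two
  standard deviations of both series, so injected aberrations are
  reliably trimmed and the trim rate tracks `outlier_rate` (verified
  ±3 percentage points over 200 panels).
* **Survey tables** (`generate_survey()`): exact decision-class sizes
  (14/41/108 in the bundled fixture, matching the published class
  structure); planted conjunction rules, each satisfied by *exactly* its
  designed count of class members and — with `exclusive = TRUE` — by no
  object outside the class, making the planted rule certain with coverage
  `count/class size` by construction. Planted counts of one class may sum
  beyond the class size: rules with compatible literals (no attribute
  demanded at two values) legitimately share objects, exactly as the
  published coverages require (counts 5,5,2,2,2 over a class of 14).
  Assignment is greedy — fresh objects first, then compatible
  already-assigned ones — and infeasible specs (incompatible overlaps,
  duplicate exclusive patterns, counts over class size) raise errors
  listing the conflict. Free cells are drawn from class-conditional
  categorical distributions (dissatisfied skewed low, satisfied high,
  neutral centered — the asymmetry configurational studies describe),
  optionally noise-perturbed; a deterministic repair pass then removes
  accidental full-pattern matches and cross-class duplicate profiles, so
  planted counts stay exact and the table stays consistent.
* **Blockers**: for each multi-literal planted rule, one object in another
  class receives each "all literals but one" sub-pattern. Every proper
  sub-conjunction of a planted rule is thereby uncertain, so induction
  cannot shorten the planted conjunction away — which is what makes
  parameter recovery a sharp test: with noise 0 and exclusive planting,
  exhaustive induction recovers every planted conjunction with exactly its
  designed support (verified across 20 seeds in the acceptance suite).
* `generate_consistent_survey()` draws profiles from the mixture of the
  three class-conditional distributions and then assigns the decision as a
  deterministic threshold function of the mean Likert score, giving a
  consistent table ($\gamma = 1$, all accuracies 1) by construction.

All generation is seeded and byte-reproducible: same seed, same file.

### What the generator does not emulate

The generator produces *consistent* tables whose outer classes are densely
covered by exclusive certain patterns. Real survey data keeps certainty 1
on the full table but generalizes worse across folds: held-out respondents
match training rules of the wrong class in ways the generator's repaired,
exclusively-planted tables cannot. Cross-validated accuracy on the bundled
fixture is therefore high (frozen regression value 0.889 at seed 11,
sanity band 0.80–0.95) — noticeably above the low-70 % regime reported for
real surveys of this shape, and flattening the class-conditional
distributions or adding cell noise does not close the gap (measured
0.86–0.94 across those variations). Passing the fixture's tests shows the
*algebra and the pipeline* are right; it does not certify classifier
accuracy on real data. Likewise the core of a generated fixture is
whatever the seed yields (often empty) — the generator does not attempt to
reproduce any particular core attribute, and respondent demographics are
not simulated because no operation consumes them.

## Numerical choices and tie-breaks

* Consensus reproduction tolerance $10^{-3}$ (printed 4-decimal
  truncations); threshold comparison tolerance $10^{-9}$.
* Object and attribute order are preserved from input everywhere; all set
  outputs are reported in input order; blocks by first occurrence.
* LEM2 ties: fewer total matches, then attribute order, then value order.
  Classification ties: summed support, then rule order. Everything
  deterministic under a fixed seed.
* Reports print percentages to 2 decimals and consensus values to 4,
  matching the conventions of published consensus and rule tables.
* Problem sizes in the test and acceptance suites — 200 random tables up
  to 50 objects × 6 attributes for the brute-force oracle comparisons,
  20 seeds for parameter recovery, 10-fold CV on the 163-object fixture —
  were chosen so the full suite documents each property at meaningful
  scale while running in well under a minute.

## Known limitations

* Classical indiscernibility only: no dominance relations,
  variable-precision rough sets, fuzzy-rough hybrids, or discretization.
* Certain rules only: possible/approximate rules from upper
  approximations are not induced.
* The Delphi stage evaluates one round; divergent criteria are flagged,
  not re-surveyed.
* Exhaustive reduct search is exponential and intentionally capped; the
  greedy fallback returns one reduct without minimality guarantees across
  all reducts.
* The rule classifier is a reasonable deterministic default, not a claim
  about how any particular legacy software classified.
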
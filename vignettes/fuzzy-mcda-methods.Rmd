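---
title: "Methods: fuzzy AHP and fuzzy TOPSIS for group decision analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy AHP and fuzzy TOPSIS for group decision analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzymcda)
```

# The decision problem

`fuzzymcda` supports group multi-criteria decision analysis when judgments
arrive as words rather than numbers. The package was built around a concrete
clinical instance — three pediatric surgeons choosing among anesthesia
methods for circumcision surgery (general anesthesia without penile block,
with penile block, or local anesthesia) — but every stage is generic over a
two-level criteria hierarchy: a goal, main criteria, sub-criteria nested
under them, and a set of alternatives.

Two complementary ranking engines are provided:

* **Buckley's fuzzy AHP** derives criterion weights (and, applied to
  alternative-comparison matrices, local alternative weights) from
  reciprocal pairwise-comparison matrices of linguistic judgments.
* **Fuzzy TOPSIS** ranks alternatives by closeness to an ideal solution,
  starting from linguistic performance ratings and using the AHP weights to
  scale criteria.

A sensitivity stage re-aggregates per-expert results under different
expert-weighting scenarios to check whether the recommendation is robust.

# Triangular fuzzy numbers and linguistic scales

All linguistic terms map to triangular fuzzy numbers (TFNs)
$(\ell, m, u)$ with $\ell \le m \le u$. Two fixed scales are built in:

| importance term | TFN | rating term | TFN |
|---|---|---|---|
| Equal (E) | (1,1,1) | Poor (P) | (0,2.5,5) |
| Slightly Important (SI) | (1,1,3) | Fair (F) | (2.5,5,7.5) |
| Fairly Important (FI) | (1,3,5) | Good (G) | (5,7.5,10) |
| Highly Important (HI) | (3,5,7) | Very Good (VG) | (7,10,10) |
| Very Important (VI) | (5,7,9) | | |
| Extremely Important (EI) | (7,9,9) | | |

Reciprocal judgments are written `"1/X"` and decode to
$(1/u, 1/m, 1/\ell)$. Multiplication, reciprocals and roots use the
standard component-wise approximation. This is exact only for degenerate
(crisp) triples, but it is the convention under which the packaged study's
worked values were produced, and it makes the crisp case a strict special
case: triples $(x,x,x)$ reproduce ordinary arithmetic exactly, which the
test suite exploits for exact-recovery checks.

# Buckley weight extraction

For an $n \times n$ judgment matrix $\tilde C = [\tilde c_{ij}]$ per expert
(aggregated across $K$ experts by the entry-wise arithmetic mean when
individual matrices are available), each item's fuzzy geometric mean and
fuzzy weight are

$$\tilde r_i = \big(\tilde c_{i1} \otimes \cdots \otimes \tilde c_{in}\big)^{1/n},
\qquad
\tilde w_i = \tilde r_i \otimes \big(\tilde r_1 + \cdots + \tilde r_n\big)^{-1},$$

with the fuzzy reciprocal applied to the component-wise sum. The geometric
mean is used because it extends cleanly to fuzzy entries and yields a unique
solution for reciprocal matrices.

## Defuzzification: two rules, used in two places

Crisp weights are obtained by **component-sum normalization**:
$w_i = (\ell_i + m_i + u_i) / \sum_j (\ell_j + m_j + u_j)$, which sums to 1
by construction. This is the rule the study's worked duration example uses
(judgment VI between the two duration sub-criteria gives 0.87/0.13, printed
as 0.88/0.12 from rounded intermediates).

For **local alternative weights** (one alternatives-comparison matrix per
sub-criterion) the package instead defaults to the unnormalized **centroid**
$(\ell_i + m_i + u_i)/3$ of each fuzzy weight. This was a genuine design
fork: the study's published per-alternative table is reproducible only under
the centroid reading — its columns do not sum to 1 (e.g. the
duration-of-operation column 0.08/0.57/0.45) — while its criterion-level
weights are sum-normalized. Both rules are exposed via the `defuzz`
argument; the defaults mirror the published tables. A consequence worth
knowing: global AHP scores synthesized from centroid locals need not sum
to 1 across alternatives.

Global scores multiply down the hierarchy:
$\mathrm{score}(A) = \sum_s w_{\text{main}(parent(s))} \, w_s \,
\mathrm{local}(A, s)$.

# Consistency checking

Fuzzy judgment matrices are checked with Saaty's principal-eigenvalue test
after per-entry defuzzification: $CI = (\lambda_{\max} - n)/(n - 1)$,
$CR = CI / RI(n)$ with the standard random-index table, and the conventional
$CR \le 0.1$ acceptability gate. The defuzzification rule is configurable
(`centroid` default, `modal`, `geometric`) because no single rule is
canonical for fuzzy matrices.

An honest caveat: the packaged study's own judgment matrices *fail* this
gate. The consensus main-criteria matrix has $CR = 0.201$ under the centroid
rule (0.135 modal, 0.105 geometric-mean), and several 3x3
alternative-comparison matrices are far worse (up to 1.19). The study
reports much smaller CR values without stating how they were computed; no
standard defuzzification-plus-eigenvalue procedure reproduces them. The
pipeline therefore treats $CR > 0.1$ as a warning, not an error, and the
test suite documents the discrepancy with a deliberately failing assertion
rather than a loosened threshold. For 2x2 matrices $CR = 0$ identically, so
only the main-criteria and alternatives matrices carry information.

# Fuzzy TOPSIS conventions

The TOPSIS stage follows the study's applied conventions by default, each
switchable:

* **Normalization** divides every rating component by the rating scale's
  maximum upper value (10), keeping entries in $[0,1]$
  (`divisor_rule = "scale-max"`). The per-criterion extremal rule (fuzzy
  division by the criterion's best entry, with a cost-attribute branch) is
  available as `"extremal"`; the packaged study treats all eight
  sub-criteria as benefit attributes, since ratings are desirability
  judgments.
* **Weighting** multiplies each normalized entry by the crisp product
  $w_{\text{main}} \times w_{\text{sub}}$ of AHP weights — per expert when
  the expert supplied pairwise matrices, otherwise the consensus weights.
  General trapezoidal weighting reduces here to this crisp-triangular case;
  trapezoidal fuzzy numbers are not modeled as a first-class type (a
  documented limitation, not a loss for this family of studies).
* **Ideals** default to the fixed points $(1,1,1)$ and $(0,0,0)$ — the
  extremes of the normalized weighted space — because the study's worked
  separation distances measure against 1 and 0, not against the
  per-criterion extremal rows of the textbook definition. `"extremal"` mode
  implements the latter.
* **Distance** defaults to the `"study"` form
  $d(\tilde a, \tilde b) = \tfrac13 \sqrt{\sum_{c} (a_c - b_c)^2}$,
  which the study's worked values force (0.565 to the positive ideal for
  the weighted value (0.011, 0.022, 0.033)). The standard vertex form
  $\sqrt{\tfrac13 \sum (a_c - b_c)^2}$ is available and differs exactly by
  the factor $\sqrt 3$, so rankings are identical under either; only the
  absolute separations change.

Separations sum per-criterion distances, and the closeness coefficient
$CC_i = S_i^- / (S_i^* + S_i^-)$ ranks alternatives in $[0,1]$. Under fixed
ideals, raising any benefit rating of an alternative can only increase its
closeness (a property the tests verify), and an alternative rated best
everywhere is guaranteed the top rank.

# Sensitivity analysis

Experts' final scores — global AHP scores and TOPSIS closeness coefficients
— are combined as scenario-weighted means. Aggregation happens at the
final-score level deliberately: when each expert carries their own criterion
weights, scores are the only level at which experts are commensurable.
Scenario weights given as percentages are normalized to sum exactly to 1.
In the packaged study only one expert's individual pairwise matrices are
recorded; the other two experts inherit the consensus weights, which is why
their AHP scores coincide with the consensus scores while their TOPSIS
scores still differ through their own ratings. One expert's ratings favor a
different alternative, yet all four published weighting scenarios leave the
group recommendation unchanged — the robustness claim the stage exists to
check.

# The synthetic-data generator

`generate_panel()` builds panels with known ground truth so that every
stage can be validated without the study data. It emulates exactly the
structure the analysis assumes:

* shared ground-truth weight vectors per pairwise group, drawn from a flat
  Dirichlet (normalized Gamma(3) draws) unless supplied;
* per-expert judgment matrices $a_{ij} = w_i / w_j$, optionally snapped to
  the nearest linguistic term and perturbed by uniform step noise of at
  most `noise_steps` positions along the ordered term ladder
  $1/EI < \cdots < 1/SI < E < SI < \cdots < EI$, with the lower triangle
  reset to reciprocals so matrices stay valid;
* linguistic ratings drawn uniformly from the rating scale, or, under a
  `dominance` setting, one alternative rated maximal everywhere with all
  others strictly lower.

The generator's default shape (4 main criteria, 2 sub-criteria each, 3
alternatives, 3 experts) matches the packaged study. With `noise_steps = 0`
and no snapping the matrices are exactly consistent, so the full AHP
pipeline must recover the ground truth to $10^{-9}$ at every hierarchy
level and every consistency ratio must be 0 — the package's strongest
correctness checks. With snapping, recovery is only as good as the scale's
quantization, which is the realistic regime: a six-term scale cannot encode
a ratio of, say, 2.

What the generator does **not** emulate: correlation between experts,
systematic response styles (e.g. centrality bias), missing judgments, or
cost-direction rating scales. Passing tests on synthetic panels therefore
demonstrate algorithmic correctness, not robustness to those features of
real panels.

# Numerical choices and degenerate inputs

* Published values are printed truncated to 2–3 decimals; fixture
  comparisons use an absolute tolerance of 0.01 per component (5e-4 for
  3-decimal worked values) rather than re-truncating package output.
* Equality of weights is asserted to machine-level tolerances (1e-9 to
  1e-12) wherever the arithmetic is exact.
* `rank_alternatives()` breaks ties by input order and flags them; tied
  entries share the better rank.
* Snapping tie-breaks: several importance terms share modal value 1, so a
  ratio equidistant between terms resolves toward the identity term E.
* Reciprocals and geometric means require strictly positive components;
  zero lower bounds (the P rating) are fine everywhere else because the
  rating path never inverts entries. Cost-attribute normalization rejects
  entries with non-positive components since it divides by them.
* Eigenvalues of defuzzified reciprocal matrices are real-positive in
  theory; the implementation takes the largest real part and clamps tiny
  negative $CI$ round-off to zero.

# Problem sizes in the test suite

The suite runs entirely on desk-scale problems: 2x2 to 4x4 judgment
matrices, 3 alternatives by 8 sub-criteria rating grids, panels of 2–3
experts, property loops of 15–100 random cases under fixed seeds, and a
100-seed perturbation study for the consistency monotonicity check. A full
run takes a few seconds.

# Known limitations

* Hierarchies are exactly two criterion levels deep; deeper trees would
  need recursive synthesis.
* Incomplete pairwise matrices are rejected, not imputed.
* Trapezoidal fuzzy numbers and alternative fuzzy-AHP schemes (extent
  analysis, $\lambda$-max) are out of scope.
* The consistency ratio of a *fuzzy* matrix is inherently
  convention-dependent; results should quote the defuzzification rule,
  which the `consistency_report` object carries.
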
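---
title: "Methods: Boolean-matrix deduction and cost-aware annotation learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean-matrix deduction and cost-aware annotation learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmlp)
```

This vignette is the package's own account of its models, conventions
and design choices: what is computed, under which assumptions, which
knobs matter, and what a green test does and does not establish.

## 1. The deduction model

A metabolic network here is purely qualitative: directed reactions with
reactant and product *sets* (stoichiometric coefficients reduced to
presence/absence), gated by gene–protein–reaction (GPR) rules. The
availability semantics is that of a one-token-per-place net: a
metabolite is either available or not, and a reaction fires when every
reactant is available and its rule is active. Quantities, fluxes and
thermodynamics are deliberately out of scope — the package predicts
*reachability* phenotypes, not growth rates.

`bmlp_ie()` computes the producible-set fixpoint with three Boolean
kernels only (elementwise OR, AND–OR matrix product, equality). The one
non-obvious construction: "all reactants available" under these kernels
is `NOT(R1 · NOT v)` — a single multiplication against the complement
vector flags any reaction with at least one missing reactant. Zero-
reactant reactions (exchange/source reactions) have an all-zero `R1`
row, are never blocked, and fire whenever their mask bit is on: the
empty conjunction is true.

Numerical/termination choices:

* Convergence is exact equality of successive bit-vectors; each
  non-final iteration adds at least one metabolite, so a hard cap of
  n+1 iterations is enforced and its violation raised as an internal
  error rather than silently looped.
* Matrices are dense base-R 0/1 integer matrices. The networks in scope
  (tens to a few thousand reactions) make sparse storage or bit-packing
  unnecessary; the contract is value-level, so a sparse backend could be
  swapped in without observable change.
* Reversible reactions in imported GEM JSON are split into `_fwd`/`_rev`
  directed reactions sharing the rule. Token semantics is directional
  and the import would otherwise have to guess a direction; splitting is
  conservative (reachability can only grow).
* Masked rules (`?`) evaluate to *false*: a reaction whose catalyst is
  unknown and receives no hypothesised gene has no enzyme. This makes
  the empty hypothesis maximally falsifiable — it predicts no phenotypic
  effect for any experiment, and the first positive label prunes it.

`forward_chain_oracle()` is a deliberately naive symbolic saturation
with the same semantics. It exists so the matrix engine is never the
only witness of its own correctness; the test suite checks exact
agreement on hundreds of random networks, and the two implementations
share no code path.

## 2. Hypothesis scoring

A hypothesis is a set of ground facts `function(gene, reaction)`;
`size(h)` counts facts. Scoring follows the minimum-description-length
compression

\[ compression(h,E) = |E^+| - \frac{|E^+|}{pc_h}\,(size(h) + fp_h) \]

with the posterior \(p'(h\mid E) \propto 2^{compression(h,E)}\)
(computed as a base-2 softmax with max-shift; ordering by posterior and
by compression coincide by construction). Conventions the formula
itself does not fix:

* **pc counts positives over all candidate experiments**, labelled and
  unlabelled — generality is estimated on the whole instance pool. The
  labelled-only alternative would make `pc = 0` ubiquitous in early
  iterations and the score degenerate.
* **pc = 0 with positives present** yields a \(-\infty\) sentinel
  (posterior mass exactly 0), not a finite penalty: such a hypothesis
  explains no positive and the formula is undefined there.
* **No positives seen yet**: every hypothesis scores 0. Selection then
  falls back to the tie rules (smaller size first), so with no evidence
  the empty hypothesis is preferred — a built-in Occam default.
* **Entropy of a subset is not renormalised.** The selection heuristic
  uses \(J_H = -\sum p' \log_2 p'\) over the consistent / inconsistent
  subsets with the *global* posteriors, following the literal form of
  the heuristic. Renormalising within the subset is a defensible
  alternative; it was rejected to keep \(J_{H_t} + J_{\overline{H_t}}\)
  equal to the full-space entropy, which makes the uniform-cost
  reduction (Section 3) exact.
* The description-length prior \(p(h)=2^{-size(h)}\) is exported for
  completeness but does not participate in selection: the operational
  pipeline ranks by compression only, which already embeds the size
  penalty.

## 3. Experiment selection

The expected-cost heuristic for a candidate experiment \(t\) is

\[ EC(t) = C_t + p(t)\,\bar m\,J_{H_t} + (1-p(t))\,\bar m\,J_{\overline{H_t}} \]

with \(\bar m\) the mean cost of the other remaining unlabelled
experiments (0 when \(t\) is the last), and \(p(t)\) the posterior mass
of hypotheses predicting a positive outcome. Exact EC ties (within
1e-12) are broken by a shuffle drawn once per run from the run seed, so
runs are reproducible and the tie rule is not an accident of input
order. With uniform costs the rule provably reduces to minimising
\(p\,J_{H_t} + (1-p)\,J_{\overline{H_t}}\), i.e. pure expected residual
entropy; the acceptance suite verifies the reduction against an
independent reimplementation on random states.

The exact expected-cost recurrence (a min over full decision trees) is
implemented only as a test oracle on instances with \(|T|, |H| \le 4\);
the heuristic's agreement rate with it is reported by the test run
(about 0.7–0.8 on random instances) but not asserted tightly — the
heuristic is an approximation by design, and making it the production
selector is exactly the point.

Budget semantics are cumulative: an experiment is affordable iff its
cost fits in the unspent budget. An optional `fixed_init` flag replaces
the first selection by the cheapest discriminative affordable
experiment. The loop stops at a singleton version space, at budget
exhaustion, or when everything is labelled; the returned hypothesis is
the alive compression maximiser with ties broken by smaller size, then
input order.

Held-out accuracy, recorded per step for the diagnostics, is measured
against oracle labels on the *full* candidate grid, including already-
labelled experiments: the grid is a fixed synthetic test set, and
excluding labelled items would make the metric's denominator drift
across steps.

## 4. The synthetic world

`generate_gem()` states the world the benchmarks run in; its defaults
are fixed once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| internal layers × metabolites | 3 × 6 | deep enough for multi-step pathways, small enough for second-scale fixpoints |
| reactions | 40 (+ nutrient uptakes) | ~1.5 reactions per metabolite, the density regime of curated GEM subsystems |
| genes | 15 | yields a 121-hypothesis digenic space and a 484-experiment grid (≤2 deletions × ≤1 nutrient), the scale of the published digenic recovery task |
| isoenzyme fraction | 0.3 | OR rules common but not dominant, as in curated GPRs |
| nutrients | 3, log-uniform cost in [1, 100] | reagent prices span orders of magnitude; normalised so the cheapest costs 1, one gram per reagent assumed |
| essential metabolites | 3 | several independent lethality routes, so not every positive label implicates the target |

Construction guarantees rather than samples the important properties:
every internal metabolite has a spanning producer fed from strictly
earlier layers (wild-type viability on the base medium is validated
with `bmlp_ie()` at construction and is an error otherwise); the target
pathway is private (its intermediate and end point have no other
producers, and the target genes appear in no other rule), so in digenic
mode single deletions of either isoenzyme gene are silent while the
double deletion is lethal; the first two nutrients rescue the target
intermediate and end point, making auxotrophy-rescue experiments and
the cost/information trade-off real. Distractor reactions may form
cycles — harmless, since reachability is monotone.

What the generator does *not* emulate: compartments, reaction
reversibility within the synthetic networks, stoichiometric yield,
regulation, and measurement noise (oracle labels are exact). A green
benchmark therefore establishes that the learner recovers planted
annotations efficiently under correct deduction — not that it tolerates
noisy phenotyping.

## 5. The sample-complexity diagnostic, and a known red assertion

`sample_complexity_ratios()` compares \(\epsilon/s_{active}(\epsilon)\)
with \((\epsilon+\phi)/s_{passive}(\epsilon)\), where \(s(\epsilon)\) is
the first step at which a trace's held-out error reaches \(\epsilon\)
and \(\phi\) is the smallest minimal reduction ratio among the active
learner's selections (taken empirically from the trace; published
values of \(\phi\) are run-specific). Benchmark curves aggregate
step-wise mean accuracy across runs, carrying each run's final accuracy
forward.

The acceptance suite asserts the inequality
\(ratio_{active} \ge ratio_{passive}\) for *all* \(\epsilon > 0\), and
that assertion is deliberately left failing. Whenever \(\phi > 0\) —
and here \(\phi\) is always positive, because the best possible split
of the 121-hypothesis digenic space by one experiment is 3/121 — the
pointwise inequality is structurally impossible at both extremes: as
\(\epsilon \to 0^+\) the passive ratio tends to
\(\phi/s_{passive}(0) > 0\) while the active ratio vanishes linearly
(the regime where the underlying bound's additive constant dominates),
and at coarse error levels reached by both strategies at the same step
\(s\), \((\epsilon+\phi)/s > \epsilon/s\) identically. In the mid-range
(here \(0.004 \lesssim \epsilon \lesssim 0.067\)) the inequality holds
at every grid point, which is the substantive content of the
diagnostic. The headline comparisons — median experiments-to-recovery
and median reagent cost, active vs random — are asserted and pass
(41 vs 152 experiments; 0 vs ~378 cost units on the 20-gem × 10-repeat
benchmark).

## 6. Degenerate inputs and edge conventions

* Empty medium, empty hypothesis, empty deletion sets: all legal;
  `bmlp_ie` on an all-zero mask returns the medium unchanged.
* Reactant and product sets of one reaction may overlap; the fixpoint
  is monotone so this cannot oscillate.
* A version space emptied by inconsistent labels (possible only when
  the true hypothesis is outside H) aborts the run with a warning and a
  partial trace.
* Budget 0 with positive costs yields a zero-step trace; the returned
  hypothesis is then the smallest (the empty one, when present).
* All file outputs are written atomically (write-then-rename);
  interrupted runs never leave truncated CSV/JSON.

## 7. Known limitations

* Deduction is Boolean: no flux, no growth-rate regression, no partial
  phenotypes.
* The learner only selects from user-supplied finite hypothesis and
  experiment grids; it does not invent hypotheses.
* The expected-cost selector is the one-step heuristic, not the exact
  decision-tree recurrence (exponential; implemented only as a test
  oracle).
* CLI parameter files are JSON rather than YAML: no YAML parser is
  available in the supported dependency set, and the schema is
  unchanged.
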
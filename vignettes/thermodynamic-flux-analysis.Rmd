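---
title: "Thermodynamics-constrained flux analysis: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics-constrained flux analysis: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoflux)
```

## The model

Flux balance analysis maximizes a cellular objective `c'v` over the
polytope `S v = 0`, `lb <= v <= ub`. Its blind spot is directionality:
stoichiometry admits flux around internal cycles and through reactions in
directions that no concentration state could drive. The second law closes
the gap. A reaction proceeds in a direction only if its transformed Gibbs
energy change in that direction is negative,

$$\Delta_r G'_j \;=\; \Delta_r G'^0_j \;+\; RT \sum_i n_{ij} \ln x_i,$$

with standard transformed reaction energies $\Delta_r G'^0$ assembled from
per-metabolite formation energies (group-contribution estimates carrying
standard errors) and activities $x_i$ confined to a physiological range.

The coupled program splits every reaction into non-negative forward and
reverse components and attaches a binary $Z$ to each directed component
with known thermodynamics:

1. $v_j \le Z_j\,v^{max}_j$ — flux is permitted only when the direction is
   declared active;
2. $\Delta_r G'_j + (K_j + \varepsilon) Z_j \le K_j$ — an active direction
   must be exergonic ($\le -\varepsilon$); the reverse component uses the
   negated energy;
3. $\Delta_r G'_j = \Delta_r G'^0_j + s_j + RT \sum_i n_{ij} \ln x_i$,
   with slack $s_j$ bounded by `n_se` standard errors of the estimate;
4. for each lumped reaction (below): $\Delta_r G'_{L}
   \le (K_L+\varepsilon)\,y_L - \varepsilon$ and
   $y_L + \sum_{j \in L} Z_j \le N_L$, so that when *all* members run
   simultaneously, $y_L$ is forced to 0 and the lump's energy must be
   negative.

Around any internal cycle the $\Delta_r G'^0$ telescope to zero and the
mixing terms cancel, so no activity assignment makes every step downhill:
futile cycles are excluded, feasible pathways untouched.

**Lumping.** When a metabolite's formation energy cannot be estimated,
every reaction touching it has unknown energy and cannot carry constraint
(1)–(3). Positive combinations of such reactions whose net stoichiometry
cancels all unknown metabolites *can* be constrained: the package searches
the nullspace of the unknown-metabolite submatrix restricted to
unknown-energy reactions, snaps the combination to the smallest integer
multipliers (members ordered lexicographically; a negative weight means
the member participates through its reverse direction), and derives the
lump's energy and error from its net stoichiometry. Unknown-energy
reactions no combination can cancel are reported and left unconstrained —
a conscious relaxation, recorded in every run log.

**TVA.** With growth fixed (an equality, by default at the plain-FBA
optimum), each constrained reaction's $\Delta_r G'$ expression is
minimized and maximized over the mixed-integer feasible set. By default
the uncertainty slack is pinned to zero here, so ranges reflect the
freedom in metabolite activities alone; `with_uncertainty = TRUE` restores
the slack and provably contains the default ranges.

**Classification.** With cutoffs `eps_eq` and `eps_far` (kcal/mol):
regulatory candidate if $dG_{max} < -\mathrm{eps_{far}}$; threshold of
regulation if $-\mathrm{eps_{far}} \le dG_{max} < -\mathrm{eps_{eq}}$;
bottleneck if the range reaches the band $[-\mathrm{eps_{eq}},
+\mathrm{eps_{eq}}]$ from below or spans it ($dG_{max} \ge
-\mathrm{eps_{eq}}$ and $dG_{min} \le +\mathrm{eps_{eq}}$); otherwise
unclassified. The partition is exhaustive and exclusive. Near-equilibrium
cutoffs for biochemical systems are conventions, not measurements, so both
are mandatory, echoed in every report, and the third analysis script
sweeps them; on the bundled core network the labels are stable under
±0.25 kcal/mol perturbations of both cutoffs.

**Expression validation.** Genes reach reactions through flattened GPR
rules; each gene contributes one range width (max − min of retained log2
fold changes), with measurements kept only when their coefficient of
variation is strictly below `cv_max`. Widths of the regulatory class are
compared against the bottleneck class with a two-sided Wilcoxon rank-sum
test (exact when the smaller sample has ≤ 8 values and no ties, normal
approximation with tie/continuity correction otherwise) and a Welch
unequal-variance t-test. Exactly these two global tests are run; there is
nothing to correct for multiplicity.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `R`, `T` | 1.9859e-3 kcal/(mol K), 298.15 K | fixes RT ≈ 0.5922 kcal/mol |
| `ln_activity_min/max` | ln(1e-5), ln(0.02) | activity range, mol/L |
| `n_se` | 2 | allowed deviation of each energy, in standard errors |
| `eps_thermo` | 1e-6 kcal/mol | closed-set margin for the strict inequality |
| `eps_eq`, `eps_far` | 2, 5 kcal/mol | classification cutoffs |
| `cv_max` | 0.2 | strict CV filter on expression measurements |

The 1e-5–0.02 M activity window and the two-standard-error energy band
are the standard choices of the mixed-integer formulation this package
implements; the transformed-energy convention excludes protons from both
the standard and mixing terms (fixed pH) and water from the mixing term
(activity 1). Per-reaction energy errors are combined in quadrature from
formation errors — treating group-contribution errors as independent is
an acknowledged approximation, and a reaction-level `se` in the input
table overrides it.

## Numerical choices

All programs are solved through the GLPK standalone solver behind a thin
build–solve–extract contract (CPLEX-LP files in, printable solutions out;
any MILP backend honouring the contract could be substituted). Big-M
constants are per-reaction — $|\Delta_r G'^0| + n_{se}\,se + RT \sum
|n_{ij}| \max(|\ln x|) + 1$ — rather than one global constant, keeping
relaxations tight. The strict inequality "active ⇒ exergonic" is closed
with `eps_thermo`; integrality and relative MIP gaps are 1e-6; GLPK's
branch-and-cut is deterministic, and TVA output order is always input
order. Reversible reactions are split rather than modelled with a
trichotomy variable: at most one direction can be active because the two
energy constraints are mutually exclusive, so no extra constraint is
needed. Degenerate inputs are handled explicitly: reactions with no known
energy and no lump are logged as unconstrained rather than silently
dropped or fatal; an exchange or objective-weighted (biomass) reaction
never carries a thermodynamic constraint; infeasible growth fixings
produce a classed error advising a feasibility pre-check.

## What the synthetic data emulates — and what it does not

The generators stand in for a genome-scale reconstruction, its
thermodynamic table, and a microarray compendium:

* **Network fixtures** assign formation energies first and derive every
  reaction energy from them, so thermodynamics are loop-consistent to
  machine precision by construction — the loop law is a property of the
  generator, and the tests confirm the pipeline preserves it. The
  `futile_cycle` kind plants a three-step internal cycle (zero formation
  standard errors there: with uncertainty slack, small cycle fluxes become
  legitimately feasible, which would blur the planted truth); the
  `unknown_metabolite` kind plants an intermediate whose cancellation
  multiplier varies with the seed; `mini_core` is a deterministic
  ~19-reaction acetate-fed network with a TCA-like loop whose
  near-equilibrium steps (MDH at +0.5, FUM at −0.3 kcal/mol) are designed
  bottlenecks, whose first-committed biosynthetic steps sit 7–11 kcal/mol
  clear of the regulatory cutoff, and whose DXPS-like step is placed so
  its feasible maximum (−3.0 kcal/mol) falls between the cutoffs. Class
  margins were chosen by hand analysis of the attainable mixing-term
  ranges (±RT·Σ|n|·Δln x) so that growth-fixing, which can only narrow
  ranges, cannot move a label.
* **Expression fixtures** draw per-gene, per-experiment log2 fold changes
  from zero-centred normals whose *scale* is the class dispersion
  (regulated 3, bottleneck 1 by default — the planted contrast is width,
  not direction), across 21 experiments by default, with a configurable
  fraction (default 0.25) of measurements failing the CV filter.

Passing tests on these fixtures show that the optimisation, lumping,
classification and statistics do what the formalism says on networks whose
ground truth is known exactly. They do not show that a real
reconstruction's energies are accurate, that real fold-change dispersions
are normal, or that real regulatory sites follow the thermodynamic
prediction — those are claims about data, not about this code.

## Verification strategy and problem sizes

The mixed-integer solver is cross-checked against an independently coded
oracle: exhaustive enumeration of all directionality patterns, each
reduced to an LP written in a different file format through a separate
code path. The test suite runs this comparison (optima and TVA ranges, to
1e-6 kcal/mol) on 25 seeded fixtures with up to ~8 constrained directions;
calibration of the rank-sum test uses 200 null replicates at 20 genes per
class (large enough that the near-continuous normal-approximation regime
measures calibration rather than the exact test's discreteness), and power
is estimated at the planted dispersion ratio of 3 with 10 genes per class
over 100 seeds. These sizes keep the full suite under a minute while the
enumeration stays exhaustive.

## Known limitations

* Energies are consumed, not estimated: no group decomposition, no
  ionic-strength or pH re-transformation.
* The per-reaction uncertainty slack treats energy errors as independent;
  correlated group errors would call for shared group-level variables.
* No loopless-FVA shortcuts: TVA is two MILP solves per reaction, fine at
  fixture scale, slow for genome-scale models without a stronger backend.
* Exchange coefficients are joined as opaque literature annotations; the
  package does not compute them from labeling data.
* Genome-scale reproduction (a 542×611 network grown on acetate/fumarate
  at fixed 0.055 1/hr) is supported as a user-supplied-data workflow: the
  model and thermodynamic tables are not redistributable here, so the
  bundled analyses run on the synthetic study networks instead.
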
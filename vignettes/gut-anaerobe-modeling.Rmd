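---
title: "Condition-aware metabolic modeling of gut anaerobes with gutGEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-aware metabolic modeling of gut anaerobes with gutGEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutGEM)
```

## The modeling problem

A genome-scale metabolic model (GEM) represents an organism's metabolism
as a stoichiometric matrix $S$ over reactions with flux bounds and
gene–protein–reaction (GPR) rules. At steady state, flux balance
analysis (FBA) predicts a flux distribution by solving

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\;\; lb \le v \le ub,$$

with $c$ selecting the biomass reaction. For gut anaerobes — the setting
this package is built for — raw draft models routinely mispredict growth
and short-chain fatty acid (SCFA) secretion until several layers of
curation are applied: the growth medium must be translated into
exchange-flux caps, reaction directionalities must respect
thermodynamics, spurious energy-generating cycles (EGCs) introduced by
gap filling must be removed, and transcriptome data can deactivate
routes the cell does not express. gutGEM implements each layer as a
separate, testable operation and connects them into a pipeline that also
extends to multi-species communities.

## The constraint engine and its LP core

All analyses reduce to small dense linear programs. Because no LP solver
package is available as a dependency in this environment, the package
ships its own bounded-variable two-phase primal simplex
(`R/lp-simplex.R`). Design points that matter for reproducibility:

* **Anti-cycling.** Dantzig pricing normally; after a stretch of
  degenerate iterations the pivot rule switches to Bland's rule, which
  guarantees termination.
* **Numerical hygiene.** The basis inverse is maintained by rank-one
  (eta) updates and refactorized every 60 iterations; solutions are
  snapped to bounds within 1e-9 and phase-1 feasibility is accepted below
  1e-7 (scaled by the right-hand side).
* **Validation.** The test suite compares the engine against exhaustive
  vertex enumeration of the flux polytope on hundreds of seeded random
  problems (to 1e-9 relative), and against cobrapy/GLPK — an entirely
  independent implementation — on the toy anaerobe.

Parsimonious FBA (pFBA) fixes the biomass optimum and minimizes
$\sum_i |v_i|$ through the standard forward/backward variable split with
unit weights. Point fluxes are reported from pFBA wherever alternate
optima could make a plain FBA solution arbitrary; plain FBA solutions
carry a "representative, possibly degenerate" flag in their metadata.
Deletion growth in essentiality analysis uses plain FBA, since only the
optimum matters against the threshold $f_{ess} = 0.9$.

The zero-flux tolerance is 1e-6 mmol/gDW/h throughout (the LP noise
floor), and default bounds are ±1000 mmol/gDW/h.

## Media

`estimateUptakeCap()` converts two concentration measurements into an
average specific exchange flux, $v = (C_t - C_0)/(\Delta t \cdot X)$
(mmol/gDW/h; uptake negative, secretion positive), used as a
conservative cap on the matching exchange reaction. The bulk amino-acid
default of 0.5 mmol/gDW/h reflects defined-medium practice for gut
communities. Exchanges not listed in a medium follow a policy; the
default closes uptake and leaves secretion open (lb 0, ub 1000), which
prevents phantom nutrient uptake. Overrides are applied last, e.g.
closing cellobiose uptake entirely when experiment says the substrate is
untouched.

## Thermodynamic curation

`assignDirectionality()` applies the ±30 kJ/mol convention to
transformed reaction Gibbs energies: strictly below −30 the reaction is
clamped forward (lb → 0), strictly above +30 clamped reverse (ub → 0),
and the closed band, boundary values included, stays reversible. The
comparisons are deliberately strict, matching the inequality convention
of the thermodynamic tables the operation consumes (computed for
gut-like conditions: pH 6, 310 K, ionic strength 0.25 M). Exchanges are
never constrained; transporters can be exempted by id since
condition-specific ΔrG′ for transport is rarely trustworthy. A clamp
that would invert the bounds is refused with a warning rather than
applied.

`detectEGCs()` closes every exchange, adds one dissipation reaction per
energy currency (ATP, GTP, NADH, NADPH, FADH2, proton-motive force, with
textbook hydrolysis stoichiometries) and maximizes its flux; anything
above tolerance is a cycle generating energy from nothing. Two
adaptations keep the screen honest on lumped models: water/proton terms
are dropped from a dissipation reaction when the model does not track
those species (the core currency pair must be present or the currency is
skipped), and internal reactions with forced flux (a maintenance lower
bound) are relaxed to zero during the screen so the report contains the
cycle itself, not whatever the forcing drags along. The active cycle is
read from a parsimonious flux distribution at the dissipation maximum.

`integrateCandidates()` adds the top-*n* reactions of a ranked
candidate list, re-applies the directionality rule, and then removes
added reactions participating in detected cycles greedily — lowest rank
first — until the screen is clean. Reactions of the original model are
never auto-removed. Growth inflation (growth after / before) is reported
but never acted on automatically, because no quantitative inflation rule
is defensible in general.

## Transcriptome contextualization

CPM is computed directly ($count/\sum count \times 10^6$) and the
high-expression threshold is the 70th percentile of CPM *over the model
genes present in the profile*, not the whole transcriptome — the model
is what the threshold will act on. Expression maps onto reactions
through the GPR with AND = min (a complex is limited by its scarcest
subunit) and OR = max (isoenzymes are as good as the best one);
reactions without gene association stay unscored and are never
penalized.

GIMME solves

$$\min_v \sum_i c_i |v_i|,\qquad c_i = \max(0,\; t - score_i),$$

subject to steady state, bounds, and biomass ≥ 0.9 of its optimum (the
0.9 default follows the package-wide 90% convention; it is a
configurable argument). The scope is restricted to gene-associated,
non-blocked reactions: a reaction that cannot carry flux under the
medium regardless of expression says nothing about expression, so
penalizing it would only distort the objective. The split-sum
formulation of $|v_i|$ is used; it is exact for nonnegative weights.

`pruneInactive()` deactivates — zero bounds, never structural deletion —
reactions that are idle in the contextualized solution *and*
gene-associated, non-spontaneous and non-essential. Spontaneous
diffusion steps and essential reactions are protected even at zero
observed flux, since a pFBA-stage zero can be a degeneracy artifact.

## Community modeling

`buildCommunity()` embeds member models block-diagonally: ids are
namespaced per species, each member's exchange reactions are rewired
into transfer reactions between the member's own extracellular
metabolite and a shared pool metabolite, and the pool gets
community-level exchanges. Pool identity uses the member metabolite id
itself unless an explicit mapping table says otherwise. All member
bounds are scaled by the species' fixed relative abundance $a_k$, so
fluxes are per gram community dry weight, and the community objective is
$\sum_k a_k\, v_{biomass,k}$. A single member at $a = 1$ therefore
reproduces its monoculture solution exactly (asserted to 1e-9 in the
tests).

Cross-feeding is inferred from community FVA at 90% of the community
optimum, over the transfer reactions: a transfer maximum above tolerance
means the species can produce the metabolite into the pool, a minimum
below −tolerance that it can consume it, and both signs give direction
"both". A metabolite is flagged cross-fed when one species can produce
it and a *different* one consume it within the same solution space.
Edges whose largest absolute flux stays below 0.01 mmol/gDW/h are
flagged low-flux rather than dropped. Networks export as SIF or GraphML
for external visualization.

## The synthetic world

The generators emulate the biology the pipeline is meant to recover,
with integer stoichiometries and round ΔrG′ values so every number is
hand-checkable.

**Toy anaerobe** (`makeToyAnaerobe()`). Glucose (cap 5 mmol/gDW/h) is
oxidized to acetyl-CoA, producing 4 NADH per glucose that must be
re-oxidized; the only valves are a hydrogenase capped at 1 mmol/gDW/h
and butyrate synthesis (2 NADH per butyrate). The terminal butyrate step
is either a CoA transferase fed by medium acetoacetate — which
regenerates acetoacetyl-CoA and is therefore the cheap electron sink —
or a lumped kinase route that wastes the thioester bond. Under the
default medium the optimum routes all butyrate through the transferase
(9.5 mmol/gDW/h at growth 2.4375/h) and secretes surplus acetyl-CoA as
acetate. The five-reaction lysine branch (LYSAM → DH36M → DH35O → A53C →
AB3CL, ATP-costing ABC import) is exactly carbon- and redox-neutral and
so carries zero flux at the optimum while remaining feasible in FVA —
the transcriptomically supported but energetically idle pathway pattern.
Setting the transport ATP cost to zero, deactivating the thiolase and
closing acetoacetate uptake makes the lysine branch the only electron
sink: it then carries flux (the condition-driven switch). A
methylmalonyl-CoA propionate branch is present and structurally able to
run, but confers no benefit and stays silent; its CoA-priming step
(SUCCT) is blocked at steady state because the loop balances CoA
internally. The kinase lumping (no ATP recovered) is a deliberate
simplification that makes the transferase route strictly preferred —
the real kinase route recovers substrate-level ATP, but the toy needs an
unambiguous energetic ordering for its ground truth.

**Expression counts** (`makeToyExpression()`). All non-designated genes
share one count so that, with no low genes, every reaction score ties at
the percentile threshold and the GIMME penalty vector is exactly zero;
designated low genes draw seeded counts of 1–10. No dispersion modeling
is attempted: counts only need to straddle the threshold, and a green
GIMME test establishes rerouting behavior, not RNA-seq realism.

**Toy community** (`makeToyCommunity()`). Three guilds with abundances
(0.59, 0.26, 0.15): a degrader D hydrolyzing polymer into public-good
glucose, a fermenter S making acetate plus either acetaldehyde or
succinate, and a utilizer U that grows only on the by-products and is
the sole butyrate producer. D and S have saturable internal capacities
so the community optimum genuinely distributes growth across the chain
rather than letting the most efficient guild take everything; U's
reversible succinate shunt creates the one engineered "both"-direction
edge. The recorded edge list (11 edges over 4 cross-fed metabolites) is
re-derived by community FVA in the tests, not trusted from construction.

**What a green test does not establish.** The toys are redox-coupled
caricatures: no proton or water bookkeeping, no real biomass
composition, and growth rates ~100× gut-realistic values (a real
*F. plautii*-scale model grows at ~0.01/h, the toy at ~2.4/h). Passing
tests certify the algorithms — LP correctness, rule application,
pipeline wiring, ground-truth recovery — not the biology of any real
organism.

## Degenerate inputs and numerical choices

* Infeasible FBA returns a status, never an error; FVA and essentiality,
  which need a feasible reference, raise errors that name the failing
  stage.
* Essentiality with zero wild-type growth is undefined and an error.
* Formula-less metabolites make a reaction "unverifiable" in the balance
  check rather than imbalanced — draft models are incompletely annotated
  and absence of evidence is not imbalance.
* Gene ids are opaque strings; no normalization is attempted, so
  expression tables must use the model's identifiers.
* The SBML reader accepts bounds as FBC v2 parameter references, FBC v1
  flux-bound lists, or COBRA-style kineticLaw locals, falling back to
  the `reversible` attribute with ±1000 defaults — deposited models mix
  all of these dialects.

## Known limitations

No loopless FBA or full thermodynamic flux analysis (directionality
clamping is a static approximation); no dynamic community modeling
(abundances are fixed inputs); no draft reconstruction, ΔG′ estimation
or candidate ranking — those artifacts are consumed as inputs. The LP
core is tuned for the dense, small problems of curated gut GEMs and toy
networks; genome-scale models with tens of thousands of reactions would
want a sparse revised simplex or an external solver behind the same
interface.
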
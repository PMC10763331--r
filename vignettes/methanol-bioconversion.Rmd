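---
title: "Constraint-based analysis of methanol bioconversion in methylotrophic yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of methanol bioconversion in methylotrophic yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methflux)
```

## The problem

Methylotrophic yeasts such as *Ogataea polymorpha* assimilate methanol via
peroxisomal methanol oxidase and the xylulose-monophosphate (XuMP) cycle,
and dissimilate it via formaldehyde and formate to CO2. Engineered strains
can convert methanol into platform chemicals; this package analyses three
such products — malate (C4), acetone (C3), and isoprene (C5) — with flux
balance analysis (FBA) on a curated core metabolic network, asking: what is
the best attainable molar yield per product, how does it trade off against
growth, and how do enforced pathway usages (blocked or forced TCA flux,
forced glyoxylate shunt) reshape both the yields and the flux
distributions? A companion module covers the unit and yield arithmetic of
shake-flask methanol fermentations.

## The model

FBA treats metabolism as a linear program: find a flux vector $v$
(mmol/gDW/h) maximising an objective $c^\top v$ subject to steady state
$S v = 0$ and bounds $l \le v \le u$, where $S$ is the stoichiometric
matrix. Yields are reported as the product exchange flux divided by the
methanol uptake flux, both in mmol/gDW/h, hence mol/mol.

`buildCoreModel()` constructs the network (74 reactions, 75 metabolites,
four compartments) from scratch:

* methanol uptake, peroxisomal methanol oxidase (producing H2O2, consumed
  by catalase — no NADH is gained at this step) and formaldehyde export;
* XuMP assimilation: dihydroxyacetone synthase
  (formaldehyde + Xu5P -> DHA + GAP), DHA kinase, and a *lumped*
  pentose-phosphate rearrangement `3 DHAP + 2 GAP + 2 H2O -> 3 Xu5P + 2 Pi`
  that regenerates the acceptor. The lump conserves carbon and phosphate
  exactly; the analysis depends only on net carbon and redox stoichiometry,
  not on PPP detail;
* the NADH-producing dissimilatory branch
  (formaldehyde -> formate -> CO2, one NADH per step);
* lumped lower glycolysis (GAP -> pyruvate, +2 ATP, +1 NADH);
* mitochondrial pyruvate dehydrogenase, a full TCA cycle, and a citrate
  transporter;
* the glyoxylate shunt (cytosolic aconitase, isocitrate lyase, malate
  synthase);
* a cytosolic PDH bypass (pyruvate decarboxylase, NAD-linked aldehyde
  dehydrogenase, acetyl-CoA synthetase) as the cytosolic acetyl-CoA source
  — the route yeasts actually use, since non-oleaginous yeasts lack
  ATP-citrate lyase;
* the cytosolic reductive-TCA malate route (pyruvate carboxylase +
  cytosolic malate dehydrogenase) with a Mae1-style malate exporter;
* the acetone pathway: thiolase, then either acetoacetyl-CoA *hydrolase*
  (YbgC-style, cofactor-free; the default, chosen because it needs no
  acetate co-substrate) or the CoA-transferase (CtfAB-style) variant by
  option, then acetoacetate decarboxylase;
* the mevalonate pathway to DMAPP (HMG-CoA synthase and reductase, a
  lumped kinase/decarboxylase step costing 3 ATP and releasing CO2, IPP
  isomerase) and isoprene synthase;
* respiration lumped per cofactor at configurable P/O ratios, an ATP
  maintenance reaction, a lumped NADH shuttle (the malate–aspartate
  shuttle analog) and a lumped NADPH source;
* a lumped biomass reaction drawing 3 GAP, 5 pyruvate, 4 acetyl-CoA,
  3 OAA, 8 NADPH and 30 ATP per gDW.

Metabolite formulas follow the charged-species conventions of the BiGG
database with explicit protons, so **every internal reaction is elementally
balanced** over C, H, O, N, P, S (`validateMassBalance()` returns zero
rows). The biomass pseudo-metabolite is assigned the exact elemental
residual of its precursor draw (C44 per unit flux), so even the biomass
reaction balances and carbon accounting closes: at any optimum, methanol
carbon in equals CO2 + product + biomass carbon out to < 1e-6
(`carbonBalance()`).

Yield ceilings follow from the formulas alone: methanol carries 1 carbon
and 6 electrons, so the carbon-perfect ceiling is 1/4, 1/3, 1/5 mol/mol
for malate, acetone, isoprene, and the electron ceiling 6/12, 6/16, 6/28 is
looser in each case. The malate route attains its carbon ceiling of
0.25 mol/mol exactly: 3 of every 4 methanol are assimilated to pyruvate,
the 4th is dissimilated to CO2 and NADH, and pyruvate carboxylase +
cytosolic MDH capture both into one malate. The enabling step is the
carboxylation: blocking pyruvate carboxylase drops the optimum to 1/6,
whereas deleting the dissimilatory branch does not move it at all, because
every CO2 lost in a decarboxylation can be re-fixed.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `uptake` | 10 mmol/gDW/h | methanol exchange lower bound (sole carbon source) |
| `po_nadh`, `po_fadh2` | 1.5, 1.0 | P/O ratios of the lumped respiration |
| `atp_maintenance` | 0 | non-growth ATP demand (no published value exists for these conditions) |
| `acetone_route` | `"hydrolase"` | hydrolase vs CoA-transferase acetone step |
| default bounds | (0, 1000) / (-1000, 1000) | irreversible / reversible reactions |

All fluxes are mmol/gDW/h throughout; no unit conversion happens inside the
model layer.

## Numerical choices

No LP solver usable for equality-constrained bounded problems ships with
this R installation, so the package carries its own dense bounded-variable
two-phase primal simplex (`methflux:::.simplexSolve`). Phase 1 uses one
artificial variable per row, which makes rank-deficient stoichiometric
matrices (conserved moieties such as the adenylate and CoA pools)
unproblematic; Dantzig pricing switches permanently to Bland's rule after a
stall, guaranteeing termination under the heavy degeneracy typical of FBA
vertices. The solver is exact to roundoff at this problem size and is
cross-validated in the tests against hand-solved instances and against a
reference constraint-based implementation run on the model JSON.

Tolerances: feasibility 1e-9, steady-state residual 1e-6, yield equality
comparisons 1e-4.

An FBA optimum is generally a degenerate vertex and the flux vector at it
is not unique. For reproducibility, `solveFBA()` returns by default the
optimal vector minimising the total absolute flux (a second LP with the
objective pinned — parsimonious FBA). This affects only representative
flux distributions (hence the PCA), never objective values or yields, and
makes every downstream output byte-reproducible.

## Scenarios and calibration

`scenarioSpecs()` encodes five pathway scenarios as bound edits over
literature reaction aliases: an unconstrained reference (Ref), blocked TCA
(TCA-; PDH, citrate synthase, citrate transport, 2-oxoglutarate
dehydrogenase and acetolactate synthase capped at zero), forced TCA (TCA+;
2-oxoglutarate dehydrogenase lower bound at its feasibility maximum),
forced glyoxylate shunt (GlxStd; isocitrate lyase at its feasibility
maximum), and forced-impaired glyoxylate shunt (GlxVar; GlxStd plus the
mitochondrial MDH pinned at its feasibility minimum). Calibrated bounds
are found by flux variability with no objective fixing and pulled back by
a relative slack of 1e-6 so the forced model stays feasible
(`calibrateForcedBound()`).

Two deliberate choices here:

* **Calibrated bounds are recomputed on the core model** rather than
  copied from the published full-model settings (7.8 for the
  dehydrogenase, 10 for isocitrate lyase, -10/2.85 for the mitochondrial
  MDH). Those numbers are vertices of the full reconstruction's flux
  space and are kept only as reference metadata; the *procedure* — the
  extreme flux that still supports a feasible solution — is what carries
  over.
* The GlxVar MDH edit reads the published pair as "reverse flux allowed
  down to the uptake rate, forward flux capped at the feasible minimum",
  i.e. the transporter-facing bound is a generous constant while the
  forward cap is calibrated (`calibrate:min` on the GlxStd-applied
  model). This pins the enzyme at its least possible activity, matching
  the scenario's "impaired" reading.

On the core network, the calibrated TCA+ bound is 3.33 mmol/gDW/h and the
forced-glyoxylate bound 1.67 mmol/gDW/h at uptake 10; at these extremes the
committed cycle absorbs all assimilable carbon and every product optimum is
zero, which reproduces the all-zero forced-TCA column of the published
grid. Infeasible cells, would they occur, are reported per cell with a
warning and yield 0 — the shipped slack guarantees feasibility, so both
readings of a printed "0" (true zero optimum vs near-infeasible forcing)
are covered.

Scenario definitions can also be loaded from YAML/JSON
(`readScenarioConfig()`; a bundled copy sits in
`system.file("extdata", "scenarios.yaml", package = "methflux")`).

## Production envelopes

`productionEnvelope()` fixes the biomass flux at each of `n_points`
(default 21) fractions of the maximal growth rate and maximises the
product exchange. By construction the yield at fraction 0 is the
zero-growth maximum and the yield at fraction 1 is zero (at maximal growth
no carbon is left). Because every envelope ends at zero, the drop
normalised by the zero-growth yield is 1 for all products; the discriminating
quantity is the absolute slope in yield per unit growth rate, which is
steepest for malate — its zero-growth yield is the largest, so it pays the
most per unit of growth. Tests assert monotonicity, the anchors, and this
slope ordering rather than absolute growth rates: the biomass composition
is a documented synthetic lump, so absolute growth numbers are
model-specific and only the envelope *shape* is meaningful.

## PCA of flux distributions

`runFluxPCA()` centres columns by default and does not scale them (all
fluxes share one unit); scaling is available by flag and drops
zero-variance columns with a warning. Components are computed by singular
value decomposition and signed so that each component's largest-magnitude
loading is positive, making scores reproducible. The test suite checks the
result against a brute-force eigen-decomposition of the covariance matrix.

`scenarioDistances()` reports Euclidean distances in the space of the
first k components (default 2, as such maps are plotted) and a
single-linkage clustering cut at the largest merge-height gap.

On the core model the 15 scenario-product solutions show the three pathway
modes exactly as expected per product: the reference and blocked-TCA
solutions coincide (distance 0), the two glyoxylate solutions coincide,
and the forced-TCA solution stands apart, with within-mode spread strictly
below every cross-mode distance. Across products, however, the picture is
scale-dependent: in a 74-reaction network the product pathway itself
carries a large share of total flux, so the malate rows sit farther from
the acetone/isoprene rows than the reference mode sits from the glyoxylate
mode, and the largest-gap cut over all 15 points returns two clusters
(forced-TCA vs the rest) instead of three. In a genome-scale
reconstruction the product pathway is diluted over thousands of reactions
and the scenario signal dominates. The tests therefore assert the
three-mode separation per product, and the acetone–isoprene rows are the
nearest cross-product neighbours in every scenario, reflecting their
shared acetoacetyl-CoA trunk.

## Fermentation arithmetic

The fermentation module implements the arithmetic conventions of
shake-flask methanol cultivations: %(v/v) to g/L via a methanol density of
792 g/L (consistent with the usual 0.5 % = 4 g/L and 1 % = 8 g/L
equivalences), g/L to mM, molar yields, volumetric productivities,
percent-of-reference values, and evaporation correction. Display rounding
mirrors reporting practice (integer percents and g/L, one decimal for
g/L/d) but raw values are always retained; percent-remaining calculations
reference the *nominal* (display-rounded) initial charge, as such
experiments quote it.

No standard formula exists for correcting shake-flask titers for
evaporation; `evaporationCorrect()` uses the volume-ratio rule: the
current volume is estimated from the daily flask weight loss at a medium
density of 1000 g/L (configurable), and each measured concentration is
multiplied by current/initial volume. The correction is per-timepoint
multiplicative and order-independent, and corrected titers never exceed
measured ones when volume was lost.

## What the core network does and does not show

The network is the desk-scale stand-in for a ~900-gene reconstruction. It
reproduces structural results — the 0.25 mol/mol malate ceiling and its
attainment, the near-equality of reference and blocked-TCA optima, the
yield cost of forcing the glyoxylate shunt, the all-zero forced-TCA
column, envelope shapes, and the scenario-mode geometry — because these
follow from pathway stoichiometry that the core network shares with the
full model. It does not reproduce numbers that depend on the full model's
content: the published acetone (0.2) and isoprene (0.11) reference yields
(core model: 1/6 and 0.09 — the core acetyl-CoA route loses one carbon per
pyruvate with no recovery options a larger network offers), absolute
growth rates, or the small positive glyoxylate-scenario yields (the
calibrated forcing is tighter on a small network). Passing tests therefore
validate the method and the structural claims, not full-model numerics.

Other known limitations: biomass contains no nitrogen or sulfur (the
medium block is out of scope, so there is no N source; the lump is
documented and element-consistent); protons are balanced as explicit
species but no membrane potential or pH effect is modelled; charge
balancing is skipped because no charge assignments are published for this
system; compartments carry no volume. Problem sizes used throughout the
tests and the acceptance script — the 15-cell grid, envelopes at 5–21
points, one model build per suite — were chosen as the smallest sizes that
exercise every code path.
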
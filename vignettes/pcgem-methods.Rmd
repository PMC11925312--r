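---
title: "Proteome-constrained modeling with pcgem: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-constrained modeling with pcgem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgem)
```

## The modeling problem

Mature red blood cells have no nucleus and no protein synthesis: the enzyme
complement a cell carries at the end of erythropoiesis is the complement it
keeps, slowly degrading, for its whole circulating life. Their metabolism is
therefore a natural target for *proteome-constrained* genome-scale modeling,
in which the classical flux balance analysis (FBA) problem

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; v_{lb} \le v \le v_{ub}$$

is augmented with explicit protein, complex, and enzyme variables so that a
measured proteome bounds the attainable flux states. `pcgem` implements that
augmentation for any stoichiometric model plus two tables (proteins and
catalytic complexes), fits measured proteomes to the augmented model by
weighted quadratic programming, relaxes the fit into context-specific models,
and classifies reactions by how strongly their maximum flux tracks their
enzyme abundance across samples.

## The proteome-constrained model

`build_pc_model()` adds, per protein $j$, a dilution flux $p_j \ge 0$
(nmol/gDW) that draws $w_j p_j$ mg/gDW from a mass budget, where $w_j$ is the
protein molar mass (mg/nmol, computed from sequence with average residue
masses plus one water, or supplied in Da). The budget is partitioned:

* a total pool $P_{total} \le 1000$ mg/gDW (100% of cell dry weight),
* a hemoglobin pool $P_{HB} = \sum_{j \in HB} w_j p_j$ with a floor of
  900 mg/gDW — hemoglobin is at least ~90% of red-cell protein — and
* a low-abundance pool $P_{LA} \le 100$ mg/gDW for everything else,

with $P_{total} = P_{HB} + P_{LA}$. Complexes $x_l \ge 0$ assemble from
subunit proteins according to integer copy numbers ($C x \le p$; unused
protein drains through slack sinks). For each catalyzed reaction the member
complexes feed one *enzyme entity* split into forward and reverse parts,
$e^{fwd}_i + e^{rev}_i = \sum_l B_{il}\, r_l\, x_l$, and flux is capped by
capacity,

$$-k_{avg}\, e^{rev}_i \le v_i \le k_{avg}\, e^{fwd}_i .$$

Key assumptions, stated plainly:

1. protein mass may not exceed the dry-weight budget;
2. each gene maps to one protein whose mass follows from its sequence;
3. a complex has one effective rate constant regardless of which of its
   reactions it serves;
4. enzyme abundance caps flux but never forces it (all coupling
   inequalities carry slack sinks);
5. all protein species live in a single model compartment.

Every constraint is realized as a pseudo-metabolite balance with
pseudo-reactions (`prot_`, `cplx_`, `enz_fwd_`/`enz_rev_`, `budget_`,
`sink_` prefixes), so a proteome-constrained model is still an ordinary
stoichiometric model: the same simplex, the same FVA code, and the same SBML
writer apply to it unchanged.

### Rate constants

Effective rate constants start from a single average turnover,
$k_{avg} = 65\,\mathrm{s^{-1}} = 2.34 \times 10^5\,\mathrm{hr^{-1}}$.
Complex-level constants scale with complex molar mass $M_l$ relative to the
mean complex mass, $k_l = k_{avg} (M_l / \bar M)^{3/4}$ — catalytic capacity
tracks solvent-accessible surface area, which grows roughly as mass to the
3/4 — and the ratios $r_l = k_l / k_{avg}$ weight each complex's
contribution to its enzyme pool. Surface-area scaling conventions differ in
the base quantity and the sign of the exponent; we scale by *molar mass*
with exponent $+3/4$ — the reading in which heavier complexes are faster
per mole, as surface-area scaling implies — and expose `mass_exponent` in
`budget_config()` so the alternative convention can be audited.
Reverse constants are zeroed for irreversible reactions
($v_{lb} \ge 0$).

### Units in the capacity coupling

Fluxes are mmol/gDW/hr while enzyme abundances are nmol/gDW. A literal
$v \le k e$ with $k$ in 1/hr is dimensionally inconsistent by the
nmol-to-mmol factor; `pcgem` includes the conversion explicitly
(`enzyme_flux_scale = 1e-6` in `budget_config()`), so one nmol/gDW of
enzyme with $k = k_{avg}$ supports at most $0.234$ mmol/gDW/hr of flux.
Without this factor no physiological enzyme abundance could ever limit a
metabolic flux, and the capacity constraints would be decorative.

## Fitting a measured proteome

Measured abundances are first scaled to the budgets
(`normalize_to_budget()`): hemoglobin proteins to 95% of protein content
($P_{HB,ub} = 950$ mg/gDW) and the remaining measured proteins to the
residual 5% ($P_{LA,ub} = 50$ mg/gDW), preserving within-group proportions.
`fit_proteome()` then solves the convex QP

$$\min \sum_j c_j (p_j - p^{data}_j)^2,\qquad
  c_j = \begin{cases} 1/p^{data}_j & p^{data}_j > 0\\
                      1 & p^{data}_j = 0\\
                      0 & p^{data}_j \text{ missing}\end{cases}$$

over the full constraint set, with the fitting budgets installed. Weighting
inversely to abundance keeps the fit honest for scarce proteins and
penalizes expression of proteins measured at zero; missing values (which are
*not* zeros — detection failure is overwhelmingly technical) leave their
protein unconstrained by the objective. Because the data are scaled exactly
onto the budget caps, the data vector itself is feasible and the optimum is
essentially exact (objective below 1e-10 on synthetic panels).

No flux objective is imposed during fitting: the QP decides $v, p, x, e$
jointly under steady state alone. The formulation leaves this open; adding a
flux objective would bias the fitted proteome toward whatever that objective
rewards, which is the opposite of what a context-specific model is for.

## Context-specific models and slack

`build_context_model()` replaces the generic protein bounds with
sample-specific ones built from the best-fit vector $p'$ and a slack term
$s$ (default 0.03):

* a relaxation pool $P_R \le s \sum_j w_j p'_j$ joins the budget partition
  ($P_{total} = P_{HB} + P_{LA} + P_R \le 1000$);
* measured proteins move in $[(1-s)\,p'_j,\; p'_j + s P_{R,ub}/w_j]$;
* unmeasured proteins move in $[0,\; s P_{R,ub}/w_j]$.

The pool absorbs the mass freed by relaxed lower bounds and caps the molar
headroom of the upper bounds; unmeasured-but-essential enzymes get just
enough allowance to carry flux instead of making the whole model infeasible.
`calibrate_slack()` picks $s$ by maximizing a physiological objective (the
sodium/potassium pump by default) and then minimizing the relaxation budget
actually used, across an increasing grid; the chosen value is the smallest
grid point whose objective reaches 99% of the largest-grid objective. On
models whose objective remains enzyme-limited at every grid value the
objective keeps growing with $s$ and the criterion selects the grid maximum
with a warning — the plateau exists only when network constraints take over,
as they do at genome scale.

## Variability analysis and classification

`pc_fva()` computes per-reaction flux ranges with the objective constrained
to fractions {0, 0.5, 0.9, 0.99} of its maximum. The *effective* envelope is
the union over fractions; because the constrained polytopes nest, that union
equals the fraction-0 range — the per-fraction ranges are still reported for
auditing tighter operating regimes. `enzyme_abundance_range()` optimizes
$e^{fwd}_i + e^{rev}_i$ under the same constraints.

`classify_reactions()` computes the Spearman correlation $\rho$ between each
reaction's maximum flux and its enzyme abundance across samples:
abundance-dependent ($\rho \ge 0.8$), abundance-correlated
($0.5 \le \rho < 0.8$), abundance-independent otherwise. Spontaneous
(GPR-free) reactions and blocked reactions are always
abundance-independent; an undefined $\rho$ (constant flux or abundance) is
independent and flagged. The three classes partition the classified
reactions by construction. `build_representative_model()` collapses many
context models into one by taking componentwise envelope bounds.

## The synthetic study generator

`make_toy_gem()` builds a deterministic ~17-reaction red-cell-like network:
glucose uptake, a lumped glycolysis with an isozyme pair, a
sodium/potassium pump (heterotetrameric complex, the default objective)
closed by passive cation leaks, lactate/proton export, a glycogen-storage
branch, and a fatty-acid-synthesis branch whose malonyl-CoA precursor has no
producer — a planted blocked branch mirroring the textbook incapacity of
mature red cells for de novo lipogenesis. All reactions are mass- and
charge-balanced with real elemental formulas.

`sample_donor_proteomes()` emulates the structure of a storage-study donor
panel: three storage days (10, 23, 42) per donor; hemoglobin at 95% of
protein mass; low-abundance proteins log-normal across donors (log-sd 0.5,
a typical between-donor spread for plasma-membrane and cytosolic enzymes)
with small within-donor day noise and a gentle multiplicative storage
drift (0.995/day); missing-at-random masking at rate 0.1; per-donor
hemoglobin concentrations (Normal(13.5, 1.2) g/dL, a few missing to
exercise imputation); and metadata columns generated as noisy monotone
functions of chosen enzyme abundances. One enzyme (the glucose transporter)
is *planted* as abundance-limiting: its abundance scale (median 10 nmol/gDW)
is chosen so that its capacity $0.234\,r\,(p' + sP_{R,ub}/w)$ stays inside
the window between zero and the network's own throughput limits across the
whole log-normal range, making its reaction's maximum flux a strictly
monotone function of its abundance. Sample sizes in the tests (50 donors,
150 samples, 10 generator seeds) keep the full pipeline — one QP fit plus
roughly twenty LPs per sample — to a few seconds per seed.

What passing the recovery tests does **not** show about real data: the
generator has no peptide-level quantification noise, no batch structure, no
abundance-dependent missingness (an optional mode exercises it), no
correlated proteome modules, and a planted ground truth in which exactly one
constraint binds. Recovery on this panel validates the machinery, not the
biology.

## Numerical choices

* **LP solver.** A compiled bounded-variable primal simplex (two-phase,
  Dantzig pricing with Bland fallback, row equilibration). Proteome
  models mix stoichiometric coefficients of order 1 with rate constants of
  order 1e5 and molar masses of order 1e-2, so rows are scaled by their
  largest coefficient before solving. Pivot tolerance 1e-9; lower bounds
  must be finite (the conventional ±1000 sentinel), upper bounds may be
  infinite.
* **QP solver.** The dual active-set method of `quadprog`, which requires a
  strictly positive-definite quadratic form; variables outside the fitting
  objective receive a diagonal ridge of 1e-13. The ridge perturbs fitted
  abundances by a relative ~1e-8 on realistic scales — far below the 1e-6
  recovery tolerance — and is a solver tolerance, not a model parameter.
  Stoichiometric equality rows are reduced to a row basis first (conserved
  moieties make $S$ rank-deficient, which the active-set method cannot
  tolerate).
* **Blocked reactions**: FVA at fraction 0 with tolerance 1e-6 mmol/gDW/hr.
* **Lexicographic calibration**: the first-stage optimum is fixed to within
  1e-9 (relative) before minimizing the relaxation budget.
* **Ties and ranks**: Spearman uses average ranks; an exactly constant
  vector yields an undefined correlation rather than 0.
* **Reference lines** for connectivity distributions are drawn in
  (rank, log10 degree) space, because degree distributions are heavy-tailed
  and curvature is only interpretable on the log scale.
* **Merged-compartment connectivity** counts the reactions in which any
  compartment instance of a metabolite participates. Summing matrix rows
  instead (as `stoichiometric_matrix(merge_compartments = TRUE)` does)
  would cancel pure transport reactions and could make a merged degree
  smaller than a per-compartment degree.
* **Motif pruning** removes a currency pair (e.g. ATP/ADP) from a reaction
  only when both members appear on opposite sides; partial matches leave
  the reaction untouched, so primary chemistry survives.

## Limitations

* Complexes catalyzing several reactions contribute their full abundance to
  every associated enzyme entity; capacity is an upper envelope, not a
  partition, so simultaneous fluxes through shared-enzyme reactions can
  jointly exceed what the physical enzyme pool would allow.
* Enzyme entities are one-per-reaction; reactions with identical complex
  sets are not merged.
* The SBML dialect covers the core + flux-bounds + gene-association subset
  used by constraint-based tools; kinetic laws, units, and layout packages
  are out of scope.
* Balance checking treats generic R-groups as inert pseudo-elements and
  excludes reactions carrying them, mirroring how pooling reactions are
  excluded from published balance statistics.
* At genome scale (thousands of reactions × thousands of samples) the dense
  simplex is the bottleneck; the design target here is the desk-scale
  regime of the test suite and the synthetic study.

## A worked run

```{r pipeline}
model <- make_toy_gem()
tables <- make_protein_tables(model)
pc <- build_pc_model(model, tables$proteins, tables$complexes)
pc

panel <- sample_donor_proteomes(tables, synthetic_spec(n_donors = 10,
                                                      seed = 1))
prep <- prepare_samples(panel$raw_matrix, panel$hb_table)
res <- classify_pipeline(pc, prep$samples, "NAKATPASE")
table(res$classification$class)
subset(res$classification, reaction_id == "GLCt")
```

The planted glucose transporter is recovered as abundance-dependent with
$\rho = 1$; spontaneous leaks and the blocked lipogenesis branch are forced
abundance-independent.
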
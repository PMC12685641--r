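---
title: "Modeling cGAS-STING/IL-6/FOXO-driven autophagy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cGAS-STING/IL-6/FOXO-driven autophagy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological system and the model

Non-small cell lung cancer (NSCLC) cells accumulate cytosolic
double-stranded DNA, which the sensor cGAS converts — via the second
messenger cGAMP — into activation of the ER-membrane adaptor STING.
Activated cGAMP-STING has two consequences that this package models
jointly: (i) the canonical inflammatory arm, in which Golgi-localized
TBK1 and IKK drive IRF3 and NF-κB into the nucleus to transcribe type I
interferon and IL-6, feeding JAK/STAT signaling; and (ii) a noncanonical
autophagy arm, in which the ER-Golgi intermediate compartment (ERGIC)
donates an isolation membrane that matures, with WIPI2/COP-II and
PI3K assistance, into the phagophore and finally the autophagosome.
The two arms are coupled through the FOXO transcription factors:
IL-6-activated STAT3 dimers release FOXO1 and FOXO3a for nuclear
import, where they transcribe the ATG genes (ATG5, ATG7, ATG12,
ATG16L, LC3-2) whose conjugation cascade builds the
LC3/ATG12/5/16L machinery that seals the phagophore. Energy stress
(extracellular ADP, the Warburg effect) enters through AMP/ULK1, and
growth-factor signaling through EGF/PI3K/AKT/mTORC1/HIF-1α; LPS/TLR4
contributes TBK1- and IKK-recruiting TRAF3/TRAF6.

`build_nsclc_model()` encodes this narrative as a deterministic
compartmental kinetic model with

* six compartments (cytoplasm, plasma membrane, nucleus, ER membrane,
  Golgi, ERGIC), all of unit volume so amounts equal concentrations;
* 72 dynamic signaling species plus 17 constant boundary templates —
  eight gene loci and nine external or buffered pools (dsDNA, EGF, LPS,
  IL-10, extracellular ADP, ATP, GTP, AMPγ, the ATG10 enzyme pool);
* 83 irreversible reactions typed by the usual convention: mass action
  for association, dissociation and translocation; Michaelis-Menten for
  enzymatic conversion; Hill kinetics for gene expression, with the
  transcription factor as the modifier driving the rate and the gene
  locus as a conserved template.

Dynamic species start inside the 10^3–10^6 molecule band that signaling
species occupy; gene loci are held at constant copy number. The reported
census counts the dynamic species (72); the interaction network below
sees all 89 participating entities.

### Parameterization

No rate constants are published for this system; every parameter in the
curated model is a calibrated default, chosen once so that (a) all
trajectories are bounded on the 100 s horizon, and (b) the qualitative
100 s outcome holds — the strongest net accumulators include the
autophagosome, nuclear FOXO1/FOXO3a, and ER-membrane cGAMP-STING, which
is the observable signature of the coupled immune–autophagy axis.
Unimolecular steps carry rate constants of order 10^-3–1 s^-1,
bimolecular associations 10^-9–10^-6 per molecule per second, and
transcription maximal rates of order 10^2–10^3 molecules/s with
half-saturation constants of 10^4–10^5 driver molecules. These are
physically plausible scales, not fitted values, and the package
documents them as such.

## Simulation

`simulate_model()` integrates dx/dt = N v(x) (N the stoichiometric
matrix with boundary rows zeroed) with the implicit
backward-differentiation family (the stiff NDF/ODE15s family), relative
tolerance 1e-6 and absolute tolerance 1e-9 by default, reporting 201
evenly spaced states over [0, 100] s. States are clipped to zero after
integration only within the solver's absolute tolerance; deeper
negativity is treated as an integration failure. The default horizon,
output density and tolerances are package choices — the underlying
method only prescribes a stiff implicit solver and a 100 s horizon.

## Forward local sensitivities

`local_sensitivities()` computes the time-dependent derivatives
∂x_i(t)/∂p_j of every species with respect to every rate parameter and
initial amount by integrating the forward (variational) equations

dS/dt = J_x(t) S + J_p(t), S(0) = ∂x_0/∂p,

with analytic Jacobians of the three rate-law families. The states are
solved first on a fine grid by the stiff BDF solver; the sensitivity
system — linear and time-varying — is then advanced with the A-stable
implicit trapezoid rule, factoring one dense n×n matrix per step and
reusing it across all input columns. With 2000 substeps on the 100 s
horizon the scheme's O(h²) error sits far below the 1e-4 relative
agreement demanded of it by the finite-difference oracle tests. The
default normalization is fully dedimensionalized,
(p_j/x_i)·∂x_i/∂p_j, with entries defined as 0 where x_i(t) = 0,
because the downstream PCA mixes species whose abundances span three
orders of magnitude; raw derivatives remain available for oracle
comparisons.

Two numerical caveats are documented in the test helpers: a central
finite-difference oracle at step 10^-6·p is dominated by integrator
noise for the smallest bimolecular constants, so the oracle uses the
noise-optimal step 10^-3·p; and comparisons are restricted to entries
whose dedimensionalized magnitude |S|·p/max|x| exceeds 1e-4, the
oracle's own noise floor on molecule-count scales.

`aggregate_sensitivities()` collapses time into the m×n score matrix A
consumed by the PCA: the default is the L2 norm over the time grid
(root integral of squared sensitivity, trapezoid rule); integral of
|S| and final-time magnitude are alternatives.

## PCA ranking and the key-species band

`run_pca()` mean-centers the columns of A (no variance scaling,
classical princomp behavior) and decomposes by singular values, with a
fixed sign convention (largest-magnitude loading element positive).
The per-species score is a package-defined interpretation, stated
prominently because the underlying method never defines one: the
variance-weighted L2 norm of the species' component scores over the
leading components explaining ≥ 90% of variance, rescaled so the score
distribution has unit median. The rescaling makes the conventional
selection band [0.8, 1.2] — species of near-median, broadly propagated
sensitivity — meaningful on arbitrary models. Because the band's
original scale is unrecoverable, membership claims on the curated model
are qualitative (the band does contain the energy-sensing ULK1 complex
and cytoplasmic ADP, among ~25 others) rather than an exact list.

## Flux ranking

`compute_fluxes()` evaluates every reaction's instantaneous rate at the
final simulated state (t = 100 s) by default — the reading time is not
prescribed anywhere, and a trapezoidal time average is available —
and ranks reactions by descending flux in mol/s. `top_reactions()`
filters at a threshold (500 mol/s by default); on the packaged verbatim
transcription of the published 27-row high-flux table
(`published_flux_table()`), that filter retains exactly the 27 printed
rows, headed by "LC3/ATG12/5/16L -> Autophagosome" at 215,000 mol/s.
The absolute fluxes of the curated simulation are not expected to
reproduce those printed values — they depend on the unpublished
parameterization — which is why the printed table ships as a fixture.

## Quasi-potential reduction

`quasi_potential_landscape()` attaches to each reaction a triple:
sensitivity (largest aggregated sensitivity over the reaction's own
parameters, L2 over species, rescaled to unit median), flux, and peak
concentration of its first non-template product. The combined rank is
the mean of the three per-axis descending ranks; the dome apex of the
landscape is the low-rank region. `reduce_model()` retains a reaction
when it passes all three explicit criteria — sensitivity within 0.2 of
1 (mirroring the 0.8–1.2 band), flux ≥ 500 mol/s, concentration at or
above the 0.85 quantile — or when it sits among the top 12 by combined
rank. Under these defaults the curated model retains 12 of 83 reactions
(85.5%, reported as 86% after rounding), and the retained set contains
the autophagosome-forming, FOXO-translocating and ERGIC-membrane steps.
The reduction is a selection tool, not a formal model-order reduction:
re-simulating the retained subsystem in isolation loses the removed
upstream drives, so the package's smoke check asserts only that
retained products stay within three orders of magnitude and that the
nuclear-FOXO accumulation signature persists.

## The interaction network

`model_to_network()` converts the kinetic model into a directed species
graph: every reactant and modifier points at every product; species on
both sides of a reaction (templates, catalytic complexes) act as
sources only, so no self-loops arise; gene-expression reactions follow
the transcription convention TF → gene → transcript, mirroring the
physical order of binding and synthesis; parallel edges collapse. On
the curated model this yields 89 nodes and 102 edges, and the
undirected simple view has radius 11, diameter 19 and mean local
clustering coefficient 0.034 — the clustering is carried by three
biologically motivated triangles (STAT3 dimer with each FOXO's
cytoplasmic/nuclear pair, and ULK1-complex/PI3K/phagophore).

`centrality()` implements the twelve CytoHubba-style metrics on the
undirected simple view (the only reading consistent with the
radius/diameter/clustering figures): degree, harmonic closeness,
betweenness, stress (raw shortest-path counts), eccentricity
(reciprocal of the longest shortest path), radiality, local clustering,
MNC and DMNC (largest neighborhood component and its density e/n^1.7),
MCC (sum of (|C|-1)! over maximal cliques, falling back to degree for
nodes whose only cliques are edges), bottleneck, and EPC (mean
component size containing the node over seeded random edge-retention
realizations; 1000 realizations at keep probability 0.5 by default, and
the seed is mandatory). For bottleneck, the classical definition counts
shortest-path-tree subtrees larger than a quarter of the network; a
literal BFS tree depends on node ordering, so the package uses the
label-independent content of that definition — the set of nodes whose
shortest paths from the root are all funneled through the candidate
(its dominated set in the shortest-path DAG). `hub_frequency()` counts,
for each node, the number of metrics in whose top-20 list it appears;
on the curated network the maximal-frequency hubs are the phagophore,
the STAT3 dimer and nuclear FOXO3a — precisely the immune–autophagy
bridges.

## Crosstalk scoring

`crosstalk_scores()` implements score(v) = deg_total(v) − deg_within(v)
on the undirected view, where a neighbor is "within" when it shares at
least one pathway label (an "all labels" variant is available).
Because a label mismatch is symmetric, crosstalk points necessarily
appear on both ends of every mismatched edge; an annotation that
yields an exact target set must therefore place those edges among the
targets. The packaged annotation over nine pathways (cGAS-STING, IFN1,
IL-6, IL-10, EGF/EGFR, ADP/AMP, LPS/TLR4, autophagy, JAK/STAT) is a
hand-curated, editable interpretation of the pathway narrative — it is
shipped as data (`write_annotation()`), not inferred from a database —
and under it exactly six nodes score positively: JAK1/TYK2, the STAT3
dimer, PI3K, nuclear FOXO1 and FOXO3a, and the phagophore.

## Synthetic models and what the tests show

`random_model()` draws seeded random kinetic models with the same
structural statistics the analyses assume: several compartments, the
three rate-law families in configurable proportions, initial amounts
log-uniform in 10^3–10^6, stoichiometries of 1–2, a spanning
construction that keeps the reaction graph connected, and the
gene-template convention for Hill steps (which also keeps trajectories
non-negative). `perturb_model()` jitters parameters log-uniformly and
`random_graph()` supplies Erdős–Rényi fixtures for the centrality
oracles. Determinism under seed is the master invariant; generators
save and restore the global RNG state.

These synthetic families are the test bed for the machinery — forward
sensitivities against finite differences, centralities against
enumeration oracles, SBML round trips — but they do not claim to match
the unpublished parameter distribution of any real model, and passing
them demonstrates correctness of the algorithms, not biological
validity of a particular parameterization.

## Problem sizes and reproducibility

The shipped analyses run at desk scale: the curated model (89 states,
~190 sensitivity inputs) simulates in a few seconds and completes the
full sensitivity pass in well under a minute; oracle suites use 5-10
node fixtures where exhaustive enumeration is feasible. All stochastic
stages (EPC, generators) require explicit seeds, and the pipeline
manifest is byte-reproducible for a fixed model and seed.

## Known limitations

* Rate constants are calibrated defaults, not fitted values; absolute
  simulated fluxes and sensitivities are parameterization-dependent.
* No stochastic simulation, events, dosing, or parameter estimation.
* The SBML layer covers the package's own three-family subset of Level
  3 Version 2; foreign kinetic laws are rejected with a named error
  rather than approximated.
* Crosstalk results are only as good as the pathway annotation, which
  is interpretive by construction.
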
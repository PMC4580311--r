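---
title: "Methods: compartmentalized methylotrophic metabolism, 13C labeling, and multi-omics regulation calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmentalized methylotrophic metabolism, 13C labeling, and multi-omics regulation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xumpflux)
```

# The biological problem

Methylotrophic yeasts such as *Pichia pastoris* (*Komagataella* spp.) grow
on methanol by oxidizing it to formaldehyde inside peroxisomes (alcohol
oxidase, with stoichiometric hydrogen peroxide detoxified by catalase) and
then either dissimilating the formaldehyde to CO~2~ for energy (two NADH
per methanol) or assimilating it via dihydroxyacetone synthase (DAS), which
condenses formaldehyde onto xylulose-5-phosphate. Regeneration of that
pentose acceptor is the crux of the pathway: the xylulose-monophosphate
(XuMP) cycle rearranges sugar phosphates so that three fixed formaldehyde
leave one net triose phosphate for biosynthesis, in close analogy to the
Calvin cycle. A duplicated, methanol-inducible and peroxisomally targeted
enzyme set (aldolase, transaldolase, pentose-phosphate isomerase and
epimerase isoforms, and the sedoheptulose-1,7-bisphosphatase Shb17)
supports a fully compartmentalized cycle that runs through
sedoheptulose-1,7-bisphosphate, rather than borrowing the cytosolic
non-oxidative pentose phosphate pathway.

`xumpflux` makes that systems-level analysis executable: a
compartment-resolved stoichiometric model with carbon atom maps, a
steady-state ^13^C label simulator and flux estimator, chemostat balance
arithmetic, the transcript/protein regulation-calling rules, and
peroxisome-enrichment scoring - each stage paired with a seeded synthetic
data generator so the whole pipeline is testable without any external
data.

# The metabolic model

The shipped model (`load_network(xump_model_path())`) has 52 metabolites
and 46 reactions across four compartments (suffixes `_e`, `_c`, `_p`,
`_m`). Identical species in different compartments are distinct
metabolites and transport steps are explicit reactions, because the
central scientific claim being encoded is compartmentalization. Carbon
indices are 1-based with C1 at the carbonyl end of sugars; triose
phosphates are numbered so DHAP C1 carries the phosphate, matching
fructose-bisphosphate C1.

Choices worth knowing:

* **Lumping.** GAPDH/PGK, PGM/enolase, the oxidative PPP
  (G6P &rarr; Ru5P + CO~2~ + 2 NADPH), citrate synthase through isocitrate
  dehydrogenase, and the respiratory chain are single lumped reactions;
  the lumping table travels inside the model JSON. The model therefore
  documents its own reaction count (46) rather than matching any
  particular published count.
* **Cofactors** (ATP, NAD(P)H, FADH~2~, O~2~, H~2~O~2~, glutathione, ...)
  are conserved moieties: they are excluded from the balanced rows of the
  stoichiometric matrix, carry no traced carbons, and their net production
  under a flux vector is reported by `cofactor_trace()`. Carbon balance is
  enforced for every reaction; full elemental balance is advisory and
  checked only where all participants carry formulas.
* **Molecular symmetry.** Dihydroxyacetone, succinate, and fumarate are
  symmetric molecules; the corresponding reactions carry two equally
  weighted atom maps (identity and reversal), which the simulator expands
  into parallel half-flux edges.
* **Biomass** drain coefficients are literature-typical yeast precursor
  demands (mmol/gCDW), clearly marked in the model file as defaults not
  measured in this study; they enter the stoichiometric matrix as a
  `BIOMASS` pseudo-reaction on request.
* **Variants.** `build_variant(net, "classical_ppp")` removes the nine
  peroxisomal rearrangement reactions (no Shb17, no
  sedoheptulose-1,7-bisphosphate) and adds pentose/triose transporters so
  the cytosolic non-oxidative PPP regenerates xylulose-5-phosphate. Both
  topologies are carbon balanced and achieve the same net
  3 HCHO &rarr; 1 GAP conversion - their stoichiometric equivalence is
  exactly why the localization question needed proteome and labeling
  evidence, and the package asserts it as an invariant:

```{r net-reactions}
net <- load_network(xump_model_path())
net_reaction(net, xump_cycle_multiset(), keep = c("HCHO_p", "GAP_p"))
net_reaction(net, dissimilation_multiset(), keep = c("HCHO_c", "CO2_c"))
```

# Label simulation

`simulate_mdvs()` propagates substrate labeling (e.g. 20 % fully
^13^C-labelled methanol plus 80 % at the natural ^13^C abundance of
0.0107, built by `tracer_mixture()`) to the mass distribution vectors
(MDVs) of measured fragments at metabolic and isotopic steady state. The
implementation uses the elementary metabolite unit (EMU) decomposition:
only the carbon subsets that can influence a measured fragment are
tracked, grouped by size, and each size solves one linear system; products
assembled from several precursor units take the convolution of the factor
MDVs. Reversible reactions carry a net and a non-negative exchange flux
(forward `max(v,0)+exch`, backward `max(-v,0)+exch`); boundary pools not
named in the labeling are fed at natural abundance.

Two independent routes compute the same quantity:

* `simulate_mdvs()` - the EMU cascade (production code);
* `brute_force_isotopomers()` - a fixed-point iteration on the full
  2^n^ positional-isotopomer distribution of every reachable pool
  (capped at 25 carbons total). Condensation reactions between two
  intracellular pools make the full isotopomer system bilinear, so the
  oracle iterates to its unique steady state (tolerance 10^-13^) instead
  of attempting a one-shot linear solve.

The test suite demands agreement to 10^-9^ on every fixture, plus the
closed-form limits: natural-abundance-only labeling gives binomial MDVs,
pure tracer puts all mass in m~n~, and MDVs are invariant under uniform
flux scaling.

The default fragment table (`default_fragment_map()`) is the field's
conventional amino-acid-to-precursor backbone mapping (Ala&larr;pyruvate,
Ser/Gly&larr;3-phosphoglycerate, Asp/Thr&larr;oxaloacetate,
Glu&larr;&alpha;-ketoglutarate, Val&larr;2&times;pyruvate,
Phe&larr;2&times;PEP+erythrose-4-phosphate). It is a documented convention,
configurable via `fragment_map()`; measured MDVs are assumed already
corrected for derivatization-atom isotopes.

# Flux estimation

`fit_fluxes()` minimizes the variance-weighted sum of squared residuals
`sum(((sim - meas)/sd)^2)` over a free-flux basis of the steady-state null
space (`parameterize_free_fluxes()`), optionally augmented with exchange
fluxes bounded in `[0, 10 x uptake]` - unbounded exchange makes the EMU
systems ill-conditioned. Design choices:

* Bounded Levenberg-Marquardt (minpack.lm) with `n_starts` random
  initializations from a mandatory seed; no hidden RNG anywhere.
  Convergence tolerances: gradient 10^-8^, step 10^-10^.
* Measured extracellular rates (uptake reactions, CER, OUR, growth rate)
  enter as additional weighted residuals, never as hard equalities,
  because measured rates carry stated uncertainties.
* Irreversibility bounds are enforced by penalty residuals on the net
  fluxes; fitted solutions satisfy `max|S v| < 1e-8 max|v|` by
  construction of the basis.
* Identifiability is checked by the numerical rank of the measurement
  Jacobian at the optimum (relative tolerance 10^-7^ plus an absolute
  sensitivity floor of 10^-4^ sd-units per unit flux); unidentifiable
  parameter sets produce a warning, never a silent fix.
* `monte_carlo_ci()` gives parametric-bootstrap percentile intervals:
  measurements re-perturbed at their stated sds, refit warm-started from
  the point estimate.
* `normalize_fluxes()` reports percent Cmol: flux times carbons moved,
  relative to the carbon uptake of a basis reaction.

Statistical calibration is tested rather than assumed: on the built-in
scrambling toy (one free flux), noise-free recovery is exact to 10^-3^
relative with SSR &rarr; 0; the SSR over 20 noisy replicates stays within
`[dof/2, 2 dof]` of the chi-square expectation; and the bootstrap 95 %
interval covers the true flux in a binomially consistent fraction of 200
simulations. The toy is small deliberately - each fit takes well under a
second, so the 200-simulation coverage study runs in about a minute -
and the identical machinery drives the full model.

# Chemostat physiology

`biomass_yield()` computes Y~X/S~ = D / &Sigma; q~s~MW~s~;
`reduction_balance()` closes the electron balance
(4·OUR + &gamma;~X~·&mu;~Cmol~) / &Sigma; q~s~&gamma;~s~ with degrees of
reduction per carbon of 4.0 (glucose), 4.67 (glycerol), 6.0 (methanol) and
configurable biomass parameters (&gamma;~X~ = 4.2, 26.4 g/Cmol - literature
values, not measured here). Feed glucose is dosed as the monohydrate; the
anhydrous molecular weight 180.16 g/mol is used with the conversion
documented here (180.16/198.17 for feed-based cross-checks).
`monoisotopic_mz()` covers the exact-mass identification arithmetic (the
[M-H]^-^ ion of sedoheptulose-1,7-bisphosphate, C~7~H~16~O~13~P~2~, at m/z
368.9993). Report rounding is two decimals for yields and log~2~ fold
changes, matching the source tables; full precision is kept internally.
The shipped growth-parameter table records a known rounding quirk: the CO~2~
exchange rates print as a ~12 % difference while the running text calls it
13 %, presumably from unrounded source values.

# Omics regulation calls

Transcripts: significantly regulated when FC &ge; 1.5 (inclusive - the
boundary phrasing is ambiguous in common usage, so the inclusive reading
is documented) with Benjamini-Yekutieli adjusted p < 0.05. The BY
adjustment is the `c(m) = sum(1/i)` step-up variant valid under arbitrary
dependence; `by_adjust()` wraps `stats::p.adjust(method = "BY")` and the
tests pin it to hand-computed values. Proteins: two significance tiers
(|FC| > 1.5 with p < 0.1, or 1.3 < |FC| &le; 1.5 with p < 0.05), both
requiring > 50 % of identified replicates to agree in direction;
|FC| &le; 1.3 with p > 0.05 is unchanged; everything else is excluded from
further analysis. Fold-change magnitude is symmetric
(|FC| = max(FC, 1/FC)).

`classify_pairs()` places each gene in the 3&times;3 grid of transcript
&times; protein calls; unchanged/unchanged is the background and the
differential fraction is 1 minus the background share of complete pairs.
All non-empty cells are reported; any seven-group presentation is a view
of whichever cells are populated. Genes without a transcript measurement
form their own `not_available` category and are excluded from the Pearson
correlation (`correlate_pairs()`).

# Proteome quantification

`filter_peptides()` applies the three exclusion rules - ion intensity
below 300, protein ratios deriving from a single peptide spectrum,
proteins identified in fewer than three replicates - and logs every
exclusion with its reason. `protein_ratio()` removes peptide log-ratios
outside median &plusmn; 1.5 IQR (the upstream software's exact outlier rule
is unpublished; this default is configurable), averages the rest with
optional inverse-variance weights, and tests the mean against zero with a
t-test. `enrichment_ratios()` computes summed peroxisome/homogenate peak
area ratios normalized so the reference protein (Aox1) is exactly 1;
proteins absent from homogenates are flagged `only_in_pex` (">>1"),
proteins absent from peroxisomal preparations get ratio 0.

`pts1_screen()` is deliberately a simple C-terminal tripeptide screen
([SAC][KRH][LM], with a configurable twilight table and an exception list
for Aox1's unusual -ARF tail), not a re-implementation of machine-learned
PTS1 predictors; the shipped reference verdicts serve as a regression
fixture, and with the default tables the screen reproduces all of them.

# Synthetic data

Every generator is a pure function of its spec; RNG streams derive from
(seed, stage name) so adding a stage never shifts another stage's draws.

* `gen_mdv_dataset()`: simulated MDVs plus additive Gaussian noise per
  mass isotopomer (default sd 0.004), clipped at zero and renormalized to
  sum 1 (common MFA practice; renormalization shrinks the per-entry sd by
  sqrt(1-1/k), which the calibration test accounts for).
* `gen_omics_tables()`: 575 genes, 130 planted regulated pairs in grid
  cells dominated by concordant up-regulation, background log~2~FC pairs
  drawn from a correlated bivariate normal (&rho; = 0.78) truncated below
  the unchanged threshold so zero-noise recovery is exact; replicate
  structure is 3 transcript and 6 protein replicates with p-values from
  one-sample t-tests of the replicate fold changes. With replicate noise
  exactly 0 the t-statistics are degenerate, so p is emitted as 0 for
  planted effects and 1 otherwise.
* `gen_peptide_table()`: per-peptide lognormal base abundances, planted
  enrichment factors, and planted `only_in_pex`/`absent_in_pex` proteins.
* `gen_chemostat_obs()`: a truth constructed to close carbon and electron
  balances exactly (CER from the carbon balance, OUR from the
  degree-of-reduction balance), with relative Gaussian observation noise.

What passing these tests shows - and does not show - about real data: the
generators reproduce the *statistical structure* each stage assumes
(noise law, replicate design, planted effects), so the tests certify the
algorithms, not the biology. Real measurements add systematic effects the
generators do not emulate: correlated mass-spectrometric noise and
derivatization artifacts in MDVs, normalization residuals and
probe-specific biases in microarrays, shared-peptide ambiguity in
proteomics, and model misspecification in the network itself.

# Known limitations

* Steady-state ^13^C analysis only; no transient labeling.
* The model is a documented 46-reaction core, not a genome-scale
  reconstruction; no thermodynamic or kinetic layer.
* Measured MDVs must be pre-corrected for derivatization atoms.
* The brute-force oracle is limited to 25 carbons by design.
* The PTS1 screen is a motif lookup, not a predictor.
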
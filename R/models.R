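# Canonical reaction multisets of the shipped model, and small built-in
# networks used in examples, tests, and the demo pipeline.

#' Reaction multiset of the peroxisomal XuMP cycle
#'
#' Fixing three formaldehyde onto xylulose-5-phosphate and regenerating the
#' three pentose phosphates through the sedoheptulose-1,7-bisphosphate
#' route leaves one net triose phosphate: the multiset sums to
#' 3 HCHO + 3 ATP + 2 H2O -> GAP + 3 ADP + 2 Pi.
#'
#' @return named numeric vector of reaction multiplicities.
#' @export
xump_cycle_multiset <- function() {
  c(DAS = 3, DAK = 3, TPI_p = 1, FBA_p = 1, FBP_p = 1, TKL_p1 = 1,
    SBA = 1, SHB17 = 1, TKL_p2 = 1, RKI_p = 1, RPE_p = 1)
}

#' Reaction multiset of cytosolic formaldehyde dissimilation
#'
#' Glutathione-dependent formaldehyde oxidation to CO2:
#' HCHO + 2 NAD+ + H2O -> CO2 + 2 NADH.
#' @return named numeric vector of reaction multiplicities.
#' @export
dissimilation_multiset <- function() c(FLD = 1, FGH = 1, FDH = 1)

#' Full methanol assimilation multiset (uptake through triose export)
#'
#' Adds methanol uptake, alcohol oxidase, catalase, and peroxisomal triose
#' export to the XuMP cycle: 3 MeOH + 1.5 O2 + 3 ATP ->
#' GAP(cytosol) + 3 ADP + 2 Pi + H2O.
#' @return named numeric vector of reaction multiplicities.
#' @export
methanol_assimilation_multiset <- function() {
  c(MEOH_up = 3, AOX = 3, CTA1 = 1.5, xump_cycle_multiset(), T_GAP = 1)
}

#' Recycling multiset of the classical-PPP variant
#'
#' The same 3 HCHO -> 1 GAP conversion routed through the cytosolic
#' non-oxidative pentose phosphate pathway (negative multiplicities run
#' reversible reactions backwards).
#' @return named numeric vector of reaction multiplicities.
#' @export
classical_recycling_multiset <- function() {
  c(DAS = 3, DAK = 3, T_DHAP = 3, T_GAP = 3, T_X5P = 3, TPI_c = 1,
    FBA_c = -2, FBPase = 2, TKL1b = -1, TAL1 = -1, TKL1a = -1,
    RKI_c = -1, RPE_c = 1)
}

#' Two-carbon scrambling toy network
#'
#' A two-carbon substrate is taken up into pool A and converted to pool B
#' along two routes: a direct isomerization preserving the carbon pairing,
#' and a cleavage/recombination route through two one-carbon pools that
#' decorrelates the carbons. With a correlated tracer (e.g. 20 % U-13C),
#' the B mass distribution identifies the flux partitioning; the network
#' has one free flux. Used in examples and parameter-recovery tests.
#'
#' @return a [metabolic_network()] with reactions `upt`, `direct`, `clv`,
#'   `rec`, `out`.
#' @export
toy_scramble_network <- function() {
  mets <- data.frame(
    id = c("S_e", "A", "X1", "X2", "B", "B_e"),
    compartment = c("extracellular", rep("cytosol", 4), "extracellular"),
    carbons = c(2, 2, 1, 1, 2, 2),
    role = c("exchange", "balanced", "balanced", "balanced", "balanced",
             "exchange"),
    stringsAsFactors = FALSE)
  rxns <- list(
    reaction("upt", c(S_e = -1, A = 1),
             atom_map = list(A = "S_e@1,S_e@2")),
    reaction("direct", c(A = -1, B = 1), reversible = TRUE,
             atom_map = list(B = "A@1,A@2")),
    reaction("clv", c(A = -1, X1 = 1, X2 = 1),
             atom_map = list(X1 = "A@1", X2 = "A@2")),
    reaction("rec", c(X1 = -1, X2 = -1, B = 1),
             atom_map = list(B = "X1@1,X2@1")),
    reaction("out", c(B = -1, B_e = 1),
             atom_map = list(B_e = "B@1,B@2")))
  metabolic_network(mets, rxns, variant = "toy", id = "toy_scramble")
}

#' Steady-state flux vector of the scrambling toy
#'
#' @param f fraction of pool A converted through the direct route.
#' @param uptake substrate uptake flux (default 1).
#' @return named flux vector at steady state.
#' @export
toy_scramble_fluxes <- function(f, uptake = 1) {
  if (f < 0 || f > 1) stopf("f must be in [0,1]")
  c(upt = uptake, direct = f * uptake, clv = (1 - f) * uptake,
    rec = (1 - f) * uptake, out = uptake)
}

#' Linear chain toy network (A -> B -> C)
#' @return a [metabolic_network()].
#' @export
toy_chain_network <- function() {
  mets <- data.frame(
    id = c("A_e", "A", "B", "C", "C_e"),
    compartment = c("extracellular", rep("cytosol", 3), "extracellular"),
    carbons = c(2, 2, 2, 2, 2),
    role = c("exchange", "balanced", "balanced", "balanced", "exchange"),
    stringsAsFactors = FALSE)
  rxns <- list(
    reaction("upt", c(A_e = -1, A = 1), atom_map = list(A = "A_e@1,A_e@2")),
    reaction("v1", c(A = -1, B = 1), atom_map = list(B = "A@1,A@2")),
    reaction("v2", c(B = -1, C = 1), atom_map = list(C = "B@1,B@2")),
    reaction("out", c(C = -1, C_e = 1), atom_map = list(C_e = "C@1,C@2")))
  metabolic_network(mets, rxns, variant = "toy", id = "toy_chain")
}

#' Branched toy network (uptake splitting into two drains)
#' @return a [metabolic_network()].
#' @export
toy_split_network <- function() {
  mets <- data.frame(
    id = c("A_e", "A", "B", "C", "B_e", "C_e"),
    compartment = c("extracellular", rep("cytosol", 3),
                    "extracellular", "extracellular"),
    carbons = rep(2, 6),
    role = c("exchange", rep("balanced", 3), "exchange", "exchange"),
    stringsAsFactors = FALSE)
  rxns <- list(
    reaction("upt", c(A_e = -1, A = 1), atom_map = list(A = "A_e@1,A_e@2")),
    reaction("vB", c(A = -1, B = 1), atom_map = list(B = "A@1,A@2")),
    reaction("vC", c(A = -1, C = 1), atom_map = list(C = "A@1,A@2")),
    reaction("outB", c(B = -1, B_e = 1), atom_map = list(B_e = "B@1,B@2")),
    reaction("outC", c(C = -1, C_e = 1), atom_map = list(C_e = "C@1,C@2")))
  metabolic_network(mets, rxns, variant = "toy", id = "toy_split")
}
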
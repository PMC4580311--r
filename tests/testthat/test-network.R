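# Compartmentalized network: loading, balance validation, net reactions,
# cofactor bookkeeping, stoichiometric matrix, variants.

test_that("shipped model loads with the XuMP cycle enzymes present", {
  net <- shipped_model()
  expect_s3_class(net, "metabolic_network")
  expect_true(all(c("DAS", "DAK", "FBA_p", "FBP_p", "SHB17", "TKL_p1",
                    "TKL_p2", "RKI_p", "RPE_p", "SBA") %in%
                    names(net$reactions)))
  expect_true(all(c("S17BP_p", "X5P_p", "S7P_p") %in% net$metabolites$id))
  expect_identical(net$variant, "xump_peroxisomal")
})

test_that("structural errors are rejected at load time", {
  mets <- data.frame(id = c("A", "B"), compartment = "cytosol",
                     carbons = c(2, 2), stringsAsFactors = FALSE)
  expect_error(
    metabolic_network(mets, list(reaction("r", c(A = -1, C = 1)))),
    "undeclared metabolite")
  expect_error(
    metabolic_network(rbind(mets, mets[1, ]), list()),
    "duplicate metabolite")
  expect_error(
    metabolic_network(transform(mets, compartment = "vacuole"), list()),
    "unknown compartment")
  # carbon count disagreeing with the formula
  bad <- data.frame(id = "A", compartment = "cytosol", carbons = 3,
                    formula = "C2H4O2", role = "balanced",
                    stringsAsFactors = FALSE)
  expect_error(metabolic_network(bad, list()), "disagrees with formula")
  # empty reaction list is a valid network
  empty <- metabolic_network(mets, list())
  expect_length(empty$reactions, 0)
  expect_equal(nrow(validate_balance(empty)), 0)
})

test_that("every shipped reaction is carbon balanced with bijective atom maps", {
  rep <- validate_balance(shipped_model())
  expect_true(all(rep$carbon_ok))
  expect_true(all(rep$atom_map_ok[!is.na(rep$atom_map_ok)]))
  expect_true(all(rep$element_ok[!is.na(rep$element_ok)]))
})

test_that("element imbalance is flagged when a product is deleted", {
  net <- shipped_model()
  rx <- net$reactions$SHB17
  rx$stoich <- rx$stoich[setdiff(names(rx$stoich), "Pi")]
  mets <- net$metabolites
  broken <- metabolic_network(mets, list(rx))
  rep <- validate_balance(broken)
  expect_false(rep$element_ok[rep$reaction == "SHB17"])
  # carbon balance still holds: only phosphate was removed
  expect_true(rep$carbon_ok[rep$reaction == "SHB17"])
})

test_that("XuMP cycle multiset nets one triose phosphate per three formaldehyde", {
  net <- shipped_model()
  nr <- net_reaction(net, xump_cycle_multiset(), keep = c("HCHO_p", "GAP_p"))
  expect_equal(nr[["HCHO_p"]], -3)
  expect_equal(nr[["GAP_p"]], 1)
  expect_equal(nr[["ATP"]], -3)
  expect_equal(nr[["ADP"]], 3)
  expect_equal(nr[["Pi"]], 2)
  expect_equal(nr[["H2O"]], -2)
  expect_length(nr, 6)
})

test_that("net_reaction rejects non-cancelling multisets and handles edge cases", {
  net <- shipped_model()
  # dropping the epimerase leaves RU5P_p uncancelled
  bad <- xump_cycle_multiset()
  bad <- bad[names(bad) != "RPE_p"]
  expect_error(net_reaction(net, bad, keep = c("HCHO_p", "GAP_p")),
               "do not cancel")
  expect_length(net_reaction(net, numeric(0)), 0)
  expect_error(net_reaction(net, c(nonexistent = 1)), "unknown reaction")
  expect_error(net_reaction(net, c(DAS = -1), keep = c("HCHO_p")),
               "irreversible")
})

test_that("dissimilation yields two NADH per formaldehyde", {
  net <- shipped_model()
  nr <- net_reaction(net, dissimilation_multiset(),
                     keep = c("HCHO_c", "CO2_c"))
  expect_equal(nr[["HCHO_c"]], -1)
  expect_equal(nr[["NADH"]], 2)
  expect_equal(nr[["NAD"]], -2)
  expect_equal(nr[["CO2_c"]], 1)
})

test_that("cofactor_trace reproduces oxygen and NADPH stoichiometry", {
  net <- shipped_model()
  # AOX consumes one O2 per methanol, catalase returns half
  tr <- cofactor_trace(net, c(AOX = 1, CTA1 = 0.5))
  expect_equal(tr[["O2"]], -0.5)
  expect_equal(cofactor_trace(net, c(ZWF_lump = 1))[["NADPH"]], 2)
  dis <- cofactor_trace(net, c(FLD = 1, FGH = 1, FDH = 1))
  expect_equal(dis[["NADH"]], 2)
  expect_true(all(cofactor_trace(net, c(DAS = 0, PGI = 0)) == 0))
  expect_error(cofactor_trace(net, c(bogus = 1)), "unknown reaction")
})

test_that("stoichiometric matrix closes over cancelling multisets", {
  net <- shipped_model()
  S <- stoichiometric_matrix(net)
  expect_identical(attr(S, "isolated"), character(0))
  ms <- xump_cycle_multiset()
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  v[names(ms)] <- ms
  imbal <- as.numeric(S %*% v)
  names(imbal) <- rownames(S)
  internal <- setdiff(rownames(S), c("HCHO_p", "GAP_p"))
  expect_true(all(abs(imbal[internal]) < 1e-12))
  expect_equal(imbal[["GAP_p"]], 1)
  # toy chain: internal columns balance
  S2 <- stoichiometric_matrix(toy_chain_network())
  expect_equal(dim(S2), c(3L, 4L))
  # isolated metabolite flagged
  iso <- metabolic_network(
    data.frame(id = c("A", "Z"), compartment = "cytosol", carbons = 1,
               stringsAsFactors = FALSE),
    list(reaction("r", c(A = -1), atom_map = NULL)))
  expect_identical(attr(stoichiometric_matrix(iso), "isolated"), "Z")
})

test_that("classical-PPP variant removes the peroxisomal rearrangements but keeps the net conversion", {
  net <- shipped_model()
  cl <- build_variant(net, "classical_ppp")
  expect_false("SHB17" %in% names(cl$reactions))
  expect_false("S17BP_p" %in% cl$metabolites$id)
  expect_true(all(c("T_X5P", "T_DHAP") %in% names(cl$reactions)))
  rep <- validate_balance(cl)
  expect_true(all(rep$carbon_ok))
  nr <- net_reaction(cl, classical_recycling_multiset(),
                     keep = c("HCHO_p", "GAP_c"))
  expect_equal(nr[["HCHO_p"]], -3)
  expect_equal(nr[["GAP_c"]], 1)
  # idempotence and unknown tags
  expect_identical(build_variant(net, "xump_peroxisomal"), net)
  expect_error(build_variant(net, "no_such_variant"), "unknown variant")
})

test_that("methanol assimilation multiset exports one cytosolic triose per three methanol", {
  nr <- net_reaction(shipped_model(), methanol_assimilation_multiset(),
                     keep = "GAP_c")
  expect_equal(nr[["MEOH_e"]], -3)
  expect_equal(nr[["GAP_c"]], 1)
  expect_equal(nr[["O2"]], -1.5)
})

test_that("atom map parsing round-trips and validates positions", {
  am <- parse_atom_map(list(GAP = "X5P@3, X5P@4, X5P@5"))
  expect_identical(am$GAP$sub, rep("X5P", 3))
  expect_identical(am$GAP$pos, 3:5)
  expect_error(parse_atom_map(list(GAP = "X5P-3")), "malformed")
})
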
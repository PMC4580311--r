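# EMU decomposition, MDV simulation, and agreement with the brute-force
# isotopomer oracle.

test_that("natural_abundance_mdv is the binomial closed form", {
  expect_equal(natural_abundance_mdv(0), 1)
  expect_equal(natural_abundance_mdv(2, 0.5), c(0.25, 0.5, 0.25))
  expect_equal(natural_abundance_mdv(3, 0.0107)[1], (1 - 0.0107)^3)
  expect_error(natural_abundance_mdv(2, 1.2), "0,1")
  expect_error(natural_abundance_mdv(-1), ">= 0")
})

test_that("EMU decomposition traces fragments to their precursor carbons", {
  # identity toy: B[1,2] resolves to {B[1,2], A[1,2]}
  chain <- toy_chain_network()
  dec <- emu_decompose(chain, fragment_map(list(B = list(B = 1:2))))
  expect_setequal(dec$emus$emu, c("B|1,2", "A|1,2", "A_e|1,2"))
  # DAS: GAP[1,2,3] derives from carbons 3-5 of xylulose-5-phosphate
  net <- shipped_model()
  dec2 <- emu_decompose(net, fragment_map(list(GAP = list(GAP_p = 1:3))))
  expect_true("X5P_p|3,4,5" %in% dec2$emus$emu)
  # every EMU term conserves summed EMU size
  for (key in names(dec2$terms)) {
    sz <- dec2$info[[key]]$size
    for (tm in dec2$terms[[key]]) {
      fsz <- sum(vapply(tm$factors, function(f) dec2$info[[f]]$size, 0L))
      expect_identical(fsz, sz)
    }
  }
})

test_that("degenerate labeling gives the closed-form MDVs", {
  s <- scramble_setup()
  fl <- toy_scramble_fluxes(0.35)
  # natural abundance only: binomial for every fragment
  nat <- substrate_labeling(S_e = list(list(weight = 1, pattern = "natural")))
  m <- simulate_mdvs(s$net, fl, nat, s$fr)
  expect_equal(m$mdvs$A, natural_abundance_mdv(2), tolerance = 1e-12)
  expect_equal(m$mdvs$B, natural_abundance_mdv(2), tolerance = 1e-12)
  # 100 % U-13C, no natural abundance: all mass in m_n
  u <- substrate_labeling(S_e = list(list(weight = 1, pattern = "U")),
                          natural_p13 = 0)
  mu_ <- simulate_mdvs(s$net, fl, u, s$fr)
  expect_equal(mu_$mdvs$B, c(0, 0, 1), tolerance = 1e-12)
  # no tracer, no natural abundance: everything m0
  zero <- substrate_labeling(S_e = list(list(weight = 1, pattern = c(0, 0))),
                             natural_p13 = 0)
  m0 <- simulate_mdvs(s$net, fl, zero, s$fr)
  expect_equal(m0$mdvs$A, c(1, 0, 0))
  expect_equal(m0$mdvs$B, c(1, 0, 0))
})

test_that("EMU and brute-force oracle agree on every toy fixture", {
  s <- scramble_setup()
  fr3 <- fragment_map(list(A = list(A = 1:2), B = list(B = 1:2),
                           X1 = list(X1 = 1),
                           AB = list(A = 1:2, B = 1:2)))  # convolution part
  for (f in c(0, 0.3, 0.62)) {
    fl <- toy_scramble_fluxes(f)
    emu <- simulate_mdvs(s$net, fl, s$lab, fr3)
    bf <- brute_force_isotopomers(s$net, fl, s$lab, fr3)
    for (fn in names(fr3))
      expect_equal(emu$mdvs[[fn]], bf$mdvs[[fn]], tolerance = 1e-9)
    expect_mdv_valid(emu)
  }
  # at f = 1 the cleavage pools are bypassed entirely
  fl1 <- toy_scramble_fluxes(1)
  expect_equal(simulate_mdvs(s$net, fl1, s$lab, s$fr)$mdvs$B,
               brute_force_isotopomers(s$net, fl1, s$lab, s$fr)$mdvs$B,
               tolerance = 1e-9)
  # chain and split toys, different tracer fraction
  chain <- toy_chain_network()
  labA <- tracer_mixture("A_e", 0.5)
  frC <- fragment_map(list(C = list(C = 1:2)))
  flc <- c(upt = 2, v1 = 2, v2 = 2, out = 2)
  expect_equal(simulate_mdvs(chain, flc, labA, frC)$mdvs$C,
               brute_force_isotopomers(chain, flc, labA, frC)$mdvs$C,
               tolerance = 1e-9)
})

test_that("MDVs are invariant under uniform flux scaling", {
  s <- scramble_setup()
  m1 <- simulate_mdvs(s$net, toy_scramble_fluxes(0.4, uptake = 1), s$lab, s$fr)
  m7 <- simulate_mdvs(s$net, toy_scramble_fluxes(0.4, uptake = 7.3), s$lab, s$fr)
  expect_equal(m1$mdvs, m7$mdvs, tolerance = 1e-12)
})

test_that("reversible exchange flux mixes labeling across pools", {
  # with infinite exchange the A and B pools equilibrate; with none, B
  # inherits only the scrambled route at f = 0
  s <- scramble_setup()
  fl <- list(net = as.list(toy_scramble_fluxes(0)),
             exch = list(direct = 0))
  m_noex <- simulate_mdvs(s$net, fl, s$lab, s$fr)
  fl$exch$direct <- 50
  m_ex <- simulate_mdvs(s$net, fl, s$lab, s$fr)
  # direct route carries correlated labeling into B only via exchange
  expect_gt(m_ex$mdvs$B[3], m_noex$mdvs$B[3])
  bf <- brute_force_isotopomers(s$net, fl, s$lab, s$fr)
  expect_equal(m_ex$mdvs$B, bf$mdvs$B, tolerance = 1e-9)
})

test_that("simulation rejects invalid inputs", {
  s <- scramble_setup()
  bad <- toy_scramble_fluxes(0.5)
  bad[["out"]] <- 0.5  # pool B accumulates
  expect_error(simulate_mdvs(s$net, bad, s$lab, s$fr), "steady state")
  expect_error(simulate_mdvs(s$net, c(toy_scramble_fluxes(0.5), zz = 1),
                             s$lab, s$fr), "unknown reaction")
  # fragment on a pool unreachable at this flux distribution
  frX <- fragment_map(list(X1 = list(X1 = 1)))
  expect_error(simulate_mdvs(s$net, toy_scramble_fluxes(1), s$lab, frX),
               "unreachable")
})

test_that("brute-force oracle enforces its state-space limit", {
  s <- scramble_setup()
  expect_error(
    brute_force_isotopomers(s$net, toy_scramble_fluxes(0.5), s$lab, s$fr,
                            max_carbons = 3L),
    "state space too large")
  # pass-through: single pool inherits substrate labeling unchanged
  chain <- toy_chain_network()
  labA <- tracer_mixture("A_e", 0.3)
  frA <- fragment_map(list(A = list(A = 1:2)))
  fl <- c(upt = 1, v1 = 1, v2 = 1, out = 1)
  m <- brute_force_isotopomers(chain, fl, labA, frA)
  exp_mdv <- 0.3 * c(0, 0, 1) + 0.7 * natural_abundance_mdv(2)
  expect_equal(m$mdvs$A, exp_mdv, tolerance = 1e-12)
})

test_that("full-model amino-acid MDVs are valid and tracer-responsive", {
  net <- shipped_model()
  v <- full_model_fluxes(net)
  lab <- tracer_mixture("MEOH_e", 0.2, others = "GLYC_e")
  m <- simulate_mdvs(net, v, lab, default_fragment_map())
  expect_length(m$mdvs, 8)
  expect_mdv_valid(m, tol = 1e-7)
  # methanol tracer must label Ala beyond natural abundance
  nat_m1 <- natural_abundance_mdv(3)[2]
  expect_gt(m$mdvs$Ala[2], nat_m1)
})

test_that("mdv_set enforces its invariants", {
  expect_error(mdv_set(list(f = c(0.5, 0.4))), "sums to")
  expect_error(mdv_set(list(f = c(1.2, -0.2))), "negative")
  expect_silent(mdv_set(list(f = c(0.25, 0.5, 0.25))))
})
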
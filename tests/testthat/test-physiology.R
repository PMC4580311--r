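# Chemostat balances, composition arithmetic, exact masses.

test_that("biomass yields reproduce the chemostat measurements", {
  glc <- growth_parameters_state("glucose")
  mg <- growth_parameters_state("methanol_glycerol")
  expect_equal(round(biomass_yield(glc), 2), 0.54)
  expect_equal(biomass_yield(mg), 0.57, tolerance = 0.01 / 0.57)
  # unit invariance: mol with kg/mol weights gives the same yield
  y1 <- biomass_yield(glc)
  st2 <- chemostat_state(D = 0.1, q_s = c(glucose = 1.02e-3))
  y2 <- st2$D / sum(st2$q_s * 180.16)
  expect_equal(y1, y2)
  expect_error(biomass_yield(chemostat_state(D = 0.1, q_s = c(glucose = 0))),
               "no substrate uptake")
})

test_that("electron balance closes on measured rates and flags missing oxygen", {
  glc <- growth_parameters_state("glucose")
  mg <- growth_parameters_state("methanol_glycerol")
  expect_gt(reduction_balance(glc, warn_open = FALSE), 0.90)
  expect_lt(reduction_balance(glc, warn_open = FALSE), 1.10)
  expect_gt(reduction_balance(mg, warn_open = FALSE), 0.90)
  expect_lt(reduction_balance(mg, warn_open = FALSE), 1.10)
  # exactly balanced synthetic state closes at 1
  tr <- gen_chemostat_obs(list(seed = 1, sd_rel = 0))$truth
  expect_equal(reduction_balance(tr, warn_open = FALSE), 1, tolerance = 1e-12)
  # consuming substrate with no oxygen uptake leaves the balance open
  open <- chemostat_state(D = 0.1, q_s = c(glucose = 1.02), OUR = 0)
  expect_warning(cl <- reduction_balance(open), "open")
  expect_lt(cl, 1)
  expect_error(reduction_balance(chemostat_state(D = 0.1, q_s = c(glucose = 1)),
                                 gamma = c(methanol = 6)),
               "degree of reduction")
})

test_that("protein synthesis rate is growth rate times protein content", {
  expect_equal(protein_synthesis_rate(0.1, 0.54), 0.054)
  expect_equal(protein_synthesis_rate(0.1, 0.40), 0.040)
  expect_equal(protein_synthesis_rate(0.1, 0), 0)
  expect_error(protein_synthesis_rate(-0.1, 0.5), "non-negative")
})

test_that("percent change matches the reported growth-parameter contrasts", {
  expect_equal(percent_change(0.40, 0.54), 35)
  expect_equal(round(percent_change(2.39, 3.09), 1), 29.3)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "positive")
  # reciprocity: applying the reverse change undoes the first
  p1 <- percent_change(2.39, 3.09); p2 <- percent_change(3.09, 2.39)
  expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1)
})

test_that("amino-acid composition arithmetic reproduces the table totals", {
  free <- aa_composition_table("free")
  cs_f <- composition_summary(data.frame(analyte = free$analyte,
                                         value_a = free$glucose,
                                         value_b = free$methanol_glycerol))
  expect_equal(round(cs_f$totals$log2fc, 2), -0.27)
  expect_equal(cs_f$totals$total_a, 52.1, tolerance = 0.002)
  expect_equal(cs_f$totals$total_b, 43.2, tolerance = 0.002)
  bound <- aa_composition_table("bound")
  cs_b <- composition_summary(data.frame(analyte = bound$analyte,
                                         value_a = bound$glucose,
                                         value_b = bound$methanol_glycerol))
  expect_equal(round(cs_b$totals$log2fc, 2), 0.55)
  ala <- cs_b$per_analyte[cs_b$per_analyte$analyte == "Ala", ]
  expect_equal(round(ala$log2fc, 2), 0.67)
  # identical columns: all fold changes zero
  same <- composition_summary(data.frame(analyte = "x", value_a = 2,
                                         value_b = 2))
  expect_equal(same$per_analyte$log2fc, 0)
  # zero denominator flags rather than crashes
  z <- composition_summary(data.frame(analyte = "x", value_a = 0,
                                      value_b = 1))
  expect_true(z$per_analyte$undefined_fc)
  expect_true(is.na(z$per_analyte$log2fc))
})

test_that("fatty-acid totals match the printed sums within rounding", {
  fa <- fatty_acid_table()
  cs <- composition_summary(data.frame(analyte = fa$analyte,
                                       value_a = fa$glucose,
                                       value_b = fa$methanol_glycerol))
  expect_equal(cs$totals$total_b, 10.67, tolerance = 0.02 / 10.67)
  expect_equal(cs$totals$total_a, 10.79, tolerance = 0.02 / 10.79)
})

test_that("monoisotopic masses match reference values to 1e-4", {
  # sedoheptulose-1,7-bisphosphate [M-H]-
  expect_equal(monoisotopic_mz("C7H16O13P2", "neg"), 368.9993,
               tolerance = 1e-4 / 368.9993)
  expect_equal(monoisotopic_mz("H2O"), 18.0106, tolerance = 1e-4 / 18)
  expect_equal(monoisotopic_mz("C6H12O6"), 180.0634, tolerance = 1e-4 / 180)
  expect_lt(abs(mass_ppm(368.9993, monoisotopic_mz("C7H16O13P2", "neg"))), 10)
  expect_error(monoisotopic_mz(""), "parse|empty")
  expect_error(monoisotopic_mz("C2Xx4"), "unknown element")
  # modes differ by two proton masses
  expect_equal(monoisotopic_mz("CH4O", "pos") - monoisotopic_mz("CH4O", "neg"),
               2 * 1.00727646688)
})

test_that("chemostat_state validates its invariants", {
  expect_error(chemostat_state(D = 0, q_s = c(glucose = 1)), "positive")
  expect_error(chemostat_state(D = 0.1, q_s = c(glucose = -1)),
               "non-negative")
})
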
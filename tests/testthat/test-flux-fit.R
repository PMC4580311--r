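# Free-flux parameterization, weighted least-squares flux estimation,
# normalization, and bootstrap confidence intervals.

test_that("free-flux dimension matches network degrees of freedom", {
  chain <- toy_chain_network()
  b0 <- parameterize_free_fluxes(chain, list(fixed = c(upt = 1)))
  expect_equal(b0$dim, 0L)
  v <- b0$v0
  expect_equal(unname(v[c("upt", "v1", "v2", "out")]), rep(1, 4))

  split <- toy_split_network()
  b1 <- parameterize_free_fluxes(split, list(fixed = c(upt = 1)))
  expect_equal(b1$dim, 1L)

  expect_error(
    parameterize_free_fluxes(chain, list(fixed = c(upt = 1),
                                         lower = c(v1 = 1),
                                         upper = c(v1 = 0))),
    "infeasible bounds")
  expect_error(
    parameterize_free_fluxes(chain, list(fixed = c(upt = 1, v1 = 2))),
    "infeasible constraints")
})

test_that("fitted fluxes satisfy steady state exactly", {
  s <- scramble_setup()
  truth <- toy_scramble_fluxes(0.7)
  clean <- simulate_mdvs(s$net, truth, s$lab, s$fr)
  meas <- measurement_set(
    mdv_set(clean$mdvs, sd = lapply(clean$mdvs, function(m) rep(0.004, length(m)))),
    rates = data.frame(quantity = "upt", value = 1, sd = 0.02),
    labeling = s$lab, fragments = s$fr)
  est <- fit_fluxes(s$net, meas, options = list(
    seed = 11, n_starts = 3, constraints = list(fixed = c(upt = 1))))
  S <- stoichiometric_matrix(s$net)
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  v[names(est$net)] <- est$net
  expect_lt(max(abs(S %*% v)), 1e-8 * max(abs(est$net)))
})

test_that("noise-free parameter recovery is exact on both model variants' toys", {
  # (primary recovery surface; the full-model variants share this machinery)
  s <- scramble_setup()
  for (f_true in c(0.25, 0.6)) {
    truth <- toy_scramble_fluxes(f_true)
    clean <- simulate_mdvs(s$net, truth, s$lab, s$fr)
    meas <- measurement_set(
      mdv_set(clean$mdvs, sd = lapply(clean$mdvs, function(m) rep(0.004, length(m)))),
      rates = data.frame(quantity = "upt", value = 1, sd = 0.02),
      labeling = s$lab, fragments = s$fr)
    est <- fit_fluxes(s$net, meas, options = list(
      seed = 7, n_starts = 5, constraints = list(fixed = c(upt = 1))))
    expect_lt(est$ssr, 1e-6)
    expect_lt(abs(est$net[["direct"]] - f_true) / max(f_true, 0.1), 1e-3)
  }
})

test_that("noisy-data SSR is consistent with the chi-square expectation", {
  s <- scramble_setup()
  truth <- toy_scramble_fluxes(0.6)
  ssrs <- vapply(seq_len(20), function(rep_i) {
    ds <- gen_mdv_dataset(s$net, truth, list(
      seed = 100 + rep_i, sd = 0.004, labeling = s$lab, fragments = s$fr))
    meas <- measurement_set(
      ds$replicates[[1]],
      rates = data.frame(quantity = "upt",
                         value = 1 + stats::rnorm(1, 0, 0.02), sd = 0.02),
      labeling = s$lab, fragments = s$fr)
    fit_fluxes(s$net, meas, options = list(
      seed = rep_i, n_starts = 2,
      constraints = list(fixed = c(upt = 1))))$ssr
  }, 0)
  dof <- 6  # 6 MDV entries + 1 rate - 1 free parameter
  m <- mean(ssrs)
  expect_gt(m, dof / 2)
  expect_lt(m, 2 * dof)
})

test_that("uninformative measurements trigger an unidentifiability warning", {
  s <- scramble_setup()
  nat <- substrate_labeling(S_e = list(list(weight = 1, pattern = "natural")))
  truth <- toy_scramble_fluxes(0.5)
  clean <- simulate_mdvs(s$net, truth, nat, s$fr)
  meas <- measurement_set(
    mdv_set(clean$mdvs, sd = lapply(clean$mdvs, function(m) rep(0.004, length(m)))),
    rates = NULL, labeling = nat, fragments = s$fr)
  expect_warning(
    fit_fluxes(s$net, meas, options = list(
      seed = 5, n_starts = 2, constraints = list(fixed = c(upt = 1)))),
    "identify")
})

test_that("flux normalization follows the percent-Cmol convention", {
  split <- toy_split_network()
  v <- c(upt = 1, vB = 0.7, vC = 0.3, outB = 0.7, outC = 0.3)
  pc <- normalize_fluxes(v, split, "upt")
  expect_equal(pc[["upt"]], 100)
  expect_equal(pc[["vB"]], 70)
  expect_equal(pc[["vC"]], 30)
  expect_equal(normalize_fluxes(v * 2, split, "upt"), pc)  # homogeneity
  expect_error(normalize_fluxes(c(v, upt = 0)[-1], split, "upt"), "positive")
  # carbon weighting: methanol uptake counts 1 carbon, glucose 6
  net <- shipped_model()
  vm <- full_model_fluxes(net)
  pcm <- normalize_fluxes(vm, net, "GLYC_up")
  expect_equal(pcm[["GLYC_up"]], 100)
  expect_equal(pcm[["MEOH_up"]],
               vm[["MEOH_up"]] * 1 / (vm[["GLYC_up"]] * 3) * 100)
})

test_that("bootstrap intervals shrink with noise and reproduce per seed", {
  s <- scramble_setup()
  truth <- toy_scramble_fluxes(0.6)
  clean <- simulate_mdvs(s$net, truth, s$lab, s$fr)
  make_meas <- function(sd) measurement_set(
    mdv_set(clean$mdvs, sd = lapply(clean$mdvs, function(m) rep(sd, length(m)))),
    rates = data.frame(quantity = "upt", value = 1, sd = 0.02),
    labeling = s$lab, fragments = s$fr)
  opts <- list(seed = 3, n_starts = 2, constraints = list(fixed = c(upt = 1)))
  est <- fit_fluxes(s$net, make_meas(0.004), opts)
  ci1 <- monte_carlo_ci(s$net, make_meas(0.004), est,
                        options = list(n_samples = 30, seed = 9))
  ci2 <- monte_carlo_ci(s$net, make_meas(0.004), est,
                        options = list(n_samples = 30, seed = 9))
  expect_identical(ci1, ci2)  # same seed, same intervals
  w1 <- with(ci1[ci1$reaction == "direct", ], ci_hi - ci_lo)
  est0 <- fit_fluxes(s$net, make_meas(1e-6), opts)
  ci0 <- monte_carlo_ci(s$net, make_meas(1e-6), est0,
                        options = list(n_samples = 30, seed = 9))
  w0 <- with(ci0[ci0$reaction == "direct", ], ci_hi - ci_lo)
  expect_lt(w0, w1 / 100)  # noise-free width collapses
  expect_error(monte_carlo_ci(s$net, make_meas(0.004), est,
                              options = list(n_samples = 1, seed = 1)),
               "n_samples")
})

test_that("cross-variant fit never beats the self-fit on compartment-resolved data", {
  # data simulated under the peroxisomal variant of the scramble toy
  # (direct route on), fitted with the route deleted: SSR must not drop
  # below the self-fit.
  s <- scramble_setup()
  truth <- toy_scramble_fluxes(0.8)
  ds <- gen_mdv_dataset(s$net, truth, list(
    seed = 42, sd = 0.004, labeling = s$lab, fragments = s$fr))
  meas <- measurement_set(ds$replicates[[1]],
                          rates = data.frame(quantity = "upt", value = 1,
                                             sd = 0.02),
                          labeling = s$lab, fragments = s$fr)
  self_fit <- fit_fluxes(s$net, meas, options = list(
    seed = 1, n_starts = 3, constraints = list(fixed = c(upt = 1))))
  # alternative topology: force everything through the scrambling route
  # (uptake identified by its measured rate, keeping one free parameter)
  alt_fit <- suppressWarnings(fit_fluxes(s$net, meas, options = list(
    seed = 1, n_starts = 3,
    constraints = list(fixed = c(direct = 0)))))
  expect_gte(alt_fit$ssr, self_fit$ssr)
})
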
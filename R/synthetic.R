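# Seeded synthetic-data generators. Every generator is a pure function of
# its spec: the RNG stream is derived from (seed, stage name), so adding a
# stage never shifts another stage's draws.

#' Generate noisy MDV datasets from a known flux vector
#'
#' Simulates steady-state MDVs under the true fluxes, adds Gaussian
#' measurement noise per mass isotopomer, clips at zero and renormalizes
#' each fragment to sum 1 (common MFA practice).
#'
#' @param network a [metabolic_network()].
#' @param true_fluxes steady-state net flux vector (or list with `net`,
#'   `exch`).
#' @param spec list: `seed` (mandatory), `sd` (noise standard deviation per
#'   mass isotopomer, default 0.004), `n_replicates` (default 1),
#'   `labeling` (a [substrate_labeling()], default 20 % U-13C mixture on
#'   every declared substrate), `fragments` (a [fragment_map()]).
#' @return list: `replicates` (list of [mdv_set()] with sds),
#'   `truth` (clean mdv_set and the flux vector), `spec`.
#' @export
gen_mdv_dataset <- function(network, true_fluxes, spec) {
  if (is.null(spec$seed)) stopf("spec$seed is mandatory")
  sd <- spec$sd %||% 0.004
  n_rep <- spec$n_replicates %||% 1L
  if (is.null(spec$fragments)) stopf("spec$fragments is mandatory")
  labeling <- spec$labeling %||% stopf("spec$labeling is mandatory")
  clean <- simulate_mdvs(network, true_fluxes, labeling, spec$fragments)
  set.seed(derive_seed(spec$seed, "gen_mdv_dataset"))
  reps <- lapply(seq_len(n_rep), function(i) {
    noisy <- lapply(clean$mdvs, function(m) {
      if (sd > 0) {
        m <- pmax(m + stats::rnorm(length(m), 0, sd), 0)
        m / sum(m)
      } else m
    })
    mdv_set(noisy, sd = lapply(clean$mdvs, function(m)
      rep(max(sd, 1e-12), length(m))), tol = 1e-7)
  })
  list(replicates = reps,
       truth = list(fluxes = true_fluxes, mdvs = clean),
       spec = spec)
}

# default proportions of the planted co-regulation groups
# (echoing the observed structure: concordant up-regulation dominates)
DEFAULT_GROUP_PROPS <- c(
  "up/up" = 0.40, "down/down" = 0.10,
  "up/unchanged" = 0.10, "unchanged/up" = 0.15,
  "down/unchanged" = 0.15, "unchanged/down" = 0.10)

#' Generate transcript and protein fold-change tables with planted groups
#'
#' Background genes draw correlated transcript/protein log2 fold changes
#' from a bivariate normal (correlation `rho`) truncated below the
#' unchanged-call threshold; `n_de` genes get planted regulation in cells
#' of the (transcript x protein) grid. Replicate values (3 transcript, 6
#' protein replicates) carry Gaussian noise, and p-values come from
#' one-sample t-tests of the replicate log2 fold changes. At
#' `sd_replicate = 0` the t-statistics are degenerate, so p is emitted as
#' 0 for planted effects and 1 otherwise.
#'
#' @param spec list: `seed` (mandatory), `n_genes` (default 575), `n_de`
#'   (default 130), `group_props` (named proportions over grid cells),
#'   `rho` (background correlation, default 0.78), `sd_background`
#'   (default 0.12), `sd_replicate` (default 0.15), `effect_range`
#'   (|log2FC| range of planted effects, default c(0.8, 2.5)),
#'   `n_rep_transcript` (3), `n_rep_protein` (6).
#' @return list: `transcripts` (gene, log2fc, pval), `proteins` (protein,
#'   rep1..rep6, log2fc, pval, consistency, n_replicates), `truth`
#'   (gene, group, planted transcript/protein effects).
#' @export
gen_omics_tables <- function(spec) {
  if (is.null(spec$seed)) stopf("spec$seed is mandatory")
  n <- spec$n_genes %||% 575L
  n_de <- spec$n_de %||% 130L
  if (n_de > n) stopf("n_de exceeds n_genes")
  props <- spec$group_props %||% DEFAULT_GROUP_PROPS
  if (any(props < 0) || abs(sum(props) - 1) > 1e-9)
    stopf("group_props must be non-negative and sum to 1")
  rho <- spec$rho %||% 0.78
  sd_bg <- spec$sd_background %||% 0.12
  sd_rep <- spec$sd_replicate %||% 0.15
  er <- spec$effect_range %||% c(0.8, 2.5)
  nrt <- spec$n_rep_transcript %||% 3L
  nrp <- spec$n_rep_protein %||% 6L
  bg_cap <- log2(1.28)  # keep background magnitudes below the 1.3 cutoff

  set.seed(derive_seed(spec$seed, "gen_omics_tables"))
  gene <- sprintf("G%04d", seq_len(n))
  # correlated, truncated background
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  t_eff <- sd_bg * z1
  p_eff <- sd_bg * (rho * z1 + sqrt(1 - rho^2) * z2)
  t_eff <- pmin(pmax(t_eff, -bg_cap), bg_cap)
  p_eff <- pmin(pmax(p_eff, -bg_cap), bg_cap)
  group <- rep("background", n)
  t_planted <- rep(FALSE, n); p_planted <- rep(FALSE, n)

  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    cells <- sample(names(props), n_de, replace = TRUE, prob = props)
    for (j in seq_len(n_de)) {
      i <- de_idx[j]
      parts <- strsplit(cells[j], "/", fixed = TRUE)[[1]]
      mag_t <- stats::runif(1, er[1], er[2])
      mag_p <- stats::runif(1, er[1], er[2])
      if (parts[1] == "up") { t_eff[i] <- mag_t; t_planted[i] <- TRUE }
      if (parts[1] == "down") { t_eff[i] <- -mag_t; t_planted[i] <- TRUE }
      if (parts[2] == "up") { p_eff[i] <- mag_p; p_planted[i] <- TRUE }
      if (parts[2] == "down") { p_eff[i] <- -mag_p; p_planted[i] <- TRUE }
      group[i] <- paste0("transcript_", parts[1], "/protein_", parts[2])
    }
  }

  summarize <- function(effects, planted, n_rep) {
    reps <- matrix(effects, n, n_rep) +
      matrix(stats::rnorm(n * n_rep, 0, sd_rep), n, n_rep)
    est <- rowMeans(reps)
    if (sd_rep == 0) {
      pval <- ifelse(planted, 0, 1)
    } else {
      se <- apply(reps, 1, stats::sd) / sqrt(n_rep)
      tstat <- est / se
      pval <- 2 * stats::pt(-abs(tstat), df = n_rep - 1)
    }
    cons <- vapply(seq_len(n), function(i)
      mean(sign(reps[i, ]) == sign(est[i])), 0)
    list(reps = reps, est = est, pval = pval, consistency = cons)
  }
  tr <- summarize(t_eff, t_planted, nrt)
  pr <- summarize(p_eff, p_planted, nrp)

  transcripts <- data.frame(gene = gene, log2fc = tr$est, pval = tr$pval,
                            stringsAsFactors = FALSE)
  proteins <- data.frame(protein = gene, stringsAsFactors = FALSE)
  for (r in seq_len(nrp)) proteins[[paste0("rep", r)]] <- pr$reps[, r]
  proteins$log2fc <- pr$est
  proteins$pval <- pr$pval
  proteins$consistency <- pr$consistency
  proteins$n_replicates <- nrp
  truth <- data.frame(gene = gene, group = group, t_effect = t_eff,
                      p_effect = p_eff, stringsAsFactors = FALSE)
  list(transcripts = transcripts, proteins = proteins, truth = truth,
       spec = spec)
}

#' Generate a peptide peak-area table with planted enrichment factors
#'
#' Each protein gets `n_peptides` peptides whose homogenate peak areas are
#' lognormal; peroxisomal areas are the planted enrichment factor times the
#' same peptide base area, with independent lognormal noise per sample
#' class. `only_in_pex` proteins have zero homogenate area,
#' `absent_in_pex` proteins zero peroxisomal area.
#'
#' @param spec list: `seed` (mandatory); `proteins` data.frame with columns
#'   `protein`, `enrichment`, `status`
#'   (`finite`/`only_in_pex`/`absent_in_pex`); `reference` (default
#'   `"AOX1"`, must be a finite-status protein); `n_peptides` (default 8);
#'   `sd_log` (lognormal sd, default 0.2); `n_replicates` (default 2 per
#'   class); `base_meanlog` (default log(1e5)).
#' @return list: `records` (peptide, protein, replicate, intensity, area,
#'   class), `truth` (the protein table with reference-normalized
#'   enrichment), `spec`.
#' @export
gen_peptide_table <- function(spec) {
  if (is.null(spec$seed)) stopf("spec$seed is mandatory")
  prot <- spec$proteins %||% data.frame(
    protein = c("AOX1", "DAS1", "SHB17", "TAL1-2", "TKL1", "PGK1", "CTA1"),
    enrichment = c(1, 14.79, 3.05, 5, 0, 0.1, 1.26),
    status = c("finite", "finite", "finite", "only_in_pex", "absent_in_pex",
               "finite", "finite"),
    stringsAsFactors = FALSE)
  reference <- spec$reference %||% "AOX1"
  if (!reference %in% prot$protein ||
      prot$status[prot$protein == reference] != "finite")
    stopf("reference protein must be present with finite status")
  np <- spec$n_peptides %||% 8L
  sd_log <- spec$sd_log %||% 0.2
  n_rep <- spec$n_replicates %||% 2L
  ml <- spec$base_meanlog %||% log(1e5)

  set.seed(derive_seed(spec$seed, "gen_peptide_table"))
  recs <- list()
  for (i in seq_len(nrow(prot))) {
    base <- exp(ml + stats::rnorm(np, 0, 0.5))
    for (r in seq_len(n_rep)) {
      noise_h <- exp(stats::rnorm(np, 0, sd_log))
      noise_p <- exp(stats::rnorm(np, 0, sd_log))
      area_h <- if (prot$status[i] == "only_in_pex") rep(0, np)
                else base * noise_h
      area_p <- if (prot$status[i] == "absent_in_pex") rep(0, np)
                else prot$enrichment[i] * base * noise_p
      recs[[length(recs) + 1L]] <- data.frame(
        peptide = sprintf("%s_pep%02d", prot$protein[i], seq_len(np)),
        protein = prot$protein[i], replicate = sprintf("hom%d", r),
        intensity = pmax(area_h, area_p) / 100,
        area = area_h, class = "homogenate", stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- data.frame(
        peptide = sprintf("%s_pep%02d", prot$protein[i], seq_len(np)),
        protein = prot$protein[i], replicate = sprintf("pex%d", r),
        intensity = pmax(area_h, area_p) / 100,
        area = area_p, class = "peroxisome", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  ref_e <- prot$enrichment[prot$protein == reference]
  truth <- prot
  truth$norm_enrichment <- ifelse(truth$status == "only_in_pex", Inf,
                                  truth$enrichment / ref_e)
  list(records = records, truth = truth, spec = spec)
}

#' Generate a noisy chemostat observation around a balanced truth
#'
#' The true state is constructed to close the carbon and electron balances
#' exactly: CER from the carbon balance and OUR from the degree-of-
#' reduction balance. Relative Gaussian noise is then applied to the
#' observed rates.
#'
#' @param spec list: `seed` (mandatory); `D` (default 0.1); `q_s` (named
#'   true uptake rates, mmol/gCDW/h; default the methanol/glycerol
#'   chemostat design); `sd_rel` (relative noise, default 0.03);
#'   `protein_content`; `feed` (g/L, used for the biomass concentration);
#'   `gamma_biomass` (4.2), `cmol_mass` (26.4).
#' @return list: `truth` and `observed` [chemostat_state()]s, `spec`.
#' @export
gen_chemostat_obs <- function(spec) {
  if (is.null(spec$seed)) stopf("spec$seed is mandatory")
  D <- spec$D %||% 0.1
  q_s <- spec$q_s %||% c(glycerol = 1.64, methanol = 0.81)
  sd_rel <- spec$sd_rel %||% 0.03
  gx <- spec$gamma_biomass %||% 4.2
  cm <- spec$cmol_mass %||% 26.4
  mu_cmol <- D / cm * 1000
  cer <- sum(q_s * SUBSTRATE_CARBONS[names(q_s)]) - mu_cmol
  our <- (sum(q_s * SUBSTRATE_GAMMA[names(q_s)]) - gx * mu_cmol) / 4
  if (cer < 0 || our < 0) stopf("unbalanced truth: negative CER or OUR")
  yield <- D / sum(q_s * SUBSTRATE_MW[names(q_s)] / 1000)
  biomass <- if (!is.null(spec$feed)) sum(unlist(spec$feed)) * yield else NA_real_
  truth <- chemostat_state(D = D, q_s = q_s, CER = cer, OUR = our,
                           biomass = biomass,
                           protein_content = spec$protein_content %||% NA_real_,
                           feed = spec$feed)
  set.seed(derive_seed(spec$seed, "gen_chemostat_obs"))
  jitter <- function(x) if (is.na(x) || sd_rel == 0) x
                        else max(x * (1 + stats::rnorm(1, 0, sd_rel)), 0)
  observed <- chemostat_state(
    D = D, q_s = vapply(q_s, jitter, 0),
    CER = jitter(cer), OUR = jitter(our), biomass = jitter(biomass),
    protein_content = truth$protein_content, feed = spec$feed)
  list(truth = truth, observed = observed, spec = spec)
}
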
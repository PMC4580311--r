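# Chemostat steady-state balances, composition-table arithmetic, and
# exact-mass utilities.

#' Molecular weights (g/mol) of the feed substrates
#' @export
SUBSTRATE_MW <- c(glucose = 180.16, glycerol = 92.09, methanol = 32.04)

#' Degrees of reduction (electrons per mole) of substrates
#'
#' Glucose 4.0, glycerol 4.67, methanol 6.0 electrons per carbon.
#' @export
SUBSTRATE_GAMMA <- c(glucose = 4.0 * 6, glycerol = 4.67 * 3, methanol = 6.0 * 1)

SUBSTRATE_CARBONS <- c(glucose = 6, glycerol = 3, methanol = 1)

#' Construct a chemostat steady state
#'
#' @param D dilution rate (1/h); equals the specific growth rate at steady
#'   state.
#' @param q_s named vector of substrate-specific uptake rates
#'   (mmol per gCDW per h); names from `names(SUBSTRATE_MW)`.
#' @param CER,OUR carbon-dioxide evolution / oxygen uptake rates
#'   (mmol per gCDW per h).
#' @param biomass steady-state biomass concentration (gCDW/L).
#' @param protein_content total protein content (g protein per gCDW).
#' @param feed named vector of feed concentrations (g/L), optional.
#' @return object of class `chemostat_state`.
#' @export
chemostat_state <- function(D, q_s, CER = NA_real_, OUR = NA_real_,
                            biomass = NA_real_, protein_content = NA_real_,
                            feed = NULL) {
  if (D <= 0) stopf("dilution rate must be positive")
  vals <- c(q_s, CER = unname(CER), OUR = unname(OUR),
            biomass = unname(biomass))
  if (any(!is.na(vals) & vals < 0)) stopf("rates and biomass must be non-negative")
  structure(list(D = D, q_s = q_s, CER = CER, OUR = OUR, biomass = biomass,
                 protein_content = protein_content, feed = feed),
            class = "chemostat_state")
}

#' Biomass yield from dilution rate and uptake rates
#'
#' Y_X/S = D / sum_i(q_s,i * MW_i / 1000), in gCDW per g substrate.
#'
#' @param state a [chemostat_state()].
#' @param mw named molecular weights (g/mol), defaulting to
#'   [SUBSTRATE_MW].
#' @return biomass yield (gCDW/gSubstrate).
#' @export
biomass_yield <- function(state, mw = SUBSTRATE_MW) {
  q <- state$q_s[state$q_s > 0]
  if (!length(q)) stopf("no substrate uptake: all q_s are zero")
  miss <- setdiff(names(q), names(mw))
  if (length(miss)) stopf("no molecular weight for substrate(s): %s",
                          paste(miss, collapse = ", "))
  state$D / sum(q * mw[names(q)] / 1000)
}

#' Electron (degree-of-reduction) balance closure
#'
#' Fraction of substrate electrons recovered in oxygen uptake and biomass:
#' (4 * OUR + gamma_X * mu_Cmol) / sum(q_s * gamma_s). A closure of 1 means
#' the redox balance closes exactly.
#'
#' @param state a [chemostat_state()].
#' @param gamma_biomass degree of reduction of biomass per Cmol
#'   (default 4.2; literature value, configurable).
#' @param cmol_mass biomass Cmol mass in g/Cmol (default 26.4).
#' @param gamma named degrees of reduction per mole of substrate.
#' @param warn_open warn when closure deviates from 1 by more than 10 %.
#' @return closure fraction (dimensionless).
#' @export
reduction_balance <- function(state, gamma_biomass = 4.2, cmol_mass = 26.4,
                              gamma = SUBSTRATE_GAMMA, warn_open = TRUE) {
  q <- state$q_s[state$q_s > 0]
  miss <- setdiff(names(q), names(gamma))
  if (length(miss)) stopf("no degree of reduction for substrate(s): %s",
                          paste(miss, collapse = ", "))
  e_in <- sum(q * gamma[names(q)])
  if (e_in <= 0) stopf("no substrate electrons")
  mu_cmol <- state$D / cmol_mass * 1000  # mmol Cmol biomass / gCDW / h
  e_out <- 4 * (if (is.na(state$OUR)) 0 else state$OUR) + gamma_biomass * mu_cmol
  closure <- e_out / e_in
  if (warn_open && abs(closure - 1) > 0.10)
    warnf("electron balance open: closure %.2f", closure)
  closure
}

#' Specific protein synthesis rate
#'
#' At steady state the specific protein synthesis rate is the product of
#' the growth rate and the cellular protein content.
#'
#' @param D specific growth rate (1/h).
#' @param protein_content g protein per gCDW.
#' @return g protein per gCDW per h.
#' @export
protein_synthesis_rate <- function(D, protein_content) {
  if (D < 0 || protein_content < 0) stopf("inputs must be non-negative")
  D * protein_content
}

#' Percent change between two conditions
#'
#' @param a reference value (> 0).
#' @param b comparison value.
#' @return (b - a) / a * 100.
#' @export
percent_change <- function(a, b) {
  if (any(a <= 0)) stopf("reference value must be positive")
  (b - a) / a * 100
}

#' Summarize a paired composition table
#'
#' For a two-condition composition table (e.g. amino-acid or fatty-acid
#' content per gram biomass), computes per-analyte and total log2 fold
#' changes (condition B over condition A) and percent changes. Zero
#' denominators yield an `undefined_fc` flag rather than an error.
#'
#' @param table data.frame with columns `analyte`, `value_a`, `value_b`
#'   (or names given via `cols`).
#' @param cols length-2 character: the columns holding conditions A and B.
#' @return list with `per_analyte` data.frame (analyte, value_a, value_b,
#'   log2fc, pct_change, undefined_fc) and `totals` (sums and their log2
#'   fold change).
#' @export
composition_summary <- function(table, cols = c("value_a", "value_b")) {
  a <- table[[cols[1]]]; b <- table[[cols[2]]]
  if (is.null(a) || is.null(b)) stopf("columns %s not found",
                                      paste(cols, collapse = ", "))
  if (any(stats::na.omit(c(a, b)) < 0)) stopf("composition values must be >= 0")
  undef <- is.na(a) | is.na(b) | a == 0
  l2 <- ifelse(undef, NA_real_, log2(b / a))
  pct <- ifelse(undef, NA_real_, (b - a) / a * 100)
  per <- data.frame(analyte = table$analyte, value_a = a, value_b = b,
                    log2fc = l2, pct_change = pct, undefined_fc = undef,
                    stringsAsFactors = FALSE)
  ta <- sum(a, na.rm = TRUE); tb <- sum(b, na.rm = TRUE)
  totals <- list(total_a = ta, total_b = tb,
                 log2fc = if (ta > 0) log2(tb / ta) else NA_real_,
                 pct_change = if (ta > 0) (tb - ta) / ta * 100 else NA_real_)
  list(per_analyte = per, totals = totals)
}

# IUPAC monoisotopic masses of the light isotopes
MONOISOTOPIC_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637064864,
  Cl = 34.968852682, F = 18.9984031627
)
PROTON_MASS <- 1.00727646688

#' Monoisotopic m/z of a molecular formula
#'
#' @param formula elemental formula string, e.g. `"C7H16O13P2"` for
#'   sedoheptulose-1,7-bisphosphate.
#' @param mode ionization mode: `"neutral"`, `"neg"` (`[M-H]-`) or
#'   `"pos"` (`[M+H]+`).
#' @return monoisotopic m/z (Da).
#' @export
monoisotopic_mz <- function(formula, mode = c("neutral", "neg", "pos")) {
  mode <- match.arg(mode)
  cnt <- parse_formula(formula)
  if (is.null(cnt) || !length(cnt)) stopf("empty formula")
  miss <- setdiff(names(cnt), names(MONOISOTOPIC_MASS))
  if (length(miss)) stopf("unknown element(s): %s", paste(miss, collapse = ", "))
  m <- sum(cnt * MONOISOTOPIC_MASS[names(cnt)])
  switch(mode, neutral = m, neg = m - PROTON_MASS, pos = m + PROTON_MASS)
}

#' Mass accuracy in parts per million
#'
#' @param measured,theoretical masses (Da).
#' @return signed ppm deviation.
#' @export
mass_ppm <- function(measured, theoretical) {
  (measured - theoretical) / theoretical * 1e6
}
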
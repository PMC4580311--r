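# Accessors for the shipped reference tables: chemostat growth parameters,
# biomass composition, and the PTS1-verdict regression fixture.

extdata <- function(file) {
  system.file("extdata", file, package = "xumpflux", mustWork = TRUE)
}

#' Shipped chemostat growth parameters
#'
#' Measured dilution-rate-0.1 chemostat physiology of the two conditions
#' (glucose vs methanol/glycerol): uptake rates, gas exchange rates,
#' biomass, yields, protein content.
#' @return data.frame with condition, quantity, value, sd, units.
#' @export
growth_parameters_table <- function() {
  utils::read.delim(extdata("growth_parameters.tsv"),
                    stringsAsFactors = FALSE)
}

#' Build a [chemostat_state()] from the shipped growth parameters
#' @param condition `"glucose"` or `"methanol_glycerol"`.
#' @return a [chemostat_state()].
#' @export
growth_parameters_state <- function(condition = c("glucose",
                                                  "methanol_glycerol")) {
  condition <- match.arg(condition)
  tab <- growth_parameters_table()
  tab <- tab[tab$condition == condition, ]
  val <- stats::setNames(tab$value, tab$quantity)
  q <- val[grep("^q_", names(val))]
  names(q) <- sub("^q_", "", names(q))
  chemostat_state(D = 0.1, q_s = q, CER = val[["CER"]], OUR = val[["OUR"]],
                  biomass = val[["biomass"]],
                  protein_content = val[["protein_content"]])
}

#' Shipped amino-acid composition table
#'
#' Protein-bound and free intracellular amino acids (mg/gCDW) of glucose-
#' versus methanol/glycerol-grown cells.
#' @param fraction `"bound"`, `"free"`, or `NULL` for both.
#' @return data.frame analyte / fraction / glucose / methanol_glycerol.
#' @export
aa_composition_table <- function(fraction = NULL) {
  tab <- utils::read.delim(extdata("aa_composition.tsv"),
                           stringsAsFactors = FALSE)
  if (!is.null(fraction)) tab <- tab[tab$fraction == fraction, ]
  tab
}

#' Shipped total fatty-acid composition table
#'
#' Total fatty acids (ug lipid per mg wet cell weight) by species for the
#' two growth conditions.
#' @return data.frame analyte / glucose / methanol_glycerol.
#' @export
fatty_acid_table <- function() {
  utils::read.delim(extdata("fatty_acids.tsv"), stringsAsFactors = FALSE)
}

#' PTS1 reference verdicts (regression fixture)
#'
#' C-terminal 12-residue tails of methanol-metabolism and control proteins
#' with their published peroxisomal-targeting verdicts
#' (yes / twilight / no), used to regression-test [pts1_screen()].
#' @return data.frame protein / tail / verdict.
#' @export
pts1_reference_table <- function() {
  utils::read.delim(extdata("pts1_reference.tsv"), stringsAsFactors = FALSE)
}
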
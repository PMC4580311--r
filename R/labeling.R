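# Substrate labeling, measured-fragment maps, and MDV containers.

#' Define substrate labeling as a mixture of positional isotopomer patterns
#'
#' Each labelled substrate is a mixture of components; a component is either
#' `"U"` (fully 13C-labelled, at the given atom purity), `"natural"`
#' (every carbon 13C with the natural-abundance probability), or a numeric
#' vector of per-carbon 13C probabilities.
#'
#' @param ... named arguments, one per substrate metabolite id; each a list
#'   of components `list(weight =, pattern =)`.
#' @param natural_p13 natural 13C abundance (default 0.0107).
#' @param purity 13C atom fraction of the fully labelled tracer (default 1).
#' @return object of class `substrate_labeling`.
#' @export
substrate_labeling <- function(..., natural_p13 = 0.0107, purity = 1.0) {
  subs <- list(...)
  if (length(subs) == 1L && is.null(names(subs)) && is.list(subs[[1]]) &&
      !is.null(names(subs[[1]])) && is.list(subs[[1]][[1]]))
    subs <- subs[[1]]
  if (natural_p13 < 0 || natural_p13 > 1) stopf("natural_p13 must be in [0,1]")
  for (s in names(subs)) {
    w <- vapply(subs[[s]], function(cp) cp$weight, 0)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stopf("labeling weights for '%s' must be non-negative and sum to 1", s)
  }
  structure(list(substrates = subs, natural_p13 = natural_p13,
                 purity = purity), class = "substrate_labeling")
}

#' Standard tracer mixture: fraction U-13C plus naturally labelled substrate
#'
#' @param substrate metabolite id of the labelled substrate.
#' @param tracer_fraction fraction of fully 13C-labelled substrate
#'   (default 0.20, the mixture used for the chemostat labelling design).
#' @param natural_p13 natural 13C abundance for the unlabelled portion.
#' @param purity tracer atom purity.
#' @param others further substrates fed at natural abundance only
#'   (character vector of metabolite ids).
#' @return a [substrate_labeling()].
#' @export
tracer_mixture <- function(substrate, tracer_fraction = 0.20,
                           natural_p13 = 0.0107, purity = 1.0,
                           others = character()) {
  if (tracer_fraction < 0 || tracer_fraction > 1)
    stopf("tracer_fraction must be in [0,1]")
  subs <- stats::setNames(lapply(substrate, function(s)
    list(list(weight = tracer_fraction, pattern = "U"),
         list(weight = 1 - tracer_fraction, pattern = "natural"))),
    substrate)
  for (s in others)
    subs[[s]] <- list(list(weight = 1, pattern = "natural"))
  substrate_labeling(subs, natural_p13 = natural_p13, purity = purity)
}

# per-carbon 13C probabilities for one labeling component
component_p13 <- function(comp, n, labeling) {
  pat <- comp$pattern
  if (identical(pat, "U")) rep(labeling$purity, n)
  else if (identical(pat, "natural")) rep(labeling$natural_p13, n)
  else {
    if (length(pat) != n) stopf("pattern length %d != carbon count %d",
                                length(pat), n)
    as.numeric(pat)
  }
}

# MDV of a source EMU: mixture over components, independent carbons within
# a component.
source_emu_mdv <- function(labeling, met, positions, n_carbons) {
  comps <- labeling$substrates[[met]]
  if (is.null(comps))
    stopf("no labeling declared for substrate '%s'", met)
  out <- numeric(length(positions) + 1L)
  for (comp in comps) {
    p <- component_p13(comp, n_carbons, labeling)[positions]
    mdv <- Reduce(mdv_convolve, lapply(p, function(pi) c(1 - pi, pi)))
    out <- out + comp$weight * mdv
  }
  out
}

# Full isotopomer distribution (2^n) of a source pool, bit i (LSB = carbon 1).
source_isotopomer_dist <- function(labeling, met, n_carbons) {
  comps <- labeling$substrates[[met]]
  if (is.null(comps))
    stopf("no labeling declared for substrate '%s'", met)
  out <- numeric(2^n_carbons)
  states <- 0:(2^n_carbons - 1L)
  for (comp in comps) {
    p <- component_p13(comp, n_carbons, labeling)
    pr <- rep(comp$weight, length(states))
    for (i in seq_len(n_carbons)) {
      bit <- bitwAnd(bitwShiftR(states, i - 1L), 1L)
      pr <- pr * ifelse(bit == 1L, p[i], 1 - p[i])
    }
    out <- out + pr
  }
  out
}

#' Binomial natural-abundance mass distribution
#'
#' @param n_carbons number of carbons in the fragment.
#' @param p13C per-carbon 13C probability.
#' @return numeric vector m0..mn summing to 1.
#' @export
natural_abundance_mdv <- function(n_carbons, p13C = 0.0107) {
  if (n_carbons < 0) stopf("n_carbons must be >= 0")
  if (p13C < 0 || p13C > 1) stopf("p13C must be in [0,1]")
  stats::dbinom(0:n_carbons, n_carbons, p13C)
}

#' Define the measured fragments
#'
#' A fragment is a list of parts; each part names a network metabolite and
#' the (1-based) carbon positions contributing to the fragment. Fragments
#' with several parts (e.g. amino acids built from two precursors) get the
#' convolution of the part distributions.
#'
#' @param ... named fragment definitions; each either
#'   `list(met = positions)` shorthand or a list of such parts.
#' @return object of class `fragment_map`.
#' @export
fragment_map <- function(...) {
  frs <- list(...)
  if (length(frs) == 1L && is.null(names(frs)) && is.list(frs[[1]]))
    frs <- frs[[1]]
  out <- lapply(frs, function(fr) {
    # each element of fr: named numeric vector of positions
    lapply(seq_along(fr), function(i)
      list(met = names(fr)[i], pos = as.integer(fr[[i]])))
  })
  structure(out, class = "fragment_map")
}

#' Default amino-acid fragment map
#'
#' The conventional precursor mapping of proteinogenic amino-acid backbones
#' ([M-57]-type full-carbon fragments): Ala from pyruvate, Ser from
#' 3-phosphoglycerate, Gly from serine C1-C2 (hence 3PG C1-C2), Asp and Thr
#' from oxaloacetate, Glu from alpha-ketoglutarate, Val from two pyruvates
#' (one decarboxylated), Phe from two PEP plus erythrose-4-phosphate.
#' This is a field convention, configurable via [fragment_map()].
#'
#' @param which subset of fragments to keep (default all).
#' @return a [fragment_map()] over metabolites of the shipped model.
#' @export
default_fragment_map <- function(which = NULL) {
  fm <- fragment_map(list(
    Ala = list(PYR_c = 1:3),
    Ser = list(PGA_c = 1:3),
    Gly = list(PGA_c = 1:2),
    Asp = list(OAA_m = 1:4),
    Thr = list(OAA_m = 1:4),
    Glu = list(AKG_m = 1:5),
    Val = list(PYR_c = 1:3, PYR_c = 2:3),
    Phe = list(PEP_c = 1:3, PEP_c = 2:3, E4P_c = 1:4)
  ))
  if (!is.null(which)) fm <- structure(fm[which], class = "fragment_map")
  fm
}

#' Construct an MDV set
#'
#' @param mdvs named list of numeric mass-isotopomer vectors (m0..mn).
#' @param sd optional named list of per-entry standard deviations.
#' @param tol tolerance on the sum-to-one invariant.
#' @return object of class `mdv_set`.
#' @export
mdv_set <- function(mdvs, sd = NULL, tol = 1e-9) {
  for (f in names(mdvs)) {
    m <- mdvs[[f]]
    if (any(m < -tol)) stopf("MDV '%s' has negative entries", f)
    if (abs(sum(m) - 1) > tol)
      stopf("MDV '%s' sums to %.12f, not 1 (tol %g)", f, sum(m), tol)
    if (!is.null(sd[[f]]) && length(sd[[f]]) != length(m))
      stopf("sd length mismatch for fragment '%s'", f)
  }
  structure(list(mdvs = mdvs, sd = sd), class = "mdv_set")
}

#' @export
print.mdv_set <- function(x, ...) {
  cat(sprintf("<mdv_set: %d fragments>\n", length(x$mdvs)))
  for (f in names(x$mdvs))
    cat(sprintf("  %-8s %s\n", f,
                paste(sprintf("%.4f", x$mdvs[[f]]), collapse = " ")))
  invisible(x)
}
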
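# Compartmentalized stoichiometric network with carbon atom maps.
#
# Metabolite ids carry a compartment suffix (_e/_c/_p/_m); the same chemical
# species in two compartments is two metabolites, and transport is an explicit
# reaction. Roles:
#   balanced  -- intracellular pool, steady-state balanced, carries carbon
#   exchange  -- boundary pool (feed substrates, evolved CO2, biomass)
#   cofactor  -- conserved moiety (ATP/NADH/O2/...); never balanced, its
#                carbons (if any) are not traced, but net production is
#                reported by cofactor_trace().

#' Construct a metabolic network
#'
#' Low-level constructor used by [load_network()] and by code that builds
#' small networks programmatically (tests, synthetic fixtures).
#'
#' @param metabolites data.frame with columns `id`, `compartment`,
#'   `carbons`, optional `formula`, `role`.
#' @param reactions list of reaction objects as built by [reaction()].
#' @param variant variant tag, e.g. `"xump_peroxisomal"` or `"classical_ppp"`.
#' @param biomass named numeric vector of biomass precursor drain
#'   coefficients (mmol per gram cell dry weight), or `NULL`.
#' @param variants optional list describing how to derive other variants
#'   (see [build_variant()]).
#' @param id model identifier.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, variant = "custom",
                              biomass = NULL, variants = NULL, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$role)) metabolites$role <- "balanced"
  need <- c("id", "compartment", "carbons")
  if (!all(need %in% names(metabolites)))
    stopf("metabolite table must have columns %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(metabolites$compartment), names(COMPARTMENTS))
  if (length(bad))
    stopf("unknown compartment(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stopf("duplicate metabolite id(s): %s",
          paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (any(metabolites$carbons < 0)) stopf("carbon_count must be non-negative")
  # carbon count must agree with formula when present (balanced species only)
  for (i in seq_len(nrow(metabolites))) {
    f <- metabolites$formula[i]
    if (!is.na(f) && nzchar(f) && metabolites$role[i] == "balanced") {
      cnt <- parse_formula(f)
      nc <- if ("C" %in% names(cnt)) unname(cnt[["C"]]) else 0L
      if (nc != metabolites$carbons[i])
        stopf("metabolite '%s': carbon_count %d disagrees with formula %s",
              metabolites$id[i], metabolites$carbons[i], f)
    }
  }
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stopf("duplicate reaction id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(reactions) <- ids
  for (rx in reactions) {
    ref <- names(rx$stoich)
    miss <- setdiff(ref, metabolites$id)
    if (length(miss))
      stopf("reaction '%s' references undeclared metabolite(s): %s",
            rx$id, paste(miss, collapse = ", "))
    for (am in rx$atom_maps) {
      miss <- setdiff(c(names(am), unlist(lapply(am, `[[`, "sub"))),
                      metabolites$id)
      if (length(miss))
        stopf("atom map of '%s' references undeclared metabolite(s): %s",
              rx$id, paste(miss, collapse = ", "))
    }
  }
  if (!is.null(biomass)) {
    miss <- setdiff(names(biomass), metabolites$id)
    if (length(miss))
      stopf("biomass drain references undeclared metabolite(s): %s",
            paste(miss, collapse = ", "))
  }
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 variant = variant, biomass = biomass, variants = variants),
            class = "metabolic_network")
}

#' Build a reaction object
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector; negative coefficients are substrates,
#'   positive are products.
#' @param reversible logical flag.
#' @param atom_map a single atom map (named list / string form, see
#'   [parse_atom_map()]) or `NULL` for cofactor-only reactions.
#' @param atom_maps list of equally weighted alternative atom maps, used for
#'   molecularly symmetric species (dihydroxyacetone, succinate, fumarate).
#' @param enzyme free-text enzyme label.
#' @param compartment free-text compartment note.
#' @return a reaction object (plain list).
#' @export
reaction <- function(id, stoich, reversible = FALSE, atom_map = NULL,
                     atom_maps = NULL, enzyme = NA_character_,
                     compartment = NA_character_) {
  if (is.null(atom_maps) && !is.null(atom_map)) atom_maps <- list(atom_map)
  atom_maps <- lapply(atom_maps %||% list(), parse_atom_map)
  list(id = id, stoich = stoich, reversible = isTRUE(reversible),
       atom_maps = atom_maps, enzyme = enzyme, compartment = compartment)
}

#' Parse an atom map
#'
#' Atom maps use the product-carbon string dialect: for every carbon-carrying
#' product, a comma-separated list `"SUB@pos"` gives, in product-carbon order
#' (1-based, C1 = carbonyl end for sugars), the substrate carbon each product
#' carbon derives from.
#'
#' @param map named list: product id -> string `"X5P_p@3,X5P_p@4,X5P_p@5"`,
#'   or an already-parsed map (returned unchanged).
#' @return named list: product id -> list(sub = character, pos = integer).
#' @export
parse_atom_map <- function(map) {
  lapply(map, function(entry) {
    if (is.list(entry)) return(entry)
    parts <- trimws(strsplit(entry, ",")[[1]])
    hit <- regmatches(parts, regexec("^(.+)@([0-9]+)$", parts))
    if (any(vapply(hit, length, 0L) != 3L))
      stopf("malformed atom map entry '%s'", entry)
    list(sub = vapply(hit, `[[`, "", 2L),
         pos = as.integer(vapply(hit, `[[`, "", 3L)))
  })
}

met_info <- function(network, id, field) {
  i <- match(id, network$metabolites$id)
  network$metabolites[[field]][i]
}

carbons_of <- function(network, ids) {
  network$metabolites$carbons[match(ids, network$metabolites$id)]
}

roles_of <- function(network, ids) {
  network$metabolites$role[match(ids, network$metabolites$id)]
}

#' Load a metabolic model from its JSON document
#'
#' The model dialect is JSON with `metabolites[]`, `reactions[]`
#' (stoichiometry as id -> coefficient maps, atom maps as product-carbon
#' strings), `variant`, `biomass`, and an optional `variants` block
#' describing how to derive alternative topologies.
#'
#' @param model_document path to a JSON file, or an equivalent R list.
#' @return a validated [metabolic_network()].
#' @export
load_network <- function(model_document) {
  doc <- if (is.character(model_document)) {
    jsonlite::fromJSON(model_document, simplifyVector = FALSE)
  } else model_document
  if (!is.list(doc)) stopf("model document must be a JSON object")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, compartment = m$compartment,
               carbons = as.integer(m$carbons %||% 0L),
               formula = m$formula %||% NA_character_,
               role = m$role %||% "balanced", stringsAsFactors = FALSE)
  }))
  if (is.null(mets))
    mets <- data.frame(id = character(), compartment = character(),
                       carbons = integer(), formula = character(),
                       role = character(), stringsAsFactors = FALSE)
  rxns <- lapply(doc$reactions %||% list(), function(r) {
    maps <- if (!is.null(r$atom_maps)) r$atom_maps
            else if (!is.null(r$atom_map)) list(r$atom_map) else list()
    reaction(id = r$id, stoich = unlist(r$stoichiometry),
             reversible = isTRUE(r$reversible), atom_maps = maps,
             enzyme = r$enzyme %||% NA_character_,
             compartment = r$compartment %||% NA_character_)
  })
  metabolic_network(mets, rxns, variant = doc$variant %||% "custom",
                    biomass = if (length(doc$biomass)) unlist(doc$biomass),
                    variants = doc$variants, id = doc$id %||% "model")
}

#' Path to the shipped P. pastoris XuMP model
#' @return file path of the packaged model JSON.
#' @export
xump_model_path <- function() {
  system.file("extdata", "ppastoris_xump.json", package = "xumpflux",
              mustWork = TRUE)
}

#' Per-reaction balance and atom-map report
#'
#' Checks carbon balance (over non-cofactor metabolites), elemental balance
#' where formulas are present on every participant (advisory), and carbon
#' bijectivity of atom maps. Report-only: nothing fails here.
#'
#' @param network a [metabolic_network()].
#' @return data.frame with one row per reaction: `carbon_ok`,
#'   `element_ok` (NA when formulas incomplete), `atom_map_ok`
#'   (NA when the reaction has no map), and a `detail` message.
#' @export
validate_balance <- function(network) {
  rows <- lapply(network$reactions, function(rx) {
    ids <- names(rx$stoich)
    counted <- roles_of(network, ids) != "cofactor"
    cbal <- sum(rx$stoich[counted] * carbons_of(network, ids)[counted])
    carbon_ok <- abs(cbal) < 1e-9
    detail <- if (carbon_ok) "" else sprintf("carbon imbalance %+g", cbal)

    forms <- met_info(network, ids, "formula")
    element_ok <- NA
    if (all(!is.na(forms) & nzchar(forms)) && length(ids)) {
      tot <- list()
      for (i in seq_along(ids)) {
        cnt <- parse_formula(forms[i])
        for (el in names(cnt)) tot[[el]] <- (tot[[el]] %||% 0) +
            rx$stoich[[ids[i]]] * cnt[[el]]
      }
      off <- names(tot)[vapply(tot, function(x) abs(x) > 1e-9, TRUE)]
      element_ok <- length(off) == 0L
      if (!element_ok)
        detail <- paste0(detail, if (nzchar(detail)) "; ",
                         "element imbalance: ", paste(off, collapse = ","))
    }

    map_ok <- NA
    if (length(rx$atom_maps)) {
      map_ok <- all(vapply(rx$atom_maps, function(am)
        atom_map_bijective(network, rx, am), TRUE))
      if (!isTRUE(map_ok))
        detail <- paste0(detail, if (nzchar(detail)) "; ",
                         "atom map not a carbon bijection")
    }
    data.frame(reaction = rx$id, carbon_ok = carbon_ok,
               element_ok = element_ok, atom_map_ok = map_ok,
               detail = detail, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(reaction = character(), carbon_ok = logical(),
                      element_ok = logical(), atom_map_ok = logical(),
                      detail = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# A map is a carbon bijection if every carbon of every traced product is
# assigned exactly one substrate carbon, and every substrate carbon of traced
# substrates is used exactly once.
atom_map_bijective <- function(network, rx, am) {
  ids <- names(rx$stoich)
  traced <- ids[roles_of(network, ids) != "cofactor" &
                carbons_of(network, ids) > 0]
  prods <- traced[rx$stoich[traced] > 0]
  subs <- traced[rx$stoich[traced] < 0]
  if (!setequal(names(am), prods)) return(FALSE)
  used <- character()
  for (p in prods) {
    entry <- am[[p]]
    if (length(entry$sub) != carbons_of(network, p)) return(FALSE)
    if (any(!entry$sub %in% subs)) return(FALSE)
    if (any(entry$pos < 1L | entry$pos > carbons_of(network, entry$sub)))
      return(FALSE)
    used <- c(used, paste0(entry$sub, "@", entry$pos))
  }
  expected <- unlist(lapply(subs, function(s)
    paste0(s, "@", seq_len(carbons_of(network, s)))))
  setequal(used, expected) && !anyDuplicated(used)
}

#' Net reaction of a weighted reaction multiset
#'
#' Sums reaction stoichiometries with the given multiplicities and requires
#' that every balanced intermediate cancels, leaving a net conversion over
#' the metabolites in `keep` plus cofactors and exchange species. Negative
#' multiplicities run a reversible reaction backwards.
#'
#' @param network a [metabolic_network()].
#' @param multiset named numeric vector, reaction id -> multiplicity.
#' @param keep balanced metabolite ids allowed to appear in the net reaction.
#' @return named numeric vector of net stoichiometric coefficients
#'   (class `net_reaction`), zero entries dropped.
#' @export
net_reaction <- function(network, multiset, keep = character()) {
  if (length(multiset) == 0L) return(structure(numeric(0), class = "net_reaction"))
  miss <- setdiff(names(multiset), names(network$reactions))
  if (length(miss))
    stopf("unknown reaction id(s): %s", paste(miss, collapse = ", "))
  net <- numeric(0)
  for (rid in names(multiset)) {
    rx <- network$reactions[[rid]]
    if (multiset[[rid]] < 0 && !rx$reversible)
      stopf("negative multiplicity for irreversible reaction '%s'", rid)
    for (m in names(rx$stoich))
      net[m] <- (if (m %in% names(net)) net[[m]] else 0) +
        multiset[[rid]] * rx$stoich[[m]]
  }
  net <- net[abs(net) > 1e-9]
  internal <- names(net)[roles_of(network, names(net)) == "balanced"]
  internal <- setdiff(internal, keep)
  if (length(internal))
    stopf("internal metabolite(s) do not cancel: %s",
          paste(sprintf("%s (%+g)", internal, net[internal]), collapse = ", "))
  structure(net, class = "net_reaction")
}

#' @export
print.net_reaction <- function(x, ...) {
  if (!length(x)) { cat("(empty net reaction)\n"); return(invisible(x)) }
  lhs <- x[x < 0]; rhs <- x[x > 0]
  fmt <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  cat(fmt(lhs), "->", fmt(rhs), "\n")
  invisible(x)
}

#' Net cofactor production of a flux vector
#'
#' Computes the linear combination sum_i v_i * n_i,species for each requested
#' species: positive values are net production.
#'
#' @param network a [metabolic_network()].
#' @param flux_vector named numeric vector of net fluxes by reaction id.
#' @param species character vector of metabolite ids to trace; defaults to
#'   the energy/redox bookkeeping set present in the network.
#' @return named numeric vector of net production rates.
#' @export
cofactor_trace <- function(network, flux_vector,
                           species = intersect(
                             c("NADH", "NADPH", "ATP", "FADH2", "O2", "CO2_e"),
                             network$metabolites$id)) {
  miss <- setdiff(names(flux_vector), names(network$reactions))
  if (length(miss))
    stopf("unknown reaction id(s) in flux vector: %s",
          paste(miss, collapse = ", "))
  out <- stats::setNames(numeric(length(species)), species)
  for (rid in names(flux_vector)) {
    st <- network$reactions[[rid]]$stoich
    hit <- intersect(names(st), species)
    out[hit] <- out[hit] + flux_vector[[rid]] * unlist(st[hit])
  }
  out
}

#' Stoichiometric matrix
#'
#' Rows are balanced metabolites, columns are reactions. All-zero rows
#' (isolated metabolites) are flagged in the `isolated` attribute.
#'
#' @param network a [metabolic_network()].
#' @return numeric matrix with dimnames; attribute `isolated` lists
#'   balanced metabolites not touched by any reaction.
#' @export
stoichiometric_matrix <- function(network) {
  mets <- network$metabolites$id[network$metabolites$role == "balanced"]
  rxns <- names(network$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (rid in rxns) {
    st <- network$reactions[[rid]]$stoich
    hit <- intersect(names(st), mets)
    S[hit, rid] <- unlist(st[hit])
  }
  isolated <- mets[rowSums(S != 0) == 0]
  attr(S, "isolated") <- isolated
  S
}

#' Derive a model variant
#'
#' The shipped model carries a `variants` block naming, per variant tag, the
#' reactions to remove and the reactions/metabolites to add. The
#' `classical_ppp` variant of the default model removes the peroxisomal
#' sugar-phosphate rearrangement reactions (no SHB17, no
#' sedoheptulose-1,7-bisphosphate) and adds pentose/triose transporters so
#' xylulose-5-phosphate is regenerated by the cytosolic non-oxidative
#' pentose phosphate pathway.
#'
#' @param base a [metabolic_network()] holding a `variants` block.
#' @param variant_tag one of the tags declared in the model (plus the base
#'   model's own tag, which returns it unchanged).
#' @return a [metabolic_network()] with the requested topology.
#' @export
build_variant <- function(base, variant_tag) {
  if (identical(variant_tag, base$variant)) return(base)
  spec <- base$variants[[variant_tag]]
  if (is.null(spec))
    stopf("unknown variant tag '%s' (model declares: %s)", variant_tag,
          paste(c(base$variant, names(base$variants)), collapse = ", "))
  rxns <- base$reactions[setdiff(names(base$reactions),
                                 unlist(spec$remove %||% list()))]
  add <- lapply(spec$add_reactions %||% list(), function(r) {
    maps <- if (!is.null(r$atom_maps)) r$atom_maps
            else if (!is.null(r$atom_map)) list(r$atom_map) else list()
    reaction(id = r$id, stoich = unlist(r$stoichiometry),
             reversible = isTRUE(r$reversible), atom_maps = maps,
             enzyme = r$enzyme %||% NA_character_,
             compartment = r$compartment %||% NA_character_)
  })
  rxns <- c(rxns, stats::setNames(add, vapply(add, `[[`, "", "id")))
  mets <- base$metabolites
  for (m in spec$add_metabolites %||% list()) {
    mets <- rbind(mets, data.frame(
      id = m$id, compartment = m$compartment,
      carbons = as.integer(m$carbons %||% 0L),
      formula = m$formula %||% NA_character_,
      role = m$role %||% "balanced", stringsAsFactors = FALSE))
  }
  # drop metabolites no longer referenced by any reaction or the biomass drain
  used <- unique(c(unlist(lapply(rxns, function(r) names(r$stoich))),
                   names(base$biomass)))
  mets <- mets[mets$id %in% used, , drop = FALSE]
  metabolic_network(mets, unname(rxns), variant = variant_tag,
                    biomass = base$biomass, variants = base$variants,
                    id = paste0(base$id, ":", variant_tag))
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network '%s' variant=%s: %d metabolites, %d reactions>\n",
              x$id, x$variant, nrow(x$metabolites), length(x$reactions)))
  invisible(x)
}
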
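# Steady-state label propagation by EMU (elementary metabolite unit)
# decomposition: the minimal set of carbon subsets needed to predict the
# measured fragments is found by backward tracing through the atom maps,
# then solved size by size as cascaded linear systems. The decomposition is
# purely structural, so it is built once and re-solved for many flux
# vectors during fitting.

emu_key <- function(met, pos) paste0(met, "|", paste(sort(pos), collapse = ","))

# Expand reactions into directed, mapped flux edges. Reversible reactions
# become a forward and a backward edge with fluxes
#   vf = max(net, 0) + exch,  vb = max(-net, 0) + exch.
# Reactions with k alternative atom maps become k edges at flux/k each
# (molecular symmetry). Unmapped reactions carry no label.
# With `net_flux = NULL` the listing is structural (unit fluxes, both
# directions of reversible reactions); otherwise edges are numeric and
# zero-flux edges are dropped when `drop_zero`.
flux_edges <- function(network, net_flux = NULL, exch_flux = NULL,
                       drop_zero = TRUE, tol = 1e-12) {
  edges <- list()
  structural <- is.null(net_flux)
  for (rx in network$reactions) {
    if (!length(rx$atom_maps)) next
    vnet <- if (structural) 1 else (net_flux[[rx$id]] %||% 0)
    vex <- if (is.null(exch_flux)) 0 else (exch_flux[[rx$id]] %||% 0)
    if (vex < 0) stopf("negative exchange flux for '%s'", rx$id)
    if (!structural && vnet < -tol && !rx$reversible)
      stopf("negative net flux through irreversible reaction '%s'", rx$id)
    vf <- max(vnet, 0) + vex
    vb <- max(-vnet, 0) + vex
    k <- length(rx$atom_maps)
    for (i in seq_len(k)) {
      am <- rx$atom_maps[[i]]
      if (structural || !drop_zero || vf > tol)
        edges[[length(edges) + 1L]] <-
          list(id = sprintf("%s.f%d", rx$id, i), rxn = rx$id, dir = "f",
               k = k, reversible = rx$reversible, flux = vf / k, map = am)
      if (rx$reversible && (structural || !drop_zero || vb > tol))
        edges[[length(edges) + 1L]] <-
          list(id = sprintf("%s.b%d", rx$id, i), rxn = rx$id, dir = "b",
               k = k, reversible = rx$reversible,
               flux = if (structural) vf / k else vb / k,
               map = invert_atom_map(am))
    }
  }
  edges
}

# numeric edge fluxes for a structural edge list; NULL when an irreversible
# reaction would run backwards
edge_flux_values <- function(edges, net_flux, exch_flux, tol = 1e-9) {
  out <- numeric(length(edges))
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    vnet <- net_flux[[e$rxn]] %||% 0
    vex <- if (is.null(exch_flux)) 0 else (exch_flux[[e$rxn]] %||% 0)
    if (vex < 0) return(NULL)
    if (!e$reversible && vnet < -tol) return(NULL)
    v <- if (e$dir == "f") max(vnet, 0) + vex else max(-vnet, 0) + vex
    out[i] <- v / e$k
  }
  out
}

# Invert a (bijective) atom map: products become substrates.
invert_atom_map <- function(am) {
  inv <- list()
  for (p in names(am)) {
    entry <- am[[p]]
    for (j in seq_along(entry$sub)) {
      s <- entry$sub[j]
      if (is.null(inv[[s]])) inv[[s]] <- list(sub = character(), pos = integer())
      # carbon `entry$pos[j]` of substrate s derives (backwards) from
      # carbon j of product p
      k <- entry$pos[j]
      inv[[s]]$sub[k] <- p
      inv[[s]]$pos[k] <- j
    }
  }
  inv
}

# For an edge producing metabolite `met`, the precursor EMUs of the product
# EMU (met, pos): group the mapped substrate carbons by substrate.
edge_precursors <- function(edge, met, pos) {
  entry <- edge$map[[met]]
  if (is.null(entry)) return(NULL)
  sub <- entry$sub[pos]; spos <- entry$pos[pos]
  split_idx <- split(seq_along(sub), sub)
  lapply(names(split_idx), function(s)
    list(met = s, pos = sort(spos[split_idx[[s]]])))
}

#' EMU decomposition of a network for a set of measured fragments
#'
#' Traces backward from the fragment EMUs through the atom maps and returns
#' the minimal EMU set, organized as size-ordered blocks of balance
#' equations. Source EMUs (metabolites named in `sources`) terminate the
#' trace.
#'
#' @param network a [metabolic_network()].
#' @param fragments a [fragment_map()].
#' @param sources metabolite ids whose labeling is an input (defaults to
#'   all `exchange`-role metabolites).
#' @param edges precomputed flux edges (internal use; defaults to the
#'   structural edge list).
#' @return list with `emus` (data.frame of EMU, metabolite, size, source
#'   flag), `terms` (per-EMU producing terms with factor EMUs), `info`,
#'   and the edge list.
#' @export
emu_decompose <- function(network, fragments,
                          sources = network$metabolites$id[
                            network$metabolites$role == "exchange"],
                          edges = flux_edges(network)) {
  nc <- stats::setNames(network$metabolites$carbons, network$metabolites$id)
  prod_index <- list()  # metabolite -> edge indices producing it
  for (i in seq_along(edges))
    for (m in names(edges[[i]]$map))
      prod_index[[m]] <- c(prod_index[[m]], i)

  queue <- unlist(unname(fragments), recursive = FALSE, use.names = FALSE)
  seen <- new.env(parent = emptyenv())
  info <- list(); terms <- list()
  while (length(queue)) {
    part <- queue[[1]]; queue <- queue[-1]
    key <- emu_key(part$met, part$pos)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    if (any(part$pos < 1L) || any(part$pos > nc[[part$met]]))
      stopf("EMU %s: positions outside 1..%d", key, nc[[part$met]])
    is_source <- part$met %in% sources
    info[[key]] <- list(met = part$met, pos = sort(part$pos),
                        size = length(part$pos), source = is_source)
    if (is_source) next
    eidx <- prod_index[[part$met]]
    if (is.null(eidx))
      stopf("EMU %s is not produced by any mapped reaction and is not a declared label source", key)
    tl <- list()
    for (i in eidx) {
      prec <- edge_precursors(edges[[i]], part$met, sort(part$pos))
      if (is.null(prec)) next
      fkeys <- vapply(prec, function(p) emu_key(p$met, p$pos), "")
      tl[[length(tl) + 1L]] <- list(edge = i, factors = fkeys)
      queue <- c(queue, prec)
    }
    terms[[key]] <- tl
  }
  emus <- do.call(rbind, lapply(names(info), function(k)
    data.frame(emu = k, met = info[[k]]$met, size = info[[k]]$size,
               source = info[[k]]$source, stringsAsFactors = FALSE)))
  emus <- emus[order(emus$size, emus$emu), , drop = FALSE]
  rownames(emus) <- NULL
  list(emus = emus, terms = terms, info = info, edges = edges)
}

# Precompiled EMU system: structural decomposition plus source MDVs, built
# once and solved for many flux vectors.
build_emu_system <- function(network, fragments, labeling) {
  nc <- stats::setNames(network$metabolites$carbons, network$metabolites$id)
  # boundary pools not named in the labeling are fed at natural abundance
  sources <- union(names(labeling$substrates),
                   network$metabolites$id[network$metabolites$role == "exchange"])
  dec <- emu_decompose(network, fragments, sources = sources)
  src_mdv <- list()
  for (k in which(dec$emus$source)) {
    key <- dec$emus$emu[k]
    met <- dec$emus$met[k]
    src_mdv[[key]] <- if (met %in% names(labeling$substrates))
      source_emu_mdv(labeling, met, dec$info[[key]]$pos, nc[[met]])
    else natural_abundance_mdv(dec$emus$size[k], labeling$natural_p13)
  }
  # metabolites produced by each edge (for influx accounting)
  edge_prods <- lapply(dec$edges, function(e) names(e$map))
  frag_keys <- lapply(fragments, function(fr)
    vapply(fr, function(part) emu_key(part$met, part$pos), ""))
  list(network = network, dec = dec, src_mdv = src_mdv,
       edge_prods = edge_prods, frag_keys = frag_keys,
       sizes = sort(unique(dec$emus$size[!dec$emus$source])))
}

emu_failure <- function(reason)
  structure(list(reason = reason), class = "emu_failure")

# Solve a precompiled EMU system at a flux vector. Returns the named list
# of fragment MDVs, or an `emu_failure` when the flux vector is invalid
# (backwards irreversible flux) or the system is singular/unreachable.
solve_emu_system <- function(sys, net_flux, exch_flux = NULL, tol = 1e-12) {
  dec <- sys$dec
  if (!is.list(net_flux)) net_flux <- as.list(net_flux)
  if (!is.null(exch_flux) && !is.list(exch_flux)) exch_flux <- as.list(exch_flux)
  fv <- edge_flux_values(dec$edges, net_flux, exch_flux)
  if (is.null(fv))
    return(emu_failure("invalid fluxes (irreversible reaction backwards)"))
  influx <- list()
  for (i in which(fv > tol))
    for (m in sys$edge_prods[[i]])
      influx[[m]] <- (influx[[m]] %||% 0) + fv[i]

  known <- sys$src_mdv
  pruned <- character()
  target_keys <- unique(unlist(sys$frag_keys, use.names = FALSE))
  for (s in sys$sizes) {
    blk <- dec$emus[dec$emus$size == s & !dec$emus$source, , drop = FALSE]
    n <- nrow(blk)
    A <- matrix(0, n, n)
    B <- matrix(0, n, s + 1L)
    inactive <- logical(n)
    for (i in seq_len(n)) {
      key <- blk$emu[i]
      tot_in <- influx[[blk$met[i]]] %||% 0
      if (tot_in <= tol) { inactive[i] <- TRUE; next }
      A[i, i] <- tot_in
      for (tm in dec$terms[[key]]) {
        v <- fv[tm$edge]
        if (v <= tol) next
        fk <- tm$factors
        if (any(fk %in% pruned))
          return(emu_failure(sprintf(
            "EMU pool %s unreachable but required at this flux distribution",
            fk[fk %in% pruned][1])))
        kn <- vapply(fk, function(f) !is.null(known[[f]]), TRUE)
        if (all(kn)) {
          B[i, ] <- B[i, ] + v * mdv_convolve_all(lapply(fk, function(f) known[[f]]))
        } else if (length(fk) == 1L) {
          j <- match(fk, blk$emu)
          if (is.na(j)) return(emu_failure(paste("unresolved EMU", fk)))
          A[i, j] <- A[i, j] - v
        } else {
          return(emu_failure(paste("unresolved factors for", key)))
        }
      }
    }
    if (any(inactive)) {
      # pools without influx may only be pruned if nothing active uses them
      used <- which(inactive & (blk$emu %in% target_keys |
                                  colSums(abs(A)) > 0))
      if (length(used))
        return(emu_failure(sprintf(
          "EMU pool %s unreachable at this flux distribution",
          blk$emu[used[1]])))
      pruned <- c(pruned, blk$emu[inactive])
      for (i in which(inactive)) {
        A[i, i] <- 1
        B[i, ] <- c(1, rep(0, s))  # placeholder, provably unused
      }
    }
    X <- tryCatch(solve(A, B), error = function(e) NULL)
    if (is.null(X))
      return(emu_failure(sprintf("singular EMU system at size %d", s)))
    for (i in seq_len(n)) known[[blk$emu[i]]] <- X[i, ]
  }
  lapply(sys$frag_keys, function(keys)
    mdv_convolve_all(lapply(keys, function(k) known[[k]])))
}

#' Simulate steady-state mass distribution vectors
#'
#' Propagates substrate labeling through the network at the given
#' steady-state flux distribution and returns one MDV per measured fragment.
#'
#' @param network a [metabolic_network()].
#' @param flux_vector named numeric vector of net fluxes (may include a
#'   `BIOMASS` pseudo-flux when the model declares biomass drains), or a
#'   list `list(net =, exch =)` carrying exchange fluxes for reversible
#'   reactions.
#' @param labeling a [substrate_labeling()].
#' @param fragments a [fragment_map()].
#' @param ss_tol steady-state tolerance on `max |S v|` relative to
#'   `max |v|`.
#' @return an [mdv_set()].
#' @export
simulate_mdvs <- function(network, flux_vector, labeling, fragments,
                          ss_tol = 1e-6) {
  fl <- split_flux(flux_vector)
  check_steady_state(network, fl$net, ss_tol)
  sys <- build_emu_system(network, fragments, labeling)
  res <- solve_emu_system(sys, fl$net, fl$exch)
  if (inherits(res, "emu_failure")) stopf("%s", res$reason)
  mdv_set(res, tol = 1e-7)
}

split_flux <- function(flux_vector) {
  if (is.list(flux_vector) && !is.null(flux_vector$net))
    list(net = flux_vector$net, exch = flux_vector$exch %||% NULL)
  else list(net = flux_vector, exch = NULL)
}

check_steady_state <- function(network, net, tol = 1e-6) {
  S <- stoichiometric_matrix(network)
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  ids <- intersect(names(net), colnames(S))
  v[ids] <- unlist(net[ids])
  resid <- as.numeric(S %*% v)
  if (!is.null(network$biomass) && "BIOMASS" %in% names(net)) {
    b <- stats::setNames(numeric(nrow(S)), rownames(S))
    hit <- intersect(names(network$biomass), rownames(S))
    b[hit] <- unlist(network$biomass[hit])
    resid <- resid - net[["BIOMASS"]] * b
  }
  bad <- setdiff(names(net), c(colnames(S), "BIOMASS"))
  if (length(bad))
    stopf("unknown reaction id(s) in flux vector: %s", paste(bad, collapse = ", "))
  scale <- max(abs(unlist(net)), 1e-12)
  if (max(abs(resid)) > tol * scale)
    stopf("flux vector is not at steady state (max imbalance %.3g at %s)",
          max(abs(resid)), rownames(S)[which.max(abs(resid))])
  invisible(TRUE)
}

influx_by_metabolite <- function(edges) {
  out <- list()
  for (e in edges)
    for (m in names(e$map))
      out[[m]] <- (out[[m]] %||% 0) + e$flux
  out
}
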
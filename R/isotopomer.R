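# Brute-force isotopomer oracle: the full 2^n positional-isotopomer
# distribution of every reachable pool is iterated to its steady state by
# fixed-point substitution. Independent of the EMU path; used to verify it.

#' Brute-force steady-state isotopomer simulation
#'
#' Computes the steady-state positional isotopomer distribution of every
#' balanced pool reachable from the measured fragments by fixed-point
#' iteration over the full 2^n state space per pool, then marginalizes to
#' fragment MDVs. Intended as a verification oracle on small networks.
#'
#' @inheritParams simulate_mdvs
#' @param max_carbons refuse networks whose reachable balanced pools carry
#'   more than this many carbons in total (default 25).
#' @param tol fixed-point convergence tolerance (sup norm).
#' @param max_iter iteration cap.
#' @return an [mdv_set()].
#' @export
brute_force_isotopomers <- function(network, flux_vector, labeling, fragments,
                                    max_carbons = 25L, tol = 1e-13,
                                    max_iter = 100000L, ss_tol = 1e-6) {
  fl <- split_flux(flux_vector)
  check_steady_state(network, fl$net, ss_tol)
  nc <- stats::setNames(network$metabolites$carbons, network$metabolites$id)
  edges <- flux_edges(network, fl$net, fl$exch, drop_zero = TRUE)
  sources <- union(names(labeling$substrates),
                   network$metabolites$id[network$metabolites$role == "exchange"])

  # reachable pools: backward closure from fragment metabolites
  prod_index <- list()
  for (i in seq_along(edges))
    for (m in names(edges[[i]]$map))
      prod_index[[m]] <- c(prod_index[[m]], i)
  queue <- unique(unlist(lapply(fragments, function(fr)
    vapply(fr, function(p) p$met, "")), use.names = FALSE))
  pools <- character(); srcs <- character()
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    if (m %in% c(pools, srcs)) next
    if (m %in% sources) { srcs <- c(srcs, m); next }
    if (is.null(prod_index[[m]]))
      stopf("pool '%s' has no labelled producer and no declared labeling", m)
    pools <- c(pools, m)
    for (i in prod_index[[m]])
      queue <- c(queue, unique(edges[[i]]$map[[m]]$sub))
  }
  total_c <- sum(nc[pools])
  if (total_c > max_carbons)
    stopf("state space too large: %d carbons across balanced pools (limit %d)",
          total_c, max_carbons)

  dist <- lapply(stats::setNames(pools, pools), function(m)
    c(1, numeric(2^nc[[m]] - 1L)))
  src_dist <- lapply(stats::setNames(srcs, srcs), function(m) {
    if (m %in% names(labeling$substrates))
      source_isotopomer_dist(labeling, m, nc[[m]])
    else {
      # undeclared boundary pool: natural abundance, independent carbons
      p <- rep(labeling$natural_p13, nc[[m]])
      states <- 0:(2^nc[[m]] - 1L)
      pr <- rep(1, length(states))
      for (i in seq_len(nc[[m]])) {
        bit <- bitwAnd(bitwShiftR(states, i - 1L), 1L)
        pr <- pr * ifelse(bit == 1L, p[i], 1 - p[i])
      }
      pr
    }
  })
  influx <- influx_by_metabolite(edges)

  get_dist <- function(m, d) if (m %in% srcs) src_dist[[m]] else d[[m]]

  for (it in seq_len(max_iter)) {
    delta <- 0
    newd <- dist
    for (m in pools) {
      acc <- numeric(2^nc[[m]])
      for (i in prod_index[[m]]) {
        e <- edges[[i]]
        acc <- acc + e$flux * edge_product_dist(e, m, nc, function(s)
          get_dist(s, dist))
      }
      acc <- acc / influx[[m]]
      delta <- max(delta, max(abs(acc - dist[[m]])))
      newd[[m]] <- acc
    }
    dist <- newd
    if (delta < tol) break
  }
  if (delta >= tol)
    warnf("isotopomer fixed point not fully converged (delta %.3g)", delta)

  mdvs <- lapply(fragments, function(fr)
    mdv_convolve_all(lapply(fr, function(part) {
      d <- get_dist(part$met, dist)
      marg <- marginalize_bits(d, part$pos, nc[[part$met]])
      bits_to_mdv(marg, length(part$pos))
    })))
  mdv_set(mdvs, tol = 1e-7)
}

# Distribution of product `met` formed by edge e: substrates assumed
# independent; the product state determines the required substrate carbon
# states, whose probabilities multiply.
edge_product_dist <- function(e, met, nc, lookup) {
  entry <- e$map[[met]]
  n <- length(entry$sub)
  subs <- unique(entry$sub)
  # marginal of each substrate over its mapped positions, ordered by the
  # product positions they feed
  margs <- lapply(subs, function(s) {
    idx <- which(entry$sub == s)
    marginalize_bits(lookup(s), entry$pos[idx], nc[[s]])
  })
  tgt <- lapply(subs, function(s) which(entry$sub == s))  # product carbons fed
  states <- 0:(2^n - 1L)
  out <- rep(1, length(states))
  for (j in seq_along(subs)) {
    pos <- tgt[[j]]
    sub_idx <- integer(length(states))
    for (k in seq_along(pos)) {
      bit <- bitwAnd(bitwShiftR(states, pos[k] - 1L), 1L)
      sub_idx <- sub_idx + bit * 2L^(k - 1L)
    }
    out <- out * margs[[j]][sub_idx + 1L]
  }
  out
}

# Marginal distribution of the given carbon positions (in order) of a full
# 2^n isotopomer distribution.
marginalize_bits <- function(dist, positions, n) {
  k <- length(positions)
  states <- 0:(2^n - 1L)
  idx <- integer(length(states))
  for (j in seq_len(k)) {
    bit <- bitwAnd(bitwShiftR(states, positions[j] - 1L), 1L)
    idx <- idx + bit * 2L^(j - 1L)
  }
  as.numeric(tapply(dist, idx, sum)[as.character(0:(2^k - 1L))])
}

# Collapse a 2^k positional distribution to an m0..mk mass distribution.
bits_to_mdv <- function(dist, k) {
  states <- 0:(2^k - 1L)
  w <- vapply(states, function(s) sum(bitwAnd(bitwShiftR(s, 0:(k - 1L)), 1L)), 0L)
  as.numeric(tapply(dist, w, sum)[as.character(0:k)])
}
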
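# Flux estimation: constrained weighted least squares of simulated against
# measured MDVs and extracellular rates, over a free-flux basis of the
# stoichiometric null space. Multi-start bounded Levenberg-Marquardt
# (minpack.lm); measured rates enter the objective as weighted residuals,
# never as hard equalities.

#' Free-flux parameterization of a network
#'
#' Builds a particular solution and a null-space basis of the steady-state
#' constraint `S v = 0` combined with any fixed-flux equalities, so that
#' every feasible net flux vector is `v0 + N theta`.
#'
#' @param network a [metabolic_network()].
#' @param constraints list with optional elements `fixed` (named numeric,
#'   equality constraints), `lower`/`upper` (named numeric bounds;
#'   irreversible reactions default to lower bound 0), `include_biomass`
#'   (append the biomass drain as pseudo-reaction `BIOMASS`).
#' @return object of class `free_flux_basis`: `v0`, `N` (columns = free
#'   directions), `dim`, `lower`, `upper`, reaction ids.
#' @export
parameterize_free_fluxes <- function(network, constraints = list()) {
  S <- stoichiometric_matrix(network)
  rxns <- colnames(S)
  if (isTRUE(constraints$include_biomass) && !is.null(network$biomass)) {
    b <- stats::setNames(numeric(nrow(S)), rownames(S))
    hit <- intersect(names(network$biomass), rownames(S))
    b[hit] <- -unlist(network$biomass[hit])
    S <- cbind(S, BIOMASS = b)
    rxns <- colnames(S)
  }
  lower <- stats::setNames(rep(-Inf, length(rxns)), rxns)
  irrev <- vapply(rxns, function(r)
    r == "BIOMASS" || !isTRUE(network$reactions[[r]]$reversible), TRUE)
  lower[irrev] <- 0
  upper <- stats::setNames(rep(Inf, length(rxns)), rxns)
  for (r in names(constraints$lower %||% list())) lower[r] <- constraints$lower[[r]]
  for (r in names(constraints$upper %||% list())) upper[r] <- constraints$upper[[r]]
  if (any(lower > upper))
    stopf("infeasible bounds for reaction(s): %s",
          paste(rxns[lower > upper], collapse = ", "))

  fixed <- constraints$fixed %||% numeric(0)
  miss <- setdiff(names(fixed), rxns)
  if (length(miss)) stopf("fixed constraint on unknown reaction(s): %s",
                          paste(miss, collapse = ", "))
  E <- matrix(0, length(fixed), ncol(S), dimnames = list(NULL, rxns))
  for (i in seq_along(fixed)) E[i, names(fixed)[i]] <- 1
  A <- rbind(S, E)
  rhs <- c(numeric(nrow(S)), unlist(fixed))

  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  # minimum-norm particular solution
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  v0 <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (dinv * crossprod(sv$u[, seq_along(sv$d), drop = FALSE], rhs))
  if (max(abs(A %*% v0 - rhs)) > 1e-8 * max(1, abs(rhs)))
    stopf("infeasible constraints: fixed fluxes inconsistent with steady state")
  v0 <- stats::setNames(as.numeric(v0), rxns)
  N <- if (r < ncol(A)) sv$v[, (r + 1L):ncol(A), drop = FALSE]
       else matrix(0, ncol(A), 0)
  rownames(N) <- rxns

  basis <- structure(list(v0 = v0, N = N, dim = ncol(N), lower = lower,
                          upper = upper, reactions = rxns),
                     class = "free_flux_basis")
  # feasibility of the flux polytope (bounds + equalities)
  feas <- project_feasible(basis)
  if (feas$violation > 1e-6)
    stopf("infeasible constraints: empty flux polytope (residual bound violation %.3g)",
          feas$violation)
  basis$theta_feasible <- feas$theta
  basis
}

# find theta minimizing squared bound violation (for feasibility + starts)
project_feasible <- function(basis) {
  if (basis$dim == 0L) {
    v <- basis$v0
    viol <- pmax(0, basis$lower - v, v - basis$upper)
    return(list(theta = numeric(0), violation = max(viol, 0)))
  }
  obj <- function(th) {
    v <- basis$v0 + as.numeric(basis$N %*% th)
    sum(pmax(0, basis$lower - v)^2 + pmax(0, v - basis$upper)^2)
  }
  fit <- stats::optim(numeric(basis$dim), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  v <- basis$v0 + as.numeric(basis$N %*% fit$par)
  list(theta = fit$par, violation = max(pmax(0, basis$lower - v, v - basis$upper), 0))
}

flux_from_theta <- function(basis, theta) {
  stats::setNames(basis$v0 + as.numeric(basis$N %*% theta), basis$reactions)
}

#' Assemble a measurement set
#'
#' @param mdvs an [mdv_set()] with per-entry standard deviations.
#' @param rates data.frame with columns `quantity`, `value`, `sd`;
#'   `quantity` is a reaction id, or one of `CER`, `OUR`, `mu`.
#' @param labeling the [substrate_labeling()] under which `mdvs` were
#'   measured.
#' @param fragments the [fragment_map()] of the measured fragments.
#' @return object of class `measurement_set`.
#' @export
measurement_set <- function(mdvs, rates = NULL, labeling, fragments) {
  for (f in names(mdvs$mdvs)) {
    if (is.null(mdvs$sd[[f]]) || any(mdvs$sd[[f]] <= 0))
      stopf("fragment '%s' needs strictly positive sds", f)
  }
  if (!is.null(rates) && nrow(rates) && any(rates$sd <= 0))
    stopf("rate sds must be strictly positive")
  structure(list(mdvs = mdvs, rates = rates, labeling = labeling,
                 fragments = fragments), class = "measurement_set")
}

rate_prediction <- function(network, v, quantity) {
  vr <- v[names(v) %in% names(network$reactions)]
  switch(quantity,
    CER = unname(cofactor_trace(network, vr, species = "CO2_e")),
    OUR = -unname(cofactor_trace(network, vr, species = "O2")),
    mu = unname(v[["BIOMASS"]]),
    {
      if (!quantity %in% names(v)) stopf("rate quantity '%s' unknown", quantity)
      unname(v[[quantity]])
    })
}

#' Fit intracellular fluxes to labeling and rate measurements
#'
#' Minimizes the variance-weighted sum of squared residuals
#' `sum(((sim - meas)/sd)^2)` over the free fluxes (and, optionally,
#' exchange fluxes of selected reversible reactions), from `n_starts`
#' random feasible initializations of a seeded RNG stream.
#'
#' @param network a [metabolic_network()].
#' @param measurements a [measurement_set()].
#' @param options list: `seed` (mandatory), `n_starts` (default 10),
#'   `constraints` (passed to [parameterize_free_fluxes()]),
#'   `exch_reactions` (reversible reaction ids whose exchange flux is
#'   fitted), `exch_upper` (bound, default 10 x largest fixed uptake),
#'   `start_radius` (spread of random starts), `penalty` (bound-violation
#'   weight, default 1e3).
#' @return object of class `flux_estimate`: net and exchange fluxes, SSR,
#'   degrees of freedom, per-start log, the free basis, and an
#'   identifiability report.
#' @export
fit_fluxes <- function(network, measurements, options = list()) {
  if (is.null(options$seed)) stopf("options$seed is mandatory")
  basis <- options$basis %||%
    parameterize_free_fluxes(network, options$constraints %||% list())
  n_starts <- options$n_starts %||% 10L
  exch_rxns <- options$exch_reactions %||% character()
  for (r in exch_rxns)
    if (!isTRUE(network$reactions[[r]]$reversible))
      stopf("exchange flux requested for non-reversible reaction '%s'", r)
  scale0 <- max(abs(unlist(options$constraints$fixed %||% 1)), 1)
  exch_upper <- options$exch_upper %||% (10 * scale0)
  penalty <- options$penalty %||% 1e3
  radius <- options$start_radius %||% scale0

  meas <- measurements
  frag_names <- names(meas$mdvs$mdvs)
  n_mdv <- sum(lengths(meas$mdvs$mdvs))
  n_rate <- if (is.null(meas$rates)) 0L else nrow(meas$rates)
  npar <- basis$dim + length(exch_rxns)
  if (npar == 0L) stopf("no free parameters: fluxes fully determined")

  emu_sys <- options$emu_system %||%
    build_emu_system(network, meas$fragments, meas$labeling)

  residual_fn <- function(par) {
    theta <- par[seq_len(basis$dim)]
    exch <- if (length(exch_rxns))
      stats::setNames(par[basis$dim + seq_along(exch_rxns)], exch_rxns)
    else NULL
    v <- flux_from_theta(basis, theta)
    viol <- pmax(0, basis$lower - v, v - basis$upper)
    sim <- solve_emu_system(emu_sys, v, exch)
    if (inherits(sim, "emu_failure")) {
      res <- rep(1e4, n_mdv + n_rate)
    } else {
      res <- unlist(lapply(frag_names, function(f)
        (sim[[f]] - meas$mdvs$mdvs[[f]]) / meas$mdvs$sd[[f]]))
      if (n_rate) {
        pred <- vapply(seq_len(n_rate), function(i)
          rate_prediction(network, v, meas$rates$quantity[i]), 0)
        res <- c(res, (pred - meas$rates$value) / meas$rates$sd)
      }
    }
    c(res, penalty * viol)
  }

  lower <- c(rep(-Inf, basis$dim), rep(0, length(exch_rxns)))
  upper <- c(rep(Inf, basis$dim), rep(exch_upper, length(exch_rxns)))

  set.seed(derive_seed(options$seed, "fit_fluxes"))
  starts <- vector("list", n_starts)
  starts[[1]] <- options$start_par %||%
    c(basis$theta_feasible, rep(0.01 * scale0, length(exch_rxns)))
  if (n_starts > 1L)
    for (i in 2:n_starts)
      starts[[i]] <- c(basis$theta_feasible +
                         stats::runif(basis$dim, -radius, radius),
                       stats::runif(length(exch_rxns), 0, exch_upper / 10))

  per_start <- list(); best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = residual_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter %||% 200L,
                           ftol = 1e-12, ptol = 1e-10, gtol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) {
      per_start[[i]] <- list(start = i, converged = FALSE, ssr = NA_real_)
      next
    }
    ssr <- sum(fit$fvec^2)
    per_start[[i]] <- list(start = i, converged = fit$info %in% 1:4,
                           ssr = ssr, par = fit$par)
    if (is.null(best) || ssr < best$ssr)
      best <- list(ssr = ssr, par = fit$par, fit = fit)
  }
  if (is.null(best)) stopf("no start converged")

  theta <- best$par[seq_len(basis$dim)]
  exch <- if (length(exch_rxns))
    stats::setNames(best$par[basis$dim + seq_along(exch_rxns)], exch_rxns)
  else NULL
  v <- flux_from_theta(basis, theta)

  # identifiability: numerical Jacobian rank at the optimum
  rank <- npar; unident <- FALSE
  if (!isTRUE(options$skip_identifiability)) {
    J <- numeric_jacobian(residual_fn, best$par)
    Jdata <- J[seq_len(n_mdv + n_rate), , drop = FALSE]
    svJ <- svd(Jdata)$d
    # relative rank tolerance plus an absolute sensitivity floor
    # (residuals are in sd units: a singular value below 1e-4 means the
    # data move by < 1e-4 sd per unit flux - effectively unidentifiable)
    rank <- sum(svJ > max(svJ) * 1e-7 + 1e-4)
    unident <- rank < npar
    if (unident)
      warnf("measurement set does not identify all %d free parameters (rank %d)",
            npar, rank)
  }

  structure(list(net = v, exch = exch, ssr = best$ssr,
                 dof = n_mdv + n_rate - npar, n_par = npar,
                 theta = theta, basis = basis, per_start = per_start,
                 identifiable = !unident, jacobian_rank = rank,
                 exch_reactions = exch_rxns,
                 seed = options$seed),
            class = "flux_estimate")
}

# forward differences, falling back to backward steps when the forward
# point leaves the feasible region (failure sentinel residuals)
numeric_jacobian <- function(fn, par, eps = 1e-6, sentinel = 9e3) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    p <- par; p[j] <- p[j] + eps
    fj <- fn(p)
    if (max(abs(fj)) >= sentinel) {
      p <- par; p[j] <- p[j] - eps
      fj <- fn(p)
      if (max(abs(fj)) >= sentinel) next  # boxed in: no usable gradient
      J[, j] <- (f0 - fj) / eps
    } else {
      J[, j] <- (fj - f0) / eps
    }
  }
  J
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("<flux_estimate: SSR %.4g, dof %d, %d free parameter(s)%s>\n",
              x$ssr, x$dof, x$n_par,
              if (x$identifiable) "" else ", UNIDENTIFIABLE"))
  invisible(x)
}

#' Normalize a flux map to percent carbon-moles of substrate uptake
#'
#' Each reaction's carbon throughput (flux times carbons moved through the
#' reaction's substrate side) is expressed as percent of the carbon uptake
#' through the basis reaction.
#'
#' @param estimate a [flux_estimate()] or a named net flux vector.
#' @param network the [metabolic_network()] the fluxes refer to.
#' @param basis_reaction uptake reaction used as the 100 % basis.
#' @return named numeric vector, percent Cmol.
#' @export
normalize_fluxes <- function(estimate, network, basis_reaction) {
  v <- if (inherits(estimate, "flux_estimate")) estimate$net else estimate
  carbons_moved <- function(rid) {
    if (rid == "BIOMASS") return(NA_real_)
    st <- network$reactions[[rid]]$stoich
    ids <- names(st)
    ok <- st < 0 & roles_of(network, ids) != "cofactor"
    sum(abs(st[ok]) * carbons_of(network, ids[ok]))
  }
  if (!basis_reaction %in% names(v)) stopf("basis reaction '%s' not in flux vector",
                                           basis_reaction)
  base <- v[[basis_reaction]] * carbons_moved(basis_reaction)
  if (!is.finite(base) || base <= 0) stopf("basis uptake flux must be positive")
  out <- vapply(names(v), function(r) {
    cm <- carbons_moved(r)
    if (!is.finite(cm)) NA_real_ else v[[r]] * cm / base * 100
  }, 0)
  out
}

#' Parametric-bootstrap confidence intervals for fitted fluxes
#'
#' Perturbs the measurements with Gaussian noise at their stated standard
#' deviations, refits from the point estimate, and reports percentile
#' intervals of the refitted net fluxes. Reproducible for a given seed.
#'
#' @param network a [metabolic_network()].
#' @param measurements the [measurement_set()] used for the fit.
#' @param estimate the converged [fit_fluxes()] result.
#' @param options list: `n_samples` (>= 2), `seed` (mandatory),
#'   `level` (default 0.95).
#' @return data.frame reaction / estimate / ci_lo / ci_hi, plus the draw
#'   matrix as attribute `draws`.
#' @export
monte_carlo_ci <- function(network, measurements, estimate, options = list()) {
  n_samples <- options$n_samples %||% 100L
  if (n_samples < 2L) stopf("n_samples must be >= 2")
  if (is.null(options$seed)) stopf("options$seed is mandatory")
  level <- options$level %||% 0.95
  set.seed(derive_seed(options$seed, "monte_carlo_ci"))
  draws <- matrix(NA_real_, n_samples, length(estimate$net),
                  dimnames = list(NULL, names(estimate$net)))
  start_par <- c(estimate$theta,
                 if (length(estimate$exch_reactions)) unname(estimate$exch))
  emu_sys <- build_emu_system(network, measurements$fragments,
                              measurements$labeling)
  for (b in seq_len(n_samples)) {
    pert <- measurements
    for (f in names(pert$mdvs$mdvs))
      pert$mdvs$mdvs[[f]] <- pert$mdvs$mdvs[[f]] +
        stats::rnorm(length(pert$mdvs$mdvs[[f]]), 0, pert$mdvs$sd[[f]])
    if (!is.null(pert$rates) && nrow(pert$rates))
      pert$rates$value <- pert$rates$value +
        stats::rnorm(nrow(pert$rates), 0, pert$rates$sd)
    fit <- tryCatch(
      fit_fluxes(network, pert, options = list(
        seed = derive_seed(options$seed, paste0("boot", b)),
        n_starts = 1L, basis = estimate$basis,
        exch_reactions = estimate$exch_reactions,
        start_par = start_par, maxiter = 100L,
        emu_system = emu_sys, skip_identifiability = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) draws[b, ] <- fit$net
  }
  a <- (1 - level) / 2
  ci <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(reaction = names(estimate$net),
                    estimate = unname(estimate$net),
                    ci_lo = ci[1, ], ci_hi = ci[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "draws") <- draws
  out
}
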
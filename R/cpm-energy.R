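#' Copy-attempt acceptance probability
#'
#' Metropolis-style acceptance rule of the CPM: a copy attempt that changes
#' the effective energy by `delta_H` is accepted with probability
#' `exp(-max(0, delta_H) / Hstar)`, so energy-decreasing copies are always
#' accepted and energy-increasing copies exponentially rarely, on the scale
#' of the intrinsic random motility `Hstar`.
#'
#' @param delta_H energy change of the proposed copy.
#' @param Hstar intrinsic random motility (> 0).
#' @return Probability in (0, 1].
#' @examples
#' acceptance_probability(0, 10)    # 1
#' acceptance_probability(10, 10)   # exp(-1)
#' @export
acceptance_probability <- function(delta_H, Hstar) {
  if (!is.numeric(Hstar) || any(Hstar <= 0))
    stop("Hstar must be > 0")
  exp(-pmax(0, delta_H) / Hstar)
}

# type-code raster (0 medium, 1 live, 2 dead) for a state
type_raster <- function(state) {
  lab <- state$labels
  codes <- integer(max(c(0L, state$agents$id)) + 1L)
  codes[state$agents$id + 1L] <- type_code(state$agents$type)
  out <- matrix(codes[lab + 1L], nrow(lab), ncol(lab))
  out[lab == 0L] <- 0L
  out
}

#' Total effective energy of a lattice state
#'
#' Brute-force evaluation of the CPM effective energy: the quadratic volume
#' constraint `sum_i lambda_i (n_i - v_i)^2` over agents (site-count
#' convention) plus the contact term summed over *ordered* Moore range-1
#' site pairs with mismatched agent ids, each weighted by the type-pair
#' contact energy.  The ordered double sum counts every unordered interface
#' pair twice, exactly as the energy is written; the local
#' [delta_energy_for_copy()] uses the same convention.
#'
#' @param state a [lattice_state()].
#' @param params a [cpm_params()].
#' @return Total effective energy (scalar).
#' @export
total_effective_energy <- function(state, params) {
  validate_lattice_state(state)
  ag <- state$agents
  vol <- sum(lambda_for_type(ag$type, params) *
               (ag$n_sites - vtarget_for_type(ag$type, params))^2)
  lab <- state$labels
  codes <- type_raster(state)
  nr <- nrow(lab); nc <- ncol(lab)
  Jflat <- params$J  # 3x3, indexed by code + 1
  contact <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    r0 <- r1 - dr; c0 <- c1 - dc
    a <- lab[r0, c0, drop = FALSE]; b <- lab[r1, c1, drop = FALSE]
    mism <- a != b
    if (!any(mism)) next
    ca <- codes[r0, c0, drop = FALSE][mism]
    cb <- codes[r1, c1, drop = FALSE][mism]
    contact <- contact + sum(Jflat[cbind(ca + 1L, cb + 1L)])
  }
  vol + contact
}

#' Local energy change of a single copy attempt
#'
#' Computes `H(after) - H(before)` for copying the agent id at
#' `source_site` onto `target_site`, from local terms only (the volume terms
#' of the two affected agents and the contact pairs involving the target
#' site).  The state is not modified.  The target must lie in the von
#' Neumann range-1 neighbourhood of the source.
#'
#' @param state a [lattice_state()].
#' @param source_site,target_site length-2 integer vectors (row, col),
#'   1-based.
#' @param params a [cpm_params()].
#' @return Energy change (scalar); 0 when both sites hold the same agent.
#' @export
delta_energy_for_copy <- function(state, source_site, target_site, params) {
  lab <- state$labels
  nr <- nrow(lab); nc <- ncol(lab)
  s <- as.integer(source_site); t <- as.integer(target_site)
  if (any(s < 1L) || s[1] > nr || s[2] > nc ||
      any(t < 1L) || t[1] > nr || t[2] > nc)
    stop("site out of lattice bounds")
  if (sum(abs(s - t)) != 1L)
    stop("target_site must be a von Neumann range-1 neighbour of source_site")
  ag <- state$agents
  cpp_delta_energy(lab, s[1] - 1L, s[2] - 1L, t[1] - 1L, t[2] - 1L,
                   ag$id, type_code(ag$type),
                   lambda_for_type(ag$type, params),
                   vtarget_for_type(ag$type, params),
                   ag$n_sites, params$J)
}

#' One Monte Carlo step of the CPM
#'
#' Performs as many copy attempts as there are lattice sites.  Each attempt
#' draws a uniform source site and a uniform von Neumann range-1 neighbour
#' as target; attempts whose target falls outside the fixed (non-periodic)
#' lattice are rejected, attempts between two sites of the same agent are
#' counted but are no-ops, and all other proposals are accepted with
#' [acceptance_probability()] of the local energy change.  Agents whose
#' site set becomes empty are removed from the registry.  Uses R's RNG
#' stream (seed with [set.seed()]); per attempt the draws are source site,
#' neighbour direction, then one acceptance uniform only when the energy
#' change is positive.
#'
#' @param state a [lattice_state()].
#' @param params a [cpm_params()].
#' @param n_steps number of Monte Carlo steps to advance.
#' @return The advanced `lattice_state` (MCS clock incremented by
#'   `n_steps`), with attribute `"accepted"` giving accepted copies in the
#'   last step.
#' @export
monte_carlo_step <- function(state, params, n_steps = 1L) {
  lab <- state$labels
  nattempts <- length(lab)
  for (k in seq_len(n_steps)) {
    ag <- state$agents
    res <- cpp_monte_carlo_step(state$labels, ag$id, type_code(ag$type),
                                lambda_for_type(ag$type, params),
                                vtarget_for_type(ag$type, params),
                                ag$n_sites, params$J,
                                params$motility_Hstar, nattempts)
    state$labels <- res$labels
    state$agents$n_sites <- res$n_sites
    state$mcs <- state$mcs + 1L
    state <- prune_empty_agents(state)
    attr(state, "accepted") <- res$accepted
  }
  state
}
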
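# small deterministic lattice fixtures used across tests

# single rectangular live cell on an otherwise-empty lattice
rect_cell_state <- function(nr = 12, nc = 12, r0 = 4, c0 = 4, h = 2, w = 2) {
  lab <- matrix(0L, nr, nc)
  lab[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1L
  lattice_state(lab)
}

# random multi-agent lattice with a mix of live and dead agents
random_state <- function(n = 16, n_agents = 3, seed = 1,
                         types = c("live", "live", "dead")) {
  set.seed(seed)
  lab <- matrix(sample(0:n_agents, n * n, replace = TRUE), n, n)
  present <- sort(unique(lab[lab != 0L]))
  lattice_state(lab, types = stats::setNames(types[present],
                                             as.character(present)))
}

# rasterized filled ellipse mask with given semi-axes (sites), optionally
# rotated by theta (radians)
ellipse_mask <- function(n, a, b, theta = 0) {
  ctr <- (n + 1) / 2
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  x <- idx$c - ctr; y <- idx$r - ctr
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  matrix((xr / a)^2 + (yr / b)^2 <= 1, n, n)
}

# apply a copy (for the global-energy oracle) and rebuild the state
apply_copy <- function(state, src, tgt) {
  lab <- state$labels
  lab[tgt[1], tgt[2]] <- lab[src[1], src[2]]
  ids <- sort(unique(lab[lab != 0L]))
  types <- stats::setNames(state$agents$type, state$agents$id)[as.character(ids)]
  lattice_state(lab, types = types)
}
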
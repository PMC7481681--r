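#' Gaussian intracellular response specification
#'
#' One phenotypic response (proliferation or death) is a Gaussian function
#' of a cell's mean oxygen concentration, parameterised biologically by a
#' target concentration, a response width, and a population multiplier.
#' The multiplier `n` is the factor by which a population held at the
#' target concentration multiplies over 10 kMCS under exponential growth,
#' so the per-MCS peak probability is `q = n^(1/10000) - 1`.  The width `w`
#' is the concentration offset at which the response probability falls to
#' the cut-off probability (one event per million MCS by default), which
#' fixes the Gaussian scale `gamma = w / sqrt(log(q) - log(q_cutoff))`.
#'
#' @param target_uM target concentration (uM) of peak response.
#' @param width_uM response width (uM): |target - cutoff concentration|.
#' @param multiplier population multiplier over 10 kMCS at the target
#'   (> 1).
#' @param cutoff_prob per-MCS probability at the cutoff offset.
#' @return An object of class `response_spec` with derived fields
#'   `peak_prob_q` (per-MCS) and `gaussian_sigma_uM` (uM).
#' @examples
#' rs <- response_spec(200, 100, 6)
#' rs$peak_prob_q                      # 6^(1/10000) - 1
#' response_probability(300, rs)       # = cutoff_prob = 1e-6
#' @export
response_spec <- function(target_uM, width_uM, multiplier,
                          cutoff_prob = 1e-6) {
  if (width_uM <= 0) stop("width_uM must be > 0")
  if (multiplier <= 1) stop("multiplier must be > 1")
  if (cutoff_prob <= 0 || cutoff_prob >= 1)
    stop("cutoff_prob must lie in (0, 1)")
  q <- multiplier^(1 / 10000) - 1
  if (q <= cutoff_prob)
    stop("peak probability q = ", signif(q, 6),
         " does not exceed cutoff_prob; response width undefined")
  sigma <- width_uM / sqrt(log(q) - log(cutoff_prob))
  structure(list(target_uM = target_uM, width_uM = width_uM,
                 multiplier = multiplier, cutoff_prob = cutoff_prob,
                 peak_prob_q = q, gaussian_sigma_uM = sigma),
            class = "response_spec")
}

#' Per-MCS response probability at a mean concentration
#'
#' Evaluates the Gaussian response
#' `q * exp(-((c - target) / gamma)^2)`, clamped to `[0, 1]`.
#'
#' @param mean_c_uM mean oxygen concentration (uM); vectorised.
#' @param response a [response_spec()].
#' @return Per-MCS probability in `[0, 1]`.
#' @export
response_probability <- function(mean_c_uM, response) {
  p <- response$peak_prob_q *
    exp(-((mean_c_uM - response$target_uM) / response$gaussian_sigma_uM)^2)
  pmin(1, pmax(0, p))
}

#' Phenotype profile: proliferation and death responses of one cell type
#'
#' @param proliferation,death [response_spec()] objects.
#' @param name optional profile name.
#' @return An object of class `phenotype_profile`.
#' @export
phenotype_profile <- function(proliferation, death, name = NULL) {
  stopifnot(inherits(proliferation, "response_spec"),
            inherits(death, "response_spec"))
  structure(list(proliferation = proliferation, death = death, name = name),
            class = "phenotype_profile")
}

# preset table: proliferation (target, width, multiplier),
# death (target, width, multiplier); concentrations in uM
.presets <- list(
  "Control"    = list(p = c(200, 100, 6), d = c(0, 50, 6)),
  "Decrease 1" = list(p = c(200, 100, 4), d = c(0, 50, 6)),
  "Shift 1"    = list(p = c(210, 100, 6), d = c(0, 50, 6)),
  "Shrink 1"   = list(p = c(200,  80, 6), d = c(0, 50, 6)),
  "Increase 1" = list(p = c(200, 100, 6), d = c(0, 50, 8)),
  "Expand 1"   = list(p = c(200, 100, 6), d = c(0, 100, 6)),
  "Decrease 2" = list(p = c(200, 100, 2), d = c(0, 50, 6)),
  "Shift 2"    = list(p = c(205, 100, 6), d = c(0, 50, 6)),
  "Shrink 2"   = list(p = c(200,  90, 6), d = c(0, 50, 6)),
  "Increase 2" = list(p = c(200, 100, 6), d = c(0, 50, 7)),
  "Expand 2"   = list(p = c(200, 100, 6), d = c(0, 75, 6))
)

#' Named phenotype presets
#'
#' The simulated intracellular profiles: a Control phenotype plus paired
#' variations of single biological parameters -- Decrease (lower
#' proliferation multiplier), Shift (higher proliferation target), Shrink
#' (narrower proliferation width), Increase (higher death multiplier) and
#' Expand (wider death width) -- at endpoint (1) and midpoint (2)
#' magnitudes.
#'
#' @param name preset name; see [preset_names()].
#' @return A [phenotype_profile()].
#' @examples
#' phenotype_preset("Control")$proliferation$multiplier
#' @export
phenotype_preset <- function(name) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  v <- .presets[[name]]
  phenotype_profile(response_spec(v$p[1], v$p[2], v$p[3]),
                    response_spec(v$d[1], v$d[2], v$d[3]),
                    name = name)
}

#' @rdname phenotype_preset
#' @export
preset_names <- function() names(.presets)

#' Sample phenotypic response events for one MCS
#'
#' For every live cell, in increasing id order, death is sampled first and
#' then proliferation (a cell that dies this MCS emits no proliferation
#' event) against the response probability of the cell's mean oxygen
#' concentration.  Dead cells are never sampled.  Consumes R's RNG: one
#' uniform per considered response per cell.
#'
#' @param state a [lattice_state()].
#' @param field oxygen concentration matrix (mM).
#' @param profile a [phenotype_profile()].
#' @return data.frame of events with columns `cell_id`, `kind`
#'   (`"die"`/`"proliferate"`) and `mcs`; zero rows when nothing fires.
#' @export
sample_responses <- function(state, field, profile) {
  live <- state$agents[state$agents$type == "live", , drop = FALSE]
  empty <- data.frame(cell_id = integer(0), kind = character(0),
                      mcs = integer(0), stringsAsFactors = FALSE)
  if (nrow(live) == 0L) return(empty)
  stats <- cpp_agent_field_stats(state$labels, field)
  mean_mM <- stats$mean[match(live$id, stats$id)]
  mean_uM <- mean_mM * 1000
  ord <- order(live$id)
  ids <- live$id[ord]; mu <- mean_uM[ord]
  p_die <- response_probability(mu, profile$death)
  p_pro <- response_probability(mu, profile$proliferation)
  events <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (stats::runif(1) < p_die[i]) {
      events[[i]] <- data.frame(cell_id = ids[i], kind = "die",
                                mcs = state$mcs, stringsAsFactors = FALSE)
    } else if (stats::runif(1) < p_pro[i]) {
      events[[i]] <- data.frame(cell_id = ids[i], kind = "proliferate",
                                mcs = state$mcs, stringsAsFactors = FALSE)
    }
  }
  events <- events[!vapply(events, is.null, logical(1))]
  if (length(events) == 0L) return(empty)
  do.call(rbind, events)
}

#' Divide a cell along its minor axis
#'
#' Principal axes are computed from the second central moments of the
#' cell's site coordinates; sites on the positive side of the minor axis
#' through the centroid (positive projection onto the major-axis direction)
#' are reassigned to a fresh agent id (`max(id) + 1`, never reused).  Both
#' daughters keep the live type and the full target volume.  Sites exactly
#' on the axis stay with the parent; for degenerate (equal-eigenvalue)
#' moments the minor axis is taken along the lattice y-direction.  Cells
#' below `min_sites` are not divided (guards accidental death of cells too
#' small to split) and the state is returned unchanged with attribute
#' `"skipped" = TRUE`.
#'
#' @param state a [lattice_state()].
#' @param cell_id id of a live cell.
#' @param params a [cpm_params()] (unused sizes are taken from it).
#' @param min_sites minimum parent size to attempt division.
#' @return Updated `lattice_state`; attribute `"daughter_id"` gives the new
#'   agent id on success.
#' @export
divide_cell <- function(state, cell_id, params = cpm_params(),
                        min_sites = 4L) {
  row <- match(cell_id, state$agents$id)
  if (is.na(row)) stop("unknown cell id ", cell_id)
  if (state$agents$type[row] != "live") stop("only live cells divide")
  sites <- agent_sites(state, cell_id)
  if (nrow(sites) < min_sites) {
    attr(state, "skipped") <- TRUE
    return(state)
  }
  ctr <- colMeans(sites)
  dx <- sweep(sites, 2, ctr)
  cov <- crossprod(dx) / nrow(sites)
  eig <- eigen(cov, symmetric = TRUE)
  if (abs(eig$values[1] - eig$values[2]) < 1e-9) {
    major <- c(0, 1)  # degenerate: minor axis along lattice y (rows), cut in x
  } else {
    major <- eig$vectors[, 1]  # eigenvector of the larger eigenvalue
    nz <- which(abs(major) > 1e-12)[1]
    if (major[nz] < 0) major <- -major  # pin sign for determinism
  }
  proj <- dx %*% major
  new_side <- proj > 1e-9  # exactly-on-axis sites stay with the parent
  if (!any(new_side) || all(new_side)) {
    attr(state, "skipped") <- TRUE
    return(state)
  }
  new_id <- max(state$agents$id) + 1L
  state$labels[sites[new_side, , drop = FALSE]] <- new_id
  n_new <- sum(new_side)
  state$agents$n_sites[row] <- state$agents$n_sites[row] - n_new
  state$agents <- rbind(state$agents,
                        data.frame(id = new_id, type = "live",
                                   n_sites = n_new,
                                   stringsAsFactors = FALSE))
  rownames(state$agents) <- NULL
  attr(state, "daughter_id") <- new_id
  state
}

#' Kill a cell
#'
#' Switches a live cell to the corresponding dead type: metabolic activity
#' ceases (zero contribution to [source_raster()], never sampled by
#' [sample_responses()]) and its volume constraint becomes zero, so the
#' Monte Carlo dynamics gradually remove it; when its last site is lost the
#' agent leaves the registry.
#'
#' @param state a [lattice_state()].
#' @param cell_id id of a live cell.
#' @return Updated `lattice_state`; killing an already-dead cell warns and
#'   is a no-op.
#' @export
kill_cell <- function(state, cell_id) {
  row <- match(cell_id, state$agents$id)
  if (is.na(row)) stop("unknown cell id ", cell_id)
  if (state$agents$type[row] == "dead") {
    warning("cell ", cell_id, " is already dead")
    return(state)
  }
  state$agents$type[row] <- "dead"
  state
}
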
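#' Lattice state of the cellular Potts model
#'
#' A `lattice_state` is the CPM configuration: an integer raster of agent
#' ids (0 = medium) plus an agent registry giving each agent's type
#' (`"live"` or `"dead"`) and cached site count, and the Monte Carlo step
#' (MCS) clock.  The raster is the authority on site ownership; the
#' registry's `n_sites` column is a cache kept in step by the operations
#' that modify the raster.
#'
#' @param labels integer matrix of agent ids, 0 for medium.
#' @param types named character vector or plain character vector giving the
#'   type of each distinct non-zero id (in increasing id order when unnamed).
#' @param mcs initial MCS clock.
#' @return An object of class `lattice_state` with elements `labels`
#'   (integer matrix), `agents` (data.frame: `id`, `type`, `n_sites`) and
#'   `mcs`.
#' @examples
#' lab <- matrix(0L, 8, 8)
#' lab[3:4, 3:4] <- 1L
#' st <- lattice_state(lab, types = c("1" = "live"))
#' st$agents
#' @export
lattice_state <- function(labels, types = NULL, mcs = 0L) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels != 0L]))
  if (is.null(types)) {
    types <- rep("live", length(ids))
    names(types) <- as.character(ids)
  } else if (is.null(names(types))) {
    if (length(types) != length(ids))
      stop("types must be named by id or match the number of agents")
    names(types) <- as.character(ids)
  }
  counts <- tabulate_ids(labels, ids)
  agents <- data.frame(id = ids,
                       type = unname(types[as.character(ids)]),
                       n_sites = counts,
                       stringsAsFactors = FALSE)
  st <- structure(list(labels = labels, agents = agents, mcs = as.integer(mcs)),
                  class = "lattice_state")
  validate_lattice_state(st)
  st
}

tabulate_ids <- function(labels, ids) {
  if (length(ids) == 0L) return(integer(0))
  tab <- tabulate(labels[labels != 0L], nbins = max(ids))
  tab[ids]
}

#' Check label/registry consistency of a lattice state
#'
#' Verifies that every non-zero label in the raster appears in the agent
#' registry, that no registered agent is absent from the raster (unless its
#' cached count is zero), that cached site counts match the raster, that ids
#' are unique, and that types are known.
#'
#' @param state a [lattice_state()].
#' @return `state`, invisibly; errors describe the first inconsistency found.
#' @export
validate_lattice_state <- function(state) {
  lab <- state$labels
  ag <- state$agents
  if (anyDuplicated(ag$id)) stop("duplicate agent ids in registry")
  if (any(ag$id == 0L)) stop("agent id 0 is reserved for medium")
  raster_ids <- sort(unique(lab[lab != 0L]))
  missing <- setdiff(raster_ids, ag$id)
  if (length(missing))
    stop("labels present in raster but missing from registry: ",
         paste(missing, collapse = ", "))
  type_code(ag$type)  # errors on unknown types
  counts <- tabulate_ids(lab, ag$id)
  counts[is.na(counts)] <- 0L
  bad <- which(counts != ag$n_sites)
  if (length(bad))
    stop("cached site count mismatch for id(s): ",
         paste(ag$id[bad], collapse = ", "))
  invisible(state)
}

#' Site coordinates of one agent
#'
#' @param state a [lattice_state()].
#' @param id agent id.
#' @return two-column matrix of (row, col) lattice coordinates (1-based).
#' @export
agent_sites <- function(state, id) {
  which(state$labels == id, arr.ind = TRUE)
}

# drop registry rows whose agents no longer own any site
prune_empty_agents <- function(state) {
  keep <- state$agents$n_sites > 0L
  state$agents <- state$agents[keep, , drop = FALSE]
  rownames(state$agents) <- NULL
  state
}

#' @export
print.lattice_state <- function(x, ...) {
  live <- sum(x$agents$type == "live")
  dead <- sum(x$agents$type == "dead")
  cat(sprintf("CPM lattice %d x %d, MCS %d: %d live, %d dead agent(s), %d occupied site(s)\n",
              nrow(x$labels), ncol(x$labels), x$mcs, live, dead,
              sum(x$agents$n_sites)))
  invisible(x)
}
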
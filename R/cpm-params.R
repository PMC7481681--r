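#' Cellular Potts model parameters
#'
#' Bundles the lattice-scale constants of the cellular Potts model (CPM):
#' the physical site length, the intrinsic random motility (the
#' temperature-like scale of the Metropolis-style acceptance rule), the
#' volume-constraint Lagrange multiplier and target volume of live cells,
#' and the symmetric type-pair contact (adhesion) energies.
#'
#' Defaults describe a nominal cell of 20 um diameter occupying 36 lattice
#' sites of 2.96 um side, with cell-cell adhesion weaker than cell-medium
#' (J_cc = 6 < J_cm = 12) so that aggregates tend to stay round.  Dead cells
#' carry no volume constraint (`lambda_dead = 0`, target 0) and reuse the
#' live contact energies unless overridden; interface minimisation then
#' gradually removes them from the lattice.
#'
#' @param site_length_um physical side length of one lattice site (um).
#' @param motility_Hstar intrinsic random motility H* (> 0).
#' @param lambda_live,lambda_dead volume-constraint multipliers (per site^2).
#' @param target_volume_sites live-cell target volume, in lattice sites.
#' @param J_cell_cell,J_cell_medium,J_dead_cell,J_dead_medium,J_dead_dead
#'   contact energies per ordered mismatched Moore-neighbour site pair.
#' @return An object of class `cpm_params`.
#' @examples
#' p <- cpm_params()
#' p$J["live", "medium"]
#' @export
cpm_params <- function(site_length_um = 2.96,
                       motility_Hstar = 10,
                       lambda_live = 2,
                       lambda_dead = 0,
                       target_volume_sites = 36,
                       J_cell_cell = 6,
                       J_cell_medium = 12,
                       J_dead_cell = J_cell_cell,
                       J_dead_medium = J_cell_medium,
                       J_dead_dead = J_cell_cell) {
  if (!is.numeric(motility_Hstar) || motility_Hstar <= 0)
    stop("motility_Hstar must be > 0")
  if (target_volume_sites < 1)
    stop("target_volume_sites must be >= 1 for live cells")
  if (site_length_um <= 0) stop("site_length_um must be > 0")
  J <- matrix(0, 3, 3, dimnames = list(c("medium", "live", "dead"),
                                       c("medium", "live", "dead")))
  J["live", "live"] <- J_cell_cell
  J["live", "medium"] <- J["medium", "live"] <- J_cell_medium
  J["dead", "live"] <- J["live", "dead"] <- J_dead_cell
  J["dead", "medium"] <- J["medium", "dead"] <- J_dead_medium
  J["dead", "dead"] <- J_dead_dead
  stopifnot(isSymmetric(J))
  structure(list(site_length_um = site_length_um,
                 motility_Hstar = motility_Hstar,
                 lambda_live = lambda_live,
                 lambda_dead = lambda_dead,
                 target_volume_sites = target_volume_sites,
                 J = J),
            class = "cpm_params")
}

# per-agent lambda / target volume by type ("live"/"dead")
lambda_for_type <- function(type, params) {
  ifelse(type == "live", params$lambda_live, params$lambda_dead)
}

vtarget_for_type <- function(type, params) {
  ifelse(type == "live", params$target_volume_sites, 0)
}

# integer type codes shared with the C++ core: 0 medium, 1 live, 2 dead
type_code <- function(type) {
  code <- match(type, c("live", "dead"))
  if (anyNA(code)) stop("unknown agent type: ", paste(type[is.na(code)]))
  code
}
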
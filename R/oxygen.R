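#' Oxygen transport parameters
#'
#' Constants of the oxygen reaction-diffusion equation: homogeneous
#' diffusivity `D` (um^2/s), per-cell uptake (fmol cell^-1 s^-1, a sink
#' spread evenly over the cell's current sites), the environmental
#' concentration at which every medium site is clamped (mM), the
#' physical-time-per-MCS coefficient `beta` (s/MCS), and the voxel volume
#' used to convert molar uptake into a concentration rate.  The model is
#' two-dimensional, so the conversion needs an out-of-plane depth; the
#' default is the nominal cell diameter (20 um), which treats each cell as
#' a slab of its nominal 314 um^2 footprint times one cell thickness --
#' i.e. per-cell molar uptake over the cell's physical volume.  The choice
#' only rescales gradient magnitudes, but it fixes the hypoxia-limited
#' aggregate size: a one-site depth would saturate growth an order of
#' magnitude below the sizes this model is meant to reach.  The depth is
#' kept as an auditable field.
#'
#' @param diffusivity_D diffusivity (um^2/s).
#' @param uptake_per_cell_s oxygen uptake per live cell (fmol/s).
#' @param env_concentration medium clamp concentration (mM).
#' @param beta_s_per_mcs seconds of physical time per MCS.
#' @param site_length_um lattice site length (um), used for `alpha^2`
#'   spacing and the default voxel volume.
#' @param depth_um out-of-plane depth (um) of the 2-D tissue slab.
#' @param site_volume_um3 voxel volume (um^3) for unit conversion.
#' @param mode `"quasi_steady"` (default; per-MCS steady-state solve) or
#'   `"explicit_substep"` (forward Euler in time).
#' @param steady_tol residual max-norm tolerance (mM/s) for the
#'   quasi-steady solve.
#' @param max_sweeps iteration cap for the quasi-steady solve.
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(diffusivity_D = 2500,
                          uptake_per_cell_s = 0.5,
                          env_concentration = 0.2,
                          beta_s_per_mcs = 0.1,
                          site_length_um = 2.96,
                          depth_um = 20,
                          site_volume_um3 = site_length_um^2 * depth_um,
                          mode = c("quasi_steady", "explicit_substep"),
                          steady_tol = 1e-9,
                          max_sweeps = 200000L) {
  if (diffusivity_D <= 0) stop("diffusivity_D must be > 0")
  if (env_concentration <= 0) stop("env_concentration must be > 0")
  if (beta_s_per_mcs <= 0) stop("beta_s_per_mcs must be > 0")
  structure(list(diffusivity_D = diffusivity_D,
                 uptake_per_cell_s = uptake_per_cell_s,
                 env_concentration = env_concentration,
                 beta_s_per_mcs = beta_s_per_mcs,
                 site_length_um = site_length_um,
                 site_volume_um3 = site_volume_um3,
                 mode = match.arg(mode),
                 steady_tol = steady_tol,
                 max_sweeps = as.integer(max_sweeps)),
            class = "oxygen_params")
}

#' Uniform initial oxygen field for a lattice state
#'
#' @param state a [lattice_state()] (fixes the raster shape).
#' @param params an [oxygen_params()].
#' @return Numeric matrix of concentrations (mM), uniform at the
#'   environmental concentration.
#' @export
oxygen_field <- function(state, params = oxygen_params()) {
  matrix(params$env_concentration, nrow(state$labels), ncol(state$labels))
}

#' Per-site oxygen source raster
#'
#' Maps respiration onto a concentration rate raster (mM/s): each live
#' cell's total uptake is divided evenly over its current sites and
#' converted through the voxel volume (1 fmol/um^3 = 1 mol/L, i.e. 1000
#' mM).  Dead cells and medium contribute zero -- metabolic activity ceases
#' on death.
#'
#' @param state a [lattice_state()].
#' @param params an [oxygen_params()].
#' @return Numeric matrix of signed rates (mM/s; sinks are negative).
#' @export
source_raster <- function(state, params = oxygen_params()) {
  lab <- state$labels
  out <- matrix(0, nrow(lab), ncol(lab))
  ag <- state$agents
  live <- ag[ag$type == "live", , drop = FALSE]
  if (nrow(live) == 0L) return(out)
  if (any(live$n_sites == 0L))
    stop("live cell with zero sites: ",
         paste(live$id[live$n_sites == 0L], collapse = ", "))
  # fmol/s per site -> fmol/um^3/s = mol/L/s = 1000 mM/s
  rate <- -params$uptake_per_cell_s / live$n_sites /
    params$site_volume_um3 * 1000
  per_id <- numeric(max(ag$id))
  per_id[live$id] <- rate
  occ <- lab != 0L
  out[occ] <- per_id[lab[occ]]
  out
}

# forward-Euler stability bound for the 2-D 5-point stencil
explicit_dt_bound <- function(params) {
  params$site_length_um^2 / (4 * params$diffusivity_D)
}

#' One explicit forward-Euler substep of the oxygen equation
#'
#' Second-order central differences in space, one forward-Euler step of
#' length `dt` in time, applied at cell-occupied sites; medium sites are
#' re-clamped to the environmental concentration and concentrations are
#' kept non-negative (uptake saturates at anoxia).  `dt` must respect the
#' stability bound `alpha^2 / (4 D)`.
#'
#' @param field concentration matrix (mM).
#' @param state a [lattice_state()] aligned with `field`.
#' @param sources rate raster (mM/s) from [source_raster()].
#' @param dt substep length (s).
#' @param params an [oxygen_params()].
#' @param n_steps number of substeps to take.
#' @return Updated concentration matrix.
#' @export
oxygen_step_explicit <- function(field, state, sources, dt,
                                 params = oxygen_params(), n_steps = 1L) {
  bound <- explicit_dt_bound(params)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability bound alpha^2/(4D) = %g",
                 dt, bound))
  cpp_explicit_substeps(field, state$labels, sources, params$diffusivity_D,
                        params$site_length_um, params$env_concentration,
                        dt, as.integer(n_steps))
}

#' Relax the oxygen field over one MCS
#'
#' In `"quasi_steady"` mode (the default) the field is relaxed to the
#' steady state of the reaction-diffusion equation by projected successive
#' over-relaxation, with every medium site clamped to the environmental
#' concentration, until the residual max-norm falls below the configured
#' tolerance.  This is justified by `beta` being chosen so that diffusion
#' is much faster than cell motility.  In `"explicit_substep"` mode the
#' field is instead advanced `ceiling(beta / dt)` forward-Euler substeps
#' covering `beta` seconds of physical time.
#'
#' @param field concentration matrix (mM).
#' @param state a [lattice_state()] aligned with `field`.
#' @param params an [oxygen_params()].
#' @param sources optional precomputed rate raster; defaults to
#'   [source_raster()] of `state`.
#' @param omega over-relaxation factor for the quasi-steady solve; the
#'   default 0 auto-selects the optimal factor for the occupied region's
#'   size.
#' @return Relaxed concentration matrix with attributes `"sweeps"` and
#'   `"residual"` in quasi-steady mode.
#' @export
relax_oxygen <- function(field, state, params = oxygen_params(),
                         sources = source_raster(state, params),
                         omega = 0) {
  stopifnot(all(dim(field) == dim(state$labels)))
  if (params$mode == "quasi_steady") {
    res <- cpp_relax_quasi_steady(field, state$labels, sources,
                                  params$diffusivity_D,
                                  params$site_length_um,
                                  params$env_concentration,
                                  params$steady_tol, params$max_sweeps,
                                  omega)
    if (res$residual >= params$steady_tol)
      stop(sprintf(paste0("quasi-steady oxygen solve did not converge: ",
                          "residual %.3e mM/s after %d sweeps (tol %.1e)"),
                   res$residual, res$sweeps, params$steady_tol))
    out <- res$conc
    attr(out, "sweeps") <- res$sweeps
    attr(out, "residual") <- res$residual
    out
  } else {
    dt <- 0.9 * explicit_dt_bound(params)
    n <- ceiling(params$beta_s_per_mcs / dt)
    oxygen_step_explicit(field, state, sources, dt, params, n_steps = n)
  }
}

#' Mean oxygen concentration over a cell's sites
#'
#' @param field concentration matrix (mM).
#' @param cell_sites two-column (row, col) matrix of the cell's sites, as
#'   from [agent_sites()].
#' @return Arithmetic mean concentration (mM).
#' @export
cell_mean_concentration <- function(field, cell_sites) {
  if (is.null(dim(cell_sites))) cell_sites <- matrix(cell_sites, ncol = 2)
  if (nrow(cell_sites) == 0L) stop("empty cell site set")
  mean(field[cell_sites])
}
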
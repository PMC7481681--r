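#' Simulation run configuration
#'
#' The standard protocol: five 36-site cells start at the centre of a
#' square containment domain of 600 um width (203 sites of 2.96 um), the
#' medium is clamped at 0.2 mM oxygen, and the run lasts at least 100 kMCS
#' -- long enough for a unified-Richards fit to capture the final aggregate
#' size (profiles that converge more slowly default to 150 kMCS, and the
#' strongest proliferation decrease to 250 kMCS).
#'
#' @param profile a preset name (see [preset_names()]) or a
#'   [phenotype_profile()].
#' @param lattice_side lattice side length in sites.
#' @param n_initial_cells number of initial 6x6 cells (1..5 placed as a
#'   centred plus-shaped cluster).
#' @param total_kmcs run length in kMCS; defaults per profile.
#' @param sample_interval_mcs sampling cadence (MCS).
#' @param seed RNG seed for the run.
#' @param cpm a [cpm_params()].
#' @param oxygen an [oxygen_params()].
#' @param output_dir optional directory for run artifacts.
#' @param write_snapshots write lattice/oxygen snapshots at each sample
#'   (ignored without `output_dir`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(profile = "Control",
                       lattice_side = 203L,
                       n_initial_cells = 5L,
                       total_kmcs = NULL,
                       sample_interval_mcs = 1000L,
                       seed = 1L,
                       cpm = cpm_params(),
                       oxygen = oxygen_params(site_length_um =
                                                cpm$site_length_um),
                       output_dir = NULL,
                       write_snapshots = FALSE) {
  if (is.character(profile)) {
    name <- profile
    profile <- phenotype_preset(profile)
  } else {
    stopifnot(inherits(profile, "phenotype_profile"))
    name <- if (is.null(profile$name)) "custom" else profile$name
  }
  if (is.null(total_kmcs)) total_kmcs <- default_total_kmcs(name)
  if (total_kmcs < 1) stop("total_kmcs must be >= 1")
  if (n_initial_cells < 1) stop("n_initial_cells must be >= 1")
  if (lattice_side < 20) stop("lattice too small to hold the initial cells")
  structure(list(profile = profile, profile_name = name,
                 lattice_side = as.integer(lattice_side),
                 n_initial_cells = as.integer(n_initial_cells),
                 total_kmcs = total_kmcs,
                 sample_interval_mcs = as.integer(sample_interval_mcs),
                 seed = as.integer(seed), cpm = cpm, oxygen = oxygen,
                 output_dir = output_dir,
                 write_snapshots = isTRUE(write_snapshots)),
            class = "run_config")
}

#' @rdname run_config
#' @param profile_name preset name.
#' @export
default_total_kmcs <- function(profile_name) {
  if (profile_name %in% "Decrease 2") return(250L)
  if (profile_name %in% c("Decrease 1", "Shift 1", "Shift 2",
                          "Shrink 1", "Shrink 2")) return(150L)
  100L
}

#' Initial lattice and oxygen field for a run
#'
#' Places up to five 6x6 live cells as a contiguous plus-shaped cluster at
#' the lattice centre (centre block first, then below, above, left, right)
#' and a uniform oxygen field at the environmental concentration.
#'
#' @param config a [run_config()].
#' @return List with `state` ([lattice_state()]) and `field` (matrix, mM).
#' @export
initialize_state <- function(config) {
  n <- config$lattice_side
  if (config$n_initial_cells > 5L)
    stop("the plus-shaped cluster supports at most 5 initial cells")
  offs <- list(c(0L, 0L), c(6L, 0L), c(-6L, 0L), c(0L, -6L), c(0L, 6L))
  base <- as.integer(floor((n - 6) / 2)) + 1L
  lab <- matrix(0L, n, n)
  for (i in seq_len(config$n_initial_cells)) {
    r0 <- base + offs[[i]][1]; c0 <- base + offs[[i]][2]
    if (r0 < 1L || c0 < 1L || r0 + 5L > n || c0 + 5L > n)
      stop("initial cells exceed the lattice domain")
    if (any(lab[r0:(r0 + 5L), c0:(c0 + 5L)] != 0L))
      stop("initial cells overlap")
    lab[r0:(r0 + 5L), c0:(c0 + 5L)] <- i
  }
  state <- lattice_state(lab, types = stats::setNames(
    rep("live", config$n_initial_cells),
    as.character(seq_len(config$n_initial_cells))))
  list(state = state, field = oxygen_field(state, config$oxygen))
}

#' Run a growth-dynamics experiment
#'
#' The per-MCS schedule is: one Monte Carlo step of copy attempts, oxygen
#' relaxation over the step, stochastic response sampling at each live
#' cell's mean concentration, then immediate application of deaths followed
#' by divisions.  Every sampling interval (1 kMCS by default) the aggregate
#' area, live-cell count, best-fit-ellipse eccentricity (from 1 kMCS
#' onwards) and the proliferation/death probability areas are recorded; at
#' the end the growth curve is fitted to the unified Richards model and all
#' classical submodels with the 15-cell adjusted-time origin.  All
#' randomness flows from `set.seed(config$seed)`, so a (config, seed) pair
#' reproduces outputs exactly.
#'
#' @param config a [run_config()].
#' @param progress print a progress line every 10 kMCS.
#' @return An object of class `growth_run`: list with the `growth_curve`,
#'   `series` (per-sample eccentricity and probability areas), `fits`
#'   (a [compare_growth_fits()] result, or `NULL` with `fit_error` when the
#'   curve cannot be fitted), the final `state` and `field`, the event log
#'   and the config.
#' @export
run_experiment <- function(config, progress = FALSE) {
  set.seed(config$seed)
  init <- initialize_state(config)
  state <- init$state; field <- init$field
  profile <- config$profile
  cpm <- config$cpm; oxp <- config$oxygen
  total_mcs <- config$total_kmcs * 1000L
  ival <- config$sample_interval_mcs
  alpha <- cpm$site_length_um
  samples <- list(); series <- list(); log <- list()
  record <- function(k) {
    am <- aggregate_mask(state, alpha)
    ecc <- if (k >= 1000L && sum(am$mask) >= 3L)
      tryCatch(fit_ellipse(am$mask, alpha)$eccentricity,
               error = function(e) NA_real_) else NA_real_
    list(sample = data.frame(mcs = k, area_mm2 = am$area_mm2,
                             cell_count = sum(state$agents$type == "live")),
         ser = data.frame(mcs = k, eccentricity = ecc,
                          pa_proliferation_um2 = probability_area(
                            field, am$mask, profile$proliferation, alpha),
                          pa_death_um2 = probability_area(
                            field, am$mask, profile$death, alpha)))
  }
  rec <- record(0L)
  samples[[1]] <- rec$sample; series[[1]] <- rec$ser
  if (!is.null(config$output_dir))
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(total_mcs)) {
    state <- monte_carlo_step(state, cpm)
    field <- relax_oxygen(field, state, oxp)
    ev <- sample_responses(state, field, profile)
    if (nrow(ev)) {
      for (id in ev$cell_id[ev$kind == "die"])
        state <- kill_cell(state, id)
      for (id in ev$cell_id[ev$kind == "proliferate"])
        state <- divide_cell(state, id, cpm)
      log[[length(log) + 1L]] <- ev
    }
    if (k %% ival == 0L) {
      rec <- record(k)
      samples[[length(samples) + 1L]] <- rec$sample
      series[[length(series) + 1L]] <- rec$ser
      if (!is.null(config$output_dir) && config$write_snapshots)
        write_snapshot(state, field, config$output_dir, k, config)
      if (progress && k %% (10L * ival) == 0L)
        message(sprintf("MCS %d: %d live cells, area %.4g mm^2", k,
                        rec$sample$cell_count, rec$sample$area_mm2))
    }
  }
  samples <- do.call(rbind, samples)
  curve <- growth_curve(samples$mcs, samples$area_mm2, samples$cell_count)
  fits <- tryCatch(compare_growth_fits(curve), error = function(e) e)
  fit_error <- NULL
  if (inherits(fits, "error")) { fit_error <- conditionMessage(fits); fits <- NULL }
  run <- structure(list(curve = curve, series = do.call(rbind, series),
                        fits = fits, fit_error = fit_error,
                        state = state, field = field,
                        events = if (length(log)) do.call(rbind, log)
                                 else NULL,
                        config = config),
                   class = "growth_run")
  if (!is.null(config$output_dir)) write_run_outputs(run)
  run
}

#' @export
print.growth_run <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("Growth run '%s' (seed %d): %d kMCS, final area %.4g mm^2, %d live cells\n",
              x$config$profile_name, x$config$seed, x$config$total_kmcs,
              last$area_mm2, last$cell_count))
  if (!is.null(x$fits)) print(x$fits) else
    cat("  (growth models not fitted: ", x$fit_error, ")\n", sep = "")
  invisible(x)
}

#' Synthetic unified-Richards growth curve
#'
#' Samples the unified-Richards curve on a 1 kMCS grid with optional
#' multiplicative Gaussian noise, attaching synthetic cell counts that
#' cross 15 exactly at `origin_kmcs` (so the fitting pipeline recovers the
#' generator's adjusted-time origin).  With `noise_sd = 0` the samples lie
#' exactly on the model curve and [fit_growth()] recovers the parameters.
#'
#' @param A,W0,S model parameters (areas in mm^2).
#' @param G growth rate per 100 kMCS of adjusted time, the reporting scale
#'   of [fit_growth()], which therefore recovers `G` directly.
#' @param noise_sd multiplicative noise SD.
#' @param seed optional seed.
#' @param total_kmcs curve length (kMCS).
#' @param origin_kmcs time at which the synthetic count reaches 15 cells.
#' @return A [growth_curve()].
#' @export
simulate_growth_curve <- function(A, W0, G, S, noise_sd = 0, seed = NULL,
                                  total_kmcs = 100, origin_kmcs = 10) {
  if (!is.null(seed)) set.seed(seed)
  kmcs <- seq(0, total_kmcs, by = 1)
  t_adj <- kmcs - origin_kmcs
  model <- urichards(t_adj, A, W0, G / 100, S)  # G per 100 kMCS -> per kMCS
  counts <- pmax(0L, as.integer(floor(15 * model / W0 + 1e-9)))
  area <- model
  if (noise_sd > 0)
    area <- pmax(0, model * (1 + stats::rnorm(length(model), 0, noise_sd)))
  growth_curve(kmcs * 1000, area, counts)
}
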
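#' Read and write growth curves as CSV
#'
#' Columns: `mcs`, `area_mm2`, `cell_count`.  An `origin_mcs` attribute, if
#' set, travels as a commented header line.
#'
#' @param curve a [growth_curve()].
#' @param path file path.
#' @return `read_growth_curve` returns a [growth_curve()];
#'   `write_growth_curve` returns `path` invisibly.
#' @export
write_growth_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  o <- attr(curve, "origin_mcs")
  if (!is.null(o)) writeLines(sprintf("# origin_mcs: %d", o), con)
  utils::write.csv(as.data.frame(curve)[c("mcs", "area_mm2", "cell_count")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  first <- readLines(path, n = 1L)
  origin <- NULL
  if (grepl("^# origin_mcs:", first))
    origin <- as.integer(sub("^# origin_mcs:\\s*", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  growth_curve(df$mcs, df$area_mm2, df$cell_count, origin_mcs = origin)
}

# one flat record per fit, mirroring the reported coefficient table
fit_report_row <- function(fit, profile = NA_character_, trial = NA_integer_) {
  co <- fit$coefficients; ci <- fit$ci_halfwidths
  data.frame(profile = profile, trial = trial, model = fit$model,
             A_mm2 = unname(co["A"]), ci_A = unname(ci["A"]),
             W0_mm2 = unname(co["W0"]),
             G_per100kmcs = unname(co["G"]), ci_G = unname(ci["G"]),
             S = unname(co["S"]), ci_S = unname(ci["S"]),
             r_squared = fit$r_squared, origin_mcs = fit$origin_mcs,
             stringsAsFactors = FALSE)
}

#' Write a fit report as JSON
#'
#' @param fits a `growth_fit` or `growth_fit_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  rows <- do.call(rbind, lapply(fits, fit_report_row))
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# lattice + oxygen snapshot: gzipped text rasters and a JSON agent table
write_snapshot <- function(state, field, dir, mcs, config = NULL) {
  stem <- file.path(dir, sprintf("snapshot_%06d", mcs))
  con <- gzfile(paste0(stem, "_labels.txt.gz"), "w")
  utils::write.table(state$labels, con, row.names = FALSE, col.names = FALSE)
  close(con)
  con <- gzfile(paste0(stem, "_oxygen_mM.txt.gz"), "w")
  utils::write.table(signif(field, 10), con, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  meta <- list(mcs = mcs, agents = state$agents,
               units = list(concentration = "mM", length = "um"),
               alpha_um = if (is.null(config)) NA else
                 config$cpm$site_length_um,
               beta_s_per_mcs = if (is.null(config)) NA else
                 config$oxygen$beta_s_per_mcs,
               seed = if (is.null(config)) NA else config$seed)
  jsonlite::write_json(meta, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(stem)
}

# run artifact writer: growth curve CSV, series CSV, fit report JSON
write_run_outputs <- function(run) {
  dir <- run$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_growth_curve(run$curve, file.path(dir, "growth_curve.csv"))
  utils::write.csv(run$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  if (!is.null(run$fits))
    write_fit_report(run$fits, file.path(dir, "fit_report.json"))
  ecc <- run$series$eccentricity[run$series$mcs >= 1000]
  summ <- suppressWarnings(eccentricity_summary(ecc))
  final <- run$series[nrow(run$series), ]
  jsonlite::write_json(
    list(eccentricity = summ,
         final_pa_proliferation_um2 = final$pa_proliferation_um2,
         final_pa_death_um2 = final$pa_death_um2),
    file.path(dir, "analysis_summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  manifest <- list(profile = run$config$profile_name,
                   seed = run$config$seed,
                   lattice_side = run$config$lattice_side,
                   total_kmcs = run$config$total_kmcs,
                   alpha_um = run$config$cpm$site_length_um,
                   beta_s_per_mcs = run$config$oxygen$beta_s_per_mcs,
                   oxygen_mode = run$config$oxygen$mode,
                   complete = TRUE,
                   fit_error = run$fit_error,
                   package_version =
                     as.character(utils::packageVersion("emergrow")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
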
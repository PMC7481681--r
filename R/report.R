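#' Reference full-scale fit coefficients
#'
#' Unified-Richards coefficients and classical-model coefficients of
#' determination reported for full-scale reference runs of this model
#' (203x203 lattice, 100-250 kMCS) for every phenotype preset: three
#' trials each of Control and Decrease 1, one trial per remaining preset.
#' Areas are stored in mm^2 (the printed scaling of the summary text is
#' 10^-3 mm^2; [aggregate_fit_table()] reports both).  Shipped as
#' `inst/extdata/reference_fits.csv`.
#'
#' @return data.frame with one row per trial: `profile`, `trial`, `A_mm2`,
#'   `ci_A`, `W0_mm2`, `G_per100kmcs`, `ci_G`, `S`, `ci_S`, `origin_mcs`
#'   and the four model `r2_*` columns.
#' @export
reference_fits <- function() {
  path <- system.file("extdata", "reference_fits.csv", package = "emergrow")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate per-trial fit reports by profile
#'
#' Trial-level fit coefficients are summarised per profile by their mean
#' and standard deviation, the aggregation used to report a parameter set's
#' emergent growth metrics across repeated trials.  Means of `A` and `W0`
#' are reported both in mm^2 and in the 10^-3 mm^2 printed scaling.
#'
#' @param fits data.frame of per-trial rows with columns `profile`,
#'   `A_mm2`, `W0_mm2`, `G_per100kmcs`, `S` (e.g. [reference_fits()] or
#'   rows assembled from [fit_growth()] results with the internal report
#'   writer).
#' @return data.frame with one row per profile: `n_trials`, mean and sd of
#'   each coefficient, plus `A_e3mm2` and `W0_e3mm2` (means scaled by
#'   10^3).
#' @examples
#' tab <- aggregate_fit_table(reference_fits())
#' tab[tab$profile == "Control", c("A_e3mm2", "G_mean", "S_mean")]
#' @export
aggregate_fit_table <- function(fits) {
  stopifnot(all(c("profile", "A_mm2", "W0_mm2", "G_per100kmcs", "S") %in%
                  names(fits)))
  out <- lapply(split(fits, fits$profile), function(d) {
    data.frame(profile = d$profile[1], n_trials = nrow(d),
               A_mean = mean(d$A_mm2), A_sd = stats::sd(d$A_mm2),
               W0_mean = mean(d$W0_mm2), W0_sd = stats::sd(d$W0_mm2),
               G_mean = mean(d$G_per100kmcs), G_sd = stats::sd(d$G_per100kmcs),
               S_mean = mean(d$S), S_sd = stats::sd(d$S),
               A_e3mm2 = mean(d$A_mm2) * 1000,
               W0_e3mm2 = mean(d$W0_mm2) * 1000,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$profile), , drop = FALSE]
}
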
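#' Growth curve container
#'
#' Sampled aggregate growth: one row per sampling interval (1 kMCS in the
#' simulation protocol) with the MCS clock, total aggregate area in mm^2,
#' and the live-cell count.  The adjusted-time origin -- the first sample
#' with at least a threshold number of cells, used to damp small-population
#' stochasticity in fits -- is carried as metadata once set by
#' [set_growth_origin()].
#'
#' @param mcs integer sample times (strictly increasing, constant spacing).
#' @param area_mm2 aggregate areas (>= 0).
#' @param cell_count live-cell counts.
#' @param origin_mcs optional adjusted-time origin.
#' @return An object of class `growth_curve`: a data.frame with columns
#'   `mcs`, `area_mm2`, `cell_count` and attribute `origin_mcs`.
#' @export
growth_curve <- function(mcs, area_mm2, cell_count, origin_mcs = NULL) {
  if (is.unsorted(mcs, strictly = TRUE))
    stop("mcs must be strictly increasing")
  if (length(mcs) > 2 && length(unique(diff(mcs))) != 1L)
    stop("sampling interval must be constant")
  if (any(area_mm2 < 0)) stop("areas must be >= 0")
  df <- data.frame(mcs = as.integer(mcs), area_mm2 = area_mm2,
                   cell_count = as.integer(cell_count))
  structure(df, origin_mcs = origin_mcs,
            class = c("growth_curve", "data.frame"))
}

#' Set the adjusted-time origin of a growth curve
#'
#' The origin is the first sample whose cell count reaches `threshold`
#' (15 cells in the analysis protocol); earlier samples acquire negative
#' adjusted times and are excluded from fitting.
#'
#' @param curve a [growth_curve()].
#' @param threshold cell-count threshold.
#' @return The curve with attribute `origin_mcs` set.
#' @export
set_growth_origin <- function(curve, threshold = 15L) {
  hit <- which(curve$cell_count >= threshold)
  if (length(hit) == 0L)
    stop("cell count never reached ", threshold,
         " (maximum observed: ", max(curve$cell_count), ")")
  attr(curve, "origin_mcs") <- curve$mcs[hit[1]]
  curve
}

#' @rdname growth_curve
#' @param x,... print method arguments.
#' @export
print.growth_curve <- function(x, ...) {
  o <- attr(x, "origin_mcs")
  cat(sprintf("Growth curve: %d samples, MCS %d..%d, origin %s\n",
              nrow(x), min(x$mcs), max(x$mcs),
              if (is.null(o)) "unset" else paste0(o, " MCS")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

# residual function on normalised time; G on the reported per-100-kMCS scale
.ur_resid <- function(par, tau, y, T_kmcs, S_fixed) {
  S <- if (is.na(S_fixed)) par[["S"]] else S_fixed
  urichards(tau, par[["A"]], par[["W0"]], par[["G"]] * T_kmcs / 100, S) - y
}

#' Fit a growth model to an aggregate growth curve
#'
#' Nonlinear least squares of the unified Richards model (or a classical
#' submodel with fixed shape) to the samples at adjusted time >= 0, with
#' time normalised to `[0, 1]` and the fitted growth rate reported in units
#' of (100 kMCS)^-1.  Bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) with up to three starts; asymptotic 95%
#' confidence half-widths from the Jacobian at the optimum (t-quantile,
#' `n - p` degrees of freedom) and the coefficient of determination
#' `R^2 = 1 - SSR/SST`.
#'
#' @param curve a [growth_curve()]; the origin is set with `threshold` if
#'   unset.
#' @param model one of `"urichards"`, `"bertalanffy"` (S = 2/3),
#'   `"gompertz"` (S -> 1), `"logistic"` (S = 2).
#' @param threshold cell-count threshold for [set_growth_origin()].
#' @return An object of class `growth_fit` with coefficients `A`, `W0`
#'   (mm^2), `G` ((100 kMCS)^-1) and `S`, 95% CI half-widths, `r_squared`,
#'   the adjusted-time origin and fit window.
#' @examples
#' crv <- simulate_growth_curve(A = 0.12, W0 = 0.005, G = 2.7, S = 1.4,
#'                              noise_sd = 0, seed = 1)
#' fit <- fit_growth(crv)
#' coef(fit)
#' @export
fit_growth <- function(curve, model = c("urichards", "bertalanffy",
                                        "gompertz", "logistic"),
                       threshold = 15L) {
  model <- match.arg(model)
  if (is.null(attr(curve, "origin_mcs")))
    curve <- set_growth_origin(curve, threshold)
  origin <- attr(curve, "origin_mcs")
  t_adj <- (curve$mcs - origin) / 1000           # kMCS
  keep <- t_adj >= 0
  if (sum(keep) < 8L)
    stop("need at least 8 samples at adjusted time >= 0; have ", sum(keep))
  t_adj <- t_adj[keep]; y <- curve$area_mm2[keep]
  T_kmcs <- max(t_adj)
  tau <- t_adj / T_kmcs
  S_fixed <- .model_shapes[[model]]
  maxa <- max(y)
  free <- if (is.na(S_fixed)) c("A", "W0", "G", "S") else c("A", "W0", "G")
  lower <- c(A = 1e-10, W0 = 1e-10, G = 1e-9, S = 0.1)[free]
  upper <- c(A = 10 * maxa, W0 = maxa, G = 100, S = 3)[free]
  starts <- list(c(A = 1.05 * maxa, W0 = max(y[1], 1e-8), G = 2, S = 1.5),
                 c(A = 1.2 * maxa, W0 = max(y[1], 1e-8), G = 0.5, S = 0.8),
                 c(A = 1.01 * maxa, W0 = max(maxa / 50, 1e-8), G = 5,
                   S = 2.2))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  best <- NULL
  for (st in starts) {
    par0 <- pmin(pmax(st[free], lower), upper)
    fit <- try(minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                                  fn = .ur_resid, tau = tau, y = y,
                                  T_kmcs = T_kmcs, S_fixed = S_fixed,
                                  control = ctrl), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:4 && fit$deviance <= best$deviance) break
  }
  if (is.null(best))
    stop("growth-model fit failed to converge for model '", model, "'")
  par <- best$par
  coefs <- c(A = unname(par[["A"]]), W0 = unname(par[["W0"]]),
             G = unname(par[["G"]]),
             S = if (is.na(S_fixed)) unname(par[["S"]]) else S_fixed)
  fitted <- urichards(tau, coefs["A"], coefs["W0"],
                      coefs["G"] * T_kmcs / 100, coefs["S"])
  resid <- y - fitted
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - ssr / sst
  n <- length(y); p <- length(free)
  ci <- stats::setNames(rep(NA_real_, 4), c("A", "W0", "G", "S"))
  J <- .num_jacobian(function(q) .ur_resid(q, tau, y, T_kmcs, S_fixed),
                     par)
  vc <- try(ssr / (n - p) * solve(crossprod(J)), silent = TRUE)
  if (!inherits(vc, "try-error") && all(diag(vc) >= 0)) {
    half <- stats::qt(0.975, n - p) * sqrt(diag(vc))
    ci[names(par)] <- half
  }
  if (!is.na(S_fixed)) ci["S"] <- 0
  structure(list(model = model, coefficients = coefs, ci_halfwidths = ci,
                 r_squared = r2, origin_mcs = origin,
                 duration_kmcs = T_kmcs, n = n,
                 data = data.frame(t_adj_kmcs = t_adj, area_mm2 = y),
                 fitted = fitted, residuals = resid,
                 deviance = ssr, info = best$info),
            class = "growth_fit")
}

# forward-difference Jacobian of a residual function
.num_jacobian <- function(fn, par, eps = 1e-7) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par),
              dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-4)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - f0) / h
  }
  J
}

#' Fit the unified Richards model and all classical submodels
#'
#' Fits `urichards`, `bertalanffy`, `gompertz` and `logistic` to one curve;
#' since the classical models are nested in the unified Richards form, its
#' `R^2` is at least each classical `R^2` up to optimiser tolerance.
#'
#' @inheritParams fit_growth
#' @return Named list of [fit_growth()] results, class `growth_fit_set`.
#' @export
compare_growth_fits <- function(curve, threshold = 15L) {
  if (is.null(attr(curve, "origin_mcs")))
    curve <- set_growth_origin(curve, threshold)
  fits <- lapply(growth_model_tags(), function(m)
    fit_growth(curve, model = m, threshold = threshold))
  names(fits) <- growth_model_tags()
  structure(fits, class = "growth_fit_set")
}

#' @export
print.growth_fit_set <- function(x, ...) {
  cat("Growth-model comparison (R^2):\n")
  for (m in names(x))
    cat(sprintf("  %-12s R^2 = %.4f  S = %.3f\n", m, x[[m]]$r_squared,
                x[[m]]$coefficients["S"]))
  invisible(x)
}

#' @export
print.growth_fit <- function(x, ...) {
  co <- x$coefficients; ci <- x$ci_halfwidths
  cat(sprintf("%s growth fit (n = %d, origin %d MCS, window %.0f kMCS)\n",
              x$model, x$n, x$origin_mcs, x$duration_kmcs))
  cat(sprintf("  A  = %.4g mm^2 (%.4g x 10^-3 mm^2) +/- %.3g\n",
              co["A"], co["A"] * 1000, ci["A"]))
  cat(sprintf("  W0 = %.4g mm^2 (%.4g x 10^-3 mm^2)\n", co["W0"],
              co["W0"] * 1000))
  cat(sprintf("  G  = %.4g / 100 kMCS +/- %.3g\n", co["G"], ci["G"]))
  if (x$model == "urichards")
    cat(sprintf("  S  = %.4g +/- %.3g\n", co["S"], ci["S"]))
  else
    cat(sprintf("  S  = %.4g (fixed, %s)\n", co["S"], x$model))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients,
                    ci95_halfwidth = object$ci_halfwidths)
  attr(out, "r_squared") <- object$r_squared
  attr(out, "model") <- object$model
  class(out) <- c("summary.growth_fit", "data.frame")
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat(sprintf("Model: %s   R^2 = %.4f\n", attr(x, "model"),
              attr(x, "r_squared")))
  print.data.frame(x)
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' Predicted aggregate area from a growth fit
#'
#' @param object a [fit_growth()] result.
#' @param mcs MCS times at which to predict (absolute, same clock as the
#'   fitted curve); defaults to the fitted sample times.
#' @param ... unused.
#' @return Predicted areas (mm^2).
#' @export
predict.growth_fit <- function(object, mcs = NULL, ...) {
  co <- object$coefficients
  t_adj <- if (is.null(mcs)) object$data$t_adj_kmcs
           else (mcs - object$origin_mcs) / 1000
  tau <- t_adj / object$duration_kmcs
  urichards(tau, co["A"], co["W0"], co["G"] * object$duration_kmcs / 100,
            co["S"])
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$data$t_adj_kmcs, x$data$area_mm2,
                 xlab = "adjusted time (kMCS)", ylab = "aggregate area (mm^2)",
                 main = sprintf("%s fit (R^2 = %.4f)", x$model, x$r_squared),
                 ...)
  tt <- seq(0, max(x$data$t_adj_kmcs), length.out = 200)
  graphics::lines(tt, predict(x, mcs = x$origin_mcs + tt * 1000), col = 2)
  invisible(x)
}

#' Simulate noisy growth curves from a fitted model
#'
#' @param object a [fit_growth()] result.
#' @param nsim number of curves.
#' @param seed optional seed.
#' @param noise_sd multiplicative Gaussian noise standard deviation.
#' @param ... unused.
#' @return List of [growth_curve()] objects.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL,
                                noise_sd = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  co <- object$coefficients
  lapply(seq_len(nsim), function(i)
    simulate_growth_curve(co["A"], co["W0"], co["G"], co["S"],
                          noise_sd = noise_sd,
                          total_kmcs = object$duration_kmcs +
                            object$origin_mcs / 1000,
                          origin_kmcs = object$origin_mcs / 1000))
}
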
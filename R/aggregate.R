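#' Aggregate mask and area
#'
#' The aggregate is every non-medium site (live and dead cells alike,
#' without connected-component filtering by default -- the protocol grows a
#' single aggregate); its area is the site count times the physical site
#' area, reported in mm^2.
#'
#' @param state a [lattice_state()].
#' @param site_length_um lattice site length (um).
#' @param largest_component if `TRUE`, restrict the mask to its largest
#'   4-connected component (robustness option).
#' @return List with `mask` (logical matrix) and `area_mm2`.
#' @examples
#' lab <- matrix(0L, 10, 10); lab[3:8, 3:8] <- 1L
#' aggregate_mask(lattice_state(lab))$area_mm2  # 36 * 2.96^2 um^2 in mm^2
#' @export
aggregate_mask <- function(state, site_length_um = 2.96,
                           largest_component = FALSE) {
  mask <- state$labels != 0L
  if (largest_component && any(mask)) {
    comp <- .label_components(mask)
    keep <- which.max(tabulate(comp[comp > 0L]))
    mask <- comp == keep
  }
  list(mask = mask, area_mm2 = sum(mask) * site_length_um^2 * 1e-6)
}

# 4-connected component labelling by flood fill
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (comp[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && comp[j] == 0L) { comp[j] <- nxt; queue <- c(queue, j) }
      }
    }
  }
  comp
}

#' Best-fit-ellipse eccentricity of an aggregate mask
#'
#' Second central moments of the mask's site coordinates define the
#' best-fit ellipse: the covariance eigenvalues give the squared semi-axes
#' (up to a common factor) and the eccentricity is
#' `sqrt(1 - (minor/major)^2)`, which is invariant to rotation and scale.
#'
#' @param mask logical matrix (or a [lattice_state()], from which the
#'   non-medium mask is taken).
#' @param site_length_um site length (um), for the reported axes.
#' @return List with `centroid_um`, `major_semiaxis_um`,
#'   `minor_semiaxis_um` and `eccentricity`; errors on degenerate masks
#'   (fewer than 3 sites or all collinear).
#' @export
fit_ellipse <- function(mask, site_length_um = 2.96) {
  if (inherits(mask, "lattice_state")) mask <- mask$labels != 0L
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3L) stop("degenerate mask: fewer than 3 sites")
  ctr <- colMeans(pts)
  cov <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12) stop("degenerate mask: sites are collinear")
  # ellipse with matching second moments has semi-axis 2*sqrt(eigenvalue)
  major <- 2 * sqrt(ev[1]) * site_length_um
  minor <- 2 * sqrt(ev[2]) * site_length_um
  list(centroid_um = ctr * site_length_um,
       major_semiaxis_um = major,
       minor_semiaxis_um = minor,
       eccentricity = sqrt(1 - (minor / major)^2))
}

#' Summary statistics of an eccentricity time series
#'
#' Normalised histogram of all eccentricity samples (bin width 0.1 over
#' `[0, 1]`, right-open except the last bin) plus the mean and standard
#' deviation over the final 25 samples (the last 25 kMCS at the 1 kMCS
#' sampling cadence), the window used to detect consistently eccentric
#' final shapes.
#'
#' @param eccentricity numeric vector of eccentricity samples in `[0, 1)`,
#'   ordered in time.
#' @return List with `histogram` (named bin weights summing to 1),
#'   `window_mean`, `window_sd` (sample SD over the last 25 samples; `NA`
#'   with a warning when fewer than 25 samples are available) and `n`.
#' @export
eccentricity_summary <- function(eccentricity) {
  e <- eccentricity[!is.na(eccentricity)]
  edges <- seq(0, 1, by = 0.1)
  bins <- cut(e, breaks = edges, right = FALSE, include.lowest = FALSE)
  # right-open bins [a, a+0.1); fold anything == 1 into the last bin
  bins[e >= 1 - 1e-12] <- levels(bins)[10]
  h <- table(bins) / length(e)
  if (length(e) >= 25L) {
    w <- utils::tail(e, 25L)
    wm <- mean(w); ws <- stats::sd(w)
  } else {
    warning("fewer than 25 samples: window statistics unset")
    wm <- NA_real_; ws <- NA_real_
  }
  list(histogram = stats::setNames(as.numeric(h), levels(bins)),
       window_mean = wm, window_sd = ws, n = length(e))
}

#' Probability area of a phenotypic response
#'
#' Integrates a response's per-site probability over the aggregate domain:
#' `sum over mask sites of q * exp(-((c_site - target)/gamma)^2) * alpha^2`
#' (in um^2), using the oxygen concentration at each site (not the per-cell
#' mean).  At the final aggregate size the probability areas of
#' proliferation and death are expected to balance: total proliferation
#' equals total death.
#'
#' @param field oxygen concentration matrix (mM).
#' @param mask logical aggregate mask aligned with `field`.
#' @param response a [response_spec()].
#' @param site_length_um site length (um).
#' @return Probability-weighted area (um^2).
#' @export
probability_area <- function(field, mask, response, site_length_um = 2.96) {
  stopifnot(all(dim(field) == dim(mask)))
  if (!any(mask)) return(0)
  c_uM <- field[mask] * 1000
  sum(response_probability(c_uM, response)) * site_length_um^2
}
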
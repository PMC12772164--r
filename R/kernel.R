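#' Effort-kernel utilization mask
#'
#' Kernel-density level-set mask containing a stated fraction of weighted
#' fishing activity. A weighted bivariate Gaussian KDE with a full
#' (anisotropic) normal-reference bandwidth matrix H = n_eff^(-1/3) * S
#' (Wand-Jones normal-scale rule for d = 2, with S the weighted covariance
#' of ping positions and n_eff the Kish effective sample size) is evaluated
#' at the grid cell centres; densities are normalized to sum to one, cells
#' are ranked by density, and the mask keeps the top cells whose cumulative
#' probability of use does not exceed \code{percentile}.
#'
#' @param pings data.frame with \code{lon}, \code{lat} and
#'   \code{time_forward} (used as weights).
#' @param grid list with numeric \code{lat} and \code{lon} cell-centre
#'   vectors (e.g. from a \code{daily_field}), or a \code{daily_field}.
#' @param percentile cumulative probability of use retained, default 0.75.
#' @param weights optional weight vector overriding \code{time_forward}.
#' @return object of class \code{effort_kernel}: list with \code{lat},
#'   \code{lon}, \code{in_kernel} (lat x lon logical matrix),
#'   \code{density} (lat x lon, sums to 1), \code{percentile},
#'   \code{bandwidth}.
#' @export
effort_kernel_mask <- function(pings, grid, percentile = 0.75, weights = NULL) {
  if (inherits(grid, "daily_field")) grid <- list(lat = grid$lat, lon = grid$lon)
  if (is.null(weights)) weights <- pings$time_forward
  ok <- !is.na(pings$lon) & !is.na(pings$lat) & !is.na(weights) & weights > 0
  x <- cbind(pings$lon[ok], pings$lat[ok]); w <- weights[ok]
  if (nrow(x) < 30L) stop("effort_kernel_mask: need >= 30 weighted pings")
  if (percentile <= 0 || percentile > 1)
    stop("effort_kernel_mask: percentile must be in (0, 1]")
  w <- w / sum(w)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc * w, xc) / (1 - sum(w^2))  # weighted covariance
  n_eff <- 1 / sum(w^2)
  H <- n_eff^(-1 / 3) * S
  # bandwidth floor for degenerate point clouds
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("effort_kernel_mask: degenerate point cloud; bandwidth floor applied")
    H <- H + diag(1e-4, 2)
  }
  Hi <- solve(H)
  norm_const <- 1 / (2 * pi * sqrt(det(H)))
  cells <- expand.grid(lon = grid$lon, lat = grid$lat)  # lat outer loop
  dens <- numeric(nrow(cells))
  for (j in seq_len(nrow(cells))) {
    d1 <- x[, 1] - cells$lon[j]; d2 <- x[, 2] - cells$lat[j]
    q <- Hi[1, 1] * d1 * d1 + 2 * Hi[1, 2] * d1 * d2 + Hi[2, 2] * d2 * d2
    dens[j] <- sum(w * exp(-0.5 * q))
  }
  dens <- dens * norm_const
  dens <- dens / sum(dens)
  # rank cells by density, keep cumulative probability <= percentile
  o <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[o])
  keep_ranked <- cum <= percentile + 1e-12
  if (!any(keep_ranked)) keep_ranked[1] <- TRUE
  in_kernel <- logical(length(dens))
  in_kernel[o[keep_ranked]] <- TRUE
  if (percentile >= 1) in_kernel <- dens > 0
  # reshape to (lat x lon): cells vary lon fastest within each lat block
  dm <- matrix(dens, nrow = length(grid$lon), ncol = length(grid$lat))
  km <- matrix(in_kernel, nrow = length(grid$lon), ncol = length(grid$lat))
  structure(list(lat = grid$lat, lon = grid$lon,
                 in_kernel = t(km), density = t(dm),
                 percentile = percentile, bandwidth = H),
            class = "effort_kernel")
}

#' @export
print.effort_kernel <- function(x, ...) {
  cat(sprintf("<effort_kernel> %.0f%% utilization mask: %d of %d cells\n",
              100 * x$percentile, sum(x$in_kernel), length(x$in_kernel)))
  invisible(x)
}

#' Fraction of weighted pings inside a kernel mask
#'
#' Utility to check the mass property of an \code{\link{effort_kernel_mask}}:
#' the weight share of pings whose nearest grid cell is in the mask.
#'
#' @param mask an \code{effort_kernel}.
#' @param pings ping data.frame with \code{lon}, \code{lat},
#'   \code{time_forward}.
#' @param weights optional weights overriding \code{time_forward}.
#' @return scalar in [0, 1].
#' @export
kernel_mass <- function(mask, pings, weights = NULL) {
  if (is.null(weights)) weights <- pings$time_forward
  i <- findInterval(pings$lat, c(-Inf, mask$lat[-1] - diff(mask$lat) / 2, Inf))
  j <- findInterval(pings$lon, c(-Inf, mask$lon[-1] - diff(mask$lon) / 2, Inf))
  inside <- mask$in_kernel[cbind(i, j)]
  sum(weights[inside]) / sum(weights)
}
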